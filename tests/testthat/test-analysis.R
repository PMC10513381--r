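test_that("radius of gyration: point masses and closed forms", {
  expect_equal(radius_of_gyration(matrix(c(1, 2, 3), 1), 5), 0)
  expect_equal(radius_of_gyration(rbind(c(0, 0, 0), c(0, 0, 2)), c(1, 1)), 1)
  # mass weighting: heavy bead pulls the COM, Rg from the definition
  xyz <- rbind(c(0, 0, 0), c(0, 0, 1))
  m <- c(3, 1)
  com <- 0.25
  expect_equal(radius_of_gyration(xyz, m),
               sqrt((3 * com^2 + 1 * (1 - com)^2) / 4))
  expect_error(radius_of_gyration(matrix(numeric(0), 0, 3)), "empty")
})

test_that("largest-cluster detection matches brute-force union-find", {
  one <- chain_topology("G", "hps")
  box <- cg_box(20)
  # hand-placed chain of five + one outlier: the chain is the cluster
  sys6 <- make_cg_system(one, 6)
  pos <- rbind(c(1, 1, 1), c(1, 1, 4), c(1, 1, 7), c(1, 1, 10), c(1, 4, 10),
               c(12, 12, 12))
  expect_identical(identify_largest_cluster(pos, sys6, box, cutoff = 5),
                   1:5)
  # one molecule; and all-separated molecules
  expect_identical(identify_largest_cluster(matrix(c(1, 1, 1), 1),
                                            make_cg_system(one, 1), box), 1L)
  spread <- matrix(c(1, 1, 1, 8, 8, 8, 15, 15, 15), 3, byrow = TRUE)
  expect_identical(identify_largest_cluster(spread, make_cg_system(one, 3),
                                            box, cutoff = 5), 1L)
  # randomized systems up to 50 molecules, including periodic wrap-around
  for (seed in 1:12) {
    n <- 10 + (seed * 7) %% 41
    sys <- make_cg_system(one, n)
    pos <- with(list(), {
      set.seed(seed)
      matrix(runif(3 * n, 0, 20), n, 3)
    })
    expect_identical(identify_largest_cluster(pos, sys, box, cutoff = 4),
                     brute_largest_cluster(pos, box, 4),
                     info = paste("seed", seed))
  }
})

test_that("step-profile densities are recovered exactly and mass conserved", {
  fx <- generate_fixture("slab_step_profile", rho_dense = 300,
                         rho_dilute = 20, dense_halfwidth = 10)
  prof <- density_profile(list(fx$state$positions), fx$system, fx$state$box,
                          center_on_cluster = FALSE, frames = 1)
  pt <- coexistence_densities(prof, dense_halfwidth = 10, dilute_min_z = 15)
  expect_equal(pt$rho_dense, fx$info$rho_dense, tolerance = 1e-12)
  expect_equal(pt$rho_dilute, fx$info$rho_dilute, tolerance = 1e-12)
  expect_gte(pt$rho_dense, pt$rho_dilute)
  # sum(density * bin volume) equals the total system mass
  binmass <- sum(prof$density * prof$bin_width *
                 prod(prof$box$lengths[1:2])) /
             slabsim_constants()$amu_nm3_to_mg_mL
  expect_equal(binmass, sum(fx$system$beads$mass), tolerance = 1e-9)
})

test_that("a uniform gas gives a flat profile at the global density", {
  one <- chain_topology("G", "hps")
  n <- 4000
  sys <- make_cg_system(one, n)
  box <- cg_box(c(10, 10, 60))
  set.seed(42)
  pos <- cbind(runif(n, 0, 10), runif(n, 0, 10), runif(n, 0, 60))
  prof <- density_profile(list(pos), sys, box, center_on_cluster = FALSE,
                          frames = 1)
  rho_global <- n * one$beads$mass[1] / prod(box$lengths) *
    slabsim_constants()$amu_nm3_to_mg_mL
  expect_equal(mean(prof$density), rho_global, tolerance = 1e-9)
  # flat within Poisson noise: ~n/60 beads per bin, 5 sigma band
  per_bin <- n / 60
  expect_lt(max(abs(prof$density / rho_global - 1)),
            5 / sqrt(per_bin))
  pt <- coexistence_densities(prof, 5, 20)
  expect_equal(pt$rho_dense, pt$rho_dilute, tolerance = 5 / sqrt(per_bin * 10))
})

test_that("cluster centering is idempotent", {
  fx <- generate_fixture("slab_step_profile", rho_dilute = 0)
  p1 <- density_profile(list(fx$state$positions), fx$system, fx$state$box,
                        center_on_cluster = TRUE, frames = 1)
  # center once by hand, then the centered profile of the shifted frame
  pos <- fx$state$positions
  cl <- identify_largest_cluster(pos, fx$system, fx$state$box, 5)
  com <- colMeans(pos[cl, , drop = FALSE])
  pos2 <- pos; pos2[, 3] <- pos2[, 3] - com[3]
  p2 <- density_profile(list(pos2), fx$system, fx$state$box,
                        center_on_cluster = TRUE, frames = 1)
  expect_equal(p1$density, p2$density, tolerance = 1e-9)
})

test_that("coexistence windows validate their geometry", {
  fx <- generate_fixture("slab_step_profile")
  prof <- density_profile(list(fx$state$positions), fx$system, fx$state$box,
                          center_on_cluster = FALSE, frames = 1)
  expect_error(coexistence_densities(prof, 30, 20), "dense_halfwidth <")
  expect_error(coexistence_densities(prof, 10, 45), "half the box")
})

test_that("critical-point fit recovers noiseless and noisy truth", {
  beta <- 0.325
  A_true <- 25; Tc_true <- 320
  Tg <- seq(230, 310, by = 10)
  drho <- A_true * (Tc_true - Tg)^beta
  pts <- data.frame(temperature = Tg, rho_dilute = 30,
                    rho_dense = 30 + drho)
  fit <- fit_critical_point(pts)
  expect_equal(fit$Tc, Tc_true, tolerance = 1e-8)
  expect_equal(fit$A, A_true, tolerance = 1e-8)
  expect_equal(unname(coef(fit)["beta"]), beta)
  expect_equal(predict(fit, 280), A_true * 40^beta, tolerance = 1e-6)
  # degenerate input
  expect_error(fit_critical_point(pts[c(1, 1), ]), "degenerate")
  expect_error(fit_critical_point(pts[1, , drop = FALSE]), "at least 2")
})

test_that("persistence length: rigid rod and freely rotating chain", {
  # rigid straight chain: C(n) = 1, infinite lp
  rod <- list(cbind(0, 0, seq(0, 10, by = 0.5)))
  pf <- persistence_length(rod, seq_len(21), fit_range = 2:8)
  expect_true(all(abs(pf$correlation - 1) < 1e-12))
  expect_identical(pf$lp, Inf)
  expect_equal(pf$correlation[1], 1)     # C(0) = 1 by construction
  # freely rotating chain against the closed form lp = -b / ln cos theta
  theta <- 0.45; b <- 0.4
  chains <- freely_rotating_chain(50, theta, b, n_chains = 400, seed = 8)
  fit <- persistence_length(chains, 1:51, fit_range = 2:12)
  expect_equal(fit$mean_bond_length, b, tolerance = 1e-9)
  expect_equal(fit$lp, -b / log(cos(theta)), tolerance = 0.05)
})

test_that("short chains and non-positive correlations are handled", {
  expect_error(persistence_length(list(matrix(0, 2, 3)), 1:2), "at least 3")
  # strongly kinked chain: C(n) hits <= 0 inside the requested range
  zig <- cbind(c(0, 1, 0, 1, 0, 1, 0), c(0, 0.1, 0, 0.1, 0, 0.1, 0), 0)
  expect_warning(persistence_length(list(zig), 1:7, fit_range = 2:5),
                 "shrinking")
})
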