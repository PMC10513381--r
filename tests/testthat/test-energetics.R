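test_that("pair potentials vanish beyond and are continuous at the cutoff", {
  el <- electrostatics_spec()
  cases <- list(
    list(form = "ashbaugh_hatch",
         p = list(epsilon = 0.8368, sigma = 0.6, lambda = 0.7)),
    list(form = "wang_frenkel",
         p = list(epsilon = 1.2, sigma = 0.55, nu = 1, mu = 2)),
    list(form = "moff_contact",
         p = list(epsilon = -1.1, sigma = 0.6, eta = 7, r0 = 0.8,
                  eps_rep = 0.8368)),
    list(form = "excluded_volume", p = list(eps_rep = 0.8368, sigma = 0.7)),
    list(form = "debye_huckel",
         p = list(q1 = 1, q2 = -1, dielectric = 80, ld = el$debye_length)))
  for (cs in cases) {
    u <- evaluate_pair_potential(cs$form, cs$p, c(2.0, 2.5, 10), cutoff = 2.0)
    expect_identical(u, c(0, 0, 0))
    just_in <- evaluate_pair_potential(cs$form, cs$p, 2.0 - 1e-9, cutoff = 2.0)
    expect_lt(abs(just_in), 1e-6)      # continuity via the energy shift
  }
  expect_error(evaluate_pair_potential("ashbaugh_hatch",
                 cases[[1]]$p, -1), "r must be")
  expect_error(evaluate_pair_potential("nope", list(), 1), "unknown")
})

test_that("Debye-Hueckel with a zero charge is exactly zero", {
  u <- evaluate_pair_potential("debye_huckel",
         list(q1 = 0, q2 = -1, dielectric = 80, ld = 1), c(0.3, 1, 2))
  expect_identical(u, c(0, 0, 0))
})

test_that("Wang-Frenkel minimum equals -epsilon of the pair", {
  ff <- load_mpipi()
  tab <- ff$pair[["protein|protein"]]
  for (pair in list(c("F", "F"), c("R", "rU"), c("G", "K"))) {
    p <- list(epsilon = tab$epsilon[pair[1], pair[2]],
              sigma = tab$sigma[pair[1], pair[2]], nu = tab$nu, mu = tab$mu)
    opt <- optimize(function(r) pair_val <- evaluate_pair_potential(
      "wang_frenkel", p, r), c(0.3, 3 * p$sigma))
    expect_equal(opt$objective, -p$epsilon, tolerance = 1e-6)
  }
})

test_that("a single free bead has zero energy and force", {
  top <- chain_topology("A", "hps")
  st <- cg_state(matrix(c(2, 2, 2), 1), cg_box(6))
  ef <- compute_energy_forces(as_cg_system(top), st, load_hps("Urry"))
  expect_equal(unclass(ef$energy), c(bond = 0, angle = 0, fan_bond = 0,
                                     pair = 0, electrostatic = 0, total = 0))
  expect_equal(ef$forces, matrix(0, 1, 3))
})

test_that("two charged beads reproduce the closed-form pair + DH energies", {
  top <- make_cg_system(chain_topology("K", "hps"), 2)   # two +1 lysines
  ff <- load_hps("Urry")
  r <- 0.9
  pos <- rbind(c(3, 3, 3), c(3 + r, 3, 3))
  ef <- compute_energy_forces(top, cg_state(pos, cg_box(10)), ff)
  aa <- aa_parameters()
  sig <- aa$sigma_nm[aa$code == "K"]
  lam <- aa$lambda_urry[aa$code == "K"] - 0.08
  u_pair <- evaluate_pair_potential("ashbaugh_hatch",
              list(epsilon = 0.8368, sigma = sig, lambda = lam), r,
              cutoff = ff$pair_cutoff)
  el <- ff$electrostatics
  u_dh <- evaluate_pair_potential("debye_huckel",
            list(q1 = 1, q2 = 1, dielectric = el$dielectric,
                 ld = el$debye_length), r, cutoff = el$cutoff)
  expect_equal(ef$energy[["pair"]], u_pair, tolerance = 1e-12)
  expect_equal(ef$energy[["electrostatic"]], u_dh, tolerance = 1e-12)
})

test_that("breakdown components sum to the total", {
  fx <- generate_fixture("dsdna", n_bp = 5)
  ef <- compute_energy_forces(fx$system, fx$state, fx$ff)
  e <- unclass(ef$energy)
  expect_equal(e[["total"]], sum(e[c("bond", "angle", "fan_bond", "pair",
                                     "electrostatic")]),
               tolerance = 1e-12)
})

test_that("energy is invariant under rigid and lattice translations", {
  rep <- random_chain_system(10, 3, 9, seed = 5)
  ff <- load_hps("Urry")
  box <- cg_box(9)
  comp <- compile_forces(rep$system, ff, box)
  e0 <- compute_energy_forces(comp, rep$coords,
                              want_forces = FALSE)$energy[["total"]]
  shifted <- sweep(rep$coords, 2, c(1.7, -0.4, 3.1), `+`)
  e1 <- compute_energy_forces(comp, shifted,
                              want_forces = FALSE)$energy[["total"]]
  expect_equal(e1, e0, tolerance = 1e-10)
  # whole-box lattice translation of a single molecule (periodicity)
  lat <- rep$coords
  idx <- rep$system$bead_ranges$start[2]:rep$system$bead_ranges$end[2]
  lat[idx, 1] <- lat[idx, 1] + box$lengths[1]
  e2 <- compute_energy_forces(comp, lat,
                              want_forces = FALSE)$energy[["total"]]
  expect_equal(e2, e0, tolerance = 1e-10)
  # net force is zero (translation invariance of the gradient)
  f <- compute_energy_forces(comp, rep$coords)$forces
  expect_equal(colSums(f), c(0, 0, 0), tolerance = 1e-9)
})

test_that("the screened interaction approaches Coulomb as salt -> 0", {
  r <- 1.5
  coulomb <- slabsim_constants()$coulomb_k * (1 * -1) / (80 * r)
  u <- vapply(c(100, 1, 1e-3, 1e-6), function(salt) {
    ld <- debye_length(salt, 300, 80)
    evaluate_pair_potential("debye_huckel",
      list(q1 = 1, q2 = -1, dielectric = 80, ld = ld), r)
  }, numeric(1))
  expect_true(all(diff(abs(u - coulomb)) < 0))
  # at 1e-6 mM the screening length is ~1e4 nm: residual exp(-r/ld) ~ 1.5e-4
  expect_equal(u[4], coulomb, tolerance = 1e-3)
})

test_that("overlapping beads raise an explicit error, not NaN", {
  top <- make_cg_system(chain_topology("A", "hps"), 2)
  pos <- rbind(c(2, 2, 2), c(2, 2, 2 + 1e-6))
  expect_error(compute_energy_forces(top, cg_state(pos, cg_box(6)),
                                     load_hps("Urry")),
               "overlap")
})

test_that("neighbor-listed energies equal brute force exactly", {
  rep <- random_chain_system(12, 4, 10, seed = 2)
  comp <- compile_forces(rep$system, load_hps("Urry"), cg_box(10))
  nl <- build_neighbor_list(comp, rep$coords)
  e_bf <- compute_energy_forces(comp, rep$coords, want_forces = FALSE)$energy
  e_nl <- compute_energy_forces(comp, rep$coords, neighbor_list = nl,
                                want_forces = FALSE)$energy
  expect_identical(unclass(e_bf), unclass(e_nl))
  # distant beads -> empty list
  far <- make_cg_system(chain_topology("A", "hps"), 2)
  compf <- compile_forces(far, load_hps("Urry"), cg_box(12))
  nlf <- build_neighbor_list(compf, rbind(c(1, 1, 1), c(6, 6, 6)))
  expect_equal(sum(lengths(nlf$groups)), 0)
  # excluded bonded pairs never appear in the candidate set
  dimer <- as_cg_system(chain_topology("KK", "hps"))
  compd <- compile_forces(dimer, load_hps("Urry"), cg_box(12))
  expect_length(compd$groups, 0)        # only pair was 1-2 bonded
  expect_null(compd$el)
  expect_error(build_neighbor_list(compf, rbind(c(1, 1, 1), c(2, 2, 2)),
                                   skin = 4), "box too small")
})
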