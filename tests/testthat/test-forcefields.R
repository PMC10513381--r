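test_that("Debye length follows the closed form and its scalings", {
  # independent hand evaluation of the 1:1 electrolyte formula
  kB <- slabsim_constants()$kB
  lB <- slabsim_constants()$coulomb_k / (80 * kB * 300)
  c_nm3 <- 0.1 * 6.02214076e23 / 1e24
  expect_equal(debye_length(100, 300, 80), 1 / sqrt(8 * pi * lB * c_nm3),
               tolerance = 1e-12)
  expect_equal(debye_length(400, 300, 80), debye_length(100, 300, 80) / 2,
               tolerance = 1e-12)
  salts <- c(10, 50, 150, 500)
  expect_true(all(diff(debye_length(salts, 300, 80)) < 0))
  expect_error(debye_length(-1, 300, 80), "positive")
})

test_that("HPS assignment: effective hydropathy transform and symmetry", {
  ff <- load_hps("Urry", mu = 1, delta = 0.08)
  tab <- ff$pair[["protein|protein"]]
  expect_equal(tab$form, "ashbaugh_hatch")
  expect_equal(ff$provenance, "HPS-Urry(mu=1,delta=0.08)")
  # mu = 1, delta = 0 leaves the raw scale untouched
  ff0 <- load_hps("KR", mu = 1, delta = 0)
  aa <- aa_parameters()
  expect_equal(unname(ff0$pair[["protein|protein"]]$lambda[aa$code]),
               aa$lambda_kr)
  # 20x20 mixing-rule sigma symmetric under residue swap
  codes <- aa$code
  sig_mat <- outer(tab$sigma[codes], tab$sigma[codes], `+`) / 2
  expect_identical(sig_mat, t(sig_mat))
})

test_that("Mpipi tables are symmetric and cover protein + RNA pairs", {
  ff <- load_mpipi()
  tab <- ff$pair[["protein|protein"]]
  expect_identical(tab$epsilon, t(tab$epsilon))
  expect_identical(tab$sigma, t(tab$sigma))
  expect_true(all(tab$sigma > 0))
  # every cross pair of a protein+RNA topology resolves
  pro <- chain_topology("MKVF", "mpipi")
  rna <- chain_topology("ACGU", "mpipi", kind = "rna")
  sys <- make_cg_system(list(pro, rna), c(1, 1))
  pos <- rbind(build_straight_chain("MKVF"),
               build_straight_chain("ACGU") + 2)
  ef <- compute_energy_forces(sys, cg_state(pos, cg_box(10)), ff)
  expect_true(is.finite(ef$energy[["total"]]))
  # spot-check entries against the shipped (checksummed) registry files
  eps_file <- slabsim:::read_param_matrix("mpipi_epsilon_synthetic.tsv")
  expect_identical(tab$epsilon["F", "R"], eps_file["F", "R"])
  expect_identical(tab$sigma["rA", "K"],
                   slabsim:::read_param_matrix("mpipi_sigma_synthetic.tsv")["rA", "K"])
})

test_that("MOFF epsilon matrix is symmetric and covers a dimer topology", {
  ff <- load_moff()
  eps <- ff$pair[["protein|protein"]]$epsilon
  expect_identical(eps, t(eps))
  seqc <- paste(rep(aa_parameters()$code, 2), collapse = "")
  dimer <- chain_topology(seqc, "moff")       # all 20 residues, twice
  pos <- build_straight_chain(seqc) * 0.9 +
    matrix(rep(c(2, 2, 1), each = 2 * 20), ncol = 3)
  ef <- compute_energy_forces(as_cg_system(dimer),
                              cg_state(pos, cg_box(25)), ff)
  expect_true(is.finite(ef$energy[["total"]]))
  eps_file <- slabsim:::read_param_matrix("moff_epsilon_synthetic.tsv")
  for (pair in list(c("A", "A"), c("K", "E"), c("W", "F")))
    expect_identical(eps[pair[1], pair[2]], eps_file[pair[1], pair[2]])
})

test_that("MRG-CG coefficients convert kcal->kJ exactly once", {
  raw <- slabsim:::mrg_bonded_raw()
  ff <- load_mrg_dna(rescaled = FALSE)
  bond <- ff$bonded$mrg_bond
  expect_equal(unname(bond$k["k2"]),
               4.184 * raw$k2[raw$term == "bond"])
  fan0 <- ff$bonded$mrg_fan_0
  expect_equal(unname(fan0$k["k4"]), 4.184 * raw$k4[!is.na(raw$delta) &
                                                    raw$delta == 0])
})

test_that("implicit-ion rescaling touches bonded terms only", {
  plain <- load_mrg_dna(rescaled = FALSE)
  resc <- load_mrg_dna(rescaled = TRUE, bond_scale = 0.9)
  # field-by-field diff: electrostatics and pair tables identical
  expect_identical(plain$electrostatics, resc$electrostatics)
  expect_identical(plain$pair, resc$pair)
  for (key in names(plain$bonded)) {
    expect_equal(resc$bonded[[key]]$k, 0.9 * plain$bonded[[key]]$k)
    expect_identical(resc$bonded[[key]]$x0, plain$bonded[[key]]$x0)
  }
})

test_that("fan-bond coefficient keys cover exactly the tabulated deltas", {
  ff <- load_mrg_dna()
  deltas <- sort(unique(na.omit(slabsim:::mrg_bonded_raw()$delta)))
  fan_keys <- grep("^mrg_fan_", names(ff$bonded), value = TRUE)
  expect_setequal(fan_keys, paste0("mrg_fan_", deltas))
  top <- build_dsdna_topology(10)
  expect_true(all(top$bonds$coef[top$bonds$kind == "fan_bond"] %in% fan_keys))
})

test_that("cross combination gives excluded volume + screened Coulomb", {
  ffc <- combine_cross(load_moff(), load_mrg_dna())
  expect_true("dna|protein" %in% names(ffc$pair))
  expect_equal(ffc$pair[["dna|protein"]]$form, "excluded_volume")
  # one protein bead + one DNA bead at distance r: energy equals the sum of
  # independently evaluated closed forms
  pro <- chain_topology("K", "moff")
  dna <- build_dsdna_topology(1)
  sys <- make_cg_system(list(pro, dna), c(1, 1))
  pos <- rbind(c(5, 5, 5), c(6.2, 5, 5), c(6.2, 5, 5.34))
  st <- cg_state(pos, cg_box(12))
  ef <- compute_energy_forces(sys, st, ffc)
  aa <- aa_parameters(); dn <- dna_parameters()
  sig <- (aa$sigma_nm[aa$code == "K"] + dn$sigma_nm[1]) / 2
  el <- ffc$electrostatics
  r <- c(1.2, sqrt(1.2^2 + 0.34^2))
  ev <- sum(evaluate_pair_potential("excluded_volume",
            list(eps_rep = 0.8368, sigma = sig), r, cutoff = ffc$pair_cutoff))
  # protein-DNA charge products, against the closed Debye-Hueckel form
  dh_pd <- sum(evaluate_pair_potential("debye_huckel",
            list(q1 = 1, q2 = -1, dielectric = el$dielectric,
                 ld = el$debye_length), r, cutoff = el$cutoff))
  # DNA-DNA pair (the two paired nucleotides are fan-bonded, not excluded)
  dh_dd <- evaluate_pair_potential("debye_huckel",
            list(q1 = -1, q2 = -1, dielectric = el$dielectric,
                 ld = el$debye_length), 0.34, cutoff = el$cutoff)
  ev_dd <- evaluate_pair_potential("excluded_volume",
            list(eps_rep = 0.8368, sigma = dn$sigma_nm[1]), 0.34,
            cutoff = ffc$pair_cutoff)
  expect_equal(ef$energy[["electrostatic"]], dh_pd + dh_dd, tolerance = 1e-10)
  expect_equal(ef$energy[["pair"]], ev + ev_dd, tolerance = 1e-10)
  expect_error(combine_cross(load_moff(),
                 load_mrg_dna(electrostatics = electrostatics_spec(salt_mM = 150))),
               "electrostatics")
})

test_that("parameter tables carry verified checksums", {
  sums <- slabsim:::param_provenance()
  expect_length(sums, 7)
  expect_true(all(nchar(sums) == 32))
})
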