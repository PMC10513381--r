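# Synthetic ready-to-run systems.  These are first-class generators used
# both by the test suite and by users exploring the engine: every fixture
# is deterministic given its seed and returns a complete
# (system, force field, state) triple.

#' Generate a synthetic ready-to-run system
#'
#' Kinds:
#' \describe{
#'   \item{harmonic_dimer}{Two glycine beads joined by the stiff harmonic
#'     backbone bond, nonbonded interactions excluded; the analytic
#'     minimum is the bond rest length.}
#'   \item{toy_idp}{A 30-residue mixed-sequence disordered chain with the
#'     HPS(Urry) force field, started from a straight chain.}
#'   \item{dsdna}{A 20-bp double-stranded DNA with the MRG-CG model in
#'     ladder geometry.}
#'   \item{lj_cluster}{`n` phenylalanine beads (pair hydropathy 1, i.e. a
#'     plain Lennard-Jones well) on a perturbed cubic lattice, no
#'     charges: the NVE test system.}
#'   \item{slab_step_profile}{`n_mol` single-bead molecules placed
#'     uniformly so the slab has an exact two-density step profile with
#'     chosen dense/dilute densities (mg/mL); the analysis-path oracle.}
#'   \item{ideal_gas}{Non-interacting beads in a cubic box (pair form
#'     "none"): the analytic NPT reference.}
#' }
#'
#' @param kind Fixture kind (see Details).
#' @param seed RNG seed; generation is deterministic given it.
#' @param n Bead count (lj_cluster, ideal_gas).
#' @param n_bp Base pairs (dsdna).
#' @param n_mol Molecule count (slab_step_profile).
#' @param rho_dense,rho_dilute Target step densities, mg/mL.
#' @param dense_halfwidth Half-width of the dense slab region, nm.
#' @param box_lengths Box edge lengths, nm.
#' @return List with `system`, `ff`, `state` and a kind-specific `info`.
#' @export
generate_fixture <- function(kind = c("harmonic_dimer", "toy_idp", "dsdna",
                                      "lj_cluster", "slab_step_profile",
                                      "ideal_gas"),
                             seed = 1, n = 13, n_bp = 20, n_mol = 400,
                             rho_dense = 300, rho_dilute = 20,
                             dense_halfwidth = 10,
                             box_lengths = NULL) {
  kind <- match.arg(kind)
  switch(kind,
    harmonic_dimer = {
      top <- chain_topology("GG", "hps")
      box <- cg_box(box_lengths %||% 10)
      pos <- matrix(c(4.8, 5, 5, 5.18, 5, 5), 2, 3, byrow = TRUE)
      ff <- load_hps("Urry")
      list(system = as_cg_system(top), ff = ff,
           state = cg_state(pos, box),
           info = list(r0 = ff$bonded$harmonic_ca$r0,
                       k = ff$bonded$harmonic_ca$k))
    },
    toy_idp = {
      seqc <- "MKASNDYTRQATQSYGAEPTQPGQGYSDKS"    # 30-residue mixed IDR-like
      top <- chain_topology(seqc, "hps")
      box <- cg_box(box_lengths %||% 25)
      pos <- sweep(build_straight_chain(seqc), 2, c(12.5, 12.5, 7), `+`)
      list(system = as_cg_system(top), ff = load_hps("Urry"),
           state = cg_state(pos, box), info = list(sequence = seqc))
    },
    dsdna = {
      top <- build_dsdna_topology(n_bp)
      box <- cg_box(box_lengths %||% max(20, n_bp * 0.34 * 2))
      pos <- sweep(dsdna_coordinates(top), 2,
                   c(0.5, 0.5, 0.25) * box_lengths %||% max(20, n_bp * 0.34 * 2),
                   `+`)
      list(system = as_cg_system(top), ff = load_mrg_dna(),
           state = cg_state(pos, box), info = list(n_bp = n_bp))
    },
    lj_cluster = {
      top <- make_cg_system(chain_topology("F", "hps"), n)
      box <- cg_box(box_lengths %||% 20)
      grid <- as.matrix(expand.grid(x = 0:2, y = 0:2, z = 0:2))[seq_len(n), ]
      pos <- with_private_seed(seed,
        grid * 0.62 + matrix(stats::rnorm(3 * n, sd = 0.02), n, 3))
      pos <- sweep(pos, 2, box$lengths / 2 - colMeans(pos), `+`)
      list(system = top, ff = load_hps("KR", mu = 1, delta = 0),
           state = cg_state(pos, box), info = list(n = n))
    },
    slab_step_profile = {
      # stratified placement: beads sit exactly at 1-nm bin centers, equal
      # counts per bin, so the binned profile IS the constructed step
      box <- cg_box(box_lengths %||% c(8, 8, 80))
      one <- chain_topology("W", "hps")
      mass <- one$beads$mass[1]
      Lz <- box$lengths[3]; area <- box$lengths[1] * box$lengths[2]
      centers <- seq(-Lz / 2 + 0.5, Lz / 2 - 0.5, by = 1)
      dense_bins <- centers[abs(centers) < dense_halfwidth]
      dil_bins <- setdiff(centers, dense_bins)
      k_d <- max(1, round(rho_dense / .amu_nm3_to_mg_mL * area / mass))
      k_l <- max(0, round(rho_dilute / .amu_nm3_to_mg_mL * area / mass))
      z <- c(rep(dense_bins, each = k_d), rep(dil_bins, each = k_l))
      n_tot <- length(z)
      sys <- make_cg_system(one, n_tot)
      pos <- with_private_seed(seed,
        cbind(stats::runif(n_tot) * box$lengths[1],
              stats::runif(n_tot) * box$lengths[2], z))
      true_dense <- k_d * mass / area * .amu_nm3_to_mg_mL
      true_dil <- k_l * mass / area * .amu_nm3_to_mg_mL
      list(system = sys, ff = load_hps("Urry"),
           state = cg_state(pos, box),
           info = list(rho_dense = true_dense, rho_dilute = true_dil,
                       dense_halfwidth = dense_halfwidth, mass = mass,
                       n_total = n_tot))
    },
    ideal_gas = {
      one <- chain_topology("G", "hps")
      sys <- make_cg_system(one, n)
      box <- cg_box(box_lengths %||% 10)
      pos <- with_private_seed(seed,
        matrix(stats::runif(3 * n), n, 3) %*% diag(box$lengths))
      ff <- new_force_field("ideal-gas",
                            list("protein|protein" = list(form = "none")),
                            list(harmonic_ca = harmonic_ca_bond()),
                            electrostatics_spec())
      # no charges: strip them so no electrostatic group is built
      sys$beads$charge <- 0
      list(system = sys, ff = ff, state = cg_state(pos, box),
           info = list(n = n))
    })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Sample a freely rotating chain
#'
#' Synthetic polymer sampler: successive bond vectors make a fixed angle
#' `theta` with their predecessor and a uniform azimuth, giving the
#' closed-form persistence length lp = -b / log(cos(theta)).
#'
#' @param n_bonds Bonds per chain.
#' @param theta Bend angle between successive bonds, radians.
#' @param b Bond length, nm.
#' @param n_chains Number of independent chains.
#' @param seed RNG seed.
#' @return List of coordinate matrices (one per chain).
#' @export
freely_rotating_chain <- function(n_bonds, theta, b = 1, n_chains = 1,
                                  seed = 1) {
  with_private_seed(seed, lapply(seq_len(n_chains), function(cc) {
    u <- matrix(0, n_bonds, 3)
    u[1, ] <- c(0, 0, 1)
    for (k in 2:n_bonds) {
      prev <- u[k - 1, ]
      # orthonormal frame around prev
      ref <- if (abs(prev[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
      e1 <- ref - sum(ref * prev) * prev
      e1 <- e1 / sqrt(sum(e1^2))
      e2 <- c(prev[2] * e1[3] - prev[3] * e1[2],
              prev[3] * e1[1] - prev[1] * e1[3],
              prev[1] * e1[2] - prev[2] * e1[1])
      phi <- stats::runif(1, 0, 2 * pi)
      u[k, ] <- cos(theta) * prev +
        sin(theta) * (cos(phi) * e1 + sin(phi) * e2)
    }
    rbind(0, apply(u * b, 2, cumsum))
  }))
}
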