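# Force-field assignments.  A force_field object carries:
#   * pair tables keyed by the molecule-kind pair they scope
#     ("protein|protein", "dna|dna", "protein|dna", ...),
#   * bonded coefficient sets keyed by the coef labels used in topologies,
#   * a shared Debye-Hueckel electrostatics spec,
#   * the nonbonded exclusion rule (1-2 and 1-3 bonded neighbours).
# All energies are stored in kJ/mol; kcal-tabulated coefficients are
# converted exactly once on load.

#' Debye screening length of a 1:1 electrolyte
#'
#' Closed form: kappa^-2 = eps_r * kB*T / (8 pi * l_unit * NA * c) with the
#' Coulomb prefactor in the package unit system, i.e.
#' kappa^2 = 8 pi * lB * c_number with Bjerrum length
#' lB = coulomb_k / (eps_r * kB * T).
#'
#' @param salt_mM Monovalent salt concentration, mM.
#' @param temperature_K Temperature, K.
#' @param dielectric Relative dielectric constant.
#' @return Screening length kappa^-1 in nm.
#' @export
debye_length <- function(salt_mM, temperature_K = 300, dielectric = 80) {
  if (any(salt_mM <= 0) || any(temperature_K <= 0) || any(dielectric <= 0))
    stop("salt, temperature and dielectric must be positive")
  lB <- .coulomb_k / (dielectric * .kB * temperature_K)   # nm
  c_nm3 <- salt_mM * 1e-3 * 6.02214076e23 * 1e-24          # ions per nm^3
  1 / sqrt(8 * pi * lB * c_nm3)
}

#' Implicit-ion electrostatics specification
#'
#' @param salt_mM Monovalent salt concentration, mM.
#' @param temperature_K Temperature entering the screening length, K.
#' @param dielectric Relative dielectric constant (default 80, water).
#' @param cutoff Electrostatic cutoff, nm (energy-shifted truncation).
#' @return A list with the inputs plus the derived `debye_length` (nm).
#' @export
electrostatics_spec <- function(salt_mM = 100, temperature_K = 300,
                                dielectric = 80, cutoff = 3.5) {
  list(salt_mM = salt_mM, temperature_K = temperature_K,
       dielectric = dielectric, cutoff = cutoff,
       debye_length = debye_length(salt_mM, temperature_K, dielectric))
}

new_force_field <- function(provenance, pair, bonded, electrostatics,
                            pair_cutoff = 2.0) {
  structure(list(provenance = provenance, pair = pair, bonded = bonded,
                 electrostatics = electrostatics,
                 exclusions = "1-2,1-3", pair_cutoff = pair_cutoff,
                 checksums = param_provenance()),
            class = "force_field")
}

#' @export
print.force_field <- function(x, ...) {
  cat(sprintf("force_field: %s\n", x$provenance))
  cat(sprintf("  pair tables: %s\n", paste(names(x$pair), collapse = ", ")))
  cat(sprintf("  bonded sets: %s\n", paste(names(x$bonded), collapse = ", ")))
  el <- x$electrostatics
  cat(sprintf("  Debye-Hueckel: %.0f mM, %g K, eps_r %g, kappa^-1 %.3f nm, cutoff %g nm\n",
              el$salt_mM, el$temperature_K, el$dielectric, el$debye_length,
              el$cutoff))
  invisible(x)
}

harmonic_ca_bond <- function() {
  # stiff harmonic Calpha-Calpha bond: U = k/2 (r - r0)^2
  list(form = "harmonic", k = 8368, r0 = 0.38)   # kJ/mol/nm^2, nm
}

#' Load a hydropathy-scale (HPS) protein force field
#'
#' Ashbaugh-Hatch pair potential in which the attractive tail of a
#' Lennard-Jones well is scaled by the mean hydropathy of the residue
#' pair, transformed as `mu * lambda - delta`; plus Debye-Hueckel
#' electrostatics and stiff harmonic backbone bonds.  `scale = "Urry"`
#' with `mu = 1, delta = 0.08` is the optimal parameter set for
#' condensate simulations; `scale = "KR"` uses the normalized
#' Kapcha-Rossky scale with `delta = 0`.
#'
#' @param scale Hydropathy scale, "Urry" or "KR".
#' @param mu Global hydropathy scale factor.
#' @param delta Global hydropathy shift.
#' @param epsilon Pair well depth, kJ/mol.
#' @param electrostatics An [electrostatics_spec()].
#' @param pair_cutoff Nonbonded cutoff, nm.
#' @return A `force_field`.
#' @export
load_hps <- function(scale = c("Urry", "KR"), mu = 1,
                     delta = if (match.arg(scale) == "Urry") 0.08 else 0,
                     epsilon = 0.8368,
                     electrostatics = electrostatics_spec(),
                     pair_cutoff = 2.0) {
  scale <- match.arg(scale)
  aa <- aa_parameters()
  lam <- setNames(if (scale == "Urry") aa$lambda_urry else aa$lambda_kr,
                  aa$code)
  if (anyNA(lam)) stop("incomplete lambda table")
  pair <- list("protein|protein" = list(
    form = "ashbaugh_hatch", epsilon = epsilon,
    sigma = setNames(aa$sigma_nm, aa$code),
    lambda = lam, mu = mu, delta = delta))
  new_force_field(sprintf("HPS-%s(mu=%g,delta=%g)", scale, mu, delta),
                  pair, list(harmonic_ca = harmonic_ca_bond()),
                  electrostatics, pair_cutoff)
}

#' Load the Wang-Frenkel (Mpipi-style) protein/RNA force field
#'
#' Pair interactions use the Wang-Frenkel potential with per-pair epsilon
#' and sigma tables covering the 20 amino acids and the four RNA
#' nucleotides, plus Debye-Hueckel electrostatics with 0.75-scaled
#' charges.  The shipped epsilon/sigma matrices are synthetic stand-ins
#' built from a documented hydropathy recipe (see
#' `inst/extdata/mpipi_*_synthetic.tsv`), not the published calibration.
#'
#' @inheritParams load_hps
#' @param nu,mu_wf Wang-Frenkel shape exponents.
#' @return A `force_field`.
#' @export
load_mpipi <- function(electrostatics = electrostatics_spec(salt_mM = 150),
                       pair_cutoff = 2.0, nu = 1, mu_wf = 2) {
  eps <- mpipi_epsilon(); sig <- mpipi_sigma()
  types <- c(aa_parameters()$code, paste0("r", rna_parameters()$code))
  if (!all(types %in% rownames(eps)) || !all(types %in% rownames(sig)))
    stop("Mpipi tables do not cover all protein + RNA types")
  tab <- list(form = "wang_frenkel", epsilon = eps, sigma = sig,
              nu = nu, mu = mu_wf)
  pair <- list("protein|protein" = tab, "protein|rna" = tab,
               "rna|rna" = tab)
  new_force_field("Mpipi(synthetic tables)", pair,
                  list(harmonic_ca = harmonic_ca_bond()),
                  electrostatics, pair_cutoff)
}

#' Load the contact-matrix (MOFF-style) protein force field
#'
#' Pair interactions combine a 1/r^12 excluded-volume core with a
#' tanh-switched contact well whose strength is the per-residue-pair
#' epsilon_ij matrix (attractive where negative).  The shipped epsilon
#' matrix is a synthetic stand-in (see
#' `inst/extdata/moff_epsilon_synthetic.tsv`).
#'
#' @inheritParams load_hps
#' @param eta Switching steepness, nm^-1.
#' @param r0 Switching midpoint, nm.
#' @param eps_rep Excluded-volume prefactor, kJ/mol.
#' @return A `force_field`.
#' @export
load_moff <- function(electrostatics = electrostatics_spec(),
                      pair_cutoff = 2.0, eta = 7, r0 = 0.8,
                      eps_rep = 0.8368) {
  eps <- moff_epsilon()
  aa <- aa_parameters()
  if (!all(aa$code %in% rownames(eps)))
    stop("MOFF epsilon matrix does not cover all 20 residues")
  if (max(abs(eps - t(eps))) > 0) stop("MOFF epsilon matrix not symmetric")
  pair <- list("protein|protein" = list(
    form = "moff_contact", epsilon = eps,
    sigma = setNames(aa$sigma_nm, aa$code),
    eta = eta, r0 = r0, eps_rep = eps_rep))
  new_force_field("MOFF(synthetic table)", pair,
                  list(harmonic_ca = harmonic_ca_bond()),
                  electrostatics, pair_cutoff)
}

#' Load the MRG-CG DNA force field (implicit ions)
#'
#' Polynomial bond, angle and inter-strand fan-bond terms (quartic in the
#' deviation from the rest geometry), converted exactly once from the
#' kcal-tabulated coefficients to kJ/mol; excluded-volume nonbonded
#' interactions between non-bonded nucleotides; Debye-Hueckel
#' electrostatics on the phosphate charges.  With `rescaled = TRUE` all
#' bonded coefficients are multiplied by `bond_scale`, the package's
#' implicit-ion recalibration of the bonded strengths (electrostatics is
#' untouched).
#'
#' @inheritParams load_hps
#' @param rescaled Apply the implicit-ion bonded rescaling?
#' @param bond_scale Rescaling factor applied when `rescaled` is TRUE.
#' @param eps_rep Excluded-volume prefactor, kJ/mol.
#' @return A `force_field`.
#' @export
load_mrg_dna <- function(rescaled = TRUE, bond_scale = 0.9,
                         electrostatics = electrostatics_spec(),
                         pair_cutoff = 2.0, eps_rep = 0.8368) {
  raw <- mrg_bonded_raw()
  scale <- if (rescaled) bond_scale else 1
  bonded <- list()
  for (r in seq_len(nrow(raw))) {
    row <- raw[r, ]
    coefs <- scale * .kcal2kJ * c(k2 = row$k2, k3 = row$k3, k4 = row$k4)
    set <- list(form = "poly", x0 = row$x0, k = coefs,
                angular = identical(row$term, "angle"))
    key <- switch(row$term,
                  bond = "mrg_bond", angle = "mrg_angle",
                  fan = paste0("mrg_fan_", row$delta))
    bonded[[key]] <- set
  }
  dna <- dna_parameters()
  pair <- list("dna|dna" = list(
    form = "excluded_volume", eps_rep = eps_rep,
    sigma = setNames(dna$sigma_nm, paste0("d", dna$code))))
  new_force_field(sprintf("MRG-CG(rescaled=%s)", rescaled), pair, bonded,
                  electrostatics, pair_cutoff)
}

#' Combine a protein and a nucleic-acid force field
#'
#' Merges the two assignments; cross protein-nucleic-acid pairs interact
#' through excluded volume plus Debye-Hueckel electrostatics only.  Both
#' assignments must share the same electrostatics spec.
#'
#' @param protein_ff,na_ff `force_field` objects.
#' @param eps_rep Cross excluded-volume prefactor, kJ/mol.
#' @return A merged `force_field`.
#' @export
combine_cross <- function(protein_ff, na_ff, eps_rep = 0.8368) {
  el1 <- protein_ff$electrostatics; el2 <- na_ff$electrostatics
  if (!isTRUE(all.equal(el1[c("salt_mM", "temperature_K", "dielectric")],
                        el2[c("salt_mM", "temperature_K", "dielectric")])))
    stop("electrostatics specs differ; cannot combine")
  pair <- c(protein_ff$pair, na_ff$pair)
  # sigma registry across kinds for the cross excluded-volume rule
  aa <- aa_parameters(); dna <- dna_parameters(); rna <- rna_parameters()
  sig <- c(setNames(aa$sigma_nm, aa$code),
           setNames(dna$sigma_nm, paste0("d", dna$code)),
           setNames(rna$sigma_nm, paste0("r", rna$code)))
  na_kinds <- unique(unlist(strsplit(names(na_ff$pair), "\\|")))
  for (nk in setdiff(na_kinds, "protein")) {
    key <- paste(sort(c("protein", nk)), collapse = "|")
    if (is.null(pair[[key]]))
      pair[[key]] <- list(form = "excluded_volume", eps_rep = eps_rep,
                          sigma = sig)
  }
  new_force_field(paste(protein_ff$provenance, na_ff$provenance, sep = " + "),
                  pair, c(protein_ff$bonded, na_ff$bonded),
                  protein_ff$electrostatics,
                  max(protein_ff$pair_cutoff, na_ff$pair_cutoff))
}
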