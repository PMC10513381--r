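# Internal unit system: nm, ps, amu, kJ/mol, elementary charge, Kelvin.

# Boltzmann constant, kJ/mol/K
.kB <- 0.00831446261815324

# kcal -> kJ
.kcal2kJ <- 4.184

# Coulomb prefactor e^2/(4 pi eps0), kJ nm / mol / e^2
.coulomb_k <- 138.935458

# amu/nm^3 -> mg/mL
.amu_nm3_to_mg_mL <- 1.66053906660

# 1 bar in kJ/mol/nm^3
.bar2kJ_mol_nm3 <- 0.0602214076

#' Physical constants used by slabsim
#'
#' Returns the constants fixing the internal unit system (nm, ps, amu,
#' kJ/mol, elementary charge, Kelvin).
#'
#' @return Named list with `kB` (kJ/mol/K), `kcal2kJ`, `coulomb_k`
#'   (kJ nm/mol/e^2), `amu_nm3_to_mg_mL`, `bar2kJ_mol_nm3`.
#' @export
slabsim_constants <- function() {
  list(kB = .kB, kcal2kJ = .kcal2kJ, coulomb_k = .coulomb_k,
       amu_nm3_to_mg_mL = .amu_nm3_to_mg_mL,
       bar2kJ_mol_nm3 = .bar2kJ_mol_nm3)
}

# Run `code` with a private RNG stream seeded by `seed`, restoring the
# caller's RNG state afterwards.  All stochastic slabsim operations go
# through this so a user-facing seed argument is the single source of
# randomness.
with_private_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}
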