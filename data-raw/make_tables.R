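# One-off generator for inst/extdata parameter tables.
# Real data (aa_properties, nucleotides) written verbatim; the pair matrices
# are synthetic stand-ins built by the deterministic recipe below.

ed <- file.path("inst", "extdata")
dir.create(ed, recursive = TRUE, showWarnings = FALSE)

aa <- data.frame(
  code  = c("A","R","N","D","C","Q","E","G","H","I",
            "L","K","M","F","P","S","T","W","Y","V"),
  name3 = c("ALA","ARG","ASN","ASP","CYS","GLN","GLU","GLY","HIS","ILE",
            "LEU","LYS","MET","PHE","PRO","SER","THR","TRP","TYR","VAL"),
  mass_amu = c(71.0788,156.1875,114.1038,115.0886,103.1388,128.1307,
               129.1155,57.0519,137.1411,113.1594,113.1594,128.1741,
               131.1926,147.1766,97.1167,87.0782,101.1051,186.2132,
               163.1760,99.1326),
  sigma_nm = c(0.504,0.656,0.568,0.558,0.548,0.602,0.592,0.450,0.608,0.618,
               0.618,0.636,0.618,0.636,0.556,0.518,0.562,0.678,0.646,0.586),
  charge_hps  = c(0,1,0,-1,0,0,-1,0,0.5,0,0,1,0,0,0,0,0,0,0,0),
  charge_moff = c(0,1,0,-1,0,0,-1,0,0.25,0,0,1,0,0,0,0,0,0,0,0),
  charge_mpipi = c(0,0.75,0,-0.75,0,0,-0.75,0,0.375,0,0,0.75,0,0,0,0,0,0,0,0),
  lambda_kr = c(0.730,0.000,0.432,0.378,0.595,0.514,0.459,0.649,0.514,0.973,
                0.973,0.514,0.838,1.000,1.000,0.595,0.676,0.946,0.865,0.892),
  lambda_urry = c(0.602941,0.558824,0.588235,0.294118,0.647059,0.558824,
                  0.000000,0.573529,0.764706,0.705882,0.720588,0.382353,
                  0.676471,0.823529,0.758824,0.588235,0.588235,1.000000,
                  0.897059,0.664706)
)

write_tsv <- function(df, file, header) {
  con <- file(file.path(ed, file), "w")
  writeLines(header, con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
}

write_tsv(aa, "aa_properties.tsv", c(
  "# Amino-acid bead registry: residue masses (amu), van der Waals diameters",
  "# sigma (nm), bead charges (e) under the HPS, MOFF and Mpipi conventions,",
  "# and normalized KR / Urry hydropathy scales (dimensionless)."))

dna <- data.frame(
  code = c("A","C","G","T"),
  name3 = c("DA","DC","DG","DT"),
  mass_amu = c(313.21, 289.18, 329.21, 304.20),
  sigma_nm = 0.80,
  charge = -1)
write_tsv(dna, "dna_nucleotides.tsv", c(
  "# One-bead-per-nucleotide DNA registry: nucleotide-residue masses (amu),",
  "# excluded-volume diameter sigma (nm), phosphate charge (e)."))

rna <- data.frame(
  code = c("A","C","G","U"),
  name3 = c("RA","RC","RG","RU"),
  mass_amu = c(329.21, 305.18, 345.21, 306.17),
  sigma_nm = 0.84,
  charge = -0.75)
write_tsv(rna, "rna_nucleotides.tsv", c(
  "# One-bead-per-nucleotide RNA registry (Mpipi convention): masses (amu),",
  "# sigma (nm), scaled phosphate charge (e)."))

# ---- synthetic pair matrices ------------------------------------------------
# Deterministic recipe (documented in the package): hydropathy-product wells.
lam_kr <- setNames(aa$lambda_kr, aa$code)
lam_u  <- setNames(aa$lambda_urry, aa$code)
sig    <- setNames(aa$sigma_nm, aa$code)

moff_eps <- round(outer(lam_kr, lam_kr, function(a, b) -3.0 * a * b + 0.8), 3)
stopifnot(isSymmetric(moff_eps))
con <- file(file.path(ed, "moff_epsilon_synthetic.tsv"), "w")
writeLines(c(
  "# SYNTHETIC stand-in for the MOFF 20x20 contact-strength matrix eps_ij",
  "# (kJ/mol).  Values are generated from the deterministic recipe",
  "#   eps_ij = -3.0 * lambda_KR_i * lambda_KR_j + 0.8",
  "# and are NOT the published maximum-entropy-optimized values."), con)
write.table(data.frame(code = rownames(moff_eps), moff_eps,
                       check.names = FALSE),
            con, sep = "\t", quote = FALSE, row.names = FALSE)
close(con)

mp_types <- c(aa$code, paste0("r", rna$code))
lam_mp <- c(lam_u, setNames(rep(0.9, 4), paste0("r", rna$code)))
sig_mp <- c(sig, setNames(rep(0.84, 4), paste0("r", rna$code)))
cation <- c("R", "K")
pi_grp <- c("F", "W", "Y", "rA", "rC", "rG", "rU")
bonus <- function(a, b) {
  0.8 * ((a %in% cation & b %in% pi_grp) | (b %in% cation & a %in% pi_grp)) +
  0.6 * (a %in% pi_grp & b %in% pi_grp)
}
mp_eps <- matrix(0, 24, 24, dimnames = list(mp_types, mp_types))
mp_sig <- mp_eps
for (a in mp_types) for (b in mp_types) {
  mp_eps[a, b] <- round(0.2 + 2.2 * sqrt(lam_mp[a] * lam_mp[b]) + bonus(a, b), 3)
  mp_sig[a, b] <- round((sig_mp[a] + sig_mp[b]) / 2, 3)
}
stopifnot(isSymmetric(mp_eps), isSymmetric(mp_sig))
for (nm in c("epsilon", "sigma")) {
  m <- if (nm == "epsilon") mp_eps else mp_sig
  un <- if (nm == "epsilon") "kJ/mol" else "nm"
  con <- file(file.path(ed, sprintf("mpipi_%s_synthetic.tsv", nm)), "w")
  writeLines(c(
    sprintf("# SYNTHETIC stand-in for the Mpipi 24x24 Wang-Frenkel %s matrix (%s)", nm, un),
    "# covering the 20 amino acids plus RNA nucleotides rA/rC/rG/rU.",
    "# Generated from a documented hydropathy-based recipe with cation-pi and",
    "# pi-pi bonuses; NOT the published PMF-calibrated values."), con)
  write.table(data.frame(code = rownames(m), m, check.names = FALSE),
              con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
}

mrg <- data.frame(
  term  = c("bond", "angle", "fan", "fan", "fan", "fan", "fan"),
  delta = c(NA, NA, -2L, -1L, 0L, 1L, 2L),
  x0    = c(0.340, 180, 1.209, 1.057, 1.000, 1.057, 1.209),
  k2    = c(200, 0.0134, 1.0, 2.0, 4.0, 2.0, 1.0),
  k3    = c(-100, 0, 0, 0, 0, 0, 0),
  k4    = c(800, 1e-6, 2, 4, 8, 4, 2))
write_tsv(mrg, "mrg_bonded_synthetic.tsv", c(
  "# SYNTHETIC stand-in for the MRG-CG DNA polynomial bonded coefficients.",
  "# U(x) = k2 x^2 + k3 x^3 + k4 x^4 with x = r - r0 (bond/fan, x0 in nm,",
  "# k_n in kcal/mol/nm^n) or x = theta - theta0 (angle, x0 in degrees,",
  "# k_n in kcal/mol/degree^n).  Coefficients chosen for B-DNA-like geometry",
  "# and bending stiffness; NOT the published renormalization-group values."))

md5 <- tools::md5sum(list.files(ed, pattern = "\\.tsv$", full.names = TRUE))
writeLines(sprintf("%s  %s", unname(md5), basename(names(md5))),
           file.path(ed, "MD5SUMS"))
cat("wrote", length(md5), "tables\n")
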