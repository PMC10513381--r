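# Parameter table registry.  Tables live in inst/extdata as plain-text TSV
# with '#' header comments stating content and units; MD5SUMS records their
# checksums, verified at load time so provenance can be logged run-to-run.

param_file <- function(name) {
  path <- system.file("extdata", name, package = "slabsim")
  if (!nzchar(path)) stop("parameter table not found: ", name)
  path
}

param_checksum <- function(name) {
  path <- param_file(name)
  sums <- read.table(param_file("MD5SUMS"), header = FALSE,
                     col.names = c("md5", "file"),
                     stringsAsFactors = FALSE)
  expected <- sums$md5[sums$file == name]
  actual <- unname(tools::md5sum(path))
  if (length(expected) != 1L || !identical(expected, actual))
    stop("checksum mismatch for parameter table ", name)
  actual
}

read_param_table <- function(name) {
  param_checksum(name)
  read.table(param_file(name), header = TRUE, sep = "\t",
             comment.char = "#", stringsAsFactors = FALSE,
             check.names = FALSE)
}

read_param_matrix <- function(name) {
  df <- read_param_table(name)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  stopifnot(identical(rownames(m), colnames(m)))
  m
}

# cached accessors ------------------------------------------------------------
.param_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .param_cache)) assign(key, expr, envir = .param_cache)
  get(key, envir = .param_cache)
}

#' Amino-acid bead parameters
#'
#' Residue-level bead registry: masses (amu), van der Waals diameters
#' (nm), bead charges (e) under the HPS / MOFF / Mpipi conventions
#' (the three differ in the histidine charge and in the Mpipi 0.75
#' charge scaling), and the normalized KR and Urry hydropathy scales.
#'
#' @return A data frame with one row per amino acid, keyed by one-letter
#'   `code`.
#' @export
aa_parameters <- function() cached("aa", read_param_table("aa_properties.tsv"))

#' @rdname aa_parameters
#' @export
dna_parameters <- function() cached("dna", read_param_table("dna_nucleotides.tsv"))

#' @rdname aa_parameters
#' @export
rna_parameters <- function() cached("rna", read_param_table("rna_nucleotides.tsv"))

moff_epsilon <- function() cached("moff_eps", read_param_matrix("moff_epsilon_synthetic.tsv"))
mpipi_epsilon <- function() cached("mp_eps", read_param_matrix("mpipi_epsilon_synthetic.tsv"))
mpipi_sigma <- function() cached("mp_sig", read_param_matrix("mpipi_sigma_synthetic.tsv"))
mrg_bonded_raw <- function() cached("mrg", read_param_table("mrg_bonded_synthetic.tsv"))

param_provenance <- function() {
  files <- c("aa_properties.tsv", "dna_nucleotides.tsv", "rna_nucleotides.tsv",
             "moff_epsilon_synthetic.tsv", "mpipi_epsilon_synthetic.tsv",
             "mpipi_sigma_synthetic.tsv", "mrg_bonded_synthetic.tsv")
  vapply(files, param_checksum, character(1))
}
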