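# Coarse-grained topologies: one bead per residue (protein/RNA) or per
# nucleotide (DNA).  A cg_topology holds the beads of a single molecule plus
# its bonded-term records; a cg_system is a flattened collection of molecule
# copies with global bead indices.  Indices are 1-based throughout, the R
# convention; PDB serials coincide with bead indices on write.

aa3_to_code <- function() {
  aa <- aa_parameters()
  setNames(aa$code, aa$name3)
}

#' Simulation box
#'
#' @param lengths Numeric length-3 (or scalar, recycled) edge lengths in nm.
#' @param periodic Logical length-3 (or scalar) periodicity flags.
#' @return An object of class `cg_box`.
#' @export
cg_box <- function(lengths, periodic = TRUE) {
  lengths <- rep_len(as.numeric(lengths), 3L)
  periodic <- rep_len(as.logical(periodic), 3L)
  if (any(!is.finite(lengths)) || any(lengths <= 0))
    stop("box lengths must be positive and finite")
  structure(list(lengths = lengths, periodic = periodic), class = "cg_box")
}

# minimum-image displacement matrix (n x 3), orthorhombic boxes only
min_image <- function(d, box) {
  for (k in 1:3) if (box$periodic[k]) {
    L <- box$lengths[k]
    d[, k] <- d[, k] - L * round(d[, k] / L)
  }
  d
}

new_cg_topology <- function(beads, bonds, sequence, kind) {
  stopifnot(all(beads$mass > 0))
  structure(list(beads = beads, bonds = bonds,
                 sequence = sequence, kind = kind),
            class = "cg_topology")
}

empty_bonds <- function() {
  data.frame(kind = character(), i = integer(), j = integer(),
             k = integer(), delta = integer(), coef = character(),
             stringsAsFactors = FALSE)
}

bond_rows <- function(kind, i, j, k = NA_integer_, delta = NA_integer_, coef) {
  data.frame(kind = kind, i = as.integer(i), j = as.integer(j),
             k = as.integer(k), delta = as.integer(delta), coef = coef,
             stringsAsFactors = FALSE)
}

#' Number of beads in a topology or system
#' @param x A `cg_topology` or `cg_system`.
#' @return Integer bead count.
#' @export
n_beads <- function(x) nrow(x$beads)

#' @export
print.cg_topology <- function(x, ...) {
  cat(sprintf("cg_topology: %s, %d beads, %d bonded terms\n",
              x$kind, n_beads(x), nrow(x$bonds)))
  if (nrow(x$bonds))
    print(table(x$bonds$kind))
  invisible(x)
}

protein_bead_frame <- function(codes, force_field_tag, chain = "A") {
  aa <- aa_parameters()
  idx <- match(codes, aa$code)
  if (anyNA(idx))
    stop("unknown amino-acid code: ",
         paste(unique(codes[is.na(idx)]), collapse = ", "))
  qcol <- switch(force_field_tag,
                 hps = "charge_hps", moff = "charge_moff",
                 mpipi = "charge_mpipi",
                 stop("unknown force_field_tag: ", force_field_tag))
  data.frame(name = "CA", code = codes, type = codes,
             chain = chain, resno = seq_along(codes),
             mass = aa$mass_amu[idx], charge = aa[[qcol]][idx],
             kind = "protein", stringsAsFactors = FALSE)
}

nucleotide_bead_frame <- function(codes, kind, chain = "A") {
  reg <- if (kind == "dna") dna_parameters() else rna_parameters()
  idx <- match(codes, reg$code)
  if (anyNA(idx))
    stop("unknown nucleotide code: ",
         paste(unique(codes[is.na(idx)]), collapse = ", "))
  data.frame(name = "P", code = codes,
             type = paste0(substr(kind, 1, 1), codes),
             chain = chain, resno = seq_along(codes),
             mass = reg$mass_amu[idx], charge = reg$charge[idx],
             kind = kind, stringsAsFactors = FALSE)
}

#' Build a linear protein (or RNA) topology from a sequence
#'
#' One bead per residue with masses and charges from the bead registry;
#' consecutive residues are joined by harmonic backbone bonds.  The
#' histidine charge depends on `force_field_tag` ("hps": +0.5e,
#' "moff": +0.25e, "mpipi": +0.375e with all charges scaled by 0.75).
#'
#' @param sequence One-letter amino-acid (or, with `kind = "rna"`,
#'   nucleotide) string, or character vector of codes.
#' @param force_field_tag Charge convention: "hps", "moff" or "mpipi".
#' @param kind "protein" or "rna".
#' @param chain Chain identifier.
#' @return A `cg_topology`.
#' @export
chain_topology <- function(sequence, force_field_tag = "hps",
                           kind = c("protein", "rna"), chain = "A") {
  kind <- match.arg(kind)
  codes <- split_sequence(sequence)
  beads <- if (kind == "protein")
    protein_bead_frame(codes, force_field_tag, chain)
  else nucleotide_bead_frame(codes, "rna", chain)
  n <- length(codes)
  bonds <- if (n > 1)
    bond_rows("bond", 1:(n - 1), 2:n,
              coef = if (kind == "protein") "harmonic_ca" else "harmonic_ca")
  else empty_bonds()
  new_cg_topology(beads, bonds, paste(codes, collapse = ""), kind)
}

split_sequence <- function(sequence) {
  if (length(sequence) == 1L && nchar(sequence) > 1L)
    sequence <- strsplit(sequence, "")[[1]]
  if (!length(sequence)) stop("empty sequence")
  toupper(as.character(sequence))
}

#' Straight-chain starting coordinates
#'
#' Collinear coordinates along z with exact consecutive spacing, used to
#' initialize single-chain simulations of disordered proteins.
#'
#' @param sequence Residue sequence (validated against the bead registry).
#' @param spacing Consecutive bead distance in nm; default 0.38 nm, the
#'   typical Calpha-Calpha virtual bond length.
#' @return An n x 3 coordinate matrix (nm).
#' @export
build_straight_chain <- function(sequence, spacing = 0.38) {
  if (!is.numeric(spacing) || spacing <= 0) stop("spacing must be > 0")
  codes <- split_sequence(sequence)
  aa <- aa_parameters()
  bad <- setdiff(codes, c(aa$code, dna_parameters()$code, "U"))
  if (length(bad)) stop("unknown residue code: ", paste(bad, collapse = ", "))
  n <- length(codes)
  cbind(x = numeric(n), y = numeric(n), z = (seq_len(n) - 1) * spacing)
}

mrg_fan_deltas <- function() {
  sort(unique(stats::na.omit(mrg_bonded_raw()$delta)))
}

#' Double-stranded DNA topology for the one-bead-per-nucleotide model
#'
#' Two antiparallel strands with one bead per nucleotide.  Intra-strand
#' polynomial bonds and angles connect consecutive nucleotides; inter-strand
#' "fan bonds" connect bead i on strand 1 to the beads at offsets delta from
#' its Watson-Crick partner on strand 2, for every tabulated delta whose
#' partner exists.
#'
#' @param n_bp Number of base pairs (>= 1).
#' @param sequence Optional strand-1 sequence (5'->3'); defaults to
#'   alternating "AT"/"GC"-free poly(ACGT) repeats.
#' @return A `cg_topology` of kind "dna" with `2 * n_bp` beads.
#' @export
build_dsdna_topology <- function(n_bp, sequence = NULL) {
  if (!is.numeric(n_bp) || n_bp < 1) stop("n_bp must be >= 1")
  n_bp <- as.integer(n_bp)
  if (is.null(sequence))
    sequence <- rep_len(c("A", "C", "G", "T"), n_bp)
  s1 <- split_sequence(sequence)
  if (length(s1) != n_bp) stop("sequence length must equal n_bp")
  comp <- c(A = "T", T = "A", C = "G", G = "C")
  s2 <- rev(unname(comp[s1]))           # antiparallel complement, 5'->3'
  beads <- rbind(nucleotide_bead_frame(s1, "dna", chain = "A"),
                 nucleotide_bead_frame(s2, "dna", chain = "B"))
  beads$resno <- c(seq_len(n_bp), seq_len(n_bp))
  bonds <- empty_bonds()
  if (n_bp > 1) {
    b1 <- bond_rows("bond", 1:(n_bp - 1), 2:n_bp, coef = "mrg_bond")
    b2 <- bond_rows("bond", n_bp + 1:(n_bp - 1), n_bp + 2:n_bp,
                    coef = "mrg_bond")
    bonds <- rbind(bonds, b1, b2)
  }
  if (n_bp > 2) {
    a1 <- bond_rows("angle", 1:(n_bp - 2), 2:(n_bp - 1), 3:n_bp,
                    coef = "mrg_angle")
    a2 <- bond_rows("angle", n_bp + 1:(n_bp - 2), n_bp + 2:(n_bp - 1),
                    n_bp + 3:n_bp, coef = "mrg_angle")
    bonds <- rbind(bonds, a1, a2)
  }
  for (delta in mrg_fan_deltas()) {
    i <- seq_len(n_bp)
    p2 <- (n_bp + 1L - i) + delta       # strand-2 position of the fan partner
    ok <- p2 >= 1L & p2 <= n_bp
    if (any(ok))
      bonds <- rbind(bonds, bond_rows("fan_bond", i[ok], n_bp + p2[ok],
                                      delta = delta,
                                      coef = paste0("mrg_fan_", delta)))
  }
  new_cg_topology(beads, bonds, paste(s1, collapse = ""), "dna")
}

#' Ladder coordinates for a dsDNA topology
#'
#' Ideal B-form-like placement: 0.34 nm/bp helical rise along z, the two
#' strands offset by `width` in x.  The model is calibrated to this
#' geometry (bond and fan-bond rest lengths follow from `rise` and
#' `width`).
#'
#' @param topology A dsDNA `cg_topology` from [build_dsdna_topology()].
#' @param rise Rise per base pair, nm.
#' @param width Inter-strand separation, nm.
#' @return Coordinate matrix (nm).
#' @export
dsdna_coordinates <- function(topology, rise = 0.34, width = 1.0) {
  n <- n_beads(topology) / 2L
  z1 <- (seq_len(n) - 1) * rise
  z2 <- (n - seq_len(n)) * rise         # antiparallel: position p pairs i = n+1-p
  rbind(cbind(-width / 2, 0, z1), cbind(width / 2, 0, z2))
}

# ---- PDB I/O ----------------------------------------------------------------

#' Parse a coarse-grained (or Calpha-reducible) PDB file
#'
#' Proteins are reduced to one bead per residue at the Calpha position (an
#' error names any residue lacking a CA record); DNA/RNA nucleotides are
#' reduced to one bead at the residue centroid.  Masses and charges are
#' assigned from the bead registry; the protein charge convention follows
#' `force_field_tag`.
#'
#' @param path PDB file path.
#' @param force_field_tag "hps", "moff" or "mpipi" (protein charges).
#' @return A list with `topology` (`cg_topology`) and `coords` (nm).
#' @export
parse_cg_pdb <- function(path, force_field_tag = "hps") {
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom[pdb$atom$type %in% c("ATOM", "HETATM"), , drop = FALSE]
  aa3 <- aa3_to_code()
  dna3 <- setNames(dna_parameters()$code, dna_parameters()$name3)
  rna3 <- setNames(rna_parameters()$code, rna_parameters()$name3)
  rna1 <- setNames(rna_parameters()$code, rna_parameters()$code)
  key <- paste(at$chain, at$resno, at$insert, sep = "|")
  ukey <- unique(key)
  codes <- character(length(ukey)); kinds <- character(length(ukey))
  chains <- character(length(ukey))
  xyz <- matrix(0, length(ukey), 3)
  for (u in seq_along(ukey)) {
    rows <- which(key == ukey[u])
    resid <- at$resid[rows[1]]
    chains[u] <- at$chain[rows[1]]
    if (resid %in% names(aa3)) {
      codes[u] <- aa3[[resid]]; kinds[u] <- "protein"
      ca <- rows[at$elety[rows] == "CA"]
      if (!length(ca))
        stop(sprintf("residue %s %s%s has no CA record", resid,
                     at$chain[rows[1]], at$resno[rows[1]]))
      xyz[u, ] <- unlist(at[ca[1], c("x", "y", "z")])
    } else if (resid %in% names(dna3)) {
      codes[u] <- dna3[[resid]]; kinds[u] <- "dna"
      xyz[u, ] <- colMeans(at[rows, c("x", "y", "z")])
    } else if (resid %in% names(rna3) || resid %in% names(rna1)) {
      codes[u] <- if (resid %in% names(rna3)) rna3[[resid]] else rna1[[resid]]
      kinds[u] <- "rna"
      xyz[u, ] <- colMeans(at[rows, c("x", "y", "z")])
    } else {
      stop("unknown residue code in PDB: ", resid)
    }
  }
  kind <- unique(kinds)
  if (length(kind) != 1L)
    stop("mixed molecule kinds in one PDB; parse chains separately")
  beads <- if (kind == "protein")
    protein_bead_frame(codes, force_field_tag, chain = chains)
  else nucleotide_bead_frame(codes, kind, chain = chains)
  beads$resno <- as.integer(at$resno[match(ukey, key)])
  n <- length(codes)
  same_chain <- chains[-n] == chains[-1]
  bonds <- if (n > 1 && any(same_chain))
    bond_rows("bond", which(same_chain), which(same_chain) + 1L,
              coef = if (kind == "dna") "mrg_bond" else "harmonic_ca")
  else empty_bonds()
  topo <- new_cg_topology(beads, bonds, paste(codes, collapse = ""), kind)
  list(topology = topo, coords = xyz / 10)   # Angstrom -> nm
}

#' Write a coarse-grained topology to PDB
#'
#' One ATOM record per bead ("CA" for protein, "P" for nucleotides),
#' coordinates converted nm -> Angstrom.  A list of coordinate matrices
#' produces a multi-model file.
#'
#' @param topology `cg_topology` or `cg_system`.
#' @param coords Coordinate matrix in nm, or list thereof (multi-model).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cg_pdb <- function(topology, coords, path) {
  beads <- topology$beads
  aa <- aa_parameters(); dna <- dna_parameters(); rna <- rna_parameters()
  res3 <- ifelse(beads$kind == "protein", aa$name3[match(beads$code, aa$code)],
          ifelse(beads$kind == "dna", dna$name3[match(beads$code, dna$code)],
                 rna$name3[match(beads$code, rna$code)]))
  if (!is.list(coords)) coords <- list(coords)
  con <- file(path, "w")
  on.exit(close(con))
  multi <- length(coords) > 1L
  for (m in seq_along(coords)) {
    if (multi) writeLines(sprintf("MODEL     %4d", m), con)
    x <- coords[[m]] * 10
    lines <- sprintf("ATOM  %5d  %-3s %3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00",
                     seq_len(nrow(beads)) %% 100000L, beads$name, res3,
                     substr(beads$chain, 1, 1), beads$resno %% 10000L,
                     x[, 1], x[, 2], x[, 3])
    writeLines(lines, con)
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

# ---- systems ----------------------------------------------------------------

#' Assemble a system of molecule copies
#'
#' Flattens molecule topologies into global bead/bond tables.  `bead_ranges`
#' records, for every molecule copy, the inclusive 1-based global bead index
#' interval; the ranges partition `1:n_beads`.
#'
#' @param molecules List of `cg_topology` objects.
#' @param copies Integer copy count per molecule (>= 1).
#' @return A `cg_system`.
#' @export
make_cg_system <- function(molecules, copies) {
  if (inherits(molecules, "cg_topology")) molecules <- list(molecules)
  copies <- as.integer(rep_len(copies, length(molecules)))
  if (any(copies < 1)) stop("copy counts must be >= 1")
  beads <- list(); bonds <- list(); ranges <- list()
  offset <- 0L; row <- 0L
  for (m in seq_along(molecules)) {
    top <- molecules[[m]]
    for (cp in seq_len(copies[m])) {
      row <- row + 1L
      b <- top$beads
      b$molecule <- m; b$copy <- cp
      beads[[row]] <- b
      if (nrow(top$bonds)) {
        bd <- top$bonds
        bd$i <- bd$i + offset; bd$j <- bd$j + offset
        bd$k <- bd$k + offset
        bonds[[row]] <- bd
      }
      ranges[[row]] <- data.frame(molecule = m, copy = cp,
                                  start = offset + 1L,
                                  end = offset + nrow(b))
      offset <- offset + nrow(b)
    }
  }
  structure(list(molecules = molecules, copies = copies,
                 beads = do.call(rbind, beads),
                 bonds = if (length(bonds)) do.call(rbind, bonds)
                         else empty_bonds(),
                 bead_ranges = do.call(rbind, ranges),
                 n_beads = offset),
            class = "cg_system")
}

#' @export
print.cg_system <- function(x, ...) {
  cat(sprintf("cg_system: %d molecule copies, %d beads, %d bonded terms\n",
              nrow(x$bead_ranges), x$n_beads, nrow(x$bonds)))
  invisible(x)
}

#' Coerce a single molecule to a one-copy system
#' @param topology A `cg_topology`.
#' @return A `cg_system`.
#' @export
as_cg_system <- function(topology) {
  if (inherits(topology, "cg_system")) return(topology)
  make_cg_system(list(topology), 1L)
}

random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

#' Replicate a molecule into a periodic box
#'
#' Inserts `n_copies` rigid copies at random orientations and positions
#' (seeded RNG, deterministic), rejecting placements with any inter-copy
#' bead pair closer than `min_dist` under the minimum-image convention.
#'
#' @param molecule A `cg_topology`.
#' @param coords Reference coordinates for one copy (nm).
#' @param n_copies Number of copies.
#' @param box A `cg_box`.
#' @param min_dist Minimum allowed inter-copy bead distance, nm.
#' @param seed RNG seed.
#' @param max_attempts Insertion attempts per copy before giving up.
#' @return List with `system` (`cg_system`) and `coords` (global matrix, nm).
#' @export
replicate_into_box <- function(molecule, coords, n_copies, box,
                               min_dist = 0.5, seed = 1,
                               max_attempts = 10000L) {
  if (min_dist <= 0) stop("min_dist must be > 0")
  coords <- as.matrix(coords)
  cen <- sweep(coords, 2, colMeans(coords))
  if (2 * sqrt(max(rowSums(cen^2))) > min(box$lengths))
    stop("molecule does not fit in the box")
  nb <- nrow(coords)
  placed <- matrix(NA_real_, n_copies * nb, 3)
  n_placed <- 0L
  with_private_seed(seed, {
    for (cp in seq_len(n_copies)) {
      ok <- FALSE
      for (att in seq_len(max_attempts)) {
        cand <- cen %*% t(random_rotation())
        cand <- sweep(cand, 2, stats::runif(3) * box$lengths, `+`)
        if (n_placed > 0L) {
          prev <- placed[seq_len(n_placed * nb), , drop = FALSE]
          d2 <- min_pair_dist2(cand, prev, box)
          if (d2 < min_dist^2) next
        }
        placed[(cp - 1L) * nb + seq_len(nb), ] <- cand
        n_placed <- cp
        ok <- TRUE
        break
      }
      if (!ok)
        stop(sprintf("insertion failed: placed %d of %d copies",
                     n_placed, n_copies))
    }
  })
  list(system = make_cg_system(list(molecule), n_copies), coords = placed)
}

# smallest squared minimum-image distance between two bead sets
min_pair_dist2 <- function(a, b, box) {
  best <- Inf
  for (i in seq_len(nrow(a))) {
    d <- min_image(sweep(b, 2, a[i, ]), box)
    best <- min(best, min(rowSums(d * d)))
  }
  best
}
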