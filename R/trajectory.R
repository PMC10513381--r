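# Trajectory container and file formats.  The authoritative storage format
# is a self-describing columnar text file; exporters to multi-model PDB and
# binary CHARMM DCD are provided for interoperability.

#' Trajectory container
#'
#' @param frames List of N x 3 coordinate matrices, nm.
#' @param times Frame times, ps (strictly increasing).
#' @param box A `cg_box` (fixed across frames).
#' @param metadata Named list; must carry provenance, seed and unit-system
#'   entries for reproducibility.
#' @param energies Optional energy-log data frame.
#' @return A `cg_trajectory`.
#' @export
cg_trajectory <- function(frames, times, box, metadata = list(),
                          energies = NULL) {
  if (length(times) != length(frames))
    stop("times and frames lengths differ")
  if (length(times) > 1 && any(diff(times) <= 0))
    stop("frame times must be strictly increasing")
  structure(list(frames = frames, times = times, box = box,
                 metadata = metadata, energies = energies),
            class = "cg_trajectory")
}

#' @export
print.cg_trajectory <- function(x, ...) {
  cat(sprintf("cg_trajectory: %d frames, %d beads, t in [%g, %g] ps\n",
              length(x$frames),
              if (length(x$frames)) nrow(x$frames[[1]]) else 0,
              if (length(x$times)) min(x$times) else NA,
              if (length(x$times)) max(x$times) else NA))
  invisible(x)
}

#' @export
length.cg_trajectory <- function(x) length(x$frames)

#' Write / read the columnar text trajectory format
#'
#' Lossless round trip of positions (to the stored 9-significant-digit
#' precision), box and time.  Metadata (provenance, seed, units) is
#' mandatory; reading a file without it is rejected.
#'
#' @param trajectory A `cg_trajectory`.
#' @param path File path.
#' @return `write_trajectory`: `path` invisibly; `read_trajectory`: a
#'   `cg_trajectory`.
#' @export
write_trajectory <- function(trajectory, path) {
  md <- trajectory$metadata
  for (need in c("provenance", "seed", "units"))
    if (is.null(md[[need]]))
      stop("trajectory metadata lacks required entry: ", need)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# slabsim-trajectory v1", con)
  for (k in names(md))
    writeLines(sprintf("# meta %s: %s", k, paste(md[[k]], collapse = " ")), con)
  writeLines(sprintf("# box %.9g %.9g %.9g periodic %d %d %d",
                     trajectory$box$lengths[1], trajectory$box$lengths[2],
                     trajectory$box$lengths[3],
                     as.integer(trajectory$box$periodic[1]),
                     as.integer(trajectory$box$periodic[2]),
                     as.integer(trajectory$box$periodic[3])), con)
  for (f in seq_along(trajectory$frames)) {
    m <- trajectory$frames[[f]]
    writeLines(sprintf("FRAME %d %.9g %d", f, trajectory$times[f], nrow(m)), con)
    writeLines(sprintf("%.9g %.9g %.9g", m[, 1], m[, 2], m[, 3]), con)
  }
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  lines <- readLines(path)
  if (!length(lines) || lines[1] != "# slabsim-trajectory v1")
    stop("not a slabsim trajectory file")
  meta_lines <- grep("^# meta ", lines, value = TRUE)
  md <- list()
  for (ln in meta_lines) {
    kv <- sub("^# meta ", "", ln)
    key <- sub(":.*$", "", kv)
    md[[key]] <- sub("^[^:]*: ", "", kv)
  }
  for (need in c("provenance", "seed", "units"))
    if (is.null(md[[need]]))
      stop("trajectory file lacks required metadata: ", need)
  boxln <- grep("^# box ", lines, value = TRUE)
  if (length(boxln) != 1) stop("missing box record")
  bv <- strsplit(boxln, " +")[[1]]
  box <- cg_box(as.numeric(bv[3:5]), as.logical(as.integer(bv[7:9])))
  starts <- grep("^FRAME ", lines)
  frames <- list(); times <- numeric()
  for (s in seq_along(starts)) {
    hdr <- strsplit(lines[starts[s]], " +")[[1]]
    n <- as.integer(hdr[4])
    rows <- lines[(starts[s] + 1):(starts[s] + n)]
    vals <- suppressWarnings(
      matrix(as.numeric(unlist(strsplit(rows, " "))), ncol = 3, byrow = TRUE))
    if (anyNA(vals) || nrow(vals) != n)
      stop("corrupted frame ", s)
    frames[[s]] <- vals
    times[s] <- as.numeric(hdr[3])
  }
  cg_trajectory(frames, times, box, md)
}

#' Export a trajectory to multi-model PDB
#'
#' Frames become MODEL records loadable by [parse_cg_pdb()] (frame 1) and
#' standard viewers.
#'
#' @param trajectory A `cg_trajectory`.
#' @param topology The matching `cg_topology` / `cg_system`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
trajectory_to_pdb <- function(trajectory, topology, path) {
  write_cg_pdb(topology, trajectory$frames, path)
}

#' Export a trajectory to binary CHARMM DCD
#'
#' Minimal single-precision DCD writer (coordinates in Angstrom) for
#' interoperability with standard analysis tools.
#'
#' @param trajectory A `cg_trajectory`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
trajectory_to_dcd <- function(trajectory, path) {
  nfrm <- length(trajectory$frames)
  natom <- nrow(trajectory$frames[[1]])
  con <- file(path, "wb")
  on.exit(close(con))
  rec <- function(writer) {
    # Fortran unformatted record: byte count, payload, byte count
    tmp <- raw()
    tcon <- rawConnection(tmp, "wb")
    writer(tcon)
    payload <- rawConnectionValue(tcon)
    close(tcon)
    writeBin(length(payload), con, size = 4)
    writeBin(payload, con)
    writeBin(length(payload), con, size = 4)
  }
  icntrl <- integer(20)
  icntrl[1] <- nfrm; icntrl[2] <- 1L; icntrl[3] <- 1L; icntrl[4] <- nfrm
  icntrl[20] <- 24L
  rec(function(c2) {
    writeChar("CORD", c2, nchars = 4, eos = NULL)
    writeBin(icntrl, c2, size = 4)
  })
  rec(function(c2) {
    writeBin(1L, c2, size = 4)
    writeChar(formatC("written by slabsim", width = -80), c2, nchars = 80,
              eos = NULL)
  })
  rec(function(c2) writeBin(as.integer(natom), c2, size = 4))
  for (f in trajectory$frames) {
    a <- f * 10                          # nm -> Angstrom
    for (d in 1:3)
      rec(function(c2) writeBin(as.numeric(a[, d]), c2, size = 4))
  }
  invisible(path)
}
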