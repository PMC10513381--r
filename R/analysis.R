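# Condensate and polymer observables: radius of gyration, contact-network
# clustering, slab density profiles, coexistence densities, critical-point
# fitting (3D-Ising exponent frozen), and persistence length.

#' Mass-weighted radius of gyration
#'
#' @param coords n x 3 coordinate matrix, nm (unwrapped / whole molecule).
#' @param masses Bead masses, amu (> 0).
#' @return Rg in nm.
#' @export
radius_of_gyration <- function(coords, masses = rep(1, nrow(coords))) {
  coords <- as.matrix(coords)
  if (!nrow(coords)) stop("empty selection")
  if (any(masses <= 0)) stop("masses must be > 0")
  com <- colSums(coords * masses) / sum(masses)
  d <- sweep(coords, 2, com)
  sqrt(sum(masses * rowSums(d * d)) / sum(masses))
}

# make each molecule copy whole across periodic boundaries by walking its
# bond graph from the first bead and minimum-imaging every step
unwrap_system <- function(pos, system, box) {
  bonds <- system$bonds[system$bonds$kind == "bond", , drop = FALSE]
  ranges <- system$bead_ranges
  for (r in seq_len(nrow(ranges))) {
    idx <- ranges$start[r]:ranges$end[r]
    if (length(idx) == 1L) next
    sub <- bonds[bonds$i %in% idx & bonds$j %in% idx, , drop = FALSE]
    if (!nrow(sub)) next
    seen <- rep(FALSE, length(idx)); names(seen) <- idx
    queue <- idx[1]; seen[as.character(idx[1])] <- TRUE
    while (length(queue)) {
      b <- queue[1]; queue <- queue[-1]
      nb <- c(sub$j[sub$i == b], sub$i[sub$j == b])
      for (x in nb) if (!seen[as.character(x)]) {
        d <- min_image(matrix(pos[x, ] - pos[b, ], 1), box)
        pos[x, ] <- pos[b, ] + d
        seen[as.character(x)] <- TRUE
        queue <- c(queue, x)
      }
    }
  }
  pos
}

molecule_coms <- function(pos, system, box, unwrap = TRUE) {
  if (unwrap) pos <- unwrap_system(pos, system, box)
  ranges <- system$bead_ranges
  m <- system$beads$mass
  t(vapply(seq_len(nrow(ranges)), function(r) {
    idx <- ranges$start[r]:ranges$end[r]
    colSums(pos[idx, , drop = FALSE] * m[idx]) / sum(m[idx])
  }, numeric(3)))
}

#' Largest cluster of molecules in a contact network
#'
#' Molecules are nodes; an edge joins two molecules whose center-of-mass
#' minimum-image distance is below `cutoff`.  Returns the molecule-copy
#' indices of the largest connected component; ties are broken in favour
#' of the component containing the lowest molecule index.
#'
#' @param positions N x 3 bead coordinates, nm.
#' @param system A `cg_system`.
#' @param box A `cg_box`.
#' @param cutoff Contact cutoff on COM distances, nm (default 5).
#' @return Sorted integer vector of molecule-copy indices (1-based).
#' @export
identify_largest_cluster <- function(positions, system, box, cutoff = 5) {
  if (cutoff <= 0) stop("cutoff must be > 0")
  com <- molecule_coms(positions, system, box)
  n <- nrow(com)
  if (n == 1L) return(1L)
  ii <- rep.int(seq_len(n - 1L), times = (n - 1L):1L)
  jj <- sequence((n - 1L):1L, from = 2:n)
  d <- min_image(com[ii, , drop = FALSE] - com[jj, , drop = FALSE], box)
  touch <- rowSums(d * d) < cutoff^2
  g <- igraph::graph_from_edgelist(cbind(ii[touch], jj[touch]),
                                   directed = FALSE)
  g <- igraph::add_vertices(g, max(0, n - igraph::vcount(g)))
  comp <- igraph::components(g)
  best <- which(comp$csize == max(comp$csize))
  if (length(best) > 1L) {
    first_member <- vapply(best, function(b) min(which(comp$membership == b)),
                           numeric(1))
    best <- best[which.min(first_member)]
  }
  sort(which(comp$membership == best))
}

#' Slab density profile along z
#'
#' Frame-averaged mass density profile along the box z axis (the slab's
#' elongated axis).  With `center_on_cluster`, every frame is first
#' translated so the largest cluster's center of mass sits at z = 0 (the
#' box center); bins span [-Lz/2, Lz/2].  Densities are mg/mL.
#'
#' @param trajectory A `cg_trajectory`, or list of position matrices.
#' @param system A `cg_system`.
#' @param box A `cg_box` (taken from the trajectory if absent).
#' @param bin_width Bin width, nm.
#' @param center_on_cluster Center the largest cluster each frame?
#' @param cluster_cutoff Contact cutoff for the cluster search, nm.
#' @param frames Frame indices to use; default the second half.
#' @return A `density_profile` with `z` (bin centers, nm), `density`
#'   (mg/mL), `bin_width`, `n_frames`, `box`.
#' @export
density_profile <- function(trajectory, system, box = NULL, bin_width = 1,
                            center_on_cluster = TRUE, cluster_cutoff = 5,
                            frames = NULL) {
  if (bin_width <= 0) stop("bin_width must be > 0")
  flist <- if (inherits(trajectory, "cg_trajectory")) trajectory$frames
           else trajectory
  if (is.null(box)) box <- trajectory$box
  if (box$lengths[3] < max(box$lengths))
    stop("slab analysis expects the elongated axis to be z")
  if (is.null(frames))
    frames <- seq.int(max(1L, floor(length(flist) / 2) + 1L), length(flist))
  Lz <- box$lengths[3]
  edges <- seq(-Lz / 2, Lz / 2, by = bin_width)
  if (abs(edges[length(edges)] - Lz / 2) > 1e-9)
    edges <- c(edges, Lz / 2)           # last bin absorbs the remainder
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  vols <- diff(edges) * box$lengths[1] * box$lengths[2]
  m <- system$beads$mass
  acc <- numeric(length(mids))
  for (f in frames) {
    pos <- flist[[f]]
    if (center_on_cluster) {
      cl <- identify_largest_cluster(pos, system, box, cluster_cutoff)
      com <- molecule_coms(pos, system, box)
      shift <- colSums(com[cl, , drop = FALSE]) / length(cl)
      pos[, 3] <- pos[, 3] - shift[3]
    }
    z <- pos[, 3] - Lz * floor(pos[, 3] / Lz + 0.5)   # wrap to [-Lz/2, Lz/2)
    bin <- pmin(findInterval(z, edges, rightmost.closed = TRUE),
                length(mids))
    acc <- acc + as.numeric(rowsum(m, factor(bin, levels = seq_along(mids))))
  }
  dens <- acc / length(frames) / vols * .amu_nm3_to_mg_mL
  structure(list(z = mids, density = dens, bin_width = bin_width,
                 n_frames = length(frames), box = box),
            class = "density_profile")
}

#' @export
print.density_profile <- function(x, ...) {
  cat(sprintf("density_profile: %d bins of %.3g nm, %d frames, peak %.3g mg/mL\n",
              length(x$z), x$bin_width, x$n_frames, max(x$density)))
  invisible(x)
}

#' @export
plot.density_profile <- function(x, ...) {
  plot(x$z, x$density, type = "l", xlab = "z (nm)",
       ylab = "density (mg/mL)", ...)
  abline(v = 0, lty = 3)
  invisible(x)
}

#' Coexistence densities from a slab profile
#'
#' Dense-phase density is the mean over |z| < `dense_halfwidth` (5 nm for
#' HPS-style slabs, 10 nm for MOFF-style); dilute-phase density the mean
#' over |z| > `dilute_min_z` (50 nm in the standard protocol).
#'
#' @param profile A `density_profile`.
#' @param dense_halfwidth Half-width of the dense window, nm.
#' @param dilute_min_z Inner edge of the dilute window, nm.
#' @param temperature Temperature label to attach, K.
#' @return A `coexistence_point`: list(temperature, rho_dilute, rho_dense).
#' @export
coexistence_densities <- function(profile, dense_halfwidth = 5,
                                  dilute_min_z = 50, temperature = NA_real_) {
  Lz <- profile$box$lengths[3]
  if (!(dense_halfwidth < dilute_min_z && dilute_min_z < Lz / 2))
    stop("need dense_halfwidth < dilute_min_z < half the box z extent")
  dense <- abs(profile$z) < dense_halfwidth
  dilute <- abs(profile$z) > dilute_min_z
  if (!any(dense) || !any(dilute)) stop("empty analysis window")
  structure(list(temperature = temperature,
                 rho_dense = mean(profile$density[dense]),
                 rho_dilute = mean(profile$density[dilute])),
            class = "coexistence_point")
}

#' Fit the critical point of a coexistence curve
#'
#' Nonlinear least squares of rho_dense - rho_dilute = A (Tc - T)^beta
#' with the critical exponent frozen at the 3D-Ising value beta = 0.325.
#' Initial values: Tc = max(T) + 20 K, A from the coldest point.
#'
#' @param points Data frame with columns `temperature`, `rho_dilute`,
#'   `rho_dense` (or a list of `coexistence_point`s).
#' @param beta Frozen critical exponent.
#' @return A `critical_fit` with methods `print`, `summary`, `coef`,
#'   `predict`, `plot`, `residuals`.
#' @export
fit_critical_point <- function(points, beta = 0.325) {
  if (is.list(points) && !is.data.frame(points) &&
      inherits(points[[1]], "coexistence_point"))
    points <- do.call(rbind, lapply(points, function(p)
      data.frame(temperature = p$temperature, rho_dilute = p$rho_dilute,
                 rho_dense = p$rho_dense)))
  if (nrow(points) < 2) stop("need at least 2 coexistence points")
  if (length(unique(points$temperature)) < 2)
    stop("degenerate points: all at the same temperature")
  drho <- points$rho_dense - points$rho_dilute
  if (any(drho < 0)) stop("rho_dense must be >= rho_dilute")
  Tmax <- max(points$temperature)
  Tc0 <- Tmax + 20
  cold <- which.min(points$temperature)
  A0 <- drho[cold] / (Tc0 - points$temperature[cold])^beta
  df <- data.frame(T = points$temperature, drho = drho)
  fit <- minpack.lm::nlsLM(drho ~ A * (Tc - T)^beta, data = df,
                           start = list(A = A0, Tc = Tc0),
                           lower = c(A = 0, Tc = Tmax + 1e-6),
                           control = minpack.lm::nls.lm.control(maxiter = 500))
  co <- stats::coef(fit)
  structure(list(Tc = unname(co["Tc"]), A = unname(co["A"]), beta = beta,
                 fit = fit, data = points,
                 residuals = stats::residuals(fit)),
            class = "critical_fit")
}

#' @export
print.critical_fit <- function(x, ...) {
  cat(sprintf("critical_fit: Tc = %.2f K, A = %.4g, beta = %.3f (frozen)\n",
              x$Tc, x$A, x$beta))
  invisible(x)
}

#' @export
summary.critical_fit <- function(object, ...) {
  cat(sprintf("Coexistence-curve fit, rho_H - rho_L = A (Tc - T)^beta\n"))
  print(object)
  cat(sprintf("  %d points, T in [%.4g, %.4g] K, RMS residual %.4g mg/mL\n",
              nrow(object$data), min(object$data$temperature),
              max(object$data$temperature),
              sqrt(mean(object$residuals^2))))
  invisible(object)
}

#' @export
coef.critical_fit <- function(object, ...) {
  c(Tc = object$Tc, A = object$A, beta = object$beta)
}

#' @export
residuals.critical_fit <- function(object, ...) object$residuals

#' @export
predict.critical_fit <- function(object, newdata = NULL, ...) {
  T <- if (is.null(newdata)) object$data$temperature
       else if (is.data.frame(newdata)) newdata$temperature
       else as.numeric(newdata)
  ifelse(T < object$Tc, object$A * (object$Tc - T)^object$beta, 0)
}

#' @export
plot.critical_fit <- function(x, ...) {
  d <- x$data
  mid <- (d$rho_dense + d$rho_dilute) / 2
  plot(c(d$rho_dilute, d$rho_dense), rep(d$temperature, 2),
       xlab = "density (mg/mL)", ylab = "T (K)", ...)
  Tg <- seq(min(d$temperature), x$Tc, length.out = 200)
  drho <- predict(x, Tg)
  midg <- stats::approx(d$temperature, mid, xout = Tg, rule = 2)$y
  lines(midg - drho / 2, Tg, col = 2)
  lines(midg + drho / 2, Tg, col = 2)
  points((max(midg) + min(midg)) / 2, x$Tc, pch = 17, col = 2)
  invisible(x)
}

#' Polymer persistence length from bond-vector correlations
#'
#' C(n) = <u_i . u_{i+n}> averaged over positions i and frames, with u the
#' unit bond vectors of the chain; log C(n) is fitted linearly over
#' `fit_range` and lp = -b / slope with b the mean bond length.  A
#' perfectly straight chain has C(n) = 1 and infinite lp.
#'
#' @param frames List of coordinate matrices (or a `cg_trajectory`).
#' @param chain Integer bead indices of one chain, in order.
#' @param fit_range Bond separations n used in the fit.
#' @return A `persistence_fit` with methods `print`, `coef`, `plot`.
#' @export
persistence_length <- function(frames, chain, fit_range = 2:20) {
  if (inherits(frames, "cg_trajectory")) frames <- frames$frames
  if (length(chain) < 3) stop("chain must have at least 3 beads")
  nb <- length(chain) - 1L
  nmax <- min(max(fit_range), nb - 1L)
  corr <- numeric(nmax + 1L); cnt <- numeric(nmax + 1L)
  blen <- 0; bn <- 0
  for (pos in frames) {
    b <- diff(pos[chain, , drop = FALSE])
    bl <- sqrt(rowSums(b * b))
    u <- b / bl
    blen <- blen + sum(bl); bn <- bn + nb
    for (n in 0:nmax) {
      i <- seq_len(nb - n)
      corr[n + 1L] <- corr[n + 1L] + sum(rowSums(u[i, , drop = FALSE] *
                                                 u[i + n, , drop = FALSE]))
      cnt[n + 1L] <- cnt[n + 1L] + length(i)
    }
  }
  C <- corr / cnt
  b_mean <- blen / bn
  ns <- 0:nmax
  fit_range <- fit_range[fit_range <= nmax]
  pos_ok <- C[fit_range + 1L] > 0
  if (!all(pos_ok)) {
    warning("non-positive C(n) inside fit range; shrinking range")
    keep <- seq_len(max(0, which.min(c(pos_ok, FALSE)) - 1L))
    fit_range <- fit_range[keep]
  }
  if (length(fit_range) < 2) {
    lp <- NA_real_; slope <- NA_real_
  } else if (all(abs(C[fit_range + 1L] - 1) < 1e-12)) {
    lp <- Inf; slope <- 0
  } else {
    fit <- stats::lm(log(C[fit_range + 1L]) ~ fit_range)
    slope <- unname(stats::coef(fit)[2])
    lp <- if (slope >= 0) Inf else -b_mean / slope
  }
  structure(list(mean_bond_length = b_mean, n = ns, correlation = C,
                 lp = lp, slope = slope, fit_range = fit_range),
            class = "persistence_fit")
}

#' @export
print.persistence_fit <- function(x, ...) {
  cat(sprintf("persistence_fit: lp = %s nm (mean bond %.4g nm, fit n in [%d, %d])\n",
              if (is.finite(x$lp)) sprintf("%.3g", x$lp) else "Inf (rigid)",
              x$mean_bond_length,
              min(x$fit_range), max(x$fit_range)))
  invisible(x)
}

#' @export
coef.persistence_fit <- function(object, ...) {
  c(lp = object$lp, bond = object$mean_bond_length, slope = object$slope)
}

#' @export
plot.persistence_fit <- function(x, ...) {
  keep <- x$correlation > 0
  plot(x$n[keep], log(x$correlation[keep]), xlab = "bond separation n",
       ylab = "log C(n)", ...)
  if (is.finite(x$lp))
    abline(0, x$slope, col = 2)
  invisible(x)
}

#' Write a coexistence table as columnar text
#'
#' @param points Data frame of coexistence points (or list of
#'   `coexistence_point`).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_coexistence_table <- function(points, path) {
  if (!is.data.frame(points))
    points <- do.call(rbind, lapply(points, function(p)
      data.frame(temperature = p$temperature, rho_dilute = p$rho_dilute,
                 rho_dense = p$rho_dense)))
  utils::write.table(format(points, digits = 6), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
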