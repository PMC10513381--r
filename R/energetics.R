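# Energy and force evaluation under periodic boundary conditions.
#
# A system + force field + box are "compiled" once into flat numeric arrays:
# bonded term tables and, for every non-excluded bead pair, the resolved
# pair-potential parameters grouped by functional form.  Energies are then
# vectorized over those arrays; forces are the exact analytic negative
# gradient of the implemented energy.  All nonbonded forms use energy-shifted
# truncation so the potential is continuous at its cutoff.

.r_guard <- 1e-4   # nm; closer approaches in divergent terms raise an error

# ---- raw pair forms (unshifted), vectorized over r --------------------------

pair_raw <- function(form, r, p) {
  switch(form,
    ashbaugh_hatch = {
      sr6 <- (p$sigma / r)^6
      phi <- 4 * p$epsilon * (sr6^2 - sr6)
      rmin <- 2^(1/6) * p$sigma
      ifelse(r <= rmin, phi + (1 - p$lambda) * p$epsilon, p$lambda * phi)
    },
    wang_frenkel = {
      R <- 3 * p$sigma
      rs <- (R / p$sigma)^(2 * p$mu)
      alpha <- 2 * p$nu * rs *
        ((1 + 2 * p$nu) / (2 * p$nu * (rs - 1)))^(2 * p$nu + 1)
      A <- (p$sigma / r)^(2 * p$mu)
      B <- (R / r)^(2 * p$mu)
      p$epsilon * alpha * (A - 1) * (B - 1)^(2 * p$nu)
    },
    moff_contact = {
      alpha <- p$eps_rep * p$sigma^12
      alpha / r^12 + (p$epsilon / 2) * (1 + tanh(p$eta * (p$r0 - r)))
    },
    excluded_volume = {
      p$eps_rep * (p$sigma / r)^12
    },
    debye_huckel = {
      p$qq * exp(-r / p$ld) / r
    },
    none = rep(0, length(r)),
    stop("unknown pair form: ", form))
}

pair_raw_dudr <- function(form, r, p) {
  switch(form,
    ashbaugh_hatch = {
      sr6 <- (p$sigma / r)^6
      dphi <- 4 * p$epsilon * (-12 * sr6^2 + 6 * sr6) / r
      rmin <- 2^(1/6) * p$sigma
      ifelse(r <= rmin, dphi, p$lambda * dphi)
    },
    wang_frenkel = {
      R <- 3 * p$sigma
      rs <- (R / p$sigma)^(2 * p$mu)
      alpha <- 2 * p$nu * rs *
        ((1 + 2 * p$nu) / (2 * p$nu * (rs - 1)))^(2 * p$nu + 1)
      A <- (p$sigma / r)^(2 * p$mu)
      B <- (R / r)^(2 * p$mu)
      dA <- -2 * p$mu * A / r
      dB <- -2 * p$mu * B / r
      p$epsilon * alpha *
        (dA * (B - 1)^(2 * p$nu) +
         (A - 1) * 2 * p$nu * (B - 1)^(2 * p$nu - 1) * dB)
    },
    moff_contact = {
      alpha <- p$eps_rep * p$sigma^12
      -12 * alpha / r^13 - (p$epsilon * p$eta / 2) / cosh(p$eta * (p$r0 - r))^2
    },
    excluded_volume = {
      -12 * p$eps_rep * p$sigma^12 / r^13
    },
    debye_huckel = {
      -p$qq * exp(-r / p$ld) * (1 / p$ld + 1 / r) / r
    },
    none = rep(0, length(r)),
    stop("unknown pair form: ", form))
}

#' Evaluate a single nonbonded pair potential
#'
#' Scalar (vectorized over `r`) energy of one nonbonded pair under
#' energy-shifted truncation: zero at and beyond the cutoff, continuous
#' there.
#'
#' @param form One of "ashbaugh_hatch", "wang_frenkel", "moff_contact",
#'   "excluded_volume", "debye_huckel".
#' @param params Named list of parameters for the pair.  Ashbaugh-Hatch:
#'   `epsilon`, `sigma`, `lambda`; Wang-Frenkel: `epsilon`, `sigma`, `nu`,
#'   `mu`; moff_contact: `epsilon`, `sigma`, `eta`, `r0`, `eps_rep`;
#'   excluded_volume: `eps_rep`, `sigma`; debye_huckel: either `qq`
#'   (premultiplied charge product, kJ nm/mol) or `q1`, `q2`,
#'   `dielectric`, plus `ld` (Debye length, nm).
#' @param r Separation(s), nm (> 0).
#' @param cutoff Cutoff, nm; `Inf` disables truncation.
#' @return Energy in kJ/mol, zero for `r >= cutoff`.
#' @export
evaluate_pair_potential <- function(form, params, r, cutoff = Inf) {
  if (any(r <= 0)) stop("r must be > 0")
  if (form == "debye_huckel" && is.null(params$qq))
    params$qq <- params$q1 * params$q2 * .coulomb_k / params$dielectric
  u <- pair_raw(form, r, params)
  if (is.finite(cutoff)) {
    u <- u - pair_raw(form, cutoff, params)
    u[r >= cutoff] <- 0
  }
  u
}

# ---- compilation ------------------------------------------------------------

# 1-2 and 1-3 exclusion keys derived from the bond graph (fan bonds are not
# part of the graph; their bead pairs stay in the nonbonded set)
exclusion_keys <- function(bonds, N) {
  b <- bonds[bonds$kind == "bond", , drop = FALSE]
  keys <- c()
  if (nrow(b)) {
    i <- pmin(b$i, b$j); j <- pmax(b$i, b$j)
    keys <- (i - 1) * N + j
    adj <- split(c(b$j, b$i), c(b$i, b$j))
    for (centre in names(adj)) {
      nb <- adj[[centre]]
      if (length(nb) > 1) {
        cmb <- utils::combn(sort(nb), 2)
        keys <- c(keys, (cmb[1, ] - 1) * N + cmb[2, ])
      }
    }
  }
  unique(keys)
}

#' Compile a system + force field into fast evaluation tables
#'
#' Resolves every bonded term and every non-excluded bead pair into flat
#' parameter arrays grouped by functional form.  The compiled object is
#' what the integrators and the energy routines consume.
#'
#' @param system A `cg_system` (or `cg_topology`).
#' @param ff A `force_field`.
#' @param box A `cg_box`.
#' @return An object of class `cg_compiled`.
#' @export
compile_forces <- function(system, ff, box) {
  system <- as_cg_system(system)
  N <- system$n_beads
  if (N > 3000)
    stop("reference engine is desk-scale; systems above 3000 beads unsupported")
  beads <- system$beads
  bonds <- system$bonds

  # bonded tables
  bt <- list(harm = NULL, poly_bond = NULL, poly_fan = NULL, angle = NULL)
  if (nrow(bonds)) {
    for (key in unique(bonds$coef)) {
      set <- ff$bonded[[key]]
      if (is.null(set)) stop("no bonded coefficients for key: ", key)
      rows <- bonds[bonds$coef == key, , drop = FALSE]
      if (set$form == "harmonic") {
        bt$harm <- rbind(bt$harm,
          cbind(i = rows$i, j = rows$j, k = set$k, r0 = set$r0))
      } else if (rows$kind[1] == "angle") {
        bt$angle <- rbind(bt$angle,
          cbind(i = rows$i, j = rows$j, k = rows$k,
                k2 = set$k["k2"], k3 = set$k["k3"], k4 = set$k["k4"],
                x0 = set$x0))
      } else {
        tab <- cbind(i = rows$i, j = rows$j,
                     k2 = set$k["k2"], k3 = set$k["k3"], k4 = set$k["k4"],
                     x0 = set$x0)
        if (rows$kind[1] == "fan_bond") bt$poly_fan <- rbind(bt$poly_fan, tab)
        else bt$poly_bond <- rbind(bt$poly_bond, tab)
      }
    }
  }

  # candidate nonbonded pairs (i < j, exclusions removed)
  groups <- list(); el <- NULL
  if (N > 1) {
    ii <- rep.int(seq_len(N - 1L), times = (N - 1L):1L)
    jj <- sequence((N - 1L):1L, from = 2:N)
    keep <- !((ii - 1) * N + jj) %in% exclusion_keys(bonds, N)
    ii <- ii[keep]; jj <- jj[keep]
    kinds <- beads$kind; types <- beads$type
    k1 <- kinds[ii]; k2 <- kinds[jj]
    scope <- ifelse(k1 <= k2, paste(k1, k2, sep = "|"),
                    paste(k2, k1, sep = "|"))
    for (sc in unique(scope)) {
      tab <- ff$pair[[sc]]
      if (is.null(tab)) stop("no pair table for molecule kinds ", sc)
      sel <- scope == sc
      gi <- ii[sel]; gj <- jj[sel]
      ti <- types[gi]; tj <- types[gj]
      p <- switch(tab$form,
        ashbaugh_hatch = list(
          epsilon = tab$epsilon,
          sigma = (tab$sigma[ti] + tab$sigma[tj]) / 2,
          lambda = tab$mu * (tab$lambda[ti] + tab$lambda[tj]) / 2 - tab$delta),
        wang_frenkel = list(
          epsilon = tab$epsilon[cbind(ti, tj)],
          sigma = tab$sigma[cbind(ti, tj)],
          nu = tab$nu, mu = tab$mu),
        moff_contact = list(
          epsilon = tab$epsilon[cbind(ti, tj)],
          sigma = (tab$sigma[ti] + tab$sigma[tj]) / 2,
          eta = tab$eta, r0 = tab$r0, eps_rep = tab$eps_rep),
        excluded_volume = list(
          eps_rep = tab$eps_rep,
          sigma = (tab$sigma[ti] + tab$sigma[tj]) / 2),
        none = list(zero = 0),
        stop("unknown pair form: ", tab$form))
      if (any(vapply(p, function(v) anyNA(v), logical(1))))
        stop("missing pair parameters for some ", sc, " type pair")
      cutoff <- ff$pair_cutoff
      groups[[sc]] <- list(form = tab$form, ii = gi, jj = gj, pars = p,
                           cutoff = cutoff,
                           shift = pair_raw(tab$form, cutoff, p))
    }
    q <- beads$charge
    qq <- q[ii] * q[jj]
    has_q <- qq != 0
    if (any(has_q)) {
      elspec <- ff$electrostatics
      p <- list(qq = qq[has_q] * .coulomb_k / elspec$dielectric,
                ld = elspec$debye_length)
      el <- list(form = "debye_huckel", ii = ii[has_q], jj = jj[has_q],
                 pars = p, cutoff = elspec$cutoff,
                 shift = pair_raw("debye_huckel", elspec$cutoff, p))
    }
  }
  structure(list(N = N, box = box, mass = beads$mass, bt = bt,
                 groups = groups, el = el, system = system, ff = ff),
            class = "cg_compiled")
}

# subset a pair group's parameter vectors to pair indices idx
group_subset <- function(g, idx) {
  g$pars <- lapply(g$pars, function(v) if (length(v) > 1L) v[idx] else v)
  g$shift <- if (length(g$shift) > 1L) g$shift[idx] else g$shift
  g$ii <- g$ii[idx]; g$jj <- g$jj[idx]
  g
}

accumulate_forces <- function(F, idx_i, idx_j, fvec) {
  # fvec: per-pair force on bead i (i gets +, j gets -)
  n <- length(idx_i)
  if (n < 64L) {
    for (p in seq_len(n)) {
      i <- idx_i[p]; j <- idx_j[p]
      F[i, ] <- F[i, ] + fvec[p, ]
      F[j, ] <- F[j, ] - fvec[p, ]
    }
    return(F)
  }
  for (d in 1:3) {
    acc <- rowsum(c(fvec[, d], -fvec[, d]), c(idx_i, idx_j))
    rows <- as.integer(rownames(acc))
    F[rows, d] <- F[rows, d] + acc[, 1]
  }
  F
}

pair_group_ef <- function(g, pos, box, want_forces) {
  d <- min_image(pos[g$ii, , drop = FALSE] - pos[g$jj, , drop = FALSE], box)
  r2 <- rowSums(d * d)
  within <- r2 < g$cutoff^2
  if (!any(within))
    return(list(e = 0, F = NULL, ii = integer(), jj = integer()))
  g2 <- group_subset(g, within)
  r <- sqrt(r2[within])
  if (g2$form != "none" && any(r < .r_guard))
    stop("bead overlap: pair separation below ", .r_guard, " nm")
  e <- sum(pair_raw(g2$form, r, g2$pars) - g2$shift)
  Fp <- NULL
  if (want_forces) {
    fmag <- -pair_raw_dudr(g2$form, r, g2$pars) / r   # per unit d
    Fp <- d[within, , drop = FALSE] * fmag
  }
  list(e = e, F = Fp, ii = g2$ii, jj = g2$jj)
}

bonded_ef <- function(bt, pos, box, want_forces, F) {
  e_bond <- 0; e_angle <- 0; e_fan <- 0
  if (!is.null(bt$harm)) {
    tb <- bt$harm
    d <- min_image(pos[tb[, "i"], , drop = FALSE] -
                   pos[tb[, "j"], , drop = FALSE], box)
    r <- sqrt(rowSums(d * d))
    x <- r - tb[, "r0"]
    e_bond <- e_bond + sum(0.5 * tb[, "k"] * x^2)
    if (want_forces) {
      fmag <- -(tb[, "k"] * x) / r
      F <- accumulate_forces(F, tb[, "i"], tb[, "j"], d * fmag)
    }
  }
  for (kind in c("poly_bond", "poly_fan")) {
    tb <- bt[[kind]]
    if (is.null(tb)) next
    d <- min_image(pos[tb[, "i"], , drop = FALSE] -
                   pos[tb[, "j"], , drop = FALSE], box)
    r <- sqrt(rowSums(d * d))
    x <- r - tb[, "x0"]
    e <- sum(tb[, "k2"] * x^2 + tb[, "k3"] * x^3 + tb[, "k4"] * x^4)
    if (kind == "poly_bond") e_bond <- e_bond + e else e_fan <- e_fan + e
    if (want_forces) {
      du <- 2 * tb[, "k2"] * x + 3 * tb[, "k3"] * x^2 + 4 * tb[, "k4"] * x^3
      F <- accumulate_forces(F, tb[, "i"], tb[, "j"], d * (-du / r))
    }
  }
  if (!is.null(bt$angle)) {
    tb <- bt$angle
    u <- min_image(pos[tb[, "i"], , drop = FALSE] -
                   pos[tb[, "j"], , drop = FALSE], box)
    v <- min_image(pos[tb[, "k"], , drop = FALSE] -
                   pos[tb[, "j"], , drop = FALSE], box)
    nu <- sqrt(rowSums(u * u)); nv <- sqrt(rowSums(v * v))
    cth <- pmin(1, pmax(-1, rowSums(u * v) / (nu * nv)))
    th <- acos(cth) * 180 / pi                    # degrees
    x <- th - tb[, "x0"]
    e_angle <- e_angle +
      sum(tb[, "k2"] * x^2 + tb[, "k3"] * x^3 + tb[, "k4"] * x^4)
    if (want_forces) {
      # dU/dtheta_rad; chain rule for the degree-tabulated polynomial
      du <- (2 * tb[, "k2"] * x + 3 * tb[, "k3"] * x^2 +
             4 * tb[, "k4"] * x^3) * 180 / pi
      sth <- sqrt(pmax(0, 1 - cth^2))
      fac <- ifelse(sth < 1e-8, 0, du / sth)      # F = 0 at exactly straight
      uh <- u / nu; vh <- v / nv
      gi <- (vh - cth * uh) / nu * fac            # dtheta/dr_i * (-1/sin) folded
      gk <- (uh - cth * vh) / nv * fac
      F <- accumulate_forces(F, tb[, "i"], tb[, "j"], gi)
      F <- accumulate_forces(F, tb[, "k"], tb[, "j"], gk)
    }
  }
  list(e_bond = e_bond, e_angle = e_angle, e_fan = e_fan, F = F)
}

#' Potential energy breakdown and forces
#'
#' Evaluates all bonded and nonbonded terms of a compiled system under the
#' minimum-image convention.  Forces are the exact analytic negative
#' gradient of the implemented (shift-truncated) energy, so the net force
#' is zero to round-off.
#'
#' @param x A `cg_compiled` from [compile_forces()], or a `cg_system`
#'   (then `ff` and the box of `state` are used to compile).
#' @param state A `cg_state` (or bare position matrix, nm).
#' @param ff Force field (when `x` is a system).
#' @param neighbor_list Optional `cg_neighbor_list`; default brute force
#'   over all non-excluded pairs.
#' @param want_forces Compute forces as well?
#' @return List with `energy` (class `cg_energy`: bond, angle, fan_bond,
#'   pair, electrostatic, total in kJ/mol) and `forces` (N x 3 matrix,
#'   kJ/mol/nm, or NULL).
#' @export
compute_energy_forces <- function(x, state, ff = NULL, neighbor_list = NULL,
                                  want_forces = TRUE) {
  pos <- if (is.matrix(state)) state else state$positions
  if (!inherits(x, "cg_compiled")) {
    if (is.null(ff)) stop("supply a force field to compile against")
    box <- if (is.matrix(state)) stop("need a cg_state for the box")
           else state$box
    x <- compile_forces(x, ff, box)
  }
  if (!all(is.finite(pos))) stop("non-finite coordinates")
  F <- if (want_forces) matrix(0, x$N, 3) else NULL
  be <- bonded_ef(x$bt, pos, x$box, want_forces, F)
  F <- be$F
  e_pair <- 0; e_el <- 0
  groups <- x$groups; el <- x$el
  if (!is.null(neighbor_list)) {
    groups <- Map(group_subset, groups, neighbor_list$groups[names(groups)])
    if (!is.null(el)) el <- group_subset(el, neighbor_list$el)
  }
  for (g in groups) {
    res <- pair_group_ef(g, pos, x$box, want_forces)
    e_pair <- e_pair + res$e
    if (want_forces && length(res$ii))
      F <- accumulate_forces(F, res$ii, res$jj, res$F)
  }
  if (!is.null(el)) {
    res <- pair_group_ef(el, pos, x$box, want_forces)
    e_el <- res$e
    if (want_forces && length(res$ii))
      F <- accumulate_forces(F, res$ii, res$jj, res$F)
  }
  e <- c(bond = be$e_bond, angle = be$e_angle, fan_bond = be$e_fan,
         pair = e_pair, electrostatic = e_el)
  energy <- structure(c(e, total = sum(e)), class = "cg_energy")
  list(energy = energy, forces = F)
}

#' @export
print.cg_energy <- function(x, ...) {
  cat("energy breakdown (kJ/mol):\n")
  print(unclass(x))
  invisible(x)
}

#' Export an energy breakdown as columnar text
#'
#' @param energy A `cg_energy` (or list of them, one row each).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_energy_table <- function(energy, path) {
  if (inherits(energy, "cg_energy")) energy <- list(energy)
  df <- do.call(rbind, lapply(energy, function(e) as.data.frame(t(unclass(e)))))
  utils::write.table(format(df, digits = 10), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- neighbor list ----------------------------------------------------------

#' Build a Verlet neighbor list
#'
#' Candidate pairs within cutoff + skin under minimum image, per pair-form
#' group; excluded (1-2, 1-3) pairs are never present.  Energies computed
#' through the list equal brute-force energies exactly, because every pair
#' inside the cutoff is listed.
#'
#' @param compiled A `cg_compiled`.
#' @param state A `cg_state` or position matrix.
#' @param skin Skin width, nm.  The list must be rebuilt once any bead has
#'   moved further than `skin / 2` from its position at build time.
#' @return A `cg_neighbor_list`.
#' @export
build_neighbor_list <- function(compiled, state, skin = 0.3) {
  pos <- if (is.matrix(state)) state else state$positions
  box <- compiled$box
  maxcut <- max(c(vapply(compiled$groups, `[[`, numeric(1), "cutoff"),
                  if (!is.null(compiled$el)) compiled$el$cutoff else 0))
  if (maxcut + skin >= min(box$lengths[box$periodic]) / 2)
    stop("box too small: cutoff + skin must be below half the smallest edge")
  within_idx <- function(g) {
    d <- min_image(pos[g$ii, , drop = FALSE] - pos[g$jj, , drop = FALSE], box)
    which(rowSums(d * d) < (g$cutoff + skin)^2)
  }
  structure(list(groups = lapply(compiled$groups, within_idx),
                 el = if (!is.null(compiled$el)) within_idx(compiled$el)
                      else integer(),
                 skin = skin, ref_pos = pos),
            class = "cg_neighbor_list")
}

neighbor_list_stale <- function(nl, pos, box) {
  d <- min_image(pos - nl$ref_pos, box)
  max(rowSums(d * d)) > (nl$skin / 2)^2
}
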