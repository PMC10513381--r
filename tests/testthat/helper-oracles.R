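# Independent oracles used across the suite.  These deliberately avoid the
# package's fast paths: finite differences for forces, union-find for
# clusters, dense quadrature for exchange acceptance.

# central finite-difference force for bead i, dimension d
fd_force <- function(compiled, pos, i, d, h = 1e-6) {
  p1 <- pos; p1[i, d] <- p1[i, d] + h
  p2 <- pos; p2[i, d] <- p2[i, d] - h
  e1 <- compute_energy_forces(compiled, p1, want_forces = FALSE)$energy[["total"]]
  e2 <- compute_energy_forces(compiled, p2, want_forces = FALSE)$energy[["total"]]
  -(e1 - e2) / (2 * h)
}

# worst relative deviation between analytic forces and finite differences
# over a set of bead/dimension probes
fd_max_rel_err <- function(compiled, pos, probes = NULL) {
  ef <- compute_energy_forces(compiled, pos)
  n <- nrow(pos)
  if (is.null(probes))
    probes <- cbind(rep(seq_len(n), each = 3), rep(1:3, n))
  scale <- max(1, max(abs(ef$forces)))
  worst <- 0
  for (r in seq_len(nrow(probes))) {
    i <- probes[r, 1]; d <- probes[r, 2]
    fd <- fd_force(compiled, pos, i, d)
    worst <- max(worst, abs(fd - ef$forces[i, d]) / scale)
  }
  worst
}

# brute-force union-find connected components over a COM distance matrix
brute_largest_cluster <- function(com, box, cutoff) {
  n <- nrow(com)
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d <- com[i, ] - com[j, ]
    for (k in 1:3) if (box$periodic[k]) {
      L <- box$lengths[k]; d[k] <- d[k] - L * round(d[k] / L)
    }
    if (sum(d * d) < cutoff^2) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  sizes <- table(roots)
  best_root <- as.integer(names(sizes)[sizes == max(sizes)])
  best_root <- min(best_root)   # tie -> component with the lowest index
  sort(which(roots == best_root))
}

# E[min(1, exp(Delta))] for swapping a harmonic dimer between T1 and T2,
# by dense quadrature over the two bond-length Boltzmann densities
# p_T(r) ~ r^2 exp(-U(r)/kB T), U(r) = k/2 (r - r0)^2.
remd_quadrature_acceptance <- function(T1, T2, k, r0, ngrid = 600) {
  kB <- slabsim_constants()$kB
  sd_max <- sqrt(kB * max(T1, T2) / k)
  r <- seq(max(1e-6, r0 - 8 * sd_max), r0 + 8 * sd_max, length.out = ngrid)
  U <- 0.5 * k * (r - r0)^2
  w1 <- r^2 * exp(-U / (kB * T1)); w1 <- w1 / sum(w1)
  w2 <- r^2 * exp(-U / (kB * T2)); w2 <- w2 / sum(w2)
  beta1 <- 1 / (kB * T1); beta2 <- 1 / (kB * T2)
  acc <- outer(U, U, function(e1, e2) pmin(1, exp((beta1 - beta2) * (e2 - e1))))
  as.numeric(t(w1) %*% acc %*% w2)
}

# deterministic small random protein system for energy-oracle sweeps
random_chain_system <- function(seq_len_n = 12, n_copies = 3, box_len = 10,
                                tag = "hps", seed = 1) {
  codes <- aa_parameters()$code
  seqc <- paste(codes[1 + (seq_len(seq_len_n) * 7 + seed) %% 20],
                collapse = "")
  top <- chain_topology(seqc, tag)
  rep <- replicate_into_box(top, build_straight_chain(seqc), n_copies,
                            cg_box(box_len), min_dist = 0.45, seed = seed)
  rep
}
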