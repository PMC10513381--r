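# Reference integrators and sampling protocols.
#
# Langevin "middle" dynamics uses the BAOAB splitting: half kick (B), half
# drift (A), full Ornstein-Uhlenbeck velocity refresh (O), half drift, half
# kick with fresh forces.  With friction = 0 the O step is the identity and
# the scheme reduces exactly to velocity Verlet, giving the NVE limit.
# Nose-Hoover is a single-chain thermostat; the "collision frequency" of the
# spec maps to the inverse relaxation time tau of the chain variable.

#' System state
#'
#' @param positions N x 3 matrix, nm.
#' @param box A `cg_box`.
#' @param velocities N x 3 matrix, nm/ps; NULL for "not yet assigned".
#' @param time Simulation time, ps.
#' @return A `cg_state`.
#' @export
cg_state <- function(positions, box, velocities = NULL, time = 0) {
  positions <- as.matrix(positions)
  if (!all(is.finite(positions))) stop("non-finite coordinates")
  if (!is.null(velocities)) {
    velocities <- as.matrix(velocities)
    stopifnot(identical(dim(velocities), dim(positions)))
  }
  structure(list(positions = positions, velocities = velocities,
                 box = box, time = time), class = "cg_state")
}

#' @export
print.cg_state <- function(x, ...) {
  cat(sprintf("cg_state: %d beads, t = %g ps, box %s nm\n",
              nrow(x$positions), x$time,
              paste(signif(x$box$lengths, 4), collapse = " x ")))
  invisible(x)
}

#' Draw Maxwell-Boltzmann velocities
#'
#' @param masses Bead masses, amu.
#' @param temperature Target temperature, K.
#' @param seed RNG seed.
#' @return N x 3 velocity matrix, nm/ps.
#' @export
maxwell_velocities <- function(masses, temperature, seed = 1) {
  n <- length(masses)
  with_private_seed(seed,
    matrix(stats::rnorm(3 * n), n, 3) * sqrt(.kB * temperature / masses))
}

#' Kinetic temperature of a state
#'
#' Defined as 2 KE / (3 N kB).
#'
#' @param state A `cg_state` with velocities.
#' @param masses Bead masses, amu.
#' @return Temperature in K.
#' @export
kinetic_temperature <- function(state, masses) {
  v <- if (is.matrix(state)) state else state$velocities
  ke <- 0.5 * sum(masses * rowSums(v * v))
  2 * ke / (3 * length(masses) * .kB)
}

#' Thermostat specification
#'
#' @param kind "langevin_middle" or "nose_hoover".
#' @param temperature Target temperature, K.
#' @param friction Friction (Langevin) or collision/relaxation frequency
#'   (Nose-Hoover), ps^-1.
#' @param timestep Integration timestep, ps.
#' @param seed RNG seed for the stochastic parts.
#' @return A `thermostat_spec`.
#' @export
thermostat_spec <- function(kind = c("langevin_middle", "nose_hoover"),
                            temperature = 300, friction = 1,
                            timestep = 0.01, seed = 1) {
  kind <- match.arg(kind)
  if (timestep <= 0) stop("timestep must be > 0")
  if (temperature <= 0) stop("temperature must be > 0")
  structure(list(kind = kind, temperature = temperature, friction = friction,
                 timestep = timestep, seed = as.integer(seed)),
            class = "thermostat_spec")
}

resolve_schedule <- function(temperature_schedule, n_steps, default) {
  if (is.null(temperature_schedule)) return(NULL)
  if (is.function(temperature_schedule))
    return(vapply(seq_len(n_steps), temperature_schedule, numeric(1)))
  rep_len(as.numeric(temperature_schedule), n_steps)
}

#' Run molecular dynamics
#'
#' Integrates the compiled system with the requested thermostat.  The run
#' is deterministic given the thermostat seed.  Forces are refreshed from
#' a Verlet neighbor list (auto-rebuilt when stale) for systems above 60
#' beads, brute force below.
#'
#' @param system `cg_system`, `cg_topology` or `cg_compiled`.
#' @param ff Force field (ignored if `system` is compiled).
#' @param state Initial `cg_state`; velocities drawn from
#'   Maxwell-Boltzmann at the target temperature if absent.
#' @param thermostat A [thermostat_spec()].
#' @param n_steps Number of steps.
#' @param temperature_schedule Optional per-step target temperatures
#'   (vector of length `n_steps`, or function of the step index) for
#'   annealing protocols.
#' @param traj_stride,energy_stride Sampling strides in steps.
#' @param abort_energy Abort with a diagnostic when |total energy|
#'   exceeds this (kJ/mol).
#' @return List with `state` (final) and `trajectory` (`cg_trajectory`,
#'   which also carries the energy log).
#' @export
run_md <- function(system, ff = NULL, state, thermostat, n_steps,
                   temperature_schedule = NULL,
                   traj_stride = 1e4, energy_stride = 1e3,
                   abort_energy = 1e10) {
  compiled <- if (inherits(system, "cg_compiled")) system
              else compile_forces(system, ff, state$box)
  n_steps <- as.integer(n_steps)
  dt <- thermostat$timestep
  m <- compiled$mass
  pos <- state$positions
  vel <- if (is.null(state$velocities))
    maxwell_velocities(m, thermostat$temperature, thermostat$seed)
  else state$velocities
  sched <- resolve_schedule(temperature_schedule, n_steps,
                            thermostat$temperature)
  use_nl <- compiled$N > 60
  nl <- NULL
  eval_forces <- function(p) {
    if (use_nl) {
      if (is.null(nl) || neighbor_list_stale(nl, p, compiled$box))
        nl <<- build_neighbor_list(compiled, p)
      compute_energy_forces(compiled, p, neighbor_list = nl)
    } else compute_energy_forces(compiled, p)
  }
  frames <- list(); times <- numeric(); elog <- list()
  record_frame <- function(p, t) {
    frames[[length(frames) + 1L]] <<- p
    times[length(times) + 1L] <<- t
  }
  ndof <- 3 * compiled$N
  # Nose-Hoover chain variable
  xi <- 0
  res <- with_private_seed(thermostat$seed, {
    ef <- eval_forces(pos)
    F <- ef$forces
    record_frame(pos, state$time)
    if (n_steps > 0) for (step in seq_len(n_steps)) {
      Tt <- if (is.null(sched)) thermostat$temperature else sched[step]
      if (thermostat$kind == "langevin_middle") {
        vel <- vel + (0.5 * dt / m) * F
        pos <- pos + 0.5 * dt * vel
        if (thermostat$friction > 0) {
          c1 <- exp(-thermostat$friction * dt)
          sdv <- sqrt((1 - c1^2) * .kB * Tt / m)
          vel <- c1 * vel + sdv * matrix(stats::rnorm(ndof), compiled$N, 3)
        }
        pos <- pos + 0.5 * dt * vel
        ef <- eval_forces(pos); F <- ef$forces
        vel <- vel + (0.5 * dt / m) * F
      } else {                          # nose_hoover
        tau <- 1 / thermostat$friction
        Q <- ndof * .kB * Tt * tau^2
        nh_half <- function() {
          ke <- 0.5 * sum(m * rowSums(vel * vel))
          xi <<- xi + 0.25 * dt * (2 * ke - ndof * .kB * Tt) / Q
          vel <<- vel * exp(-0.5 * dt * xi)
          ke <- 0.5 * sum(m * rowSums(vel * vel))
          xi <<- xi + 0.25 * dt * (2 * ke - ndof * .kB * Tt) / Q
        }
        nh_half()
        vel <- vel + (0.5 * dt / m) * F
        pos <- pos + dt * vel
        ef <- eval_forces(pos); F <- ef$forces
        vel <- vel + (0.5 * dt / m) * F
        nh_half()
      }
      if (step %% energy_stride == 0 || step == n_steps) {
        pe <- ef$energy[["total"]]
        ke <- 0.5 * sum(m * rowSums(vel * vel))
        if (!is.finite(pe) || abs(pe) > abort_energy)
          stop(sprintf("energy divergence at step %d: E = %g kJ/mol",
                       step, pe))
        elog[[length(elog) + 1L]] <-
          c(step = step, time = state$time + step * dt, potential = pe,
            kinetic = ke, temperature = 2 * ke / (ndof * .kB))
      }
      if (step %% traj_stride == 0 || step == n_steps)
        record_frame(pos, state$time + step * dt)
    }
    list(pos = pos, vel = vel)
  })
  final <- cg_state(res$pos, state$box, res$vel,
                    time = state$time + n_steps * dt)
  traj <- cg_trajectory(frames, times, state$box,
                        metadata = list(provenance = compiled$ff$provenance,
                                        seed = thermostat$seed,
                                        units = "nm, ps, amu, kJ/mol",
                                        thermostat = thermostat$kind,
                                        timestep = dt),
                        energies = if (length(elog))
                          as.data.frame(do.call(rbind, elog)) else NULL)
  list(state = final, trajectory = traj)
}

#' Energy minimization by adaptive steepest descent
#'
#' Monotone non-increasing energy sequence; terminates when the largest
#' force component magnitude drops below `tolerance` or the step size
#' underflows.
#'
#' @param system,ff,state As in [run_md()].
#' @param tolerance Force tolerance, kJ/mol/nm.
#' @param max_iter Iteration cap.
#' @return List with `state`, `energy` (trace), `max_force`, `converged`.
#' @export
minimize <- function(system, ff = NULL, state, tolerance = 1,
                     max_iter = 10000) {
  compiled <- if (inherits(system, "cg_compiled")) system
              else compile_forces(system, ff, state$box)
  pos <- state$positions
  ef <- compute_energy_forces(compiled, pos)
  if (!is.finite(ef$energy[["total"]])) stop("non-finite starting energy")
  e <- ef$energy[["total"]]
  trace <- e
  alpha <- 1e-4
  for (it in seq_len(max_iter)) {
    fmax <- max(abs(ef$forces))
    if (fmax < tolerance) break
    cand <- pos + alpha * ef$forces
    ef2 <- tryCatch(compute_energy_forces(compiled, cand),
                    error = function(e) NULL)
    if (!is.null(ef2) && is.finite(ef2$energy[["total"]]) &&
        ef2$energy[["total"]] <= e) {
      pos <- cand; ef <- ef2; e <- ef2$energy[["total"]]
      trace <- c(trace, e)
      alpha <- alpha * 1.2
    } else {
      alpha <- alpha * 0.5
      if (alpha < 1e-14) break
    }
  }
  list(state = cg_state(pos, state$box, state$velocities, state$time),
       energy = trace, max_force = max(abs(ef$forces)),
       converged = max(abs(ef$forces)) < tolerance)
}

#' Barostat specification
#'
#' @param pressure Target pressure, bar.
#' @param move_interval Steps between Monte Carlo volume moves.
#' @param max_volume_frac Maximum fractional volume change per move.
#' @return A `barostat_spec`.
#' @export
barostat_spec <- function(pressure = 1, move_interval = 25,
                          max_volume_frac = 0.02) {
  if (pressure <= 0) stop("pressure must be > 0")
  structure(list(pressure = pressure, move_interval = as.integer(move_interval),
                 max_volume_frac = max_volume_frac),
            class = "barostat_spec")
}

molecule_com_scale <- function(pos, ranges, s) {
  # rigidly move each molecule copy so its centroid scales by s
  for (r in seq_len(nrow(ranges))) {
    idx <- ranges$start[r]:ranges$end[r]
    com <- colMeans(pos[idx, , drop = FALSE])
    pos[idx, ] <- sweep(pos[idx, , drop = FALSE], 2, com * (s - 1), `+`)
  }
  pos
}

#' NPT compression with a Monte Carlo barostat
#'
#' Alternates thermostatted MD with isotropic Monte Carlo volume moves on a
#' cubic box.  A move V -> V' rescales molecule centroids (intramolecular
#' geometry untouched) and is accepted with Metropolis probability
#' exp(-(dE + P dV - N_mol kB T ln(V'/V)) / kB T).  Moves that produce
#' overlapping beads are rejected, not fatal.
#'
#' @param system,ff,state,thermostat,n_steps As in [run_md()].
#' @param barostat A [barostat_spec()].
#' @return List with `state` (final, box updated), `volumes` (trace),
#'   `acceptance` (fraction of accepted volume moves).
#' @export
npt_compress <- function(system, ff = NULL, state, barostat, thermostat,
                         n_steps) {
  compiled <- if (inherits(system, "cg_compiled")) system
              else compile_forces(system, ff, state$box)
  if (length(unique(state$box$lengths)) != 1L)
    stop("MC barostat requires a cubic box")
  ranges <- compiled$system$bead_ranges
  n_mol <- nrow(ranges)
  kT <- .kB * thermostat$temperature
  P <- barostat$pressure * .bar2kJ_mol_nm3
  n_steps <- as.integer(n_steps)
  interval <- barostat$move_interval
  st <- state
  volumes <- prod(st$box$lengths)
  # fixed proposal half-width => symmetric proposal, plain Metropolis
  dV_max <- barostat$max_volume_frac * volumes
  attempted <- 0L; accepted <- 0L
  seg_seed <- thermostat$seed
  done <- 0L
  while (done < n_steps) {
    seg <- min(interval, n_steps - done)
    th <- thermostat; th$seed <- seg_seed
    out <- run_md(compiled, state = st, thermostat = th, n_steps = seg,
                  traj_stride = seg + 1L, energy_stride = seg + 1L)
    st <- out$state
    done <- done + seg
    seg_seed <- seg_seed + 1L
    if (done %% interval == 0L && done < n_steps + 1L) {
      attempted <- attempted + 1L
      V <- prod(st$box$lengths)
      move <- with_private_seed(seg_seed * 7919L, stats::runif(2))
      seg_seed <- seg_seed + 1L
      dV <- (2 * move[1] - 1) * dV_max
      V2 <- V + dV
      if (V2 > 0) {
        s <- (V2 / V)^(1 / 3)
        newpos <- molecule_com_scale(st$positions, ranges, s)
        newbox <- cg_box(st$box$lengths * s, st$box$periodic)
        c2 <- compiled; c2$box <- newbox
        e1 <- compute_energy_forces(compiled, st$positions,
                                    want_forces = FALSE)$energy[["total"]]
        e2 <- tryCatch(compute_energy_forces(c2, newpos,
                                             want_forces = FALSE)$energy[["total"]],
                       error = function(e) Inf)
        dW <- (e2 - e1) + P * (V2 - V) - n_mol * kT * log(V2 / V)
        if (is.finite(dW) && (dW <= 0 || move[2] < exp(-dW / kT))) {
          accepted <- accepted + 1L
          st <- cg_state(newpos, newbox, st$velocities, st$time)
          compiled$box <- newbox
        }
      }
      volumes <- c(volumes, prod(st$box$lengths))
    }
  }
  list(state = st, volumes = volumes,
       acceptance = if (attempted) accepted / attempted else NA_real_)
}

#' Replica-exchange acceptance probability
#'
#' Metropolis rule min(1, exp(Delta)) with
#' Delta = (beta_i - beta_j) (E_j - E_i).  For equal temperatures Delta = 0
#' and the probability is exactly 1.
#'
#' @param Ti,Tj Replica temperatures, K.
#' @param Ei,Ej Potential energies, kJ/mol.
#' @return Acceptance probability in `[0, 1]`.
#' @export
remd_acceptance_probability <- function(Ti, Tj, Ei, Ej) {
  delta <- (1 / (.kB * Ti) - 1 / (.kB * Tj)) * (Ej - Ei)
  pmin(1, exp(delta))
}

#' Replica-exchange specification
#'
#' @param ladder Strictly increasing temperature ladder, K.
#' @param exchange_interval Steps between exchange attempts.
#' @param seed RNG seed for the exchange decisions.
#' @return A `remd_spec`.
#' @export
remd_spec <- function(ladder, exchange_interval = 1000, seed = 1) {
  if (length(ladder) < 2) stop("ladder must contain at least 2 temperatures")
  if (any(diff(ladder) <= 0)) stop("ladder must be strictly increasing")
  structure(list(ladder = as.numeric(ladder),
                 exchange_interval = as.integer(exchange_interval),
                 seed = as.integer(seed)),
            class = "remd_spec")
}

#' Temperature replica exchange molecular dynamics
#'
#' Runs one replica per ladder temperature; every `exchange_interval`
#' steps, neighbouring pairs (alternating even/odd parity between
#' attempts) attempt a configuration swap with Metropolis probability
#' min(1, exp(Delta)), Delta = (beta_i - beta_j) (E_j - E_i).  On
#' acceptance the configurations change temperature slots and velocities
#' are rescaled by sqrt(T_new / T_old).
#'
#' @param system,ff As in [run_md()].
#' @param states List of initial `cg_state`s, one per ladder temperature.
#' @param remd A [remd_spec()].
#' @param thermostat Base [thermostat_spec()]; its temperature is
#'   overridden per replica.
#' @param n_steps Total MD steps per replica.
#' @return List with `states`, `frames` (per-slot configuration snapshots
#'   at each exchange point), `energies` (matrix, slot x attempt),
#'   `acceptance` (data frame per neighbour pair), `replica_slot`
#'   (history matrix of which replica occupies which temperature slot).
#' @export
run_remd <- function(system, ff = NULL, states, remd, thermostat, n_steps) {
  box <- states[[1]]$box
  compiled <- if (inherits(system, "cg_compiled")) system
              else compile_forces(system, ff, box)
  nT <- length(remd$ladder)
  if (length(states) != nT)
    stop("need one initial state per ladder temperature")
  n_seg <- n_steps %/% remd$exchange_interval
  beta <- 1 / (.kB * remd$ladder)
  attempted <- integer(nT - 1); accepted <- integer(nT - 1)
  replica_slot <- matrix(NA_integer_, n_seg + 1L, nT)
  replica_slot[1, ] <- seq_len(nT)
  slots <- seq_len(nT)          # slots[k]: replica id at temperature k
  energies <- matrix(NA_real_, n_seg, nT)
  frames <- rep(list(list()), nT)
  u_swap <- with_private_seed(remd$seed, stats::runif(n_seg * nT))
  uptr <- 0L
  for (seg in seq_len(n_seg)) {
    for (k in seq_len(nT)) {
      th <- thermostat
      th$temperature <- remd$ladder[k]
      th$seed <- (remd$seed + 7L * k + 131L * seg) %% .Machine$integer.max
      if (is.null(states[[k]]$velocities))
        states[[k]]$velocities <-
          maxwell_velocities(compiled$mass, remd$ladder[k], th$seed)
      out <- run_md(compiled, state = states[[k]], thermostat = th,
                    n_steps = remd$exchange_interval,
                    traj_stride = remd$exchange_interval + 1L,
                    energy_stride = remd$exchange_interval)
      states[[k]] <- out$state
      energies[seg, k] <-
        compute_energy_forces(compiled, states[[k]]$positions,
                              want_forces = FALSE)$energy[["total"]]
      frames[[k]][[seg]] <- states[[k]]$positions
    }
    start <- if (seg %% 2L == 1L) 1L else 2L
    if (start <= nT - 1L) for (k in seq(start, nT - 1L, by = 2L)) {
      attempted[k] <- attempted[k] + 1L
      p_acc <- remd_acceptance_probability(remd$ladder[k], remd$ladder[k + 1],
                                           energies[seg, k],
                                           energies[seg, k + 1])
      uptr <- uptr + 1L
      if (u_swap[uptr] < p_acc) {
        accepted[k] <- accepted[k] + 1L
        tmp <- states[[k]]; states[[k]] <- states[[k + 1]]; states[[k + 1]] <- tmp
        fac_up <- sqrt(remd$ladder[k] / remd$ladder[k + 1])
        states[[k]]$velocities <- states[[k]]$velocities * fac_up
        states[[k + 1]]$velocities <- states[[k + 1]]$velocities / fac_up
        e <- energies[seg, k]
        energies[seg, k] <- energies[seg, k + 1]; energies[seg, k + 1] <- e
        s <- slots[k]; slots[k] <- slots[k + 1]; slots[k + 1] <- s
      }
    }
    replica_slot[seg + 1L, ] <- slots
  }
  list(states = states, frames = frames, energies = energies,
       acceptance = data.frame(pair = paste(seq_len(nT - 1), 2:nT, sep = "-"),
                               attempted = attempted, accepted = accepted,
                               ratio = ifelse(attempted > 0,
                                              accepted / attempted, NA)),
       replica_slot = replica_slot, ladder = remd$ladder)
}
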