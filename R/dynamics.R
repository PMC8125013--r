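## Nuclear propagation and the surface-hopping loop.
##
## Nuclei move classically on one adiabatic surface (velocity Verlet);
## at every strict local minimum of the adiabatic gap along the
## trajectory with gap below the 30 kcal/mol gate, the Zhu-Nakamura
## probability decides stochastically whether the active state switches,
## with the momentum rescaled along the hopping direction so total
## energy is conserved exactly at the hop.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Trajectory state
#'
#' Bundle of one instant of a classical trajectory: time (atomic
#' units), coordinates and velocities (a.u.), per-coordinate masses,
#' the active adiabatic state and the cached surface evaluation.
#'
#' @param time time, atomic units.
#' @param position,velocity numeric vectors, Bohr and Bohr/a.t.u.
#' @param masses positive masses, a.u. (one per coordinate).
#' @param active `"lower"` or `"upper"`.
#' @param eval cached `zn_surface_eval` at `position` (computed if omitted).
#' @param surface surface used to fill `eval` when missing.
#' @return Object of class `zn_state`.
#' @export
trajectory_state <- function(time, position, velocity, masses, active,
                             eval = NULL, surface = NULL) {
  active <- match.arg(active, c("lower", "upper"))
  if (is.null(eval)) {
    if (is.null(surface)) stop("either 'eval' or 'surface' must be given")
    eval <- surface_eval(surface, position)
  }
  structure(list(time = time, position = position, velocity = velocity,
                 masses = masses, active = active, eval = eval),
            class = "zn_state")
}

state_kinetic <- function(state) 0.5 * sum(state$masses * state$velocity^2)

state_potential <- function(state)
  unname(state$eval$energies[if (state$active == "lower") 1 else 2])

state_total <- function(state) state_kinetic(state) + state_potential(state)

#' One velocity-Verlet step
#'
#' Standard velocity-Verlet update on the active adiabatic surface,
#' requiring exactly one new surface evaluation.
#'
#' @param state a `zn_state` (see [trajectory_state()]).
#' @param surface the surface to propagate on.
#' @param dt time step, atomic units.
#' @return The advanced `zn_state`.
#' @export
verlet_step <- function(state, surface, dt) {
  stopifnot(inherits(state, "zn_state"), dt > 0)
  gidx <- if (state$active == "lower") "lower" else "upper"
  a0 <- -state$eval$gradients[[gidx]] / state$masses
  x1 <- state$position + state$velocity * dt + 0.5 * a0 * dt^2
  ev1 <- surface_eval(surface, x1)
  a1 <- -ev1$gradients[[gidx]] / state$masses
  trajectory_state(time = state$time + dt,
                   position = x1,
                   velocity = state$velocity + 0.5 * (a0 + a1) * dt,
                   masses = state$masses,
                   active = state$active,
                   eval = ev1)
}

other_state <- function(active) if (active == "lower") "upper" else "lower"

## Refine a three-step gap minimum: parabolic interpolation of the gap
## along the path gives the seam position, and symmetric surface
## evaluations around it replace the (generally asymmetric) trajectory
## brackets.  The bracket distance is widened until the gap has grown
## to three times its minimum, i.e. until the evaluation points have
## left the avoided-crossing mixing region where adiabatic gradients do
## not yet represent diabatic forces.  Falls back to the raw brackets
## near the domain edge.
refine_crossing <- function(before, at, after, surface, grow = 3,
                            max_widen = 8L) {
  raw <- list(before = before$eval, at = at$eval, after = after$eval)
  g <- c(eval_gap(before$eval), eval_gap(at$eval), eval_gap(after$eval))
  denom <- g[1] - 2 * g[2] + g[3]
  s <- if (denom > 0) 0.5 * (g[1] - g[3]) / denom else 0
  s <- max(min(s, 0.5), -0.5)
  x_star <- if (s >= 0)
    at$position + s * (after$position - at$position)
  else
    at$position + s * (at$position - before$position)
  h0 <- (after$position - before$position) / 2
  ev_star <- tryCatch(surface_eval(surface, x_star), error = function(e) NULL)
  if (is.null(ev_star)) return(raw)
  target <- grow * eval_gap(ev_star)
  ref <- NULL
  for (m in seq_len(max_widen)) {
    cand <- tryCatch(
      list(before = surface_eval(surface, x_star - m * h0),
           at = ev_star,
           after = surface_eval(surface, x_star + m * h0)),
      error = function(e) NULL)
    if (is.null(cand)) break
    if (eval_gap(cand$before) <= eval_gap(cand$at) ||
        eval_gap(cand$after) <= eval_gap(cand$at)) break
    ref <- cand
    if (eval_gap(cand$before) >= target && eval_gap(cand$after) >= target)
      break
  }
  if (is.null(ref)) raw else ref
}

## Documented seed-splitting rule: any single trajectory of an ensemble
## is reproducible in isolation from (master_seed, index).
derive_traj_seed <- function(master_seed, index) {
  as.integer((as.numeric(master_seed) * 1009 + index) %% 2147483647)
}

#' Run configuration for surface-hopping ensembles
#'
#' Collects the protocol parameters of a simulation in laboratory
#' units.  The defaults are the reference protocol of the photoswitch
#' study: 1.0 fs time step, 500 fs per trajectory, 40 trajectories,
#' hop attempts gated at adiabatic gaps below 30 kcal/mol, dynamics
#' started on the upper (bright) state from Wigner-sampled nuclei of
#' the lower-state open-form well.
#'
#' @param dt_fs nuclear time step, fs.
#' @param t_max_fs total propagation time, fs (multiple of `dt_fs`).
#' @param n_traj number of trajectories.
#' @param gap_threshold_kcal gap gate for hop attempts, kcal/mol.
#' @param seed master seed; per-trajectory seeds are derived as
#'   `(seed * 1009 + index) mod (2^31 - 1)`.
#' @param surface surface object; `NULL` builds the default
#'   reactive-variant surrogate via [build_surrogate()].
#' @param mass_amu effective mass of the reaction coordinate, amu.
#' @param initial_state electronic state populated at t = 0.
#' @param sample_state,sample_guess_angstrom well used for Wigner
#'   sampling of the nuclei (lower-state open minimum by default).
#' @param r_threshold_angstrom product-classification threshold for the
#'   ring-closing coordinate.
#' @param energy_drift_max_kcal drift between hops beyond which a
#'   trajectory is declared failed.
#' @param refractory_steps detection holidays after a hop attempt, so
#'   one gap minimum triggers at most one attempt.
#' @return Object of class `zn_run_config`.
#' @export
run_config <- function(dt_fs = 1.0, t_max_fs = 500, n_traj = 40,
                       gap_threshold_kcal = 30, seed = 1,
                       surface = NULL, mass_amu = 6,
                       initial_state = c("upper", "lower"),
                       sample_state = c("lower", "upper"),
                       sample_guess_angstrom = 3.302,
                       r_threshold_angstrom = 1.70,
                       energy_drift_max_kcal = 10,
                       refractory_steps = 2) {
  initial_state <- match.arg(initial_state)
  sample_state <- match.arg(sample_state)
  stopifnot(dt_fs > 0, t_max_fs > 0, n_traj >= 1, gap_threshold_kcal >= 0)
  n_steps <- t_max_fs / dt_fs
  if (abs(n_steps - round(n_steps)) > 1e-9)
    stop("t_max_fs must be an integer multiple of dt_fs")
  structure(list(dt_fs = dt_fs, t_max_fs = t_max_fs, n_traj = n_traj,
                 gap_threshold_kcal = gap_threshold_kcal, seed = seed,
                 surface = surface, mass_amu = mass_amu,
                 initial_state = initial_state, sample_state = sample_state,
                 sample_guess_angstrom = sample_guess_angstrom,
                 r_threshold_angstrom = r_threshold_angstrom,
                 energy_drift_max_kcal = energy_drift_max_kcal,
                 refractory_steps = refractory_steps),
            class = "zn_run_config")
}

#' Propagate one surface-hopping trajectory
#'
#' Velocity-Verlet propagation with Zhu-Nakamura hop attempts at every
#' strict local minimum of the adiabatic gap (three-point detection,
#' one attempt per minimum) below the gap gate.  An accepted hop is
#' applied at the detected minimum: the trajectory rewinds one step,
#' switches state, rescales the momentum along the hopping direction
#' and continues.  All stochastic decisions draw from a private RNG
#' stream seeded by `seed`.
#'
#' @param surface surface object.
#' @param initial list or vector with `position` (Bohr) and `momentum`
#'   (a.u.) of the single nuclear coordinate (or vectors for
#'   multi-dimensional surfaces).
#' @param config a [run_config()] object.
#' @param seed integer seed for this trajectory.
#' @return Object of class `zn_trajectory` with the time series
#'   (atomic/internal units), hop-event log, failure flag and seed.
#'   `as.data.frame()` converts to laboratory units.
#' @export
run_trajectory <- function(surface, initial, config = run_config(), seed = 1) {
  dt <- fs_to_au(config$dt_fs)
  n <- round(config$t_max_fs / config$dt_fs)
  gap_gate <- kcal_to_hartree(config$gap_threshold_kcal)
  drift_max <- kcal_to_hartree(config$energy_drift_max_kcal)
  mass <- amu_to_au(config$mass_amu)
  pos <- as.numeric(initial$position %||% initial[[1]])
  mom <- as.numeric(initial$momentum %||% initial[[2]])
  d <- length(pos)
  masses <- rep(mass, d)

  rec <- matrix(NA_real_, nrow = n + 1, ncol = 6 + d)
  hops <- list()
  failed <- FALSE
  fail_reason <- NA_character_

  put_row <- function(i, s) {
    rec[i + 1, ] <<- c(s$time, s$position,
                       if (s$active == "lower") 1 else 2,
                       s$eval$energies, state_kinetic(s), state_total(s))
  }

  with_local_seed(seed, {
    state <- tryCatch(
      trajectory_state(0, pos, mom / masses, masses, config$initial_state,
                       surface = surface),
      error = function(e) e)
    if (inherits(state, "error")) {
      failed <- TRUE
      fail_reason <- conditionMessage(state)
      last <- -1L
    } else {
      put_row(0L, state)
      e_ref <- state_total(state)
      prev <- NULL
      refractory <- 0L
      i <- 1L
      last <- 0L
      while (i <= n) {
        new <- tryCatch(verlet_step(state, surface, dt),
                        error = function(e) e)
        if (inherits(new, "error")) {
          failed <- TRUE
          fail_reason <- conditionMessage(new)
          break
        }
        put_row(i, new)
        last <- i
        if (abs(state_total(new) - e_ref) > drift_max) {
          failed <- TRUE
          fail_reason <- sprintf("energy drift exceeded %.1f kcal/mol",
                                 config$energy_drift_max_kcal)
          break
        }
        hopped <- FALSE
        if (refractory > 0L) {
          refractory <- refractory - 1L
        } else if (!is.null(prev)) {
          ## three consecutive steps: prev (i-2), state (i-1), new (i)
          g0 <- eval_gap(prev$eval); g1 <- eval_gap(state$eval)
          g2 <- eval_gap(new$eval)
          if (g1 < g0 && g1 < g2 && g1 < gap_gate) {
            br <- refine_crossing(prev, state, new, surface)
            dia <- diabatize_crossing(br$before, br$at, br$after)
            u <- (dia$f2 - dia$f1) / sqrt(masses)
            et <- state_potential(state) +
              kinetic_along(state$velocity, masses, u)
            gprod <- mass_scaled_product(dia$f1, dia$f2, masses)
            d2 <- mass_scaled_difference_sq(dia$f1, dia$f2, masses)
            par <- zn_parameters(dia$v12, dia$ex, et, gprod, d2)
            p <- if (par$a_sq > 0)
              zn_probability(par$a_sq, par$b_sq, par$branch) else 0
            draw <- stats::runif(1)
            accepted <- draw < p
            frustrated <- FALSE
            hop_time <- state$time
            hop_pos <- state$position
            e_pre <- state_total(state)
            e_post <- NA_real_
            if (accepted) {
              target <- other_state(state$active)
              delta_e <- state_potential(state) -
                unname(state$eval$energies[if (target == "lower") 1 else 2])
              adj <- hop_adjust_momentum(state$velocity, masses, u, delta_e)
              frustrated <- adj$frustrated
              if (!frustrated) {
                state <- trajectory_state(state$time, state$position,
                                          adj$velocities, masses, target,
                                          eval = state$eval)
                put_row(i - 1L, state)   # row at the hop reflects the switch
                e_post <- state_total(state)
                e_ref <- e_post
                prev <- NULL
                hopped <- TRUE
              }
            }
            hops[[length(hops) + 1L]] <- data.frame(
              time_fs = au_to_fs(hop_time),
              position = hop_pos[1],
              gap = eval_gap(br$at), a_sq = par$a_sq, b_sq = par$b_sq,
              probability = p, draw = draw,
              accepted = accepted && !frustrated,
              frustrated = frustrated, non_lz = par$non_lz,
              e_total_pre = e_pre, e_total_post = e_post)
            refractory <- config$refractory_steps
            if (hopped) next  # re-propagate the discarded step from the hop
          }
        }
        prev <- state; state <- new
        i <- i + 1L
      }
    }
  })

  keep <- seq_len(last + 1)
  hops_df <- if (length(hops)) do.call(rbind, hops) else
    data.frame(time_fs = numeric(0), position = numeric(0), gap = numeric(0),
               a_sq = numeric(0), b_sq = numeric(0), probability = numeric(0),
               draw = numeric(0), accepted = logical(0),
               frustrated = logical(0), non_lz = logical(0),
               e_total_pre = numeric(0), e_total_post = numeric(0))
  structure(list(time_au = rec[keep, 1],
                 position = rec[keep, 2:(1 + d), drop = d == 1],
                 active = as.integer(rec[keep, 2 + d]),
                 e_lower = rec[keep, 3 + d],
                 e_upper = rec[keep, 4 + d],
                 e_kin = rec[keep, 5 + d],
                 e_total = rec[keep, 6 + d],
                 hops = hops_df,
                 failed = failed, fail_reason = fail_reason,
                 seed = seed, dt_fs = config$dt_fs,
                 mass_amu = config$mass_amu),
            class = "zn_trajectory")
}

#' @export
as.data.frame.zn_trajectory <- function(x, ...) {
  data.frame(time_fs = au_to_fs(x$time_au),
             r_angstrom = bohr_to_angstrom(as.numeric(x$position)),
             active_state = ifelse(x$active == 1L, "S0", "S1"),
             e_s0_kcalmol = hartree_to_kcal(x$e_lower),
             e_s1_kcalmol = hartree_to_kcal(x$e_upper),
             e_kin_kcalmol = hartree_to_kcal(x$e_kin),
             e_total_kcalmol = hartree_to_kcal(x$e_total))
}

#' @export
print.zn_trajectory <- function(x, ...) {
  cat(sprintf("<zn_trajectory> %d steps of %.2f fs, seed %d%s\n",
              length(x$time_au) - 1, x$dt_fs, x$seed,
              if (x$failed) paste0(" [FAILED: ", x$fail_reason, "]") else ""))
  cat(sprintf("  accepted hops: %d (of %d attempts); final state %s, final r %.3f Angstrom\n",
              sum(x$hops$accepted), nrow(x$hops),
              if (utils::tail(x$active, 1) == 1) "S0" else "S1",
              bohr_to_angstrom(utils::tail(as.numeric(x$position), 1))))
  invisible(x)
}

#' Run a surface-hopping ensemble
#'
#' Samples `n_traj` initial conditions from the ground-state Wigner
#' distribution of the lower-state open-form well, promotes each to the
#' configured initial electronic state (vertical excitation) and
#' propagates independent trajectories with per-trajectory derived
#' seeds.  Failed trajectories (domain escape or energy drift) are kept
#' in the record but excluded from ensemble statistics.
#'
#' @param config a [run_config()] object.
#' @return Object of class `zn_ensemble`: list with `trajectories`,
#'   `success` flags, `initial_conditions`, `seeds`, the resolved
#'   `config` and the surface.
#' @export
run_ensemble <- function(config = run_config()) {
  stopifnot(inherits(config, "zn_run_config"))
  surface <- config$surface %||% build_surrogate(mass_amu = config$mass_amu)
  mass <- amu_to_au(config$mass_amu)
  mode <- mode_from_curvature(surface, config$sample_state,
                              angstrom_to_bohr(config$sample_guess_angstrom),
                              mass)
  ics <- wigner_sample(mode, config$n_traj, seed = config$seed)
  seeds <- vapply(seq_len(config$n_traj),
                  function(i) derive_traj_seed(config$seed, i), integer(1))
  trajectories <- lapply(seq_len(config$n_traj), function(i) {
    run_trajectory(surface,
                   list(position = ics$position[i], momentum = ics$momentum[i]),
                   config, seed = seeds[i])
  })
  structure(list(trajectories = trajectories,
                 success = !vapply(trajectories, `[[`, logical(1), "failed"),
                 initial_conditions = ics,
                 seeds = seeds,
                 mode = mode,
                 config = config,
                 surface = surface),
            class = "zn_ensemble")
}

#' @export
print.zn_ensemble <- function(x, ...) {
  cat(sprintf("<zn_ensemble> %d trajectories (%d successful), %g fs at dt = %g fs, master seed %s\n",
              length(x$trajectories), sum(x$success),
              x$config$t_max_fs, x$config$dt_fs, format(x$config$seed)))
  invisible(x)
}

#' Write an ensemble to disk
#'
#' Writes one CSV per trajectory (`traj_###.csv`, laboratory units), a
#' combined hop-event CSV and a JSON manifest holding the resolved
#' configuration, seeds and success flags.  Floating-point output keeps
#' 15 significant digits.
#'
#' @param ensemble a `zn_ensemble`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_ensemble <- function(ensemble, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(ensemble$trajectories)) {
    df <- as.data.frame(ensemble$trajectories[[i]])
    utils::write.csv(format(df, digits = 15, trim = TRUE),
                     file.path(dir, sprintf("traj_%03d.csv", i)),
                     row.names = FALSE, quote = FALSE)
  }
  hops <- do.call(rbind, lapply(seq_along(ensemble$trajectories), function(i) {
    h <- ensemble$trajectories[[i]]$hops
    if (nrow(h)) cbind(trajectory = i, h) else NULL
  }))
  if (is.null(hops))
    hops <- data.frame(trajectory = integer(0), time_fs = numeric(0))
  else {
    hops$position_angstrom <- bohr_to_angstrom(hops$position)
    hops$gap_kcalmol <- hartree_to_kcal(hops$gap)
    hops$position <- NULL; hops$gap <- NULL
  }
  utils::write.csv(format(hops, digits = 15, trim = TRUE),
                   file.path(dir, "hops.csv"), row.names = FALSE, quote = FALSE)
  cfg <- unclass(ensemble$config)
  cfg$surface <- NULL
  manifest <- list(config = cfg,
                   surface_variant = ensemble$surface$variant %||% "custom",
                   seeds = ensemble$seeds,
                   success = ensemble$success,
                   n_success = sum(ensemble$success),
                   package_version = as.character(utils::packageVersion("zntraj")))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_initial_conditions(ensemble$initial_conditions,
                           file.path(dir, "initial_conditions.csv"))
  invisible(dir)
}

#' Read a stored ensemble
#'
#' Reconstructs the pieces of a written ensemble needed for analysis
#' (time series, active states, hop events, success flags).
#'
#' @param dir directory written by [write_ensemble()].
#' @return Object of class `zn_ensemble` (trajectories carry the fields
#'   used by the analysis functions).
#' @export
read_ensemble <- function(dir) {
  man_path <- file.path(dir, "manifest.json")
  if (!file.exists(man_path)) stop("no manifest.json in ", dir)
  manifest <- jsonlite::read_json(man_path, simplifyVector = TRUE)
  files <- sort(list.files(dir, pattern = "^traj_\\d+\\.csv$", full.names = TRUE))
  if (length(files) == 0) stop("no trajectory CSVs in ", dir)
  trajectories <- lapply(seq_along(files), function(i) {
    df <- utils::read.csv(files[i])
    structure(list(time_au = fs_to_au(df$time_fs),
                   position = angstrom_to_bohr(df$r_angstrom),
                   active = ifelse(df$active_state == "S0", 1L, 2L),
                   e_lower = kcal_to_hartree(df$e_s0_kcalmol),
                   e_upper = kcal_to_hartree(df$e_s1_kcalmol),
                   e_kin = kcal_to_hartree(df$e_kin_kcalmol),
                   e_total = kcal_to_hartree(df$e_total_kcalmol),
                   hops = data.frame(),
                   failed = !manifest$success[i],
                   fail_reason = NA_character_,
                   seed = manifest$seeds[i],
                   dt_fs = manifest$config$dt_fs,
                   mass_amu = manifest$config$mass_amu),
              class = "zn_trajectory")
  })
  hops <- utils::read.csv(file.path(dir, "hops.csv"))
  if (nrow(hops)) {
    for (i in seq_along(trajectories)) {
      h <- hops[hops$trajectory == i, , drop = FALSE]
      h$position <- angstrom_to_bohr(h$position_angstrom)
      h$gap <- kcal_to_hartree(h$gap_kcalmol)
      h$accepted <- as.logical(h$accepted)
      h$frustrated <- as.logical(h$frustrated)
      trajectories[[i]]$hops <- h
    }
  }
  cfg <- manifest$config
  config <- run_config(dt_fs = cfg$dt_fs, t_max_fs = cfg$t_max_fs,
                       n_traj = cfg$n_traj,
                       gap_threshold_kcal = cfg$gap_threshold_kcal,
                       seed = cfg$seed, mass_amu = cfg$mass_amu,
                       r_threshold_angstrom = cfg$r_threshold_angstrom)
  structure(list(trajectories = trajectories,
                 success = manifest$success,
                 seeds = manifest$seeds,
                 config = config,
                 surface = NULL),
            class = "zn_ensemble")
}
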