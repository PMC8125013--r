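## Ensemble statistics: populations, lifetime fit, hop statistics,
## product classification, quantum yield and ring-closing times.

successful_trajectories <- function(x) {
  if (inherits(x, "zn_ensemble")) x$trajectories[x$success]
  else if (inherits(x, "zn_trajectory")) list(x)
  else x
}

#' Time-dependent state populations
#'
#' Fraction of (successful) trajectories whose active state at each
#' time is the upper / lower adiabatic state.  All trajectories must
#' share the common time grid of the protocol.
#'
#' @param x a `zn_ensemble` or list of `zn_trajectory` objects.
#' @return Data frame with columns `time_fs`, `p_upper`, `p_lower`
#'   (summing to one at every time).
#' @export
populations <- function(x) {
  trajs <- successful_trajectories(x)
  if (length(trajs) == 0) stop("no successful trajectories")
  nt <- vapply(trajs, function(t) length(t$time_au), integer(1))
  if (length(unique(nt)) != 1)
    stop("trajectories do not share a common time grid")
  act <- vapply(trajs, function(t) t$active == 2L, logical(nt[1]))
  if (is.null(dim(act))) act <- matrix(act, nrow = nt[1])
  p_up <- rowMeans(act)
  data.frame(time_fs = au_to_fs(trajs[[1]]$time_au),
             p_upper = p_up, p_lower = 1 - p_up)
}

#' Fit a single-exponential decay to the upper-state population
#'
#' Unweighted least-squares fit of `y = exp(-x / t)` to the upper-state
#' population over the full time window; only the time constant is
#' free, matching the one-parameter decay law used for excited-state
#' lifetimes.
#'
#' @param pop data frame with `time_fs` and `p_upper` (as returned by
#'   [populations()]), or two numeric vectors via `time_fs`/`p_upper`.
#' @param time_fs,p_upper optional explicit vectors overriding `pop`.
#' @return Object of class `zn_decay_fit`: list with `time_constant_fs`,
#'   `residual_norm`, `se_fs` (large-sample standard error from the
#'   local curvature of the least-squares objective).
#' @export
fit_decay <- function(pop = NULL, time_fs = pop$time_fs, p_upper = pop$p_upper) {
  stopifnot(length(time_fs) == length(p_upper), length(time_fs) >= 3)
  if (any(p_upper < -1e-9 | p_upper > 1 + 1e-9))
    stop("populations must lie in [0, 1]")
  if (all(p_upper > 1 - 1e-12) || all(p_upper < 1e-12))
    stop("population curve carries no decay information")
  if (any(diff(p_upper) > 1e-9))
    warning("upper-state population is not non-increasing; fitting anyway")
  obj <- function(log_tau) {
    tau <- exp(log_tau)
    sum((exp(-time_fs / tau) - p_upper)^2)
  }
  opt <- stats::optimize(obj, c(log(1e-3), log(1e7)), tol = 1e-12)
  tau <- exp(opt$minimum)
  ## curvature-based standard error on tau (delta method through log tau)
  h <- 1e-4
  curv <- (obj(opt$minimum + h) - 2 * opt$objective + obj(opt$minimum - h)) / h^2
  n <- length(time_fs)
  sigma2 <- opt$objective / max(n - 1, 1)
  se <- if (curv > 0) tau * sqrt(2 * sigma2 / curv) else NA_real_
  structure(list(time_constant_fs = tau,
                 residual_norm = sqrt(opt$objective),
                 se_fs = se),
            class = "zn_decay_fit")
}

#' @export
print.zn_decay_fit <- function(x, ...) {
  cat(sprintf("<zn_decay_fit> time constant %.1f fs (se %.1f), residual norm %.3g\n",
              x$time_constant_fs, x$se_fs, x$residual_norm))
  invisible(x)
}

first_hop <- function(traj) {
  h <- traj$hops
  if (nrow(h) == 0) return(NULL)
  acc <- h[h$accepted, , drop = FALSE]
  if (nrow(acc) == 0) return(NULL)
  acc[1, ]
}

#' Hop statistics of an ensemble
#'
#' Per-trajectory first accepted hop times, geometries and adiabatic
#' gaps, with their means and histograms.  Later re-crossings remain in
#' each trajectory's hop log but do not enter these distributions.
#' Trajectories that never hop contribute nothing (they are counted in
#' `n_no_hop`).
#'
#' @param x a `zn_ensemble` or list of trajectories.
#' @param time_bin_fs,geom_bin_angstrom,gap_bin_kcal histogram bin
#'   widths.
#' @return List with `per_trajectory` (data frame), `mean_hop_time_fs`,
#'   `mean_hop_geometry_angstrom`, `mean_hop_gap_kcalmol`, `n_no_hop`
#'   and `histograms` (three `hist` objects).
#' @export
hop_statistics <- function(x, time_bin_fs = 20, geom_bin_angstrom = 0.1,
                           gap_bin_kcal = 0.5) {
  trajs <- successful_trajectories(x)
  rows <- lapply(seq_along(trajs), function(i) {
    fh <- first_hop(trajs[[i]])
    if (is.null(fh)) return(NULL)
    data.frame(trajectory = i,
               hop_time_fs = fh$time_fs,
               hop_geometry_angstrom = bohr_to_angstrom(fh$position),
               hop_gap_kcalmol = hartree_to_kcal(fh$gap))
  })
  per <- do.call(rbind, rows)
  n_no_hop <- length(trajs) - length(Filter(Negate(is.null), rows))
  if (is.null(per))
    return(list(per_trajectory = data.frame(), mean_hop_time_fs = NA_real_,
                mean_hop_geometry_angstrom = NA_real_,
                mean_hop_gap_kcalmol = NA_real_,
                n_no_hop = n_no_hop, histograms = NULL))
  bin_breaks <- function(v, w) {
    lo <- floor(min(v) / w) * w
    hi <- ceiling(max(v) / w) * w
    if (hi <= lo) hi <- lo + w
    seq(lo, hi, by = w)
  }
  list(per_trajectory = per,
       mean_hop_time_fs = mean(per$hop_time_fs),
       mean_hop_geometry_angstrom = mean(per$hop_geometry_angstrom),
       mean_hop_gap_kcalmol = mean(per$hop_gap_kcalmol),
       n_no_hop = n_no_hop,
       histograms = list(
         time = graphics::hist(per$hop_time_fs,
                               breaks = bin_breaks(per$hop_time_fs, time_bin_fs),
                               plot = FALSE),
         geometry = graphics::hist(per$hop_geometry_angstrom,
                                   breaks = bin_breaks(per$hop_geometry_angstrom,
                                                       geom_bin_angstrom),
                                   plot = FALSE),
         gap = graphics::hist(per$hop_gap_kcalmol,
                              breaks = bin_breaks(per$hop_gap_kcalmol,
                                                  gap_bin_kcal),
                              plot = FALSE)))
}

#' Classify the final structure of a trajectory
#'
#' A trajectory ends as the ring-closed product when its final
#' ring-closing distance is strictly below the threshold (1.70 Angstrom
#' by default); a final frame at exactly the threshold counts as open.
#'
#' @param trajectory a `zn_trajectory`.
#' @param r_threshold_angstrom classification threshold.
#' @return `"closed"` or `"open"`.
#' @export
classify_final <- function(trajectory, r_threshold_angstrom = 1.70) {
  r_final <- bohr_to_angstrom(utils::tail(as.numeric(trajectory$position), 1))
  if (r_final < r_threshold_angstrom) "closed" else "open"
}

#' Ring-closing quantum yield
#'
#' Fraction of classified trajectories ending as the closed-form
#' product, with a normal-approximation binomial standard error.
#'
#' @param classes character vector of `"open"` / `"closed"` labels, or
#'   a `zn_ensemble` (successful trajectories are classified with the
#'   configured threshold).
#' @param r_threshold_angstrom threshold used when `classes` is an
#'   ensemble.
#' @return List with `yield`, `se`, `n_closed`, `n`.
#' @export
quantum_yield <- function(classes, r_threshold_angstrom = 1.70) {
  if (inherits(classes, "zn_ensemble")) {
    thr <- classes$config$r_threshold_angstrom %||% r_threshold_angstrom
    classes <- vapply(successful_trajectories(classes), classify_final,
                      character(1), r_threshold_angstrom = thr)
  }
  if (length(classes) == 0) stop("no classified trajectories")
  if (!all(classes %in% c("open", "closed")))
    stop("classes must be 'open' or 'closed'")
  n <- length(classes)
  k <- sum(classes == "closed")
  y <- k / n
  list(yield = y, se = sqrt(y * (1 - y) / n), n_closed = k, n = n)
}

#' Ring-closing completion times
#'
#' For each trajectory classified as closed, the time of the first
#' occurrence of a ring-closing distance below the threshold.  A
#' product trajectory whose distance never dips below the threshold is
#' an internal inconsistency and raises an error.
#'
#' @param x a `zn_ensemble` or list of trajectories.
#' @param r_threshold_angstrom threshold, Angstrom.
#' @return List with `per_trajectory` (data frame `trajectory`,
#'   `ring_closing_time_fs`) and `mean_ring_closing_time_fs`.
#' @export
ring_closing_times <- function(x, r_threshold_angstrom = 1.70) {
  trajs <- successful_trajectories(x)
  thr_bohr <- angstrom_to_bohr(r_threshold_angstrom)
  rows <- lapply(seq_along(trajs), function(i) {
    tr <- trajs[[i]]
    if (classify_final(tr, r_threshold_angstrom) != "closed") return(NULL)
    idx <- which(as.numeric(tr$position) < thr_bohr)
    if (length(idx) == 0)
      stop("trajectory ", i, " classified closed but never below threshold")
    data.frame(trajectory = i,
               ring_closing_time_fs = au_to_fs(tr$time_au[idx[1]]))
  })
  per <- do.call(rbind, rows)
  list(per_trajectory = if (is.null(per)) data.frame() else per,
       mean_ring_closing_time_fs =
         if (is.null(per)) NA_real_ else mean(per$ring_closing_time_fs))
}

#' Ensemble summary
#'
#' Assembles the derived quantities of a surface-hopping ensemble in
#' one list: bookkeeping, the exponential lifetime of the upper state,
#' hop statistics, the ring-closing quantum yield with binomial
#' standard error, and ring-closing times.
#'
#' @param ensemble a `zn_ensemble`.
#' @return List (JSON-serializable via [write_summary_json()]).
#' @export
ensemble_summary <- function(ensemble) {
  stopifnot(inherits(ensemble, "zn_ensemble"))
  thr <- ensemble$config$r_threshold_angstrom
  pop <- populations(ensemble)
  fit <- tryCatch(fit_decay(pop), error = function(e) NULL)
  hs <- hop_statistics(ensemble)
  qy <- quantum_yield(ensemble)
  rc <- ring_closing_times(ensemble, thr)
  hist_to_list <- function(h) {
    if (is.null(h)) return(NULL)
    list(breaks = h$breaks, counts = h$counts)
  }
  list(n_total = length(ensemble$trajectories),
       n_success = sum(ensemble$success),
       time_constant_fs = if (is.null(fit)) NA_real_ else fit$time_constant_fs,
       time_constant_se_fs = if (is.null(fit)) NA_real_ else fit$se_fs,
       mean_hop_time_fs = hs$mean_hop_time_fs,
       mean_hop_geometry_angstrom = hs$mean_hop_geometry_angstrom,
       mean_hop_gap_kcalmol = hs$mean_hop_gap_kcalmol,
       n_no_hop = hs$n_no_hop,
       yield = qy$yield,
       yield_se = qy$se,
       n_closed = qy$n_closed,
       mean_ring_closing_time_fs = rc$mean_ring_closing_time_fs,
       r_threshold_angstrom = thr,
       histograms = if (is.null(hs$histograms)) NULL else
         lapply(hs$histograms, hist_to_list))
}

#' Write an ensemble summary as JSON
#'
#' @param summary list from [ensemble_summary()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_summary_json <- function(summary, path) {
  jsonlite::write_json(summary, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' Plot ensemble results
#'
#' Base-graphics views of an ensemble: state populations versus time,
#' or the ring-closing distance of every trajectory.
#'
#' @param x a `zn_ensemble`.
#' @param which `"populations"` or `"distance"`.
#' @param ... passed to the underlying plot call.
#' @return `x`, invisibly.
#' @export
plot.zn_ensemble <- function(x, which = c("populations", "distance"), ...) {
  which <- match.arg(which)
  if (which == "populations") {
    pop <- populations(x)
    graphics::plot(pop$time_fs, pop$p_upper, type = "l", col = "firebrick",
                   xlab = "time (fs)", ylab = "population", ylim = c(0, 1), ...)
    graphics::lines(pop$time_fs, pop$p_lower, col = "steelblue")
    graphics::legend("right", legend = c("S1", "S0"), lty = 1,
                     col = c("firebrick", "steelblue"), bty = "n")
  } else {
    trajs <- successful_trajectories(x)
    t_fs <- au_to_fs(trajs[[1]]$time_au)
    rs <- vapply(trajs, function(tr) bohr_to_angstrom(as.numeric(tr$position)),
                 numeric(length(t_fs)))
    graphics::matplot(t_fs, rs, type = "l", lty = 1,
                      col = grDevices::adjustcolor("grey30", 0.5),
                      xlab = "time (fs)", ylab = "C1-C6 distance (Angstrom)", ...)
    graphics::abline(h = x$config$r_threshold_angstrom, lty = 2)
  }
  invisible(x)
}
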