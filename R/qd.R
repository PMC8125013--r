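## Numerically exact two-state quantum dynamics on 1-D diabatic models
## (split-operator Fourier propagation) and the classic Landau-Zener
## closed form.  Ground truth for the semiclassical hop probability.

#' Gaussian wavepacket on a grid
#'
#' Builds a two-component wavepacket on a uniform grid with a
#' normalized Gaussian `exp(-(x-x0)^2/(4 sigma^2) + i p0 x)` placed on
#' one diabatic component and zero on the other.
#'
#' @param x_min,x_max,n_points uniform grid specification (Bohr).
#' @param x0,p0 centre and mean momentum, a.u.
#' @param sigma position width (standard deviation of |psi|^2), Bohr.
#' @param mass particle mass, a.u.
#' @param state diabatic component carrying the packet (1 or 2).
#' @return Object of class `zn_wavepacket`: list with `x`, `dx`, `psi`
#'   (n x 2 complex matrix), `mass`, `time`.
#' @export
gaussian_wavepacket <- function(x_min, x_max, n_points, x0, p0, sigma, mass,
                                state = 1L) {
  stopifnot(x_max > x_min, n_points >= 16, sigma > 0, mass > 0,
            state %in% c(1L, 2L))
  x <- seq(x_min, x_max, length.out = n_points)
  dx <- x[2] - x[1]
  amp <- exp(-(x - x0)^2 / (4 * sigma^2)) * exp(1i * p0 * x)
  amp <- amp / sqrt(sum(Mod(amp)^2) * dx)
  psi <- matrix(0 + 0i, n_points, 2)
  psi[, state] <- amp
  structure(list(x = x, dx = dx, psi = psi, mass = mass, time = 0),
            class = "zn_wavepacket")
}

packet_norm <- function(packet) sum(Mod(packet$psi)^2) * packet$dx

packet_populations <- function(packet) {
  p <- colSums(Mod(packet$psi)^2) * packet$dx
  names(p) <- c("diabat_1", "diabat_2")
  p
}

packet_mean_x <- function(packet, component = NULL) {
  w <- if (is.null(component)) rowSums(Mod(packet$psi)^2)
  else Mod(packet$psi[, component])^2
  tot <- sum(w)
  if (tot < 1e-12) return(NA_real_)
  sum(packet$x * w) / tot
}

diabatic_matrix_on_grid <- function(model, x) {
  if (!inherits(model, "linear_crossing"))
    stop("exact propagation requires a diabatically defined model ",
         "(linear_crossing)")
  list(h11 = model$slope_1 * x,
       h22 = model$slope_2 * x,
       v = rep(model$coupling, length(x)))
}

## pointwise adiabatic eigenvectors of the 2x2 diabatic Hamiltonian:
## lower state (-v, delta + Omega), upper state (delta + Omega, v),
## normalized; delta = (h11 - h22)/2, Omega = sqrt(delta^2 + v^2)
adiabatic_frame <- function(model, x) {
  pot <- diabatic_matrix_on_grid(model, x)
  delta <- (pot$h11 - pot$h22) / 2
  omega <- sqrt(delta^2 + pot$v^2)
  a <- delta + omega
  nrm <- sqrt(pot$v^2 + a^2)
  list(lower1 = -pot$v / nrm, lower2 = a / nrm,
       upper1 = a / nrm, upper2 = pot$v / nrm)
}

## populations of the two local adiabatic states
packet_adiabatic_populations <- function(model, packet) {
  fr <- adiabatic_frame(model, packet$x)
  lo <- fr$lower1 * packet$psi[, 1] + fr$lower2 * packet$psi[, 2]
  up <- fr$upper1 * packet$psi[, 1] + fr$upper2 * packet$psi[, 2]
  p <- c(lower = sum(Mod(lo)^2), upper = sum(Mod(up)^2)) * packet$dx
  p
}

#' Split-operator propagation of a two-state wavepacket
#'
#' Strang-split propagation in the diabatic basis: half-step with the
#' analytic exponential of the 2x2 potential matrix at every grid
#' point, full kinetic step in momentum space (FFT), half potential
#' step.  Unitary up to roundoff; the norm is monitored and the packet
#' must stay negligible at the grid edges.
#'
#' @param model a diabatically defined surface (see [linear_crossing()]).
#' @param packet a `zn_wavepacket`.
#' @param dt time step, a.u.
#' @param n_steps number of steps.
#' @param edge_tol maximum admissible probability amplitude at the grid
#'   edges before propagation aborts with an "enlarge grid" diagnostic.
#' @param check_every edge/norm check interval, steps.
#' @return The propagated `zn_wavepacket`.
#' @export
propagate_split_operator <- function(model, packet, dt, n_steps,
                                     edge_tol = 1e-6, check_every = 200L) {
  stopifnot(inherits(packet, "zn_wavepacket"), dt > 0, n_steps >= 1)
  n <- length(packet$x)
  pot <- diabatic_matrix_on_grid(model, packet$x)
  mean_e <- (pot$h11 + pot$h22) / 2
  delta <- (pot$h11 - pot$h22) / 2
  omega <- sqrt(delta^2 + pot$v^2)
  tau <- dt / 2
  ## exp(-i H tau) = e^{-i mean tau} [cos(omega tau) I
  ##                  - i sin(omega tau)/omega * (delta, v; v, -delta)]
  ph <- exp(-1i * mean_e * tau)
  ct <- cos(omega * tau)
  st_w <- ifelse(omega > 0, sin(omega * tau) / omega, tau)
  u11 <- ph * (ct - 1i * st_w * delta)
  u22 <- ph * (ct + 1i * st_w * delta)
  u12 <- ph * (-1i * st_w * pot$v)
  ## kinetic phases on the FFT frequency grid
  k <- 2 * pi * c(0:(n %/% 2), -((n - n %/% 2 - 1):1)) / (n * packet$dx)
  kin <- exp(-1i * k^2 / (2 * packet$mass) * dt)
  psi1 <- packet$psi[, 1]
  psi2 <- packet$psi[, 2]
  edge <- c(1:4, (n - 3):n)
  for (s in seq_len(n_steps)) {
    t1 <- u11 * psi1 + u12 * psi2
    t2 <- u12 * psi1 + u22 * psi2
    t1 <- stats::fft(stats::fft(t1) * kin, inverse = TRUE) / n
    t2 <- stats::fft(stats::fft(t2) * kin, inverse = TRUE) / n
    psi1 <- u11 * t1 + u12 * t2
    psi2 <- u12 * t1 + u22 * t2
    if (s %% check_every == 0L || s == n_steps) {
      if (max(Mod(psi1[edge]), Mod(psi2[edge])) > edge_tol)
        stop("wavepacket reached the grid edge: enlarge grid", call. = FALSE)
    }
  }
  packet$psi <- cbind(psi1, psi2)
  packet$time <- packet$time + n_steps * dt
  packet
}

#' Exact single-passage transition probability
#'
#' Scattering experiment on a linear-crossing model: a quasi-
#' monochromatic Gaussian packet (energy spread a fixed fraction of the
#' collision energy) starts far on one side on the lower adiabat,
#' traverses the crossing once, and the populations are read off in the
#' local adiabatic basis (pointwise rotation of the diabatic
#' amplitudes) once both channels have cleared the interaction region.
#' The upper-adiabat population is the single-passage surface-hop
#' probability that Zhu-Nakamura theory approximates.
#'
#' @param model a [linear_crossing()] with slopes of the same sign
#'   (transmission topology), so both channels leave the crossing.
#' @param collision_energy kinetic energy at the crossing, Hartree.
#' @param start_offset distance of the initial packet centre from the
#'   crossing, Bohr.
#' @param stop_offset packet-centre distance past the crossing at which
#'   populations are read off, Bohr.
#' @param n_points grid size.
#' @param dt time step, a.u.
#' @param energy_spread fractional energy spread of the packet.
#' @return List with `p_hop` (asymptotic population of the upper
#'   adiabat, i.e. the nonadiabatic transition probability),
#'   `p_adiabatic` (= 1 - p_hop, staying on the lower adiabat),
#'   `populations` (diabatic basis), `populations_adiabatic`,
#'   `n_steps`, `norm_error`.
#' @export
exact_transition_probability <- function(model, collision_energy,
                                         start_offset = 35, stop_offset = 25,
                                         n_points = 2048, dt = 2,
                                         energy_spread = 0.04) {
  stopifnot(inherits(model, "linear_crossing"))
  if (collision_energy <= 0) stop("collision energy must be positive")
  if (sign(model$slope_1) * sign(model$slope_2) <= 0)
    stop("scattering oracle needs slopes of the same sign, so both ",
         "channels propagate away from the crossing")
  mu <- model$mass
  p0 <- sqrt(2 * mu * collision_energy)
  ## sigma_E / E = 1/(sigma_x p0); quasi-monochromatic packet
  sigma <- 1 / (energy_spread * p0)
  dirn <- if (model$slope_1 < 0) 1 else -1  # travel downhill on diabat 1
  x0 <- -dirn * start_offset
  ## read-off distance scales with the packet width: the transition is
  ## only complete once the whole packet has traversed the seam
  stop_eff <- max(stop_offset, 3 * sigma)
  ## grid: room behind the start, and beyond the read-off point enough
  ## for the front of the faster (accelerated) outgoing channel, born
  ## when the leading edge first reaches the seam, to coast while the
  ## slower channel clears the interaction region
  v_x <- sqrt(2 * collision_energy / mu)
  a_max <- max(abs(model$slope_1), abs(model$slope_2)) / mu
  horizon <- (stop_eff + 6 * sigma) / v_x
  coast <- v_x * horizon + 0.5 * a_max * horizon^2
  span_lo <- start_offset + 10 * sigma
  span_hi <- coast + 12 * sigma + 30
  if (dirn > 0) {
    x_min <- -span_lo; x_max <- span_hi
  } else {
    x_min <- -span_hi; x_max <- span_lo
  }
  ## total energy fixed: kinetic at start compensates the diabat-1 slope
  e_pot0 <- model$slope_1 * x0
  ke0 <- collision_energy - e_pot0
  if (ke0 <= 0) stop("start_offset puts the packet above the total energy")
  pk <- gaussian_wavepacket(x_min, x_max, n_points,
                            x0 = x0, p0 = dirn * sqrt(2 * mu * ke0),
                            sigma = sigma, mass = mu, state = 1L)
  ## launch on the local lower adiabat (which correlates with diabat 1
  ## on the incoming side); exact for any coupling strength
  fr0 <- adiabatic_frame(model, pk$x)
  amp <- pk$psi[, 1]
  pk$psi[, 1] <- amp * fr0$lower1
  pk$psi[, 2] <- amp * fr0$lower2
  norm0 <- packet_norm(pk)
  v_min <- sqrt(2 * collision_energy / mu) / 2  # conservative mean speed
  chunk <- max(50L, ceiling(5 / (v_min * dt)))
  max_steps <- ceiling(4 * (start_offset + stop_eff + 6 * sigma) / (v_min * dt))
  done <- 0L
  repeat {
    pk <- propagate_split_operator(model, pk, dt, chunk)
    done <- done + chunk
    pop <- packet_populations(pk)
    ## both channels (where populated) must have cleared the crossing;
    ## past that point the residual diabatic rotation decays as
    ## (V12 / (slope-difference * distance))^2, far below tolerance
    xm <- vapply(1:2, function(s)
      if (pop[s] > 1e-4) dirn * packet_mean_x(pk, s) else Inf, numeric(1))
    if (min(xm) > stop_eff) break
    if (done > max_steps)
      stop("packet did not clear the interaction region: ",
           "insufficient propagation time")
  }
  pop <- packet_populations(pk)
  pop_ad <- packet_adiabatic_populations(model, pk)
  list(p_hop = unname(pop_ad["upper"]),
       p_adiabatic = unname(pop_ad["lower"]),
       populations = pop,
       populations_adiabatic = pop_ad,
       n_steps = done,
       norm_error = abs(packet_norm(pk) - norm0))
}

#' Classic Landau-Zener transition probability
#'
#' `p = exp(-2 pi V12^2 / (hbar v |dF|))` for a linear crossing
#' traversed at speed `v` with diabatic slope difference `dF`
#' (atomic units, hbar = 1).
#'
#' @param speed seam-crossing speed, a.u. (> 0).
#' @param slope_difference difference of diabatic slopes, Hartree/Bohr
#'   (non-zero).
#' @param coupling diabatic coupling V12, Hartree (> 0).
#' @return Diabatic-passage (hop) probability.
#' @export
lz_probability <- function(speed, slope_difference, coupling) {
  stopifnot(is.numeric(speed), is.numeric(slope_difference), is.numeric(coupling))
  if (speed <= 0) stop("speed must be positive")
  if (slope_difference == 0) stop("slope difference must be non-zero")
  if (coupling < 0) stop("coupling must be non-negative")
  exp(-2 * pi * coupling^2 / (speed * abs(slope_difference)))
}

#' Zhu-Nakamura single-passage probability on an analytic model
#'
#' Evaluates the Zhu-Nakamura probability for one passage through the
#' crossing of a linear model at a given collision energy, using the
#' model's analytic diabatic slopes and coupling (no trajectory
#' involved).  Used to compare the semiclassical formula against the
#' exact wavepacket result and the Landau-Zener limit.
#'
#' @param model a [linear_crossing()].
#' @param collision_energy kinetic energy at the crossing, Hartree.
#' @return Hop probability.
#' @export
zn_single_passage <- function(model, collision_energy) {
  stopifnot(inherits(model, "linear_crossing"))
  f1 <- -model$slope_1
  f2 <- -model$slope_2
  g <- mass_scaled_product(f1, f2, model$mass)
  d2 <- mass_scaled_difference_sq(f1, f2, model$mass)
  par <- zn_parameters(model$coupling, ex = 0, et = collision_energy,
                       g = g, d2 = d2)
  zn_probability(par$a_sq, par$b_sq, par$branch)
}

#' Oracle comparison scan
#'
#' Scans collision energies above the crossing of a linear model and
#' tabulates the exact wavepacket probability, the Zhu-Nakamura value
#' and the classic Landau-Zener formula.
#'
#' @param model a [linear_crossing()].
#' @param energies collision energies, Hartree.
#' @param path optional CSV output path.
#' @param ... passed to [exact_transition_probability()].
#' @return Data frame with columns `collision_energy`, `p_exact`,
#'   `p_exact_adiabatic`, `p_zn`, `p_lz`.
#' @export
oracle_scan <- function(model, energies, path = NULL, ...) {
  rows <- lapply(energies, function(e) {
    ex <- exact_transition_probability(model, e, ...)
    v <- sqrt(2 * e / model$mass)
    data.frame(collision_energy = e,
               p_exact = ex$p_hop,
               p_exact_adiabatic = ex$p_adiabatic,
               p_zn = zn_single_passage(model, e),
               p_lz = lz_probability(v, model$slope_2 - model$slope_1,
                                     model$coupling))
  })
  out <- do.call(rbind, rows)
  if (!is.null(path)) {
    utils::write.csv(format(out, digits = 15, trim = TRUE), path,
                     row.names = FALSE, quote = FALSE)
  }
  out
}
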