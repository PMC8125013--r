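## Wigner sampling of harmonic initial conditions.
##
## The ground-vibrational-state Wigner density of a harmonic mode is a
## product of Gaussians in position and momentum,
##   sigma_x = sqrt(hbar / (2 mu omega)),  sigma_p = sqrt(hbar mu omega / 2),
## centred at the equilibrium geometry with zero mean momentum.  The
## dynamics driver samples nuclei on the lower-state open-form well and
## then promotes the electronic state to the upper surface without
## touching the nuclei (vertical excitation).

## Run expr with a private RNG stream; the caller's stream is untouched.
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Harmonic mode from local surface curvature
#'
#' Locates a minimum of one adiabatic state of a surface near a guess
#' and builds the harmonic mode used for Wigner sampling: the frequency
#' is `omega = sqrt(k / mass)` with the force constant `k` taken from a
#' central finite difference of the analytic gradient at the minimum.
#'
#' @param surface a surface object.
#' @param state `"lower"` or `"upper"`: which adiabatic state to probe.
#' @param minimum_guess starting coordinate, Bohr.
#' @param mass mode mass, electron-mass units.
#' @param window half-width of the search window around the guess, Bohr.
#' @param h finite-difference step for the curvature, Bohr.
#' @return An object of class `harmonic_mode`: list with
#'   `equilibrium_position` (Bohr), `omega` (atomic units), `mass`, and
#'   `frequency_cm` for convenience.
#' @examples
#' s <- harmonic_surface(k = 0.01, x0 = 1.5)
#' mode_from_curvature(s, "lower", minimum_guess = 1.2, mass = 2000)
#' @export
mode_from_curvature <- function(surface, state = c("lower", "upper"),
                                minimum_guess, mass, window = 1.0, h = 1e-3) {
  state <- match.arg(state)
  stopifnot(is.numeric(minimum_guess), length(minimum_guess) == 1,
            is.numeric(mass), mass > 0, window > 0)
  dom <- surface_domain(surface)
  lo <- max(minimum_guess - window, dom[1])
  hi <- min(minimum_guess + window, dom[2])
  grad <- function(x) surface_eval(surface, x)$gradients[[state]]

  ## bracket a sign change of the gradient on a fine grid, then polish
  xs <- seq(lo, hi, length.out = 201)
  gs <- vapply(xs, grad, numeric(1))
  lhs <- gs[-length(gs)]; rhs <- gs[-1]
  idx <- which(lhs <= 0 & rhs >= 0 & (lhs < 0 | rhs > 0))
  if (length(idx) == 0) {
    if (all(abs(gs) < 1e-12))
      stop("surface is flat in the search window: no minimum to locate")
    stop("no local minimum of the ", state,
         " state found within the search window")
  }
  i <- idx[which.min(abs(xs[idx] - minimum_guess))]
  x0 <- stats::uniroot(grad, c(xs[i], xs[i + 1]), tol = 1e-13)$root
  if (abs(grad(x0)) >= 1e-8)
    stop("minimum search did not converge: |gradient| >= 1e-8 Hartree/Bohr")
  k <- (grad(x0 + h) - grad(x0 - h)) / (2 * h)
  if (k <= 0)
    stop("negative curvature at the located stationary point: not a minimum")
  structure(list(equilibrium_position = x0,
                 omega = sqrt(k / mass),
                 mass = mass,
                 frequency_cm = hartree_to_wavenumber(sqrt(k / mass))),
            class = "harmonic_mode")
}

#' @export
print.harmonic_mode <- function(x, ...) {
  cat(sprintf("<harmonic_mode> x0 = %.6f Bohr, omega = %.3e a.u. (%.1f cm^-1), mass = %.1f a.u.\n",
              x$equilibrium_position, x$omega, x$frequency_cm, x$mass))
  invisible(x)
}

#' Sample the ground-state Wigner distribution of a harmonic mode
#'
#' Draws independent (position, momentum) pairs from the
#' ground-vibrational-state (0 K) Wigner density of the mode: Gaussians
#' with `sigma_x = sqrt(1/(2 mu omega))` and
#' `sigma_p = sqrt(mu omega / 2)` (atomic units, hbar = 1), centred at
#' the equilibrium position with zero mean momentum.  The draw is
#' reproducible given `seed` and does not disturb the caller's RNG
#' stream.
#'
#' @param mode a `harmonic_mode` object (or list with
#'   `equilibrium_position`, `omega`, `mass`).
#' @param n number of samples (>= 1).
#' @param seed integer seed.
#' @return Data frame with columns `index`, `position` (Bohr),
#'   `momentum` (a.u.).
#' @export
wigner_sample <- function(mode, n, seed) {
  stopifnot(n >= 1, is.numeric(seed))
  if (!is.finite(mode$omega) || mode$omega <= 0) stop("mode omega must be positive")
  if (mode$mass <= 0) stop("mode mass must be positive")
  sx <- sqrt(1 / (2 * mode$mass * mode$omega))
  sp <- sqrt(mode$mass * mode$omega / 2)
  with_local_seed(seed, {
    data.frame(index = seq_len(n),
               position = stats::rnorm(n, mode$equilibrium_position, sx),
               momentum = stats::rnorm(n, 0, sp))
  })
}

#' Read / write initial-condition sets
#'
#' Initial conditions travel as plain CSV with columns `index`,
#' `position_angstrom`, `momentum_au`, so a sampled set can be archived
#' next to the trajectories it seeded.
#'
#' @param samples data frame from [wigner_sample()] (a.u. columns
#'   `position`, `momentum`).
#' @param path file path.
#' @return `write_initial_conditions()` returns `path` invisibly;
#'   `read_initial_conditions()` the data frame in internal units.
#' @export
write_initial_conditions <- function(samples, path) {
  df <- data.frame(index = samples$index,
                   position_angstrom = bohr_to_angstrom(samples$position),
                   momentum_au = samples$momentum)
  utils::write.csv(format(df, digits = 15, trim = TRUE), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_initial_conditions
#' @export
read_initial_conditions <- function(path) {
  df <- utils::read.csv(path)
  data.frame(index = df$index,
             position = angstrom_to_bohr(df$position_angstrom),
             momentum = df$momentum_au)
}
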