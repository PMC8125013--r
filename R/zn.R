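## Zhu-Nakamura hop machinery.
##
## At a crossing the semiclassical transition probability is
##   p = exp[ -(pi / (4 a)) * sqrt( 2 / (b2 + sqrt(b2^2 + s)) ) ]
## with the dimensionless effective coupling a^2 and collision energy
## b2 built from the two mass-scaled one-dimensional diabatic forces
## F1, F2, the diabatic coupling V12 and the energies Ex (crossing) and
## Et (potential plus the kinetic-energy component along the hopping
## direction):
##   a^2 = hbar^2 sqrt(G) sqrt(D2) / (2 (2 V12)^3)
##   b2  = (Et - Ex) sqrt(D2) / (2 V12 sqrt(G))
## where the multi-dimensional force reductions absorb the reduced mass:
##   G  = sum_i (1/m_i) sum_alpha F2_ia F1_ia
##   D2 = sum_i (1/m_i) sum_alpha (F2_ia - F1_ia)^2.
## In the weak-coupling, high-energy regime this reduces to the classic
## Landau-Zener exponent; that limit (and agreement with exact
## wavepacket dynamics) fixes the convention.

expand_masses <- function(masses, d) {
  if (length(masses) == d) return(masses)
  if (3 * length(masses) == d) return(rep(masses, each = 3))
  stop("masses must have one entry per coordinate or per atom (3 coordinates each)")
}

#' Mass-scaled diabatic force reductions
#'
#' Collapse the multi-dimensional diabatic force vectors of the two
#' states into the two scalars entering the Zhu-Nakamura parameters:
#' `mass_scaled_product()` returns
#' `G = sum_i (1/m_i) sum_alpha F2_ia * F1_ia` and
#' `mass_scaled_difference_sq()` returns
#' `D2 = sum_i (1/m_i) sum_alpha (F2_ia - F1_ia)^2 >= 0`.
#' For one-dimensional models these are `F1*F2/m` and `(F2-F1)^2/m`.
#'
#' @param f1,f2 diabatic force vectors of equal length (3N Cartesian
#'   components, or length 1 for model systems), Hartree/Bohr.
#' @param masses positive masses, one per coordinate or one per atom.
#' @return A scalar (atomic units).
#' @export
mass_scaled_product <- function(f1, f2, masses) {
  if (length(f1) != length(f2)) stop("force vectors must have equal dimension")
  m <- expand_masses(masses, length(f1))
  if (any(m <= 0)) stop("masses must be positive")
  sum(f1 * f2 / m)
}

#' @rdname mass_scaled_product
#' @export
mass_scaled_difference_sq <- function(f1, f2, masses) {
  if (length(f1) != length(f2)) stop("force vectors must have equal dimension")
  m <- expand_masses(masses, length(f1))
  if (any(m <= 0)) stop("masses must be positive")
  sum((f2 - f1)^2 / m)
}

#' Zhu-Nakamura dimensionless parameters
#'
#' Computes the effective coupling `a^2` and the signed collision
#' energy `b^2` from the crossing-point data.  A non-positive force
#' product `G` signals a non-Landau-Zener crossing topology (the
#' recovered diabats do not both carry the system through the seam);
#' following common trajectory-code practice its magnitude is used and
#' the situation is flagged in the result.
#'
#' @param v12 diabatic coupling, Hartree (> 0).
#' @param ex energy at the crossing point, Hartree.
#' @param et potential energy plus kinetic-energy component along the
#'   hopping direction, Hartree.
#' @param g force product from [mass_scaled_product()].
#' @param d2 squared force difference from [mass_scaled_difference_sq()].
#' @param hbar reduced Planck constant (1 in atomic units).
#' @return List with `a_sq`, `b_sq`, `branch` (+1 if `et >= ex`, else
#'   -1) and `non_lz` (TRUE when `g <= 0` was flagged).
#' @export
zn_parameters <- function(v12, ex, et, g, d2, hbar = 1) {
  stopifnot(is.numeric(v12), is.numeric(ex), is.numeric(et),
            is.numeric(g), is.numeric(d2))
  if (v12 <= 0) stop("v12 must be positive")
  if (d2 < 0) stop("d2 must be non-negative")
  non_lz <- g <= 0
  if (non_lz && d2 > 0)
    g <- abs(g)
  if (d2 == 0) {
    a_sq <- 0
    b_sq <- 0
  } else {
    if (g == 0) stop("degenerate crossing: force product is zero with d2 > 0")
    a_sq <- hbar^2 * sqrt(g) * sqrt(d2) / (2 * (2 * v12)^3)
    b_sq <- (et - ex) * sqrt(d2) / (2 * v12 * sqrt(g))
  }
  list(a_sq = a_sq, b_sq = b_sq,
       branch = if (et >= ex) 1L else -1L,
       non_lz = non_lz)
}

#' Zhu-Nakamura transition probability
#'
#' Single-passage hop probability
#' `p = exp(-(pi/(4a)) * sqrt(2 / (b2 + sqrt(b2^2 + s))))` with
#' `s = +1` for the classically allowed branch (`et >= ex`) and
#' `s = -1` otherwise.  On the forbidden branch the inner root is
#' clamped to zero when `b2^2 < 1` and the probability is zero whenever
#' the bracket is non-positive, so `p` is always real and in [0, 1]
#' and vanishes far below the crossing.
#'
#' @param a_sq effective coupling squared (> 0).
#' @param b_sq signed collision-energy parameter.
#' @param branch +1 or -1 (sign in the inner root).
#' @return Hop probability in [0, 1].
#' @examples
#' zn_probability(1, 1, 1)  # exp(-(pi/4) * sqrt(2/(1 + sqrt(2)))) ~ 0.489
#' @export
zn_probability <- function(a_sq, b_sq, branch = 1L) {
  stopifnot(is.numeric(a_sq), is.numeric(b_sq))
  if (!is.finite(a_sq) || a_sq <= 0) stop("a_sq must be positive")
  if (!branch %in% c(-1L, 1L, -1, 1)) stop("branch must be +1 or -1")
  inner <- b_sq^2 + sign(branch)
  if (inner < 0) inner <- 0
  denom <- b_sq + sqrt(inner)
  if (denom <= 0) return(0)
  p <- exp(-(pi / (4 * sqrt(a_sq))) * sqrt(2 / denom))
  min(max(p, 0), 1)
}

#' Recover diabatic data at a local gap minimum
#'
#' Builds the local diabatic picture of a crossing from three adiabatic
#' evaluations bracketing a strict local minimum of the adiabatic gap:
#' the coupling is half the minimum gap, the crossing energy is the
#' mean of the two adiabatic energies there, and the diabatic force
#' vectors follow the states diabatically through the seam (diabat 1:
#' lower-state force before, upper-state force after the minimum;
#' diabat 2 conversely; each averaged over its two one-sided
#' estimates).  Forces are negative gradients.
#'
#' @param before,at,after `zn_surface_eval` objects; `at` must have the
#'   smallest gap of the three.
#' @return List with `f1`, `f2` (diabatic force vectors, Hartree/Bohr),
#'   `v12` (Hartree), `ex` (Hartree).
#' @export
diabatize_crossing <- function(before, at, after) {
  gaps <- c(eval_gap(before), eval_gap(at), eval_gap(after))
  if (!(gaps[2] < gaps[1] && gaps[2] < gaps[3]))
    stop("'at' must be a strict local minimum of the adiabatic gap ",
         "bracketed by 'before' and 'after'")
  f1 <- -(before$gradients$lower + after$gradients$upper) / 2
  f2 <- -(before$gradients$upper + after$gradients$lower) / 2
  list(f1 = f1, f2 = f2,
       v12 = gaps[2] / 2,
       ex = mean(at$energies))
}

#' Momentum adjustment at a surface hop
#'
#' Rescales the momentum component along the hopping direction so that
#' kinetic plus (new) potential energy is conserved exactly: solves
#' `sum_i (p_i + gamma u_i)^2 / (2 m_i) = KE + deltaE` for the smaller
#' root `gamma` and applies `p -> p + gamma u`.  If the quadratic has
#' no real root (an upward hop with insufficient kinetic energy along
#' the direction) the hop is frustrated and the velocities are returned
#' unchanged.
#'
#' @param velocities current velocities, a.u.
#' @param masses positive masses, one per coordinate or per atom.
#' @param direction unit vector along the hopping direction.
#' @param delta_e potential-energy change made available to the nuclei:
#'   positive for a downward hop (kinetic energy gained), negative for
#'   an upward hop.
#' @return List with `velocities` (adjusted or original), `frustrated`
#'   (logical) and `gamma` (the applied momentum shift, `NA` when
#'   frustrated).
#' @export
hop_adjust_momentum <- function(velocities, masses, direction, delta_e) {
  d <- length(velocities)
  m <- expand_masses(masses, d)
  if (length(direction) != d) stop("direction must match the velocity dimension")
  nrm <- sqrt(sum(direction^2))
  if (nrm == 0) stop("hopping direction must be a non-zero vector")
  u <- direction / nrm
  p <- m * velocities
  a <- sum(u^2 / (2 * m))
  b <- sum(p * u / m)
  cc <- -delta_e
  disc <- b^2 - 4 * a * cc
  if (disc < 0)
    return(list(velocities = velocities, frustrated = TRUE, gamma = NA_real_))
  ## smaller-|gamma| root: least perturbation of the nuclear motion
  r1 <- (-b + sqrt(disc)) / (2 * a)
  r2 <- (-b - sqrt(disc)) / (2 * a)
  gamma <- if (abs(r1) <= abs(r2)) r1 else r2
  list(velocities = (p + gamma * u) / m, frustrated = FALSE, gamma = gamma)
}

## kinetic energy along a unit direction (used for Et)
kinetic_along <- function(velocities, masses, direction) {
  m <- expand_masses(masses, length(velocities))
  nrm <- sqrt(sum(direction^2))
  if (nrm == 0) return(0)
  u <- direction / nrm
  p <- m * velocities
  sum(p * u)^2 / (2 * sum(u^2 * m))
}
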