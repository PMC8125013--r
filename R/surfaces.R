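## Two-state potential-energy surfaces.
##
## Every surface answers surface_eval(surface, x) with both adiabatic
## energies, both adiabatic gradients and, for diabatically defined
## models, the 2x2 diabatic Hamiltonian.  Coordinates, energies and
## gradients are in atomic units (Bohr, Hartree, Hartree/Bohr).

#' Evaluate a two-state surface at one nuclear configuration
#'
#' @param surface a surface object (`linear_crossing()`,
#'   `harmonic_surface()` or `build_surrogate()`).
#' @param coordinates numeric vector of nuclear coordinates in Bohr
#'   (length 1 for the one-dimensional models shipped with the package).
#' @return An object of class `zn_surface_eval`: a list with elements
#'   `coordinates`, `energies` (lower, upper; Hartree), `gradients`
#'   (list of two vectors, Hartree/Bohr) and `diabatic` (2x2 symmetric
#'   matrix in Hartree, or `NULL` for adiabatically defined surfaces).
#' @export
surface_eval <- function(surface, coordinates) UseMethod("surface_eval")

#' Coordinate domain of a surface
#'
#' @param surface a surface object.
#' @return Numeric vector `c(lower, upper)` in Bohr; infinite for the
#'   analytic models.
#' @export
surface_domain <- function(surface) UseMethod("surface_domain")

new_surface_eval <- function(coordinates, energies, gradients, diabatic = NULL) {
  structure(
    list(coordinates = coordinates, energies = energies,
         gradients = gradients, diabatic = diabatic),
    class = "zn_surface_eval")
}

#' Adiabatic energy gap of an evaluation
#' @param ev a `zn_surface_eval` object.
#' @return Upper minus lower adiabatic energy, Hartree.
#' @export
eval_gap <- function(ev) unname(ev$energies[2] - ev$energies[1])

check_domain <- function(surface, coordinates) {
  dom <- surface_domain(surface)
  if (any(coordinates < dom[1]) || any(coordinates > dom[2]))
    stop(sprintf("coordinate %.6g Bohr outside surface domain [%.6g, %.6g] Bohr",
                 coordinates[1], dom[1], dom[2]), call. = FALSE)
  invisible(TRUE)
}

## ---------------------------------------------------------------------
## Analytic linear-crossing (Landau-Zener) model
## ---------------------------------------------------------------------

#' Linear diabatic crossing model
#'
#' Two linear diabatic potentials `H11 = slope_1 * x`, `H22 = slope_2 * x`
#' coupled by a constant off-diagonal element `V12`, crossing at the
#' origin.  This is the textbook Landau-Zener setting and the exactly
#' solvable test bed for the Zhu-Nakamura hop probability: the classic
#' Landau-Zener formula and numerically exact wavepacket dynamics are
#' both available on it.
#'
#' Slopes of the same sign give a transmission-type (Landau-Zener)
#' crossing in which both diabats carry the particle through the seam;
#' opposite signs give the nonadiabatic-tunnelling topology in which the
#' adiabatic surfaces form a well facing a barrier.
#'
#' @param slope_1,slope_2 diabatic slopes, Hartree/Bohr; must differ.
#' @param coupling constant diabatic coupling V12, Hartree; positive.
#' @param mass particle mass, electron-mass units (atomic units).
#' @return A surface object of class `c("linear_crossing", "zn_surface")`.
#' @examples
#' m <- linear_crossing(-0.006, -0.001, coupling = 0.002, mass = 2000)
#' surface_eval(m, 0)$energies    # gap at the seam is 2 * coupling
#' @export
linear_crossing <- function(slope_1, slope_2, coupling, mass = 2000) {
  stopifnot(is.numeric(slope_1), is.numeric(slope_2),
            is.numeric(coupling), is.numeric(mass))
  if (!is.finite(coupling) || coupling <= 0) stop("coupling must be positive")
  if (slope_1 == slope_2) stop("slopes must differ to define a crossing")
  if (mass <= 0) stop("mass must be positive")
  structure(list(slope_1 = slope_1, slope_2 = slope_2,
                 coupling = coupling, mass = mass),
            class = c("linear_crossing", "zn_surface"))
}

#' @export
surface_domain.linear_crossing <- function(surface) c(-Inf, Inf)

#' @export
surface_eval.linear_crossing <- function(surface, coordinates) {
  stopifnot(length(coordinates) == 1, is.finite(coordinates))
  x <- coordinates
  h11 <- surface$slope_1 * x
  h22 <- surface$slope_2 * x
  v <- surface$coupling
  mean_e <- (h11 + h22) / 2
  half <- sqrt(((h11 - h22) / 2)^2 + v^2)
  ## d/dx of mean and of the root term
  dmean <- (surface$slope_1 + surface$slope_2) / 2
  ddelta <- (surface$slope_1 - surface$slope_2) / 2
  droot <- ((h11 - h22) / 2) * ddelta / half
  new_surface_eval(
    coordinates = x,
    energies = c(mean_e - half, mean_e + half),
    gradients = list(lower = dmean - droot, upper = dmean + droot),
    diabatic = matrix(c(h11, v, v, h22), 2, 2))
}

## ---------------------------------------------------------------------
## Harmonic reference surface (integrator / sampling tests)
## ---------------------------------------------------------------------

#' Harmonic two-state reference surface
#'
#' Lower state `V(x) = offset + k/2 (x - x0)^2`, upper state shifted up
#' by a constant `gap` (parallel surfaces, no crossing).  With `k = 0`
#' both surfaces are flat and force-free.  Used for closed-form checks
#' of the integrator and of curvature-based normal-mode extraction.
#'
#' @param k force constant, Hartree/Bohr^2 (>= 0).
#' @param x0 equilibrium position, Bohr.
#' @param gap constant adiabatic separation, Hartree (> 0).
#' @param offset energy of the lower-state minimum, Hartree.
#' @return A surface object of class `c("harmonic_surface", "zn_surface")`.
#' @export
harmonic_surface <- function(k, x0 = 0, gap = 1, offset = 0) {
  stopifnot(is.numeric(k), k >= 0, gap > 0)
  structure(list(k = k, x0 = x0, gap = gap, offset = offset),
            class = c("harmonic_surface", "zn_surface"))
}

#' @export
surface_domain.harmonic_surface <- function(surface) c(-Inf, Inf)

#' @export
surface_eval.harmonic_surface <- function(surface, coordinates) {
  stopifnot(length(coordinates) == 1, is.finite(coordinates))
  x <- coordinates
  e <- surface$offset + 0.5 * surface$k * (x - surface$x0)^2
  g <- surface$k * (x - surface$x0)
  new_surface_eval(
    coordinates = x,
    energies = c(e, e + surface$gap),
    gradients = list(lower = g, upper = g))
}

## ---------------------------------------------------------------------
## Calibrated one-dimensional photoswitch surrogate
## ---------------------------------------------------------------------

#' Packaged anchor tables for the photoswitch surrogate
#'
#' Calibration anchors for the ring-closing coordinate (the C1-C6
#' interfragment distance) of the diarylethene photoswitch, with
#' energies in kcal/mol relative to the open-form ground-state minimum.
#' Two variants are shipped:
#' \describe{
#'   \item{`"scan"`}{the excited-state relaxed-scan profile: S1 falls
#'     monotonically from 73.0 kcal/mol at the open geometry
#'     (r = 3.302 A) to 45.6 kcal/mol at the S1/S0 crossing region
#'     (r = 2.103 A) and rises again to 52.0 kcal/mol at the closed
#'     geometry (r = 1.517 A), while the scan-path S0 runs
#'     34.4 -> 44.0 -> 18.9 kcal/mol.}
#'   \item{`"reactive"`}{the same S1 profile over the ground-state
#'     reaction path: S0 at 0.0 (open minimum), 40.8 (thermal
#'     ring-closing barrier, r = 1.945 A) and -5.6 kcal/mol (closed
#'     minimum).  This variant supports both wells and is the default
#'     surface for full open/closed dynamics.}
#' }
#'
#' @param variant `"scan"` or `"reactive"`.
#' @return Data frame with columns `r_angstrom`, `e_s0_kcalmol`,
#'   `e_s1_kcalmol` (NA where a state has no anchor at that geometry).
#' @export
psiv_anchors <- function(variant = c("reactive", "scan")) {
  variant <- match.arg(variant)
  path <- system.file("extdata", paste0("psiv_anchors_", variant, ".csv"),
                      package = "zntraj", mustWork = TRUE)
  read_anchor_table(path, variant = variant)
}

#' Read / write anchor tables
#'
#' Anchor tables are plain CSV with columns `r_angstrom`,
#' `e_s0_kcalmol`, `e_s1_kcalmol`; rows ordered from the open (largest
#' r) to the closed (smallest r) geometry.  Empty cells mark geometries
#' at which a state has no calibration point.
#'
#' @param path file path.
#' @param variant optional label attached to the table.
#' @param anchors an anchor data frame as returned by `psiv_anchors()`.
#' @return `read_anchor_table()` returns the anchor data frame;
#'   `write_anchor_table()` returns `path` invisibly.
#' @export
read_anchor_table <- function(path, variant = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("r_angstrom", "e_s0_kcalmol", "e_s1_kcalmol")
  if (!all(need %in% names(df)))
    stop("anchor table must have columns ", paste(need, collapse = ", "))
  df <- df[need]
  validate_anchors(df)
  attr(df, "variant") <- variant
  df
}

#' @rdname read_anchor_table
#' @export
write_anchor_table <- function(anchors, path) {
  utils::write.csv(anchors, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

validate_anchors <- function(anchors) {
  r <- anchors$r_angstrom
  if (any(!is.finite(r))) stop("anchor r values must be finite")
  if (is.unsorted(rev(r), strictly = TRUE))
    stop("anchor r values must be strictly decreasing from open to closed")
  for (st in c("e_s0_kcalmol", "e_s1_kcalmol")) {
    if (sum(is.finite(anchors[[st]])) < 3)
      stop("need at least 3 anchor points per state (", st, ")")
  }
  invisible(TRUE)
}

## Smooth floor: identity for g >= floor + w, constant floor below
## floor - w, C1 quadratic blend in between (w = band half-width).
gap_floor_fun <- function(g, floor, w) {
  out <- g
  lo <- g <= floor - w
  mid <- !lo & g < floor + w
  out[lo] <- floor
  out[mid] <- floor + (g[mid] - floor + w)^2 / (4 * w)
  out
}

gap_floor_deriv <- function(g, floor, w) {
  d <- rep(1, length(g))
  d[g <= floor - w] <- 0
  mid <- g > floor - w & g < floor + w
  d[mid] <- (g[mid] - floor + w) / (2 * w)
  d
}

#' Build the calibrated photoswitch surrogate surface
#'
#' Constructs a one-dimensional two-state adiabatic surface along the
#' ring-closing (C1-C6 distance) coordinate from a table of ab initio
#' calibration anchors.  Each state's curve is a shape-preserving
#' monotone cubic through its anchors (no spurious extrema between
#' anchors), extended beyond the anchor range by harmonic walls whose
#' minima sit exactly at the open (largest-r anchor) and closed
#' (smallest-r anchor) geometries.  A smooth gap floor keeps the
#' adiabatic separation at or above `gap_floor` near the crossing
#' region, so the adiabatic representation never becomes degenerate.
#'
#' The interpolated curves reproduce every anchor exactly provided the
#' anchor's own gap clears the floor band (`gap_floor * 1.1`); with the
#' default 1 kcal/mol floor this holds for both packaged variants.
#'
#' @param anchors anchor data frame (see [read_anchor_table()]);
#'   defaults to the packaged reactive-path table.
#' @param gap_floor minimum adiabatic S1-S0 separation, kcal/mol
#'   (default 1.0; hopping-point gaps of the reference simulations lie
#'   in the 0-4 kcal/mol range, so a ~1 kcal/mol floor preserves strong
#'   hopping while keeping the surfaces well separated).
#' @param open_wall_cm,closed_wall_cm harmonic-wall frequencies
#'   (cm^-1, together with `mass_amu`) applied beyond the open- and
#'   closed-side anchor limits.  The open well is a loose interfragment
#'   mode (default 300 cm^-1); the closed-side wall resists compressing
#'   a freshly formed C-C sigma bond and is much stiffer (default
#'   1200 cm^-1).
#' @param mass_amu effective reduced mass of the ring-closing
#'   coordinate, amu (default 6, two carbon-like fragments).
#' @param domain_angstrom coordinate domain in Angstrom; trajectories
#'   leaving it are flagged as failed.
#' @return A surface object of class `c("surrogate_surface", "zn_surface")`.
#' @examples
#' surf <- build_surrogate(psiv_anchors("scan"))
#' surrogate_energies(surf, c(3.302, 2.103, 1.517))
#' @export
build_surrogate <- function(anchors = psiv_anchors("reactive"),
                            gap_floor = 1.0,
                            open_wall_cm = 300,
                            closed_wall_cm = 1200,
                            mass_amu = 6,
                            domain_angstrom = c(0.9, 9.0)) {
  validate_anchors(anchors)
  if (!is.finite(gap_floor) || gap_floor <= 0) stop("gap_floor must be positive")
  stopifnot(open_wall_cm > 0, closed_wall_cm > 0, mass_amu > 0)

  ## internal units
  to_x <- function(r) angstrom_to_bohr(r)
  to_e <- function(e) kcal_to_hartree(e)
  curves <- lapply(c(s0 = "e_s0_kcalmol", s1 = "e_s1_kcalmol"), function(col) {
    keep <- is.finite(anchors[[col]])
    x <- to_x(anchors$r_angstrom[keep])
    y <- to_e(anchors[[col]][keep])
    ord <- order(x)
    ## zero endpoint slopes: the harmonic walls outside the anchor hull
    ## then attach with a continuous (zero) gradient
    pchip_fun(x[ord], y[ord], end_slopes = c(0, 0))
  })
  hull <- range(to_x(anchors$r_angstrom))
  mass_au <- amu_to_au(mass_amu)
  k_open <- mass_au * wavenumber_to_hartree(open_wall_cm)^2
  k_closed <- mass_au * wavenumber_to_hartree(closed_wall_cm)^2

  raw_state <- function(x, which, deriv = 0L) {
    f <- curves[[which]]
    if (x >= hull[1] && x <= hull[2]) {
      f(x, deriv)
    } else if (x > hull[2]) {
      if (deriv == 0L) f(hull[2]) + 0.5 * k_open * (x - hull[2])^2
      else k_open * (x - hull[2])
    } else {
      if (deriv == 0L) f(hull[1]) + 0.5 * k_closed * (x - hull[1])^2
      else -k_closed * (hull[1] - x)
    }
  }

  surf <- structure(
    list(anchors = anchors,
         variant = attr(anchors, "variant"),
         gap_floor = to_e(gap_floor),
         gap_band = 0.1 * to_e(gap_floor),
         k_open = k_open, k_closed = k_closed,
         mass_amu = mass_amu,
         hull = hull,
         domain = to_x(sort(domain_angstrom)),
         raw_state = raw_state),
    class = c("surrogate_surface", "zn_surface"))

  ## reject interpolants whose adiabatic ordering breaks down: a raw
  ## gap that reaches zero cannot be floored without inverting states
  xs <- seq(hull[1], hull[2], length.out = 2001)
  raw_gap <- vapply(xs, function(x) raw_state(x, "s1") - raw_state(x, "s0"),
                    numeric(1))
  if (any(raw_gap <= 0)) {
    stop(sprintf(paste0("interpolated S1 and S0 curves cross near r = %.3f ",
                        "Angstrom (raw gap %.3f kcal/mol); the gap floor ",
                        "cannot regularize a crossed adiabatic ordering"),
                 bohr_to_angstrom(xs[which.min(raw_gap)]),
                 hartree_to_kcal(min(raw_gap))), call. = FALSE)
  }
  surf
}

#' @export
surface_domain.surrogate_surface <- function(surface) surface$domain

#' @export
surface_eval.surrogate_surface <- function(surface, coordinates) {
  stopifnot(length(coordinates) == 1, is.finite(coordinates))
  check_domain(surface, coordinates)
  x <- coordinates
  e0 <- surface$raw_state(x, "s0"); d0 <- surface$raw_state(x, "s0", 1L)
  e1 <- surface$raw_state(x, "s1"); d1 <- surface$raw_state(x, "s1", 1L)
  mean_e <- (e0 + e1) / 2
  g <- e1 - e0
  gt <- gap_floor_fun(g, surface$gap_floor, surface$gap_band)
  dgt <- gap_floor_deriv(g, surface$gap_floor, surface$gap_band) * (d1 - d0)
  dmean <- (d0 + d1) / 2
  new_surface_eval(
    coordinates = x,
    energies = c(mean_e - gt / 2, mean_e + gt / 2),
    gradients = list(lower = dmean - dgt / 2, upper = dmean + dgt / 2))
}

#' Surrogate energies in laboratory units
#'
#' Convenience wrapper evaluating a surrogate surface on a vector of
#' C1-C6 distances and returning both adiabatic energies in kcal/mol
#' (relative to the open-form ground-state minimum, the calibration
#' zero).
#'
#' @param surface a `surrogate_surface` object.
#' @param r_angstrom numeric vector of distances, Angstrom.
#' @return Data frame with columns `r_angstrom`, `e_s0_kcalmol`,
#'   `e_s1_kcalmol`, `gap_kcalmol`.
#' @export
surrogate_energies <- function(surface, r_angstrom) {
  stopifnot(inherits(surface, "surrogate_surface"))
  ev <- lapply(angstrom_to_bohr(r_angstrom),
               function(x) surface_eval(surface, x)$energies)
  e <- do.call(rbind, ev)
  data.frame(r_angstrom = r_angstrom,
             e_s0_kcalmol = hartree_to_kcal(e[, 1]),
             e_s1_kcalmol = hartree_to_kcal(e[, 2]),
             gap_kcalmol = hartree_to_kcal(e[, 2] - e[, 1]))
}

#' @export
print.zn_surface <- function(x, ...) {
  cat("<", class(x)[1], ">\n", sep = "")
  if (inherits(x, "linear_crossing")) {
    cat(sprintf("  slopes: %g, %g Hartree/Bohr; V12 = %g Hartree; mass = %g a.u.\n",
                x$slope_1, x$slope_2, x$coupling, x$mass))
  } else if (inherits(x, "surrogate_surface")) {
    cat(sprintf("  variant: %s; %d anchors; gap floor %.2f kcal/mol\n",
                if (is.null(x$variant)) "custom" else x$variant,
                nrow(x$anchors), hartree_to_kcal(x$gap_floor)))
    cat(sprintf("  anchor hull: [%.3f, %.3f] Angstrom; domain [%.2f, %.2f] Angstrom\n",
                bohr_to_angstrom(x$hull[1]), bohr_to_angstrom(x$hull[2]),
                bohr_to_angstrom(x$domain[1]), bohr_to_angstrom(x$domain[2])))
  }
  invisible(x)
}
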