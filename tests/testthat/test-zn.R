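test_that("mass-scaled force reductions match a brute-force double loop", {
  set.seed(42)
  for (rep in 1:5) {
    f1 <- stats::rnorm(6); f2 <- stats::rnorm(6)
    masses <- c(12, 1)  # per-atom masses, two atoms x three coordinates
    g_loop <- 0; d_loop <- 0
    for (i in 1:2) {
      for (a in 1:3) {
        idx <- (i - 1) * 3 + a
        g_loop <- g_loop + f2[idx] * f1[idx] / masses[i]
        d_loop <- d_loop + (f2[idx] - f1[idx])^2 / masses[i]
      }
    }
    expect_equal(mass_scaled_product(f1, f2, masses), g_loop, tolerance = 1e-12)
    expect_equal(mass_scaled_difference_sq(f1, f2, masses), d_loop,
                 tolerance = 1e-12)
  }
})

test_that("force reductions handle the degenerate and orthogonal cases", {
  expect_equal(mass_scaled_product(c(1, 0, 0), c(1, 0, 0), 2), 0.5)
  expect_equal(mass_scaled_product(c(1, 0, 0), c(0, 1, 0), c(3, 5, 7)), 0)
  expect_equal(mass_scaled_difference_sq(c(0.3, -1), c(0.3, -1), c(2, 4)), 0)
  expect_equal(mass_scaled_difference_sq(0, 2, 4), 1.0)
  expect_error(mass_scaled_product(1:3, 1:2, 1), "equal dimension")
  expect_error(mass_scaled_product(1:3, 1:3, c(-1, 1, 1)), "positive")
})

test_that("ZN parameters carry the stated powers of the coupling", {
  base <- zn_parameters(v12 = 0.002, ex = 0, et = 0.01, g = 4e-8, d2 = 2e-7)
  dbl <- zn_parameters(v12 = 0.004, ex = 0, et = 0.01, g = 4e-8, d2 = 2e-7)
  expect_equal(dbl$a_sq / base$a_sq, 1 / 8, tolerance = 1e-12)
  expect_equal(abs(dbl$b_sq / base$b_sq), 1 / 2, tolerance = 1e-12)
  ## degenerate crossing: equal parallel forces
  degen <- zn_parameters(v12 = 0.002, ex = 0, et = 0.01, g = 4e-8, d2 = 0)
  expect_equal(degen$a_sq, 0)
  expect_equal(degen$b_sq, 0)
  ## non-LZ topology flagged, magnitude used
  flipped <- zn_parameters(v12 = 0.002, ex = 0, et = 0.01, g = -4e-8, d2 = 2e-7)
  expect_true(flipped$non_lz)
  expect_equal(flipped$a_sq, base$a_sq, tolerance = 1e-12)
  expect_error(zn_parameters(v12 = -1, ex = 0, et = 0, g = 1, d2 = 1),
               "positive")
})

test_that("ZN parameters match closed-form substitution on a linear model", {
  ## slopes -f1, -f2, coupling v: diabatic forces f1, f2
  f1 <- 1e-5; f2 <- 9e-5; v <- 1.5e-4; mu <- 2000; e <- 0.01
  g <- f1 * f2 / mu
  d2 <- (f2 - f1)^2 / mu
  par <- zn_parameters(v, ex = 0, et = e, g = g, d2 = d2)
  expect_equal(par$a_sq, sqrt(f1 * f2) * abs(f2 - f1) / (mu * 2 * (2 * v)^3),
               tolerance = 1e-12)
  expect_equal(par$b_sq, e * abs(f2 - f1) / (2 * v * sqrt(f1 * f2)),
               tolerance = 1e-12)
})

test_that("ZN probability matches its closed form and limiting behaviour", {
  expect_equal(zn_probability(1, 1, 1),
               exp(-(pi / 4) * sqrt(2 / (1 + sqrt(2)))), tolerance = 1e-12)
  ## strong-coupling / adiabatic limit
  expect_lt(zn_probability(1e-8, 1, 1), 1e-100)
  ## high collision energy limit
  expect_gt(zn_probability(1, 1e8, 1), 1 - 1e-3)
  expect_error(zn_probability(0, 1, 1), "positive")
  expect_error(zn_probability(1, 1, 2), "branch")
})

test_that("hop probability is monotone in collision energy and bounded", {
  f1 <- 2e-5; f2 <- 9e-5; v <- 1.5e-4; mu <- 2000
  g <- f1 * f2 / mu; d2 <- (f2 - f1)^2 / mu
  ex <- 0.005
  ets <- seq(-0.01, 0.05, length.out = 400)
  ps <- vapply(ets, function(et) {
    par <- zn_parameters(v, ex, et, g, d2)
    zn_probability(par$a_sq, par$b_sq, par$branch)
  }, numeric(1))
  expect_true(all(ps >= 0 & ps <= 1))
  expect_true(all(diff(ps) >= -1e-12))
  ## continuity on the classically allowed branch: increments shrink
  ## proportionally with the grid spacing (no O(1) jumps)
  allowed <- ets >= ex
  expect_lt(max(abs(diff(ps[allowed]))), 0.05)
  fine <- seq(ex, 0.05, length.out = 4000)
  psf <- vapply(fine, function(et) {
    par <- zn_parameters(v, ex, et, g, d2)
    zn_probability(par$a_sq, par$b_sq, par$branch)
  }, numeric(1))
  expect_lt(max(abs(diff(psf))), 0.006)
  ## vanishes far below the crossing
  expect_equal(ps[1], 0)
})

test_that("diabatization at a symmetric linear crossing recovers the model", {
  f <- 0.01; v <- 0.002
  m <- symmetric_model(f = f, v = v)
  d <- 2
  dia <- diabatize_crossing(surface_eval(m, -d), surface_eval(m, 0),
                            surface_eval(m, d))
  expect_equal(dia$v12, v, tolerance = 0.02)
  expect_equal(dia$ex, 0, tolerance = 1e-12)
  expect_equal(abs(dia$f2 - dia$f1), 2 * f, tolerance = 0.05)
  ## diabat 1 follows H11 = +f x through the seam: force -f
  expect_equal(dia$f1, -f, tolerance = 0.05)
  expect_equal(dia$f2, +f, tolerance = 0.05)
  expect_error(diabatize_crossing(surface_eval(m, 1), surface_eval(m, 2),
                                  surface_eval(m, 3)), "local minimum")
})

test_that("momentum adjustment at hops conserves energy exactly", {
  v <- c(1e-3, -2e-4, 5e-4); masses <- c(1800, 1800, 3600)
  u <- c(1, 1, 0) / sqrt(2)
  ke <- function(vv) 0.5 * sum(masses * vv^2)
  ## identity when no potential change
  same <- hop_adjust_momentum(v, masses, u, 0)
  expect_false(same$frustrated)
  expect_equal(same$velocities, v, tolerance = 1e-12)
  ## downward hop gains exactly deltaE
  de <- 2e-4
  down <- hop_adjust_momentum(v, masses, u, de)
  expect_false(down$frustrated)
  expect_equal(ke(down$velocities) - ke(v), de, tolerance = 1e-14)
  ## only the component along the direction changes
  perp <- c(1, -1, 0) / sqrt(2)
  expect_equal(sum(masses * down$velocities * perp),
               sum(masses * v * perp), tolerance = 1e-12)
  ## upward hop beyond the projected kinetic energy is frustrated
  up <- hop_adjust_momentum(v, masses, u, -10)
  expect_true(up$frustrated)
  expect_identical(up$velocities, v)
  expect_error(hop_adjust_momentum(v, masses, c(0, 0, 0), 0.1), "non-zero")
})

test_that("single-passage ZN agrees with the Landau-Zener closed form when weakly coupled", {
  m <- oracle_model(coupling = 5e-5)
  for (e in c(0.01, 0.02, 0.05)) {
    v_speed <- sqrt(2 * e / m$mass)
    p_lz <- lz_probability(v_speed, m$slope_2 - m$slope_1, m$coupling)
    expect_equal(zn_single_passage(m, e), p_lz, tolerance = 0.05 * p_lz)
  }
})
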