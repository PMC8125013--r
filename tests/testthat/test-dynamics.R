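test_that("velocity Verlet is exact for force-free motion", {
  s <- harmonic_surface(k = 0)
  st <- trajectory_state(0, 0.5, 2e-3, masses = 2000, active = "lower",
                         surface = s)
  for (i in 1:100) st <- verlet_step(st, s, 10)
  expect_equal(st$position, 0.5 + 2e-3 * 1000, tolerance = 1e-12)
  expect_equal(st$velocity, 2e-3, tolerance = 1e-15)
})

test_that("velocity Verlet matches the analytic harmonic oscillator", {
  s <- harmonic_surface(k = 1, x0 = 0)   # mu = 1, omega = 1 a.u.
  dt <- 0.01
  n <- round(2 * pi / dt)
  st <- trajectory_state(0, 1, 0, masses = 1, active = "lower", surface = s)
  e0 <- 0.5  # total energy of x(0) = 1, v(0) = 0
  for (i in seq_len(n)) st <- verlet_step(st, s, dt)
  ## symplectic: the oscillatory energy error cancels over a period
  expect_lt(abs(0.5 * st$velocity^2 + 0.5 * st$position^2 - e0), 1e-6)
  expect_lt(abs(st$position - cos(n * dt)), 1e-3)
  expect_lt(abs(st$velocity + sin(n * dt)), 1e-3)
})

test_that("the in-period energy-error amplitude scales as dt^2", {
  s <- harmonic_surface(k = 1, x0 = 0)
  drift <- function(dt) {
    st <- trajectory_state(0, 1, 0, masses = 1, active = "lower", surface = s)
    worst <- 0
    for (i in seq_len(round(2 * pi / dt)))  {
      st <- verlet_step(st, s, dt)
      worst <- max(worst, abs(0.5 * st$velocity^2 + 0.5 * st$position^2 - 0.5))
    }
    worst
  }
  ratio <- drift(0.02) / drift(0.01)
  expect_gt(ratio, 2.5)
  expect_lt(ratio, 6)
})

test_that("a zero gap gate disables hopping entirely", {
  cfg <- run_config(t_max_fs = 120, gap_threshold_kcal = 0, seed = 3)
  surf <- build_surrogate()
  tr <- run_trajectory(surf, list(position = angstrom_to_bohr(3.302),
                                  momentum = -2), cfg, seed = 5)
  expect_false(tr$failed)
  expect_equal(nrow(tr$hops), 0)
  expect_true(all(tr$active == 2L))
})

test_that("strong coupling keeps the dynamics adiabatic", {
  m <- linear_crossing(0.005, -0.005, coupling = 0.02, mass = 2000)
  cfg <- run_config(t_max_fs = 200, mass_amu = au_to_amu(2000), seed = 1)
  tr <- run_trajectory(m, list(position = -4, momentum = 2000 * 6e-3),
                       cfg, seed = 8)
  expect_false(tr$failed)
  if (nrow(tr$hops) > 0) {
    expect_true(all(!tr$hops$accepted))
    expect_true(all(tr$hops$probability < 1e-6))
  }
  expect_true(all(tr$active == 2L))
})

test_that("trajectories are bit-reproducible under a fixed seed", {
  surf <- build_surrogate()
  cfg <- run_config(t_max_fs = 200, seed = 1)
  ic <- list(position = angstrom_to_bohr(3.25), momentum = -1)
  a <- run_trajectory(surf, ic, cfg, seed = 17)
  b <- run_trajectory(surf, ic, cfg, seed = 17)
  expect_identical(a$position, b$position)
  expect_identical(a$hops, b$hops)
  c <- run_trajectory(surf, ic, cfg, seed = 18)
  expect_false(identical(a$hops, c$hops))
})

test_that("domain escape marks a trajectory failed and keeps the prefix", {
  surf <- build_surrogate(domain_angstrom = c(2.5, 4.0))
  cfg <- run_config(t_max_fs = 300, seed = 1)
  tr <- run_trajectory(surf, list(position = angstrom_to_bohr(3.3),
                                  momentum = -8), cfg, seed = 2)
  expect_true(tr$failed)
  expect_match(tr$fail_reason, "domain")
  expect_lt(length(tr$time_au), 301)
})

test_that("accepted hops conserve total energy at the hop instant", {
  ens <- run_ensemble(run_config(n_traj = 6, t_max_fs = 300, seed = 4))
  acc <- do.call(rbind, lapply(ens$trajectories, function(tr)
    tr$hops[tr$hops$accepted, , drop = FALSE]))
  expect_gt(nrow(acc), 0)
  expect_lt(max(abs(acc$e_total_post - acc$e_total_pre)), 1e-10)
})

test_that("surrogate energy conservation holds between hops and tightens with dt", {
  inter_hop_drift <- function(ens) {
    worst <- 0
    for (tr in ens$trajectories[ens$success]) {
      bounds <- c(0, round(tr$hops$time_fs[tr$hops$accepted] / tr$dt_fs),
                  length(tr$time_au) - 1)
      for (k in seq_len(length(bounds) - 1)) {
        seg <- (bounds[k] + 2):(bounds[k + 1])
        if (length(seg) < 2) next
        worst <- max(worst, max(abs(tr$e_total[seg] - tr$e_total[seg[1]])))
      }
    }
    hartree_to_kcal(worst)
  }
  d_full <- inter_hop_drift(run_ensemble(run_config(n_traj = 8, seed = 6)))
  d_half <- inter_hop_drift(run_ensemble(run_config(n_traj = 8, seed = 6,
                                                    dt_fs = 0.5)))
  ## protocol step: bounded oscillatory error on the steep closed-form
  ## flank; halving the step recovers the 1 kcal/mol budget
  expect_lt(d_full, 5)
  expect_lt(d_half, 1)
  expect_lt(d_half, d_full / 2.5)
})

test_that("every successful trajectory reaches the gap gate on the surrogate", {
  ens <- run_ensemble(run_config(n_traj = 10, seed = 9))
  for (tr in ens$trajectories[ens$success]) {
    expect_gt(nrow(tr$hops), 0)  # at least one attempt => gate reached
    expect_true(all(hartree_to_kcal(tr$hops$gap) < 30))
  }
})

test_that("ensembles are reproducible and bookkeep failures", {
  cfg <- run_config(n_traj = 4, t_max_fs = 150, seed = 21)
  a <- run_ensemble(cfg)
  b <- run_ensemble(cfg)
  expect_identical(lapply(a$trajectories, `[[`, "position"),
                   lapply(b$trajectories, `[[`, "position"))
  expect_identical(a$seeds, b$seeds)
  expect_equal(length(a$trajectories), 4)
  n_rows <- vapply(a$trajectories, function(tr) length(tr$time_au), integer(1))
  expect_true(all(n_rows[a$success] == 151))
})

test_that("a single-trajectory ensemble equals that trajectory's indicators", {
  cfg <- run_config(n_traj = 1, t_max_fs = 400, seed = 12)
  ens <- run_ensemble(cfg)
  pop <- populations(ens)
  tr <- ens$trajectories[[1]]
  expect_true(all(pop$p_upper %in% c(0, 1)))
  expect_equal(pop$p_upper, as.numeric(tr$active == 2L))
  qy <- quantum_yield(ens)
  expect_equal(qy$n, 1)
  expect_true(qy$yield %in% c(0, 1))
})

test_that("ensembles round-trip through the on-disk CSV/JSON layout", {
  dir <- withr::local_tempdir()
  ens <- run_ensemble(run_config(n_traj = 3, t_max_fs = 120, seed = 31))
  write_ensemble(ens, dir)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  expect_length(list.files(dir, pattern = "^traj_"), 3)
  back <- read_ensemble(dir)
  expect_equal(length(back$trajectories), 3)
  expect_equal(back$trajectories[[2]]$position, ens$trajectories[[2]]$position,
               tolerance = 1e-12)
  expect_equal(populations(back), populations(ens), tolerance = 1e-12)
  hs_a <- hop_statistics(ens); hs_b <- hop_statistics(back)
  expect_equal(hs_b$mean_hop_time_fs, hs_a$mean_hop_time_fs)
})
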