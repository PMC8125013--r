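test_that("populations are normalized step functions of the hop pattern", {
  trs <- lapply(c(100, 100, 100), fake_decay_traj)
  pop <- populations(trs)
  expect_true(all(pop$p_upper + pop$p_lower == 1))
  expect_true(all(pop$p_upper[pop$time_fs < 100] == 1))
  expect_true(all(pop$p_upper[pop$time_fs >= 100] == 0))
  single <- populations(list(fake_decay_traj(250)))
  expect_true(all(single$p_upper %in% c(0, 1)))
  expect_equal(single$p_upper[1], 1)
  expect_error(populations(list()), "no successful")
})

test_that("an exponential hop-time ensemble yields the generating lifetime", {
  tau <- 120
  set.seed(2024)
  hop_times <- stats::rexp(500, rate = 1 / tau)
  trs <- lapply(pmin(round(hop_times), 499), fake_decay_traj)
  fit <- fit_decay(populations(trs))
  expect_lt(abs(fit$time_constant_fs - tau) / tau, 0.10)
})

test_that("decay fitting recovers exact and noisy time constants", {
  x <- seq(0, 500, length.out = 500)
  fit <- fit_decay(time_fs = x, p_upper = exp(-x / 143))
  expect_equal(fit$time_constant_fs, 143, tolerance = 1e-6)
  set.seed(31)
  for (rep in 1:100) {
    noisy <- pmin(pmax(exp(-x / 143) + stats::runif(500, -0.05, 0.05), 0), 1)
    f <- suppressWarnings(fit_decay(time_fs = x, p_upper = noisy))
    expect_lt(abs(f$time_constant_fs - 143) / 143, 0.05)
  }
  expect_error(fit_decay(time_fs = x, p_upper = rep(1, 500)), "no decay")
  expect_error(fit_decay(time_fs = x, p_upper = rep(0, 500)), "no decay")
  expect_warning(fit_decay(time_fs = 0:10,
                           p_upper = c(1, 0.5, 0.7, rep(0.3, 8))),
                 "non-increasing")
})

test_that("hop statistics aggregate first accepted hops only", {
  t1 <- fake_traj(0:500, rep(3, 501), c(rep(2L, 100), rep(1L, 401)),
                  hops = make_hops(c(100, 220), angstrom_to_bohr(c(2.2, 2.1)),
                                   kcal_to_hartree(c(2, 3))))
  t2 <- fake_decay_traj(140); t3 <- fake_decay_traj(180)
  t2$hops$position <- angstrom_to_bohr(2.2)
  t3$hops$position <- angstrom_to_bohr(2.2)
  hs <- hop_statistics(list(t1, t2, t3))
  expect_equal(hs$mean_hop_time_fs, mean(c(100, 140, 180)))
  expect_equal(nrow(hs$per_trajectory), 3)
  ## the second hop of t1 does not enter the first-hop distribution
  expect_false(220 %in% hs$per_trajectory$hop_time_fs)
  ## identical geometries concentrate in one histogram bin
  hs2 <- hop_statistics(list(t2, t3))
  expect_equal(sum(hs2$histograms$geometry$counts > 0), 1)
  ## a no-hop trajectory contributes nothing but is counted
  hs3 <- hop_statistics(list(t2, fake_decay_traj(Inf)))
  expect_equal(hs3$n_no_hop, 1)
  expect_equal(nrow(hs3$per_trajectory), 1)
})

test_that("final-structure classification uses a strict threshold", {
  expect_equal(classify_final(fake_traj(0:1, c(3, 1.6), c(2L, 1L))), "closed")
  expect_equal(classify_final(fake_traj(0:1, c(3, 3.0), c(2L, 1L))), "open")
  expect_equal(classify_final(fake_traj(0:1, c(3, 1.70), c(2L, 1L))), "open")
})

test_that("quantum yield counts products with a binomial standard error", {
  qy <- quantum_yield(c(rep("closed", 19), rep("open", 15)))
  expect_equal(qy$yield, 19 / 34)
  expect_equal(round(100 * qy$yield), 56)
  expect_equal(qy$se, sqrt((19 / 34) * (15 / 34) / 34), tolerance = 1e-12)
  expect_equal(quantum_yield(rep("open", 8))$yield, 0)
  expect_equal(quantum_yield(rep("closed", 5))$yield, 1)
  expect_error(quantum_yield(character(0)), "no classified")
  expect_error(quantum_yield(c("closed", "weird")), "open")
})

test_that("ring-closing times take the first sub-threshold crossing", {
  mono <- fake_traj(0:400, c(seq(3.3, 1.5, length.out = 201), rep(1.5, 200)),
                    rep(1L, 401))
  idx <- which(c(seq(3.3, 1.5, length.out = 201), rep(1.5, 200)) < 1.70)[1]
  rc <- ring_closing_times(list(mono))
  expect_equal(rc$per_trajectory$ring_closing_time_fs, idx - 1)
  ## dips below, recrosses, ends closed: first occurrence counts
  r <- rep(3, 401); r[151] <- 1.65; r[350:401] <- 1.6
  dip <- fake_traj(0:400, r, rep(1L, 401))
  expect_equal(ring_closing_times(list(dip))$per_trajectory$ring_closing_time_fs,
               150)
  ## constructed products average as plain arithmetic
  mk <- function(t0) {
    r <- rep(3, 401); r[(t0 + 1):401] <- 1.6
    fake_traj(0:400, r, rep(1L, 401))
  }
  rc3 <- ring_closing_times(list(mk(150), mk(200), mk(250)))
  expect_equal(rc3$mean_ring_closing_time_fs, 200)
  ## open trajectories are excluded
  rc4 <- ring_closing_times(list(mk(150), fake_decay_traj(100)))
  expect_equal(nrow(rc4$per_trajectory), 1)
})

test_that("ring-closing timing and classification agree on the surrogate ensemble", {
  ens <- run_ensemble(run_config(n_traj = 12, seed = 2))
  rc <- ring_closing_times(ens)
  classes <- vapply(ens$trajectories[ens$success], classify_final, character(1))
  expect_equal(nrow(rc$per_trajectory), sum(classes == "closed"))
  if (nrow(rc$per_trajectory) > 0) {
    expect_true(all(rc$per_trajectory$ring_closing_time_fs >= 0))
    expect_true(all(rc$per_trajectory$ring_closing_time_fs <= 500))
    expect_true(is.finite(rc$mean_ring_closing_time_fs))
  }
})

test_that("the ensemble summary assembles all derived quantities", {
  ens <- run_ensemble(run_config(n_traj = 8, seed = 13))
  s <- suppressWarnings(ensemble_summary(ens))
  expect_equal(s$n_total, 8)
  expect_true(is.finite(s$yield) && s$yield >= 0 && s$yield <= 1)
  expect_true(is.finite(s$yield_se))
  expect_true(is.finite(s$mean_hop_time_fs))
  path <- withr::local_tempfile(fileext = ".json")
  write_summary_json(s, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$n_success, s$n_success)
  expect_equal(back$yield, s$yield, tolerance = 1e-12)
})
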