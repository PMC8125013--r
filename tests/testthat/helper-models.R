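# Shared analytic fixtures; everything is built in code at test time.

# transmission-type (same-sign slopes) crossing used against the exact
# wavepacket oracle: nearly flat incoming diabat keeps the collision
# energy well defined far from the seam
oracle_model <- function(coupling = 1.5e-4) {
  linear_crossing(-1e-5, -9e-5, coupling = coupling, mass = 2000)
}

# symmetric avoided crossing (opposite slopes) for diabatization tests
symmetric_model <- function(f = 0.01, v = 0.002, mass = 2000) {
  linear_crossing(f, -f, coupling = v, mass = mass)
}

empty_hops <- function() {
  data.frame(time_fs = numeric(0), position = numeric(0), gap = numeric(0),
             a_sq = numeric(0), b_sq = numeric(0), probability = numeric(0),
             draw = numeric(0), accepted = logical(0), frustrated = logical(0),
             non_lz = logical(0), e_total_pre = numeric(0),
             e_total_post = numeric(0))
}

make_hops <- function(time_fs, position_bohr, gap_hartree,
                      accepted = TRUE) {
  n <- length(time_fs)
  data.frame(time_fs = time_fs, position = position_bohr,
             gap = gap_hartree, a_sq = rep(1, n), b_sq = rep(1, n),
             probability = rep(1, n), draw = rep(0, n),
             accepted = rep_len(accepted, n), frustrated = rep(FALSE, n),
             non_lz = rep(FALSE, n), e_total_pre = rep(0, n),
             e_total_post = rep(0, n))
}

# hand-built trajectory carrying just the fields the analysis layer uses
fake_traj <- function(time_fs, r_angstrom, active, hops = empty_hops(),
                      failed = FALSE) {
  n <- length(time_fs)
  structure(list(time_au = fs_to_au(time_fs),
                 position = angstrom_to_bohr(r_angstrom),
                 active = as.integer(active),
                 e_lower = rep(0, n), e_upper = rep(0.05, n),
                 e_kin = rep(0, n), e_total = rep(0.05, n),
                 hops = hops, failed = failed, fail_reason = NA_character_,
                 seed = 0L, dt_fs = if (n > 1) diff(time_fs[1:2]) else 1,
                 mass_amu = 6),
            class = "zn_trajectory")
}

# step-function trajectory: upper state until hop_fs, lower afterwards
fake_decay_traj <- function(hop_fs, t_max_fs = 500, r_final = 3.0) {
  tt <- 0:t_max_fs
  active <- ifelse(tt < hop_fs, 2L, 1L)
  hops <- if (is.finite(hop_fs) && hop_fs <= t_max_fs)
    make_hops(hop_fs, angstrom_to_bohr(2.0), kcal_to_hartree(2))
  else empty_hops()
  fake_traj(tt, rep(r_final, length(tt)), active, hops = hops)
}
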