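test_that("generate_rr_intervals: deterministic, clipped, duration-bounded", {
  # constant-RR degenerate case: 5 intervals of 0.8 s fit exactly in 4 s
  p <- cardiac_params(mean_rr = 0.8, rr_sd = 0, rsa_amplitude = 0,
                      duration = 4.0, seed = 1)
  expect_equal(generate_rr_intervals(p), rep(0.8, 5))
  expect_length(beat_times_from_rr(rep(0.8, 5), 4.0), 5)  # beat at 4.0 excluded

  # Monte-Carlo CLT bound on the sample mean
  p2 <- cardiac_params(mean_rr = 0.85, rr_sd = 0.05, rsa_amplitude = 0,
                       duration = 300 * 0.85, seed = 42)
  rr <- generate_rr_intervals(p2)
  expect_gt(length(rr), 250)
  expect_lt(abs(mean(rr) - 0.85), 3 * 0.05 / sqrt(length(rr)))
  expect_true(all(rr >= 0.4 & rr <= 1.5))
  expect_lte(sum(rr), p2$duration)

  # reproducibility and RNG-state hygiene
  set.seed(777); before <- rnorm(1)
  expect_identical(generate_rr_intervals(p2), rr)
  set.seed(777)
  expect_identical(rnorm(1), before)

  expect_error(cardiac_params(duration = 0), "duration")
  expect_error(cardiac_params(mean_rr = -1), "mean_rr")
})

test_that("bridge_output follows the four-resistor formula", {
  expect_identical(bridge_output(bridge_params()), 0)          # balanced
  b <- bridge_params(r1 = 351, r2 = 350, r3 = 350, r4 = 350,
                     excitation = 5)
  expect_equal(bridge_output(b), 350 / (701 * 700) * 5, tolerance = 1e-15)
  expect_identical(bridge_output(bridge_params(r1 = 123, r2 = 77, r3 = 350,
                                               r4 = 350, excitation = 0)), 0)
  expect_error(bridge_params(r1 = 0), "positive")
  expect_error(bridge_params(r2 = -5), "positive")
})

test_that("beat_force_waveform matches the pressure-difference model", {
  # identical pressures (no delays, no attenuation) cancel exactly
  a0 <- aortic_params(delay_01 = 0, delay_12 = 0, atten_1 = 1, atten_2 = 1)
  expect_lt(max(abs(beat_force_waveform(a0, 200)$force)), 1e-12)

  # independent re-evaluation of the formula on the same grid
  a <- aortic_params()
  b <- beat_force_waveform(a, 200)
  rc <- function(t) ifelse(t >= 0 & t <= a$pulse_width,
                           a$pulse_amplitude * 0.5 *
                             (1 - cos(2 * pi * t / a$pulse_width)), 0)
  p0 <- rc(b$time)
  p1 <- a$atten_1 * rc(b$time - a$delay_01)
  p2 <- a$atten_2 * a$atten_1 * rc(b$time - a$delay_01 - a$delay_12)
  expect_equal(b$force,
               a$area_descending * (p1 - p2) - a$area_ascending * (p0 - p1))

  # I-J-K ordering with the default delayed templates
  f <- b$force
  iJ <- b$j_index
  iI <- which.min(f[1:iJ])
  iK <- iJ + which.min(f[(iJ + 1):length(f)])
  expect_true(iI < iJ && iJ < iK)
  expect_lt(f[iI], 0)
  expect_gt(f[iJ], 0)
  expect_lt(f[iK], 0)
  expect_identical(which.max(f), iJ)

  expect_error(beat_force_waveform(a, fs = 0), "fs")
})

test_that("synth_ecg centers one QRS on each R sample", {
  e <- synth_ecg(1.0, fs = 200, duration = 2)
  expect_identical(which.max(e$recording$data[1, ]) - 1L, 200L)  # 0-based

  e3 <- synth_ecg(c(0.8, 1.6, 2.4), fs = 200, duration = 3.2)
  x <- e3$recording$data[1, ]
  half <- max(x) / 2
  locmax <- which(diff(sign(diff(x))) == -2) + 1L
  expect_identical(sum(x[locmax] > half), 3L)

  e0 <- synth_ecg(numeric(0), fs = 200, duration = 1)
  expect_true(all(e0$recording$data == 0))

  expect_error(synth_ecg(c(1.6, 0.8), 200, 2), "ascending")
})

test_that("synth_bcg: weights, beat count, reproducibility", {
  rr <- rep(1.0, 12)
  s <- synth_bcg(rr, duration = 10, layout = channel_layout(c(1, 0, 0, 0)),
                 seed = 3)
  expect_true(all(s$recording$data[2:4, ] == 0))
  expect_gt(max(abs(s$recording$data[1, ])), 0)

  # constant RR 1.0 s, 10 s: beats at 0..9 but edge beats are dropped if
  # the template would overrun; spacing of the surviving J peaks is 1.0 s
  expect_true(all(abs(diff(s$true_j_times) - 1.0) < 1e-9))
  expect_identical(length(s$true_j_times), length(s$true_r_times))
  expect_true(all(s$true_j_times - s$true_r_times == 0.25))

  # J peaks land where claimed: local maxima of channel 1 at j samples
  x <- s$recording$data[1, ]
  for (jt in s$true_j_times) {
    js <- round(jt * 200) + 1L
    expect_gte(x[js], max(x[max(1, js - 10):(js + 10)]) - 1e-9)
  }

  s2 <- synth_bcg(rr, duration = 10, layout = channel_layout(c(1, 0, 0, 0)),
                  seed = 3)
  expect_identical(s$recording$data, s2$recording$data)

  expect_error(channel_layout(weights = c(0.5, 0.5, 0.5, 0.5)), "sum to 1")
  expect_error(synth_bcg(c(0.8, -0.1), 10), "RR")
})

test_that("clean-mode amplitudes sit inside the QC acceptance band", {
  pair <- small_clean_pair()
  segs <- segment_signal(pair$bcg)
  expect_true(all(segs$qc_status == "ok"))
  expect_true(all(segs$peak_to_peak > 35 & segs$peak_to_peak < 85))
})

test_that("simulate_paired / simulate_cohort invariants and determinism", {
  pair <- small_clean_pair()
  expect_s3_class(pair, "bcg_paired")
  expect_identical(n_channels(pair$bcg), 4L)
  expect_identical(n_channels(pair$ecg), 1L)
  expect_identical(length(pair$true_j_times), length(pair$true_r_times))
  expect_true(all(pair$true_j_times > pair$true_r_times))
  expect_true(all(pair$true_r_times >= 0 &
                    pair$true_j_times <= duration(pair$bcg)))

  # per-beat latency jitter stays within bounds
  pj <- simulate_paired(cardiac_params(duration = 30, seed = 5),
                        jitter_sd = 0.01)
  lat <- pj$true_j_times - pj$true_r_times
  expect_true(all(abs(lat - 0.25) < 0.06))
  expect_gt(stats::sd(lat), 0)

  # cohort defaults mirror the recording protocol (13 sitters, 10 min)
  expect_identical(eval(formals(simulate_cohort)$n_subjects), 13)
  expect_identical(eval(formals(simulate_cohort)$duration), 600)

  co <- simulate_cohort(3, duration = 30, seed = 9)
  expect_length(co, 3)
  rrs <- vapply(co, function(p) mean(diff(p$true_r_times)), numeric(1))
  expect_true(all(rrs > 0.6 & rrs < 1.1))
  expect_gt(stats::sd(rrs), 0)        # subjects differ

  co2 <- simulate_cohort(3, duration = 30, seed = 9)
  expect_identical(lapply(co, `[[`, "true_r_times"),
                   lapply(co2, `[[`, "true_r_times"))
  expect_identical(co[[2]]$bcg$data, co2[[2]]$bcg$data)

  expect_error(simulate_cohort(0), "n_subjects")
  expect_error(simulate_cohort(2, mean_rr_range = c(1, 0.5)), "ranges")
})
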