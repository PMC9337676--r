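test_that("rri_from_peaks builds successive differences", {
  s <- rri_from_peaks(annotations(c(0.0, 0.8, 1.6)))
  expect_equal(s$intervals, c(0.8, 0.8))
  expect_equal(s$onset_times, c(0.0, 0.8))

  expect_length(rri_from_peaks(annotations(1.0))$intervals, 0)
  expect_length(rri_from_peaks(numeric(0))$intervals, 0)
  expect_error(rri_from_peaks(c(1.6, 0.8)), "ascending")
})

test_that("flag_rri applies the closed 0.5-1.1 s acceptance band", {
  s <- rri_from_peaks(c(0, 0.4, 1.6, 2.4, 2.9, 4.0, 4.5) + 10)
  f <- flag_rri(s)   # intervals 0.4, 1.2, 0.8, 0.5, 1.1, 0.5
  expect_identical(f$quality,
                   c("bad_short", "bad_long", "good", "good", "good",
                     "good"))
  expect_identical(n_bad(f), 2L)
  expect_error(rri_bounds(0.5, 0.4), "min_rri")
})

test_that("channel selection minimizes bad counts with index tie-break", {
  mk <- function(bad, good = 10) {
    iv <- c(rep(0.3, bad), rep(0.8, good))
    flag_rri(structure(list(onset_times = cumsum(c(0, iv[-length(iv)])),
                            intervals = iv,
                            quality = rep("unflagged", length(iv))),
                       class = "rri_series"))
  }
  expect_identical(select_channel(list(mk(5), mk(2), mk(7), mk(4))), 2L)
  expect_identical(select_channel(list(mk(3), mk(3), mk(3), mk(3))), 1L)
  expect_identical(select_channel(list(mk(0), mk(9), mk(9), mk(9))), 1L)

  # equals brute-force argmin for permuted equal-count layouts
  counts <- c(2, 2, 5, 2)
  perms <- list(c(1, 2, 3, 4), c(4, 3, 2, 1), c(2, 1, 4, 3), c(3, 4, 1, 2))
  for (p in perms) {
    sl <- lapply(counts[p], mk)
    brute <- which(vapply(sl, n_bad, integer(1)) ==
                     min(vapply(sl, n_bad, integer(1))))[1]
    expect_identical(select_channel(sl), brute)
  }

  empty <- rri_from_peaks(numeric(0))
  expect_error(select_channel(list(empty, empty, empty, empty)),
               "no usable channel")
})

test_that("flag + select are invariant to uniform time shifts", {
  set.seed(51)
  tracks <- lapply(1:4, function(i) cumsum(runif(40, 0.4, 1.3)))
  pick <- function(shift) {
    select_channel(lapply(tracks, function(tt) {
      flag_rri(rri_from_peaks(tt + shift))
    }))
  }
  expect_identical(pick(0), pick(17.3))
  expect_identical(pick(0), pick(-5.5))
})

test_that("time-domain HRV features match hand arithmetic", {
  mk <- function(iv) flag_rri(rri_from_peaks(cumsum(c(10, iv))))

  f <- hrv_features(mk(rep(0.8, 10)))
  expect_equal(f$mean_hr, 75)
  expect_equal(f$sdnn, 0)
  expect_equal(f$rmssd, 0)
  expect_equal(f$pnn50, 0)

  f2 <- hrv_features(mk(rep(c(0.8, 1.0), 5)))      # alternating diffs 0.2
  expect_equal(f2$rmssd, 0.2)
  expect_equal(f2$pnn50, 1.0)

  f3 <- hrv_features(mk(c(0.8, 0.9, 1.0)))
  expect_equal(f3$sdnn, 0.1)                       # sample SD (n - 1)

  expect_error(hrv_features(mk(c(0.8, 0.9))), "insufficient")
})

test_that("bad intervals are excluded and break the diff chain", {
  iv <- c(0.8, 0.8, 0.3, 1.0, 1.0)                 # 0.3 flagged bad_short
  f <- flag_rri(rri_from_peaks(cumsum(c(0, iv))))
  h <- hrv_features(f)
  expect_identical(h$n_good, 4L)
  expect_equal(h$mean_hr, 60 / 0.9)
  # successive diffs only inside good runs: (0.8,0.8) and (1.0,1.0)
  expect_equal(h$rmssd, 0)
  expect_equal(h$pnn50, 0)
})

test_that("spectral features resolve a low-frequency modulation", {
  # 0.1 Hz sinusoidal RR modulation: power concentrates in the LF band
  t0 <- 0
  iv <- numeric(0)
  while (t0 < 300) {
    rr <- 0.8 + 0.05 * sin(2 * pi * 0.1 * t0)
    iv <- c(iv, rr)
    t0 <- t0 + rr
  }
  f <- hrv_features(flag_rri(rri_from_peaks(cumsum(c(0, iv)))))
  expect_false(is.na(f$lf_power))
  expect_gt(f$lf_power, 10 * f$hf_power)

  # 0.3 Hz modulation lands in the HF band instead
  t0 <- 0; iv <- numeric(0)
  while (t0 < 300) {
    rr <- 0.8 + 0.04 * sin(2 * pi * 0.3 * t0)
    iv <- c(iv, rr)
    t0 <- t0 + rr
  }
  f2 <- hrv_features(flag_rri(rri_from_peaks(cumsum(c(0, iv)))))
  expect_gt(f2$hf_power, 10 * f2$lf_power)
  expect_equal(f2$lf_hf_ratio, f2$lf_power / f2$hf_power)

  # too few intervals: spectral fields absent, time-domain still present
  f3 <- hrv_features(flag_rri(rri_from_peaks(cumsum(c(0, rep(0.8, 20))))))
  expect_true(is.na(f3$lf_power))
  expect_false(is.na(f3$mean_hr))
})
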