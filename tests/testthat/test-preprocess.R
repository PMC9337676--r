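test_that("segment layout follows the window/hop arithmetic", {
  rec <- recording(matrix(50 * sin(seq_len(2000) / 5), nrow = 1), fs = 200)
  segs <- segment_signal(rec, window_s = 1, overlap = 0.5)
  expect_identical(nrow(segs), 19L)                 # floor((2000-200)/100)+1
  expect_identical(unique(diff(segs$start_sample)), 100L)
  expect_true(all(segs$length == 200L))
  expect_identical(segs$start_sample[1], 0L)

  one <- segment_signal(recording(matrix(rnorm(200) * 20, 1), 200))
  expect_identical(nrow(one), 1L)
  none <- segment_signal(recording(matrix(rnorm(199), 1), 200))
  expect_identical(nrow(none), 0L)

  expect_error(segment_signal(rec, overlap = 1), "overlap")
  expect_error(qc_thresholds(high = 30, low = 35), "high")
})

test_that("amplitude QC classifies by raw peak-to-peak", {
  thr <- qc_thresholds()                            # 85 / 35 mV
  expect_identical(amplitude_qc(c(-45, 45), thr), "heavy_noise")   # p2p 90
  expect_identical(amplitude_qc(c(0, 30), thr), "no_contact")      # p2p 30
  expect_identical(amplitude_qc(c(0, 50), thr), "ok")              # p2p 50
  # thresholds are inclusive on the excluded side
  expect_identical(amplitude_qc(85, thr), "heavy_noise")
  expect_identical(amplitude_qc(35, thr), "no_contact")
  expect_identical(amplitude_qc(50, thr), "ok")
  expect_error(amplitude_qc(numeric(0), thr), "empty")
})

test_that("QC bookkeeping conserves counts and masks excluded spans", {
  set.seed(21)
  x <- rnorm(1400, sd = 12)             # p2p ~ 60-80 mV segments
  x[201:400] <- x[201:400] * 10         # heavy noise burst
  x[601:1000] <- 0                      # contact loss (2 s)
  rec <- recording(matrix(x, nrow = 1), fs = 200)
  segs <- segment_signal(rec)
  expect_identical(sum(segs$qc_status == "ok") +
                     sum(segs$qc_status == "heavy_noise") +
                     sum(segs$qc_status == "no_contact"),
                   nrow(segs))
  expect_gt(sum(segs$qc_status == "heavy_noise"), 0)
  expect_gt(sum(segs$qc_status == "no_contact"), 0)

  mask <- qc_mask(segs, n_samples(rec), 1)
  expect_identical(dim(mask), c(1L, 1400L))
  # samples covered only by fully-dead segments are masked out
  expect_false(any(mask[1, 701:900]))
  rep <- qc_report(segs)
  expect_identical(sum(rep$Freq), nrow(segs))
})

test_that("band-pass meets its frequency-response contract", {
  fs <- 200
  t <- seq(0, 10, by = 1 / fs)
  mid <- 400:1600                       # steady-state region
  y5 <- bandpass(sin(2 * pi * 5 * t), fs = fs)
  g5 <- sqrt(mean(y5[mid]^2)) / sqrt(0.5)
  expect_gte(g5, 0.9)
  expect_lte(g5, 1.0)

  y025 <- bandpass(sin(2 * pi * 0.25 * t), fs = fs)
  expect_lte(sqrt(mean(y025[mid]^2)) / sqrt(0.5), 0.1)   # >= 20 dB down

  expect_identical(bandpass(rep(0, 1000), fs = fs), rep(0, 1000))
  ydc <- bandpass(rep(3, 2001), fs = fs)
  expect_lt(max(abs(ydc)), 1e-6 * 3)

  set.seed(5)
  xa <- rnorm(1500); xb <- rnorm(1500)
  lin <- bandpass(2 * xa + 3 * xb, fs = fs) -
    2 * bandpass(xa, fs = fs) - 3 * bandpass(xb, fs = fs)
  expect_lt(max(abs(lin)), 1e-9)

  rec <- recording(matrix(rnorm(2 * 800), nrow = 2), fs = fs)
  out <- bandpass(rec)
  expect_identical(dim(out$data), dim(rec$data))
  expect_identical(out$fs, rec$fs)
  expect_error(bandpass(rec, low = 1, high = 120), "fs/2")
  expect_error(bandpass(rec, low = 5, high = 2), "low")
})

test_that("zero-phase filtering preserves peak timing", {
  fs <- 200
  x <- numeric(2000)
  x[1000] <- 1                          # impulse
  y <- bandpass(x, fs = fs)
  expect_identical(which.max(y), 1000L) # symmetric response, no lag
})
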