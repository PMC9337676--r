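test_that("extract_candidates finds strict local maxima", {
  c1 <- extract_candidates(c(0, 1, 0), fs = 1, height_frac = 0)
  expect_identical(c1$sample, 1L)                   # 0-based

  ramp <- extract_candidates(seq_len(50), fs = 10, height_frac = 0)
  expect_identical(nrow(ramp), 0L)

  # 1.2 Hz sine over 5 s: six maxima survive min-spacing 0.3 s
  t <- seq(0, 5, by = 1 / 200)
  cs <- extract_candidates(sin(2 * pi * 1.2 * t), fs = 200,
                           min_spacing = 0.3, height_frac = 0.1)
  expect_identical(nrow(cs), 6L)

  # plateau maxima resolve to the center sample
  cp <- extract_candidates(c(0, 1, 2, 2, 2, 1, 0), fs = 1,
                           height_frac = 0)
  expect_identical(cp$sample, 3L)

  expect_error(extract_candidates(c(1, 2), fs = 1), "3 samples")
})

test_that("candidate extraction equals a brute-force neighbor scan", {
  set.seed(31)
  for (rep in 1:10) {
    x <- rnorm(300)
    got <- extract_candidates(x, fs = 100, min_spacing = 0,
                              height_frac = 0)$sample
    brute <- which(x[2:299] > x[1:298] & x[2:299] > x[3:300])  # 1-based mid
    expect_identical(got, as.integer(brute))                   # 0-based == brute
  }
})

test_that("mask drops candidates in QC-rejected spans", {
  t <- seq(0, 5, by = 1 / 200)
  x <- sin(2 * pi * 1.2 * t)
  mask <- rep(TRUE, length(x))
  mask[1:400] <- FALSE                              # first 2 s rejected
  cs <- extract_candidates(x, 200, height_frac = 0.1, mask = mask)
  expect_true(all(cs$sample >= 400))
})

test_that("training windows carry the signed offset to the nearest R", {
  # one bump at t = 5.0 s in a 10-s trace; true R at 5.2 s
  fs <- 200
  x <- stats::dnorm(seq(0, 10, by = 1 / fs), mean = 5.0, sd = 0.02)
  rec <- recording(matrix(x, nrow = 1), fs)
  tw <- make_training_windows(rec, annotations(5.2), window_s = 3,
                              height_frac = 0)
  expect_identical(nrow(tw$X), 1L)
  expect_equal(tw$y, 0.2, tolerance = 1e-6)
  expect_identical(ncol(tw$X), 600L)
  expect_equal(unname(rowMeans(tw$X)), 0, tolerance = 1e-12)   # z-scored

  # candidate whose 3-s context overruns the recording is discarded
  x2 <- stats::dnorm(seq(0, 3 - 1 / fs, by = 1 / fs), mean = 1.0, sd = 0.02)
  tw2 <- make_training_windows(recording(matrix(x2, nrow = 1), fs),
                               annotations(1.0), window_s = 3,
                               height_frac = 0)
  expect_identical(nrow(tw2$X), 0L)

  # on clean synthetic data, J-centered windows target about -latency
  pair <- small_clean_pair()
  filt <- bandpass(pair$bcg)
  tw3 <- make_training_windows(filt, annotations(pair$true_r_times),
                               channels = 1)
  expect_gt(nrow(tw3$X), 30)
  expect_lt(max(abs(tw3$y + 0.25)), 0.05)
})

test_that("training is seeded-deterministic and validates input", {
  set.seed(41)
  X <- matrix(rnorm(30 * 600), 30, 600)
  w <- list(X = X, y = rep(0, 30))
  crit <- stopping_criteria(max_epochs = 8)
  m1 <- train_peak_model(w, crit, seed = 2)
  m2 <- train_peak_model(w, crit, seed = 2)
  expect_identical(m1$log, m2$log)
  expect_identical(m1$par$W3, m2$par$W3)

  # degenerate all-zero-target set: predictions collapse to ~0 offset
  preds <- bcghrv:::cnn_predict_batched(m1$par, X)
  expect_lt(max(abs(preds)), 0.02)

  expect_error(train_peak_model(list(X = X[, 1:500], y = rep(0, 30)),
                                crit), "inconsistent")
  expect_error(train_peak_model(list(X = NULL, y = numeric(0)), crit),
               "at least one")
})

test_that("predict_r_peaks applies the model offset and deduplicates", {
  # hand-built model: zeroed head with bias set for a constant +0.2 s
  par <- bcghrv:::cnn_init(600, scale = 1.5, seed = 1)
  par$b5 <- atanh(0.2 / 1.5)
  stub <- structure(list(par = par, fs = 200, window_s = 3, trained = TRUE,
                         log = data.frame(epoch = 1, loss = 0),
                         meta = list()),
                    class = "peak_model")
  fs <- 200
  x <- stats::dnorm(seq(0, 10, by = 1 / fs), mean = 5.0, sd = 0.02)
  out <- predict_r_peaks(stub, x, fs, height_frac = 0)
  expect_length(out$times, 1)
  expect_equal(out$times, 5.2, tolerance = 1e-6)
  expect_identical(out$source, "bcg-predicted")

  # zero candidates give an empty track
  expect_length(predict_r_peaks(stub, rep(0, 2000), fs)$times, 0)

  # predictions are strictly ascending with >= min-spacing gaps
  pair <- small_clean_pair()
  filt <- bandpass(pair$bcg)
  tr <- predict_r_peaks(stub, filt$data[1, ], fs, min_spacing = 0.3)
  expect_true(all(diff(tr$times) >= 0.3))

  expect_error(predict_r_peaks(list(), x, fs), "trained")
})

test_that("baseline detector finds clean beats and rejects silence", {
  pair <- small_clean_pair()
  filt <- bandpass(pair$bcg)
  ann <- baseline_peak_detect(filt$data[1, ], 200)
  # interior truth (edge beats may fall outside the detector's reach)
  jt <- pair$true_j_times
  jt <- jt[jt > 0.5 & jt < duration(pair$bcg) - 0.5]
  d <- vapply(jt, function(x) min(abs(ann$times - x)), numeric(1))
  expect_lt(max(d), 0.05)

  expect_length(baseline_peak_detect(rep(0, 1000), 200)$times, 0)
  expect_error(baseline_peak_detect(numeric(0), 200), "empty")

  # under motion bursts the picker over-detects rather than under-detects
  noisy <- synth_bcg(rep(0.8, 30), duration = 25,
                     layout = channel_layout(c(1, 0, 0, 0),
                                             motion_artifact_rate = 12,
                                             motion_sd = 60),
                     seed = 8)
  fx <- bandpass(noisy$recording$data[1, ], fs = 200)
  det <- baseline_peak_detect(fx, 200)
  expect_gte(length(det$times), length(noisy$true_j_times))
})
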