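test_that("epoch matching covers the documented cases", {
  # prediction within 0.1 s of the truth: the epoch is a TP
  m <- match_peaks(1.00, 1.05, span = 2)
  expect_identical(c(m$tp, m$tn, m$fp, m$fn), c(1L, 1L, 0L, 0L))

  # same epoch but 0.15 s apart: truth unmatched, epoch is an FN; the
  # unmatched prediction sits in the truth's epoch so it adds no FP
  m2 <- match_peaks(1.00, 1.15, span = 2)
  expect_identical(c(m2$tp, m2$tn, m2$fp, m2$fn), c(0L, 1L, 0L, 1L))

  # empty tracks: every epoch is a TN
  m3 <- match_peaks(numeric(0), numeric(0), span = 10)
  expect_identical(m3$tn, 10L)
  expect_identical(m3$n_epochs, 10L)

  # unmatched prediction in a truth-free epoch is an FP
  m4 <- match_peaks(c(1.02, 3.5), 1.00, span = 5)
  expect_identical(c(m4$tp, m4$tn, m4$fp, m4$fn), c(1L, 3L, 1L, 0L))

  expect_error(match_peaks(1, 1, tolerance = 0, span = 2), "tolerance")
  expect_error(match_peaks(1, 1, epoch_len = -1, span = 2), "epoch_len")
})

test_that("matching is maximum-cardinality (nearest-first would fail)", {
  # nearest-first greedy would pair 1.00-1.04 and strand both others,
  # scoring TP=1 FN=1 FP=1; the optimal assignment matches both truths
  m <- match_peaks(c(1.00, 1.08), c(0.92, 1.04), tolerance = 0.1,
                   span = 2)
  expect_identical(nrow(m$matches), 2L)
  expect_identical(c(m$tp, m$tn, m$fp, m$fn), c(2L, 0L, 0L, 0L))
})

test_that("every epoch contributes exactly one confusion count", {
  set.seed(61)
  for (rep in 1:20) {
    span <- 12
    truth <- sort(runif(sample(0:6, 1), 0, span))
    pred <- sort(runif(sample(0:6, 1), 0, span))
    m <- match_peaks(pred, truth, span = span)
    expect_identical(m$tp + m$tn + m$fp + m$fn, m$n_epochs)
  }
})

test_that("recall is monotone in the tolerance", {
  set.seed(62)
  truth <- cumsum(runif(30, 0.6, 1.0))
  pred <- truth + rnorm(30, sd = 0.06)
  span <- c(0, max(truth, pred) + 0.5)
  tols <- c(0.02, 0.05, 0.1, 0.2)
  recs <- vapply(tols, function(tl) {
    recall(match_peaks(sort(pred), truth, tolerance = tl, span = span))
  }, numeric(1))
  expect_true(all(diff(recs) >= 0))
})

test_that("accuracy and recall follow the confusion formulas", {
  mk <- function(tp, tn, fp, fn) {
    structure(list(tp = tp, tn = tn, fp = fp, fn = fn,
                   n_epochs = tp + tn + fp + fn, tolerance = 0.1,
                   epoch_len = 1, matches = NULL),
              class = "match_result")
  }
  expect_equal(accuracy(mk(1, 1, 1, 1)), 0.5)
  expect_equal(accuracy(mk(3, 2, 1, 4)), 0.5)
  expect_equal(recall(mk(3, 2, 1, 4)), 3 / 7)
  expect_equal(accuracy(mk(5, 3, 0, 0)), 1.0)
  expect_error(accuracy(mk(0, 0, 0, 0)), "undefined")
  expect_error(recall(mk(0, 5, 3, 0)), "undefined")
})

test_that("windowed HR error matches direct computation", {
  mk <- function(iv) rri_from_peaks(cumsum(c(0, iv)))
  s <- mk(rep(0.8, 50))
  e <- hr_error_bpm(s, s)
  expect_equal(e$mean, 0)
  expect_equal(e$sd, 0)

  e2 <- hr_error_bpm(mk(rep(0.8, 50)), mk(rep(1.0, 40)))
  expect_equal(e2$mean, 75 - 60)
  expect_equal(e2$sd, 0)

  expect_error(hr_error_bpm(mk(numeric(0)), s), "no comparable")

  # flagged-bad intervals are dropped before comparison by default
  iv <- rep(0.8, 50); iv[25] <- 0.2
  e3 <- hr_error_bpm(flag_rri(mk(iv)), mk(rep(0.8, 50)))
  expect_equal(e3$mean, 0)
  e4 <- hr_error_bpm(flag_rri(mk(iv)), mk(rep(0.8, 50)),
                     use_only_good = FALSE)
  expect_gt(abs(e4$mean), 0)
})

test_that("LOSO report structure, determinism, and input validation", {
  cohort <- fixture("tiny_cohort", function() {
    simulate_cohort(2, duration = 60, seed = 71)
  })
  cfg <- pipeline_config(max_epochs = 30)
  r1 <- loso_crossval(cohort, cfg, seed = 3)
  expect_identical(nrow(r1$folds), 2L)
  expect_true(all(r1$folds$accuracy >= 0 & r1$folds$accuracy <= 1))
  r2 <- loso_crossval(cohort, cfg, seed = 3)
  expect_identical(r1$folds, r2$folds)

  expect_error(loso_crossval(cohort[1], cfg), "2 subjects")
  expect_error(compare_methods(list(), cfg), "empty cohort")
})
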