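#' RR-interval physiological acceptance band
#'
#' Intervals outside the closed band `[min_rri, max_rri]` (defaults 0.5 s
#' and 1.1 s, bracketing the normal resting 0.6-1.0 s / 60-100 bpm range)
#' are flagged as bad: such deviations are typically produced by missed or
#' spurious beat detections rather than by true rhythm changes.
#'
#' @param min_rri shortest acceptable interval, seconds (default 0.5).
#' @param max_rri longest acceptable interval, seconds (default 1.1).
#' @return an `rri_bounds` list.
#' @export
rri_bounds <- function(min_rri = 0.5, max_rri = 1.1) {
  if (!(min_rri > 0 && min_rri < max_rri)) {
    stop("need 0 < `min_rri` < `max_rri`", call. = FALSE)
  }
  structure(list(min_rri = min_rri, max_rri = max_rri),
            class = "rri_bounds")
}

#' Build an RR-interval series from a peak track
#'
#' Intervals are the successive differences of the event times; each
#' interval's onset is the earlier event of its pair. Fewer than two
#' events give an empty series.
#'
#' @param track an [annotations()] track, or a strictly ascending numeric
#'   vector of event times (seconds).
#' @return an `rri_series`: fields `onset_times`, `intervals` (seconds),
#'   `quality` (per interval; `"unflagged"` until [flag_rri()] is applied).
#' @export
rri_from_peaks <- function(track) {
  times <- if (inherits(track, "bcg_annotations")) track$times
           else as.numeric(track)
  if (length(times) > 1 && is.unsorted(times, strictly = TRUE)) {
    stop("event times must be strictly ascending", call. = FALSE)
  }
  if (length(times) < 2) {
    return(structure(list(onset_times = numeric(0), intervals = numeric(0),
                          quality = character(0)),
                     class = "rri_series"))
  }
  iv <- diff(times)
  structure(list(onset_times = times[-length(times)], intervals = iv,
                 quality = rep("unflagged", length(iv))),
            class = "rri_series")
}

#' @export
print.rri_series <- function(x, ...) {
  cat(sprintf("<rri_series> %d interval(s)", length(x$intervals)))
  if (length(x$intervals) > 0) {
    cat(sprintf(", mean %.3f s, quality: %s",
                mean(x$intervals),
                paste(names(table(x$quality)), table(x$quality),
                      sep = "=", collapse = " ")))
  }
  cat("\n")
  invisible(x)
}

#' Flag physiologically implausible RR intervals
#'
#' Marks each interval `"bad_short"` if below `min_rri`, `"bad_long"` if
#' above `max_rri`, else `"good"`. The band is closed: intervals exactly
#' at a bound are good.
#'
#' @param series an `rri_series` from [rri_from_peaks()].
#' @param bounds an [rri_bounds()].
#' @return the series with `quality` set.
#' @export
flag_rri <- function(series, bounds = rri_bounds()) {
  stopifnot(inherits(series, "rri_series"), inherits(bounds, "rri_bounds"))
  q <- rep("good", length(series$intervals))
  q[series$intervals < bounds$min_rri] <- "bad_short"
  q[series$intervals > bounds$max_rri] <- "bad_long"
  series$quality <- q
  series
}

#' Count of bad intervals in a flagged series
#' @param series a flagged `rri_series`.
#' @return integer count of `bad_short` plus `bad_long` intervals.
#' @export
n_bad <- function(series) {
  sum(series$quality %in% c("bad_short", "bad_long"))
}

#' Select the best of the four channels
#'
#' The sitter's weight distributes unevenly over the four chair legs, so
#' channel quality differs; the channel whose flagged RR series has the
#' fewest bad intervals represents the subject. Ties break to the lowest
#' channel index.
#'
#' @param series_list list of flagged `rri_series`, one per channel.
#' @return 1-based index of the selected channel.
#' @export
select_channel <- function(series_list) {
  stopifnot(is.list(series_list), length(series_list) >= 1)
  lens <- vapply(series_list, function(s) length(s$intervals), integer(1))
  if (all(lens == 0)) stop("no usable channel: all series empty",
                           call. = FALSE)
  bad <- vapply(series_list, n_bad, integer(1))
  which.min(bad)   # which.min takes the first (lowest index) on ties
}

#' Time- and frequency-domain HRV features
#'
#' Computes the standard short-term HRV set from the good intervals of a
#' flagged series: mean heart rate `60 / mean(RRI)` (bpm), SDNN (sample SD
#' of intervals, s), RMSSD (root mean square of successive differences,
#' s), pNN50 (fraction of successive differences exceeding 50 ms).
#' Successive differences are only taken between intervals adjacent in
#' the original series (bad intervals break the chain; no interpolation).
#' If the longest contiguous run of good intervals has at least
#' `min_freq_n` intervals, the tachogram of that run is resampled at 4 Hz
#' by cubic spline and LF (0.04-0.15 Hz) and HF (0.15-0.4 Hz) periodogram
#' band powers (s^2) and their ratio are added; otherwise those fields
#' are `NA`.
#'
#' @param series a flagged `rri_series`.
#' @param use_only_good drop flagged-bad intervals (default `TRUE`).
#' @param min_freq_n minimum contiguous good intervals for the
#'   frequency-domain features (default 64).
#' @return list with `mean_hr`, `sdnn`, `rmssd`, `pnn50`, `lf_power`,
#'   `hf_power`, `lf_hf_ratio`, `n_good`.
#' @export
hrv_features <- function(series, use_only_good = TRUE, min_freq_n = 64L) {
  stopifnot(inherits(series, "rri_series"))
  good <- if (use_only_good) series$quality %in% c("good", "unflagged")
          else rep(TRUE, length(series$intervals))
  iv <- series$intervals[good]
  if (length(iv) < 3) stop("insufficient data: need >= 3 good intervals",
                           call. = FALSE)
  # successive differences only within contiguous good runs
  idx <- which(good)
  adjacent <- diff(idx) == 1L
  sd_pairs <- diff(series$intervals)[idx[-length(idx)][adjacent]]

  out <- list(
    mean_hr = 60 / mean(iv),
    sdnn = stats::sd(iv),
    rmssd = if (length(sd_pairs) > 0) sqrt(mean(sd_pairs^2)) else NA_real_,
    pnn50 = if (length(sd_pairs) > 0) mean(abs(sd_pairs) > 0.05)
            else NA_real_,
    lf_power = NA_real_, hf_power = NA_real_, lf_hf_ratio = NA_real_,
    n_good = length(iv)
  )

  # longest contiguous good run for the spectral features
  runs <- rle(good)
  if (any(runs$values & runs$lengths >= min_freq_n)) {
    ends <- cumsum(runs$lengths)
    cand <- which(runs$values & runs$lengths >= min_freq_n)
    best <- cand[which.max(runs$lengths[cand])]
    sel <- (ends[best] - runs$lengths[best] + 1L):ends[best]
    t_run <- series$onset_times[sel]
    iv_run <- series$intervals[sel]
    fs_r <- 4
    t_even <- seq(min(t_run), max(t_run), by = 1 / fs_r)
    if (length(t_even) >= 2 * min_freq_n) {
      tach <- stats::spline(t_run, iv_run, xout = t_even, method = "fmm")$y
      tach <- tach - mean(tach)
      n <- length(tach)
      sp <- Mod(stats::fft(tach))^2 / n / n      # periodogram, power per bin
      freq <- (seq_len(n) - 1) * fs_r / n
      lf <- sum(sp[freq >= 0.04 & freq < 0.15]) * 2
      hf <- sum(sp[freq >= 0.15 & freq < 0.40]) * 2
      out$lf_power <- lf
      out$hf_power <- hf
      out$lf_hf_ratio <- if (hf > 0) lf / hf else NA_real_
    }
  }
  out
}
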