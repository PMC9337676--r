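#' Multi-channel uniformly sampled recording
#'
#' A `bcg_recording` holds one or more synchronously sampled channels in a
#' channels-by-samples matrix, together with the sampling rate and channel
#' names. Amplitudes are in millivolts throughout the package; time is in
#' seconds from recording start and samples are 0-based, so sample `i` covers
#' the half-open interval `[start_time + i/fs, start_time + (i+1)/fs)`.
#'
#' @param data numeric matrix, channels x samples (mV). A vector is treated
#'   as a single channel.
#' @param fs sampling rate in Hz, must be positive.
#' @param channel_names optional character vector, one name per channel.
#' @param start_time recording start in seconds (default 0).
#' @return an object of class `bcg_recording` with fields `data`, `fs`,
#'   `channel_names`, `start_time`.
#' @examples
#' rec <- recording(matrix(rnorm(400), nrow = 2), fs = 200)
#' n_samples(rec)
#' duration(rec)
#' @export
recording <- function(data, fs, channel_names = NULL, start_time = 0) {
  if (is.vector(data) && is.numeric(data)) data <- matrix(data, nrow = 1)
  if (!is.matrix(data) || !is.numeric(data)) {
    stop("`data` must be a numeric matrix (channels x samples)", call. = FALSE)
  }
  if (!is.numeric(fs) || length(fs) != 1 || !is.finite(fs) || fs <= 0) {
    stop("`fs` must be a single positive number", call. = FALSE)
  }
  if (is.null(channel_names)) {
    channel_names <- paste0("ch", seq_len(nrow(data)))
  }
  if (length(channel_names) != nrow(data)) {
    stop("`channel_names` must have one entry per channel", call. = FALSE)
  }
  if (anyNA(data)) stop("`data` must not contain NA", call. = FALSE)
  structure(
    list(data = data, fs = fs,
         channel_names = as.character(channel_names),
         start_time = as.numeric(start_time)),
    class = "bcg_recording"
  )
}

#' @rdname recording
#' @param x a `bcg_recording`.
#' @export
n_channels <- function(x) nrow(x$data)

#' @rdname recording
#' @export
n_samples <- function(x) ncol(x$data)

#' @rdname recording
#' @export
duration <- function(x) ncol(x$data) / x$fs

#' @export
print.bcg_recording <- function(x, ...) {
  cat(sprintf("<bcg_recording> %d channel(s) x %d samples @ %g Hz (%.1f s)\n",
              n_channels(x), n_samples(x), x$fs, duration(x)))
  cat("  channels:", paste(x$channel_names, collapse = ", "), "\n")
  invisible(x)
}

#' Event annotation track
#'
#' An ordered list of event times (seconds) with a label and a provenance
#' tag. Used for true and predicted R-peak times and simulated J-peak times.
#'
#' @param times numeric vector of event times in seconds, must be ascending.
#' @param label single string naming the event type, e.g. `"R"` or `"J"`.
#' @param source provenance string, one of `"ecg"`, `"bcg-predicted"`,
#'   `"simulated-truth"`, `"bcg-baseline"`.
#' @return an object of class `bcg_annotations`.
#' @export
annotations <- function(times, label = "R", source = "ecg") {
  times <- as.numeric(times)
  if (anyNA(times)) stop("annotation times must not contain NA", call. = FALSE)
  if (is.unsorted(times, strictly = FALSE)) {
    stop("annotation times must be ascending", call. = FALSE)
  }
  structure(list(times = times, label = as.character(label)[1],
                 source = as.character(source)[1]),
            class = "bcg_annotations")
}

#' @export
print.bcg_annotations <- function(x, ...) {
  cat(sprintf("<bcg_annotations> %d '%s' events (source: %s)\n",
              length(x$times), x$label, x$source))
  invisible(x)
}
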