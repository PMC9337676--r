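#' Pipeline configuration
#'
#' Collects every tunable of the analysis chain with the published
#' defaults: 200 Hz sampling, 1-s/50% QC segmentation with the 35/85 mV
#' amplitude band, 1-9 Hz zero-phase band-pass, 3-s CNN windows, 0.5/1.1 s
#' RR acceptance band, and +/- 0.1 s epoch matching over 1-s epochs.
#' Module preconditions are validated here, before any stage runs.
#'
#' @param fs sampling rate, Hz.
#' @param band_low,band_high band-pass edges, Hz.
#' @param window_s,overlap QC segmentation window (s) and fractional
#'   overlap.
#' @param qc_low,qc_high amplitude QC thresholds, mV.
#' @param cnn_window_s CNN input window, seconds.
#' @param min_spacing candidate/prediction minimum spacing, seconds.
#' @param height_frac candidate height threshold, rolling-IQR
#'   units (see [extract_candidates()]).
#' @param rri_min,rri_max RR acceptance band, seconds.
#' @param tolerance,epoch_len epoch matching tolerance and epoch length,
#'   seconds.
#' @param hr_window heart-rate error window, seconds.
#' @param error_tol,margin_tol,max_epochs CNN stopping criteria.
#' @param lr,batch_size SGD step size and minibatch size.
#' @param baseline_k baseline detector threshold (rolling-SD units).
#' @param seed default RNG seed.
#' @return a validated `pipeline_config` list.
#' @export
pipeline_config <- function(fs = 200, band_low = 1, band_high = 9,
                            window_s = 1, overlap = 0.5,
                            qc_low = 35, qc_high = 85,
                            cnn_window_s = 3, min_spacing = 0.3,
                            height_frac = 3,
                            rri_min = 0.5, rri_max = 1.1,
                            tolerance = 0.1, epoch_len = 1,
                            hr_window = 10,
                            error_tol = 1e-4, margin_tol = 1e-4,
                            max_epochs = 500L, lr = 0.05,
                            batch_size = 64L, baseline_k = 1.5,
                            seed = 1L) {
  if (fs <= 0) stop("`fs` must be > 0", call. = FALSE)
  if (!(band_low > 0 && band_low < band_high && band_high < fs / 2)) {
    stop("need 0 < band_low < band_high < fs/2", call. = FALSE)
  }
  if (overlap < 0 || overlap >= 1) stop("`overlap` must be in [0, 1)",
                                        call. = FALSE)
  if (round(window_s * fs) < 2) stop("QC window must span >= 2 samples",
                                     call. = FALSE)
  if (!(qc_high > qc_low && qc_low > 0)) {
    stop("need qc_high > qc_low > 0", call. = FALSE)
  }
  if (!(rri_min > 0 && rri_min < rri_max)) {
    stop("need 0 < rri_min < rri_max", call. = FALSE)
  }
  if (tolerance <= 0) stop("`tolerance` must be > 0", call. = FALSE)
  if (error_tol <= 0 || margin_tol <= 0) {
    stop("stopping tolerances must be > 0", call. = FALSE)
  }
  structure(list(fs = fs, band_low = band_low, band_high = band_high,
                 window_s = window_s, overlap = overlap,
                 qc_low = qc_low, qc_high = qc_high,
                 cnn_window_s = cnn_window_s, min_spacing = min_spacing,
                 height_frac = height_frac,
                 rri_min = rri_min, rri_max = rri_max,
                 tolerance = tolerance, epoch_len = epoch_len,
                 hr_window = hr_window,
                 error_tol = error_tol, margin_tol = margin_tol,
                 max_epochs = as.integer(max_epochs), lr = lr,
                 batch_size = as.integer(batch_size),
                 baseline_k = baseline_k, seed = as.integer(seed)),
            class = "pipeline_config")
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(paste(deparse(unclass(config)), collapse = ""), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full analysis pipeline on one recording
#'
#' Executes filter -> segmentation/QC -> peak prediction (training a model
#' on the recording's own ground truth if none is supplied) -> RR flagging
#' -> channel selection -> HRV features, and, when ground-truth R times
#' are available, the epoch-matching validation. Every run produces a
#' manifest (config hash, seed, stage record) sufficient to reproduce it.
#'
#' @param input a `bcg_paired` (from [simulate_paired()]) or a 4-channel
#'   [recording()].
#' @param config a [pipeline_config()].
#' @param model optional pre-trained `peak_model`; required when `input`
#'   has no ground-truth annotations to train on.
#' @param truth optional [annotations()] of true R times (taken from
#'   `input` when it is a `bcg_paired`).
#' @param outdir optional directory; when given, artifacts (filtered
#'   recording, QC report, predicted track, HRV features, manifest) are
#'   written there as delimited text/JSON.
#' @return a results bundle: `qc`, `selected_channel`, `track`, `rri`,
#'   `hrv`, `validation` (or `NULL`), `model`, `manifest`.
#' @export
run_pipeline <- function(input, config = pipeline_config(), model = NULL,
                         truth = NULL, outdir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (inherits(input, "bcg_paired")) {
    rec <- input$bcg
    if (is.null(truth)) {
      truth <- annotations(input$true_r_times, "R", "simulated-truth")
    }
  } else if (inherits(input, "bcg_recording")) {
    rec <- input
  } else {
    stop("`input` must be a bcg_paired or bcg_recording", call. = FALSE)
  }
  if (abs(rec$fs - config$fs) > 1e-9) {
    stop(sprintf("recording fs (%g) differs from config fs (%g)",
                 rec$fs, config$fs), call. = FALSE)
  }

  filt <- bandpass(rec, config$band_low, config$band_high)
  segs <- segment_signal(rec, config$window_s, config$overlap,
                         qc_thresholds(config$qc_high, config$qc_low))
  mask <- qc_mask(segs, n_samples(rec), n_channels(rec))

  if (is.null(model)) {
    if (is.null(truth)) {
      stop("no `model` supplied and no ground truth to train on",
           call. = FALSE)
    }
    tw <- cohort_training_windows(
      list(list(bcg = rec, true_r_times = truth$times)), config)
    model <- train_peak_model(tw,
                              criteria = stopping_criteria(
                                config$error_tol, config$margin_tol,
                                config$max_epochs),
                              fs = config$fs,
                              window_s = config$cnn_window_s,
                              lr = config$lr, batch_size = config$batch_size,
                              seed = config$seed)
  }

  tracks <- lapply(seq_len(n_channels(filt)), function(ch) {
    predict_r_peaks(model, filt$data[ch, ], filt$fs,
                    min_spacing = config$min_spacing, mask = mask[ch, ],
                    height_frac = config$height_frac)
  })
  series <- lapply(tracks, function(tr) {
    flag_rri(rri_from_peaks(tr), rri_bounds(config$rri_min, config$rri_max))
  })
  ch <- select_channel(series)
  feats <- tryCatch(hrv_features(series[[ch]]),
                    error = function(e) NULL)

  validation <- NULL
  if (!is.null(truth) && length(truth$times) > 1) {
    half <- config$cnn_window_s / 2
    span <- c(half, duration(rec) - half)
    m <- match_peaks(tracks[[ch]], truth$times, tolerance = config$tolerance,
                     epoch_len = config$epoch_len, span = span)
    hr <- tryCatch(
      hr_error_bpm(series[[ch]], rri_from_peaks(truth$times),
                   window = config$hr_window),
      error = function(e) NULL)
    validation <- list(match = m, accuracy = accuracy(m),
                       recall = recall(m), hr_error = hr)
  }

  manifest <- list(config = unclass(config),
                   config_hash = config_hash(config),
                   seed = config$seed,
                   n_channels = n_channels(rec),
                   n_samples = n_samples(rec),
                   selected_channel = ch,
                   model_epochs = nrow(model$log),
                   model_final_loss = model$log$loss[nrow(model$log)])

  bundle <- list(qc = qc_report(segs), selected_channel = ch,
                 tracks = tracks, track = tracks[[ch]],
                 rri = series[[ch]], hrv = feats,
                 validation = validation, model = model,
                 manifest = manifest)

  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    write_recording(filt, file.path(outdir, "filtered.tsv"))
    utils::write.table(bundle$qc, file.path(outdir, "qc_report.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    write_annotations(bundle$track, file.path(outdir, "predicted_r.tsv"))
    if (!is.null(feats)) {
      utils::write.table(as.data.frame(feats),
                         file.path(outdir, "hrv_features.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    }
    save_peak_model(model, file.path(outdir, "model.json"))
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  bundle
}
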