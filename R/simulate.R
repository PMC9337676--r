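#' @keywords internal
#' Evaluate code with a temporary RNG seed, restoring global RNG state.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Cardiac rhythm parameters
#'
#' Describes the RR-interval process of one simulated subject: a Gaussian
#' beat-to-beat variability around `mean_rr` plus a sinusoidal respiratory
#' sinus arrhythmia (RSA) component. A resting adult heart beats at
#' 60-100 bpm, i.e. RR intervals of 0.6-1.0 s; generated intervals are
#' clipped to the physiological envelope 0.4-1.5 s.
#'
#' @param mean_rr mean RR interval, seconds (> 0).
#' @param rr_sd beat-to-beat Gaussian SD, seconds (>= 0).
#' @param rsa_amplitude RSA modulation amplitude, seconds.
#' @param rsa_freq RSA (breathing) frequency, Hz.
#' @param duration recording duration, seconds (> 0).
#' @param seed integer seed; identical seeds give identical interval series.
#' @return a `cardiac_params` list.
#' @export
cardiac_params <- function(mean_rr = 0.8, rr_sd = 0.05, rsa_amplitude = 0.02,
                           rsa_freq = 0.25, duration = 600, seed = 1L) {
  if (mean_rr <= 0) stop("`mean_rr` must be > 0", call. = FALSE)
  if (rr_sd < 0) stop("`rr_sd` must be >= 0", call. = FALSE)
  if (rsa_amplitude < 0) stop("`rsa_amplitude` must be >= 0", call. = FALSE)
  if (duration <= 0) stop("`duration` must be > 0", call. = FALSE)
  structure(list(mean_rr = mean_rr, rr_sd = rr_sd,
                 rsa_amplitude = rsa_amplitude, rsa_freq = rsa_freq,
                 duration = duration, seed = as.integer(seed)),
            class = "cardiac_params")
}

#' Generate an RR-interval series
#'
#' Draws successive RR intervals `mean_rr + rr_sd * eps + RSA(t)` where
#' `eps` is standard normal and RSA is a sinusoid evaluated at the beat
#' onset time, clipping each interval to \[0.4, 1.5\] s, until the beat
#' train reaches `duration`. The cumulative sum of the returned intervals
#' never exceeds `duration`.
#'
#' @param params a [cardiac_params()].
#' @return numeric vector of RR intervals in seconds.
#' @export
generate_rr_intervals <- function(params) {
  stopifnot(inherits(params, "cardiac_params"))
  with_seed(params$seed, {
    n_max <- ceiling(params$duration / 0.4) + 1L
    eps <- stats::rnorm(n_max)
    out <- numeric(n_max)
    t <- 0
    k <- 0L
    repeat {
      rr <- params$mean_rr + params$rr_sd * eps[k + 1L] +
        params$rsa_amplitude * sin(2 * pi * params$rsa_freq * t)
      rr <- min(max(rr, 0.4), 1.5)
      if (t + rr > params$duration) break
      k <- k + 1L
      out[k] <- rr
      t <- t + rr
      if (k >= n_max) break
    }
    out[seq_len(k)]
  })
}

#' Beat times implied by an RR-interval series
#'
#' Beats are placed at the cumulative-RR times starting at t = 0, so `n`
#' intervals yield `n + 1` beat times when the last one still falls strictly
#' inside `duration` (half-open convention `[0, duration)`).
#'
#' @param rr numeric RR intervals, seconds.
#' @param duration recording duration, seconds.
#' @return ascending beat times in seconds.
#' @export
beat_times_from_rr <- function(rr, duration) {
  t <- c(0, cumsum(rr))
  t[t < duration]
}

#' Wheatstone bridge parameters and output
#'
#' A load cell reads strain as the differential output of a four-resistor
#' Wheatstone bridge driven by excitation voltage `E`:
#' `e = (R1*R3 - R2*R4) / ((R1 + R2) * (R3 + R4)) * E`.
#' A balanced bridge (all arms equal) outputs exactly zero.
#'
#' @param r1,r2,r3,r4 arm resistances in ohms, all > 0. Default 350 ohm.
#' @param excitation bridge excitation voltage `E` in volts.
#' @return `bridge_params` returns a parameter list; `bridge_output` the
#'   differential output in volts.
#' @examples
#' bridge_output(bridge_params())                 # balanced: 0 V
#' bridge_output(bridge_params(r1 = 351))         # slightly unbalanced
#' @export
bridge_params <- function(r1 = 350, r2 = 350, r3 = 350, r4 = 350,
                          excitation = 5) {
  rs <- c(r1, r2, r3, r4)
  if (any(!is.finite(rs)) || any(rs <= 0)) {
    stop("all bridge resistances must be positive", call. = FALSE)
  }
  structure(list(r1 = r1, r2 = r2, r3 = r3, r4 = r4,
                 excitation = excitation),
            class = "bridge_params")
}

#' @rdname bridge_params
#' @param bridge a [bridge_params()].
#' @export
bridge_output <- function(bridge) {
  stopifnot(inherits(bridge, "bridge_params"))
  with(bridge,
       (r1 * r3 - r2 * r4) / ((r1 + r2) * (r3 + r4)) * excitation)
}

#' Aortic force model parameters
#'
#' The single-beat BCG force template is driven by the pressure-difference
#' model `F(t) = A_D * [P1(t) - P2(t)] - A_A * [P0(t) - P1(t)]` where `A_A`
#' and `A_D` are the mean cross-sectional areas of the ascending and
#' descending aorta and `P0`, `P1`, `P2` are the blood pressures at the
#' aortic inlet, the ascending/descending boundary, and the descending
#' outlet. Each pressure is a delayed, attenuated copy of a stereotyped
#' raised-cosine systolic pulse; the propagation delays produce the
#' characteristic I (down), J (dominant up), K (down) deflection sequence.
#'
#' @param area_ascending `A_A`, cm^2.
#' @param area_descending `A_D`, cm^2.
#' @param pulse_width systolic pulse width, seconds.
#' @param pulse_amplitude pulse pressure amplitude, mmHg.
#' @param delay_01 propagation delay from inlet to boundary, seconds.
#' @param delay_12 propagation delay from boundary to outlet, seconds.
#' @param atten_1,atten_2 attenuation of P1 relative to P0 and of P2
#'   relative to P1.
#' @return an `aortic_params` list.
#' @export
aortic_params <- function(area_ascending = 5.0, area_descending = 3.5,
                          pulse_width = 0.30, pulse_amplitude = 40,
                          delay_01 = 0.02, delay_12 = 0.04,
                          atten_1 = 0.95, atten_2 = 0.90) {
  if (area_ascending <= 0 || area_descending <= 0) {
    stop("aortic areas must be > 0", call. = FALSE)
  }
  if (delay_01 < 0 || delay_12 < 0) stop("delays must be >= 0", call. = FALSE)
  if (pulse_width <= 0) stop("`pulse_width` must be > 0", call. = FALSE)
  structure(list(area_ascending = area_ascending,
                 area_descending = area_descending,
                 pulse_width = pulse_width,
                 pulse_amplitude = pulse_amplitude,
                 delay_01 = delay_01, delay_12 = delay_12,
                 atten_1 = atten_1, atten_2 = atten_2),
            class = "aortic_params")
}

# raised-cosine systolic pulse, zero outside [0, width]
raised_cosine_pulse <- function(t, width, amplitude) {
  y <- numeric(length(t))
  inside <- t >= 0 & t <= width
  y[inside] <- amplitude * 0.5 * (1 - cos(2 * pi * t[inside] / width))
  y
}

#' Single-beat BCG force template
#'
#' Samples the aortic force model on a uniform grid covering the full
#' support of the three delayed pressure pulses. With the default delayed
#' templates the waveform shows, in order, the I trough, the global J
#' maximum, and the K trough.
#'
#' @param aortic an [aortic_params()].
#' @param fs sampling rate, Hz (> 0).
#' @return list with `force` (numeric vector, arbitrary force units),
#'   `time` (seconds), and `j_index` (1-based index of the global maximum).
#' @export
beat_force_waveform <- function(aortic, fs) {
  stopifnot(inherits(aortic, "aortic_params"))
  if (!is.numeric(fs) || fs <= 0) stop("`fs` must be > 0", call. = FALSE)
  total <- aortic$pulse_width + aortic$delay_01 + aortic$delay_12
  t <- seq(0, total, by = 1 / fs)
  p0 <- raised_cosine_pulse(t, aortic$pulse_width, aortic$pulse_amplitude)
  p1 <- aortic$atten_1 *
    raised_cosine_pulse(t - aortic$delay_01, aortic$pulse_width,
                        aortic$pulse_amplitude)
  p2 <- aortic$atten_2 * aortic$atten_1 *
    raised_cosine_pulse(t - aortic$delay_01 - aortic$delay_12,
                        aortic$pulse_width, aortic$pulse_amplitude)
  force <- aortic$area_descending * (p1 - p2) -
    aortic$area_ascending * (p0 - p1)
  list(force = force, time = t, j_index = which.max(force))
}

#' Four-sensor chair layout and noise model
#'
#' Describes how the sitter's mass (and hence the BCG force) distributes
#' over the four chair-leg load cells, plus the per-channel nuisance
#' components: wideband sensor/electronics noise, a respiration sinusoid,
#' slow baseline drift, and sparse 0.5-s motion-artifact bursts.
#'
#' @param weights four nonnegative fractions summing to 1 (mass over legs).
#' @param noise_sd per-channel Gaussian noise SD, mV.
#' @param motion_artifact_rate expected motion bursts per minute.
#' @param motion_sd amplitude (SD, mV) of noise inside a motion burst.
#' @param respiration_amplitude respiration sinusoid amplitude, mV
#'   (scaled per channel by `4 * weight`).
#' @param respiration_freq breathing frequency, Hz.
#' @param drift_amplitude slow baseline drift amplitude, mV.
#' @param drift_freq drift frequency, Hz.
#' @return a `channel_layout` list.
#' @export
channel_layout <- function(weights = c(0.30, 0.28, 0.22, 0.20),
                           noise_sd = 0, motion_artifact_rate = 0,
                           motion_sd = 50,
                           respiration_amplitude = 0,
                           respiration_freq = 0.25,
                           drift_amplitude = 0, drift_freq = 0.03) {
  if (length(weights) != 4 || any(weights < 0)) {
    stop("`weights` must be four nonnegative fractions", call. = FALSE)
  }
  if (abs(sum(weights) - 1) > 1e-9) {
    stop("`weights` must sum to 1 (within 1e-9)", call. = FALSE)
  }
  if (noise_sd < 0 || motion_artifact_rate < 0 || respiration_amplitude < 0) {
    stop("noise rates/amplitudes must be >= 0", call. = FALSE)
  }
  structure(list(weights = weights, noise_sd = noise_sd,
                 motion_artifact_rate = motion_artifact_rate,
                 motion_sd = motion_sd,
                 respiration_amplitude = respiration_amplitude,
                 respiration_freq = respiration_freq,
                 drift_amplitude = drift_amplitude,
                 drift_freq = drift_freq),
            class = "channel_layout")
}

#' Preset noise configurations
#'
#' `layout_clean()` has all nuisance components off; `layout_noisy()` adds
#' sensor noise, respiration, drift and motion bursts at levels typical of
#' a seated recording.
#' @param weights mass distribution over the four legs.
#' @return a [channel_layout()].
#' @export
layout_clean <- function(weights = c(0.30, 0.28, 0.22, 0.20)) {
  channel_layout(weights = weights)
}

#' @rdname layout_clean
#' @export
layout_noisy <- function(weights = c(0.30, 0.28, 0.22, 0.20)) {
  channel_layout(weights = weights, noise_sd = 2,
                 motion_artifact_rate = 2, motion_sd = 50,
                 respiration_amplitude = 8, respiration_freq = 0.25,
                 drift_amplitude = 5, drift_freq = 0.03)
}

#' Synthesize a single-lead ECG from known R-peak times
#'
#' Places one QRS-like template (sharp dominant positive R deflection with
#' small Q and S side lobes) at the sample nearest each R time. The global
#' maximum within +/- 0.05 s of each R time lands exactly on that sample.
#'
#' @param r_times ascending R-peak times, seconds, within `[0, duration)`.
#' @param fs sampling rate, Hz.
#' @param duration recording length, seconds.
#' @param noise_sd additive Gaussian noise SD, mV (default 0).
#' @param seed RNG seed for the noise.
#' @return list with `recording` (1-channel [recording()], mV) and
#'   `r_samples` (0-based sample indices of the R peaks).
#' @export
synth_ecg <- function(r_times, fs, duration, noise_sd = 0, seed = 1L) {
  if (length(r_times) > 1 && is.unsorted(r_times)) {
    stop("`r_times` must be ascending", call. = FALSE)
  }
  if (any(r_times < 0 | r_times >= duration)) {
    stop("`r_times` must lie within [0, duration)", call. = FALSE)
  }
  n <- round(duration * fs)
  x <- numeric(n)
  # QRS morphology: R spike flanked by shallow Q and S waves, ~1 mV
  tt <- seq(-0.06, 0.06, by = 1 / fs)
  qrs <- exp(-(tt / 0.012)^2) -
    0.20 * exp(-((tt + 0.022) / 0.010)^2) -
    0.25 * exp(-((tt - 0.025) / 0.011)^2)
  ctr <- which(tt == 0)
  r_samples <- integer(length(r_times))
  for (i in seq_along(r_times)) {
    s <- round(r_times[i] * fs)          # 0-based index of the R sample
    r_samples[i] <- s
    lo <- s - (ctr - 1L)
    idx <- seq(lo, lo + length(qrs) - 1L)
    keep <- idx >= 0 & idx < n
    x[idx[keep] + 1L] <- x[idx[keep] + 1L] + qrs[keep]
  }
  if (noise_sd > 0) {
    x <- x + with_seed(seed, stats::rnorm(n, sd = noise_sd))
  }
  list(recording = recording(matrix(x, nrow = 1), fs,
                             channel_names = "ecg"),
       r_samples = r_samples)
}

# mV output of the bridge when the force-sensing arm R1 is strained by
# (1 + gain * f) relative to rest; static sensitivity model.
bridge_mv <- function(f, bridge, strain_gain) {
  base <- bridge_output(bridge)
  e <- (bridge$r1 * (1 + strain_gain * f) * bridge$r3 - bridge$r2 * bridge$r4) /
    ((bridge$r1 * (1 + strain_gain * f) + bridge$r2) * (bridge$r3 + bridge$r4)) *
    bridge$excitation
  (e - base) * 1000
}

#' Synthesize a four-channel chair BCG from an RR series
#'
#' Builds the beat train (one force template per beat, the J peak placed at
#' `r_time + latency`), distributes it over the four load cells according to
#' the layout weights, converts force to millivolts through the Wheatstone
#' bridge static sensitivity, and adds the layout's respiration, drift,
#' sensor-noise and motion-burst components. The default `strain_gain` is
#' calibrated so that clean-mode per-channel peak-to-peak amplitudes fall
#' inside the 35-85 mV quality-control acceptance band.
#'
#' @param rr numeric RR intervals, seconds (beats at their cumulative sums,
#'   starting at t = 0).
#' @param duration recording length, seconds.
#' @param layout a [channel_layout()].
#' @param bridge a [bridge_params()].
#' @param aortic an [aortic_params()] for the beat template.
#' @param fs sampling rate, Hz (default 200).
#' @param latency fixed R-to-J mechanical delay, seconds (default 0.25).
#' @param jitter_sd per-beat Gaussian jitter of the latency, seconds.
#' @param strain_gain bridge strain sensitivity per unit normalized force.
#' @param seed RNG seed; fixed seed gives bit-identical output.
#' @return list with `recording` (4-channel [recording()], mV),
#'   `true_r_times` and `true_j_times` (seconds, equal length).
#' @export
synth_bcg <- function(rr, duration, layout = layout_clean(),
                      bridge = bridge_params(), aortic = aortic_params(),
                      fs = 200, latency = 0.25, jitter_sd = 0,
                      strain_gain = 0.176, seed = 1L) {
  stopifnot(inherits(layout, "channel_layout"),
            inherits(bridge, "bridge_params"))
  if (any(rr <= 0)) stop("RR intervals must be > 0", call. = FALSE)
  n <- round(duration * fs)
  r_times <- beat_times_from_rr(rr, duration)

  with_seed(seed, {
    jit <- if (jitter_sd > 0) stats::rnorm(length(r_times), sd = jitter_sd)
           else numeric(length(r_times))
    j_times <- r_times + latency + jit

    beat <- beat_force_waveform(aortic, fs)
    tpl <- beat$force / (max(beat$force) - min(beat$force))  # unit p2p
    j_off <- beat$j_index - 1L                               # samples before J

    keep <- j_times + (length(tpl) - beat$j_index) / fs < duration &
      j_times - j_off / fs >= 0
    r_times <- r_times[keep]
    j_times <- j_times[keep]

    train <- numeric(n)
    for (jt in j_times) {
      s <- round(jt * fs)                 # 0-based sample of the J peak
      idx <- seq(s - j_off, s - j_off + length(tpl) - 1L)
      train[idx + 1L] <- train[idx + 1L] + tpl
    }

    tgrid <- (seq_len(n) - 1L) / fs
    data <- matrix(0, nrow = 4, ncol = n)
    for (ch in 1:4) {
      w <- layout$weights[ch]
      sig <- bridge_mv(w * train, bridge, strain_gain)
      if (layout$respiration_amplitude > 0) {
        sig <- sig + 4 * w * layout$respiration_amplitude *
          sin(2 * pi * layout$respiration_freq * tgrid +
                stats::runif(1, 0, 2 * pi))
      }
      if (layout$drift_amplitude > 0) {
        sig <- sig + layout$drift_amplitude *
          sin(2 * pi * layout$drift_freq * tgrid + stats::runif(1, 0, 2 * pi))
      }
      if (layout$noise_sd > 0) {
        sig <- sig + stats::rnorm(n, sd = layout$noise_sd)
      }
      if (layout$motion_artifact_rate > 0) {
        n_bursts <- stats::rpois(1, layout$motion_artifact_rate * duration / 60)
        if (n_bursts > 0) {
          burst_len <- round(0.5 * fs)
          starts <- sort(stats::runif(n_bursts, 0, duration - 0.5))
          for (b in starts) {
            s0 <- round(b * fs)
            idx <- seq(s0 + 1L, min(s0 + burst_len, n))
            sig[idx] <- sig[idx] + stats::rnorm(length(idx),
                                                sd = layout$motion_sd)
          }
        }
      }
      data[ch, ] <- sig
    }
    list(recording = recording(data, fs,
                               channel_names = paste0("bcg", 1:4)),
         true_r_times = r_times, true_j_times = j_times)
  })
}

#' Simulate one paired BCG + ECG recording
#'
#' Draws an RR series from the cardiac parameters, then synthesizes the
#' four-channel chair BCG and the simultaneous single-lead ECG sharing the
#' same ground-truth R-peak times. The J peaks lag the R peaks by the fixed
#' mechanical latency (optionally jittered per beat).
#'
#' @param cardiac a [cardiac_params()].
#' @param layout a [channel_layout()].
#' @param bridge a [bridge_params()].
#' @param aortic an [aortic_params()].
#' @param fs sampling rate, Hz.
#' @param latency,jitter_sd R-to-J latency model, seconds.
#' @param ecg_noise_sd ECG additive noise SD, mV.
#' @return a `bcg_paired` object: fields `bcg`, `ecg` ([recording()]s),
#'   `fs`, `true_r_times`, `true_j_times`, and a `params` snapshot.
#' @export
simulate_paired <- function(cardiac = cardiac_params(),
                            layout = layout_clean(),
                            bridge = bridge_params(),
                            aortic = aortic_params(),
                            fs = 200, latency = 0.25, jitter_sd = 0,
                            ecg_noise_sd = 0) {
  rr <- generate_rr_intervals(cardiac)
  syn <- synth_bcg(rr, cardiac$duration, layout = layout, bridge = bridge,
                   aortic = aortic, fs = fs, latency = latency,
                   jitter_sd = jitter_sd, seed = cardiac$seed)
  ecg <- synth_ecg(syn$true_r_times, fs, cardiac$duration,
                   noise_sd = ecg_noise_sd, seed = cardiac$seed + 1L)
  stopifnot(length(syn$true_j_times) == length(syn$true_r_times),
            all(syn$true_j_times > syn$true_r_times))
  structure(list(bcg = syn$recording, ecg = ecg$recording, fs = fs,
                 true_r_times = syn$true_r_times,
                 true_j_times = syn$true_j_times,
                 params = list(cardiac = cardiac, layout = layout,
                               bridge = bridge, aortic = aortic,
                               latency = latency, jitter_sd = jitter_sd)),
            class = "bcg_paired")
}

#' @export
print.bcg_paired <- function(x, ...) {
  cat(sprintf("<bcg_paired> %.0f s @ %g Hz, %d beats (mean HR %.1f bpm)\n",
              duration(x$bcg), x$fs, length(x$true_r_times),
              60 * (length(x$true_r_times) - 1) /
                diff(range(x$true_r_times))))
  invisible(x)
}

#' Simulate a cohort of paired recordings
#'
#' Draws independent per-subject cardiac parameters uniformly within the
#' given ranges (resting adults: mean RR 0.7-1.0 s, i.e. 60-86 bpm) and
#' simulates one paired BCG+ECG recording per subject. Deterministic given
#' `seed`.
#'
#' @param n_subjects number of subjects (>= 1).
#' @param duration per-subject recording length, seconds (default 600,
#'   i.e. the ten-minute seated protocol).
#' @param mean_rr_range,rr_sd_range,rsa_amplitude_range uniform sampling
#'   ranges for the per-subject cardiac parameters (each length-2,
#'   `min <= max`).
#' @param layout a [channel_layout()] shared by all subjects.
#' @param jitter_sd per-beat R-to-J latency jitter, seconds.
#' @param seed master RNG seed.
#' @return list of `bcg_paired` objects, one per subject.
#' @export
simulate_cohort <- function(n_subjects = 13, duration = 600,
                            mean_rr_range = c(0.7, 1.0),
                            rr_sd_range = c(0.03, 0.06),
                            rsa_amplitude_range = c(0.01, 0.03),
                            layout = layout_clean(),
                            jitter_sd = 0,
                            seed = 1L) {
  if (n_subjects < 1) stop("`n_subjects` must be >= 1", call. = FALSE)
  for (rg in list(mean_rr_range, rr_sd_range, rsa_amplitude_range)) {
    if (length(rg) != 2 || rg[1] > rg[2]) {
      stop("parameter ranges must be length-2 with min <= max", call. = FALSE)
    }
  }
  draws <- with_seed(seed, list(
    mean_rr = stats::runif(n_subjects, mean_rr_range[1], mean_rr_range[2]),
    rr_sd = stats::runif(n_subjects, rr_sd_range[1], rr_sd_range[2]),
    rsa = stats::runif(n_subjects, rsa_amplitude_range[1],
                       rsa_amplitude_range[2]),
    subseed = sample.int(2^30, n_subjects)
  ))
  lapply(seq_len(n_subjects), function(i) {
    simulate_paired(
      cardiac = cardiac_params(mean_rr = draws$mean_rr[i],
                               rr_sd = draws$rr_sd[i],
                               rsa_amplitude = draws$rsa[i],
                               duration = duration,
                               seed = draws$subseed[i]),
      layout = layout, jitter_sd = jitter_sd)
  })
}
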