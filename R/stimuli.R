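# Stimulus synthesis for the two validation paradigms:
#   masker_probe        : 100-ms 1 kHz masker, 100-ms silent gap, 10-ms
#                         1 kHz probe whose level (dB re masker) is swept
#   amplitude_modulation: 1500 Hz carrier, 40 Hz sinusoidal AM, depth m
#                         swept; the unmodulated pure tone is the reference
# Waveforms are monaural pressure signals in arbitrary linear units until
# calibrated (see calibrate_level).

MASKER_FREQ <- 1000
MASKER_DUR <- 0.100
GAP_DUR <- 0.100
PROBE_DUR <- 0.010
AM_CARRIER <- 1500
AM_RATE <- 40

new_stimulus <- function(samples, sample_rate, paradigm, role, intensity,
                         level_db = NA_real_, cal_support = seq_along(samples),
                         segments = list()) {
  structure(
    list(
      samples = samples,
      sample_rate = sample_rate,
      paradigm = paradigm,
      role = role,
      intensity = intensity,
      level_db = level_db,
      cal_support = cal_support,
      segments = segments
    ),
    class = "stimulus"
  )
}

#' @export
print.stimulus <- function(x, ...) {
  cat(sprintf(
    "<stimulus> %s / %s, %.0f ms @ %g Hz, intensity = %g, level = %s dB\n",
    x$paradigm, x$role, 1000 * length(x$samples) / x$sample_rate,
    x$sample_rate, x$intensity,
    if (is.na(x$level_db)) "uncalibrated" else format(x$level_db)
  ))
  invisible(x)
}

#' Duration of a stimulus in seconds
#' @param stimulus a `stimulus` object
#' @return duration in seconds
#' @export
stimulus_duration <- function(stimulus) {
  length(stimulus$samples) / stimulus$sample_rate
}

#' Synthesize a masker-probe stimulus
#'
#' A 100-ms 1 kHz masker tone, 100 ms of silence, and a 10-ms 1 kHz probe
#' whose amplitude is set in dB relative to the masker amplitude. With
#' `include_probe = FALSE` the probe is omitted and the stimulus is the
#' reference (`role = "R"`); otherwise it is the reference-plus-test
#' (`role = "RT"`). Every tone segment gets raised-cosine on/off ramps.
#'
#' @param probe_level_db probe level in dB relative to the masker amplitude
#' @param include_probe logical; omit the probe to get the reference
#' @param sample_rate sampling rate in Hz (>= 8000)
#' @param ramp_s ramp duration per edge in seconds (default 2 ms)
#' @return a `stimulus` object (uncalibrated; see [calibrate_level()])
#' @export
synthesize_masker_probe <- function(probe_level_db, include_probe = TRUE,
                                    sample_rate = 44100, ramp_s = 0.002) {
  if (!is.numeric(sample_rate) || length(sample_rate) != 1 || sample_rate < 8000) {
    stop_invalid("sample_rate must be a single number >= 8000 Hz")
  }
  if (!is.finite(probe_level_db)) {
    stop_invalid("probe_level_db must be finite")
  }
  gain <- 10^(probe_level_db / 20)
  if (!is.finite(gain)) stop_invalid("probe_level_db produces numeric overflow")

  n_masker <- round(MASKER_DUR * sample_rate)
  n_gap <- round(GAP_DUR * sample_rate)
  n_probe <- round(PROBE_DUR * sample_rate)
  n_ramp <- round(ramp_s * sample_rate)

  t_masker <- (seq_len(n_masker) - 1) / sample_rate
  masker <- sin(2 * pi * MASKER_FREQ * t_masker) *
    raised_cosine_ramp(n_masker, n_ramp)

  probe <- numeric(n_probe)
  if (include_probe) {
    t_probe <- (seq_len(n_probe) - 1) / sample_rate
    probe <- gain * sin(2 * pi * MASKER_FREQ * t_probe) *
      raised_cosine_ramp(n_probe, n_ramp)
  }

  samples <- c(masker, numeric(n_gap), probe)
  new_stimulus(
    samples, sample_rate,
    paradigm = "masker_probe",
    role = if (include_probe) "RT" else "R",
    intensity = if (include_probe) probe_level_db else -Inf,
    cal_support = seq_len(n_masker),
    segments = list(
      masker = c(1L, n_masker),
      probe = c(n_masker + n_gap + 1L, n_masker + n_gap + n_probe)
    )
  )
}

#' Synthesize an amplitude-modulation detection stimulus
#'
#' The modulated variant is a 1500 Hz carrier with envelope
#' `(1 + m sin(2 pi 40 t))`, normalized so its maximum amplitude equals the
#' pure tone's amplitude; the unmodulated variant is the pure tone
#' (the reference). Modulation depth `m` lies in `[0, 1]`.
#'
#' @param depth modulation depth m in `[0, 1]`
#' @param is_modulated logical; `FALSE` gives the pure-tone reference
#' @param sample_rate sampling rate in Hz
#' @param duration_s stimulus duration in seconds (default 0.3, i.e. 12
#'   modulation cycles)
#' @param ramp_s ramp duration per edge in seconds
#' @return a `stimulus` object (uncalibrated)
#' @export
synthesize_am <- function(depth, is_modulated = TRUE, sample_rate = 44100,
                          duration_s = 0.300, ramp_s = 0.002) {
  if (!is.numeric(depth) || length(depth) != 1 || is.na(depth) ||
      depth < 0 || depth > 1) {
    stop_invalid("depth must lie in [0, 1]")
  }
  if (!is.numeric(sample_rate) || length(sample_rate) != 1 || sample_rate <= 0) {
    stop_invalid("sample_rate must be positive")
  }
  n <- round(duration_s * sample_rate)
  t <- (seq_len(n) - 1) / sample_rate
  carrier <- sin(2 * pi * AM_CARRIER * t)
  if (is_modulated && depth > 0) {
    env <- (1 + depth * sin(2 * pi * AM_RATE * t)) / (1 + depth)
    samples <- env * carrier
  } else {
    samples <- carrier
  }
  samples <- samples * raised_cosine_ramp(n, round(ramp_s * sample_rate))
  new_stimulus(
    samples, sample_rate,
    paradigm = "amplitude_modulation",
    role = if (is_modulated) "RT" else "R",
    intensity = if (is_modulated) depth else 0,
    cal_support = seq_len(n),
    segments = list(tone = c(1L, n))
  )
}

#' Calibrate a stimulus to a presentation level
#'
#' Reference (`role = "R"`) waveforms are scaled so that their RMS over the
#' calibration support (the masker segment for masker-probe; the full tone
#' for AM) equals `target_db` under the package dB convention
#' (`dB = 20 log10(RMS / ref)`, with 65 dB mapping to RMS 0.05). Test
#' (`role = "RT"`) waveforms must be calibrated with the gain computed from
#' their paradigm's reference, so that R and RT share one physical scale;
#' pass that reference via `reference`.
#'
#' @param stimulus a `stimulus`
#' @param target_db target presentation level in dB
#' @param reference for RT stimuli, the already-synthesized (uncalibrated)
#'   reference stimulus defining the gain; defaults to `stimulus` itself for
#'   R stimuli
#' @return the calibrated `stimulus`, with `level_db` set
#' @export
calibrate_level <- function(stimulus, target_db, reference = NULL) {
  if (is.null(reference)) {
    if (!identical(stimulus$role, "R")) {
      stop_invalid("RT stimuli must be calibrated against their reference; ",
                   "pass `reference`")
    }
    reference <- stimulus
  }
  ref_rms <- sqrt(mean(reference$samples[reference$cal_support]^2))
  if (ref_rms == 0) stop_invalid("cannot calibrate an all-zero stimulus")
  gain <- db_to_lin(target_db) / ref_rms
  stimulus$samples <- stimulus$samples * gain
  stimulus$level_db <- target_db
  stimulus
}

#' Calibrate a reference/test pair to a common scale
#'
#' Convenience wrapper: calibrates the reference to `target_db` and applies
#' the identical gain to the test stimulus.
#'
#' @param reference `stimulus` with role R
#' @param test `stimulus` with role RT, same paradigm and sample rate
#' @param target_db target level in dB (default 65)
#' @return list with elements `reference` and `test`
#' @export
calibrate_pair <- function(reference, test, target_db = 65) {
  if (!identical(reference$paradigm, test$paradigm) ||
      !identical(reference$sample_rate, test$sample_rate)) {
    stop_invalid("reference and test must share paradigm and sample rate")
  }
  list(
    reference = calibrate_level(reference, target_db),
    test = calibrate_level(test, target_db, reference = reference)
  )
}

#' Assemble a 3AFC trial
#'
#' Places the reference-plus-test (RT) stimulus uniformly at random among
#' three intervals; the other two intervals hold the reference. Samples are
#' never modified, only ordered.
#'
#' @param reference `stimulus` with role R
#' @param test `stimulus` with role RT, same paradigm and sample rate
#' @param seed integer seed for the odd-interval draw (`NULL` uses the
#'   current RNG stream)
#' @return a `trial_set`: list with `intervals` (list of 3 stimuli) and
#'   `odd_index` (1-3, position of the RT interval)
#' @export
build_trial <- function(reference, test, seed = NULL) {
  if (!identical(reference$role, "R") || !identical(test$role, "RT")) {
    stop_invalid("build_trial needs reference role R and test role RT")
  }
  if (!identical(reference$paradigm, test$paradigm) ||
      !identical(reference$sample_rate, test$sample_rate)) {
    stop_invalid("reference and test must share paradigm and sample rate")
  }
  odd <- if (is.null(seed)) {
    sample.int(3L, 1L)
  } else {
    with_seed(seed, sample.int(3L, 1L))
  }
  intervals <- list(reference, reference, reference)
  intervals[[odd]] <- test
  structure(list(intervals = intervals, odd_index = odd), class = "trial_set")
}
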