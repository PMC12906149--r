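# Stochastic surrogate auditory-nerve frontend.
#
# The frontend contract is a single operation: simulate a calibrated
# stimulus into per-band, per-fiber spike trains. The built-in surrogate
# implements it with a gammatone-style critical-band envelope analysis, a
# rate-intensity sigmoid, spike-triggered slow adaptation (producing
# forward masking), an absolute refractory period, and per-fiber
# independent random substreams. Any external auditory-nerve model can be
# plugged in by implementing `simulate_frontend()` for its own class;
# outputs are validated at the boundary.

#' ERB-rate scale helpers
#'
#' `erb_space()` returns `n` center frequencies equally spaced on the
#' ERB-rate scale between `f_lo` and `f_hi`; `erb_bandwidth()` returns the
#' equivalent rectangular bandwidth at a center frequency.
#'
#' @param f_lo,f_hi frequency range in Hz
#' @param n number of bands
#' @return `erb_space()`: numeric vector of center frequencies (Hz)
#' @export
erb_space <- function(f_lo, f_hi, n) {
  erb_rate <- function(f) 21.4 * log10(4.37 * f / 1000 + 1)
  erb_rate_inv <- function(e) (10^(e / 21.4) - 1) * 1000 / 4.37
  erb_rate_inv(seq(erb_rate(f_lo), erb_rate(f_hi), length.out = n))
}

#' @rdname erb_space
#' @param cf center frequency in Hz
#' @return `erb_bandwidth()`: bandwidth in Hz
#' @export
erb_bandwidth <- function(cf) 24.7 * (4.37 * cf / 1000 + 1)

#' Construct a frontend profile
#'
#' A profile bundles the tonotopic band set, the number of fibers per band,
#' and the single-fiber response parameters. Two named profiles are
#' provided: `"NH"` (normal hearing: 20 ERB-spaced bands 125-8000 Hz, 50
#' fibers per characteristic frequency) and `"EH"` (electric hearing: 16
#' bands mirroring a cochlear-implant electrode array, 1 fiber per band).
#' The EH profile differs from NH only in band count and fiber count; the
#' fiber-count asymmetry is what motivates the relative noise scaling of
#' the detection stage.
#'
#' @param name `"NH"` or `"EH"`
#' @param n_bands number of critical bands (default 20 for NH, 16 for EH)
#' @param f_lo,f_hi band range in Hz
#' @param fibers_per_band fibers per characteristic frequency (default 50
#'   for NH, 1 for EH)
#' @param spont_rate spontaneous rate in spikes/s (NH default 50; EH
#'   default 0.1 - a deafened cochlea has essentially no spontaneous
#'   activity)
#' @param max_rate saturated driven rate in spikes/s (EH default 400:
#'   electric stimulation drives fibers more reliably than acoustic)
#' @param threshold_db rate-intensity sigmoid midpoint on the package's
#'   absolute dB scale (the calibrated reference sits at 65 dB)
#' @param slope_db rate-intensity sigmoid slope constant in dB (EH
#'   default 3: the electric dynamic range is far narrower than the
#'   acoustic one)
#' @param floor_db envelope floor in dB: envelopes below it are clamped
#' @param adaptation_tau recovery time constant of the spike-triggered
#'   adaptation, in seconds
#' @param depression fractional rate depression per emitted spike
#' @param refractory absolute refractory period in seconds
#' @param bin_width envelope/IR time step in seconds (must exceed the
#'   refractory period; at most one spike per fiber per bin)
#' @return a `frontend_profile` object
#' @export
frontend_profile <- function(name = c("NH", "EH"),
                             n_bands = NULL,
                             f_lo = 125, f_hi = 8000,
                             fibers_per_band = NULL,
                             spont_rate = NULL,
                             max_rate = NULL,
                             threshold_db = 40,
                             slope_db = NULL,
                             floor_db = -10,
                             adaptation_tau = 0.100,
                             depression = 0.02,
                             refractory = 0.0007,
                             bin_width = 0.001) {
  name <- match.arg(name)
  if (is.null(n_bands)) n_bands <- if (name == "NH") 20L else 16L
  if (is.null(fibers_per_band)) fibers_per_band <- if (name == "NH") 50L else 1L
  if (is.null(spont_rate)) spont_rate <- if (name == "NH") 50 else 0.1
  if (is.null(max_rate)) max_rate <- if (name == "NH") 250 else 400
  if (is.null(slope_db)) slope_db <- if (name == "NH") 10 else 3
  if (fibers_per_band < 1) stop_invalid("fibers_per_band must be >= 1")
  if (bin_width <= refractory) {
    stop_invalid("bin_width must exceed the refractory period")
  }
  if (bin_width > 0.001) stop_invalid("bin_width must be <= 1 ms")
  band_cfs <- erb_space(f_lo, f_hi, n_bands)
  if (any(diff(band_cfs) <= 0)) stop_invalid("band_cfs must be strictly increasing")
  structure(
    list(
      name = name,
      n_bands = as.integer(n_bands),
      band_cfs = band_cfs,
      fibers_per_band = as.integer(fibers_per_band),
      rate_params = list(
        spont_rate = spont_rate, max_rate = max_rate,
        threshold_db = threshold_db, slope_db = slope_db,
        floor_db = floor_db
      ),
      adaptation_tau = adaptation_tau,
      depression = depression,
      refractory = refractory,
      bin_width = bin_width
    ),
    class = "frontend_profile"
  )
}

#' @export
print.frontend_profile <- function(x, ...) {
  cat(sprintf(
    "<frontend_profile> %s: %d bands (%.0f-%.0f Hz), %d fiber(s)/band\n",
    x$name, x$n_bands, min(x$band_cfs), max(x$band_cfs), x$fibers_per_band
  ))
  invisible(x)
}

#' Critical-band envelope analysis of a stimulus
#'
#' Each band applies a first-order Butterworth bandpass of one ERB
#' centered on the band CF (zero-phase, forward-backward), full-wave
#' rectification, a 150-Hz lowpass smoother, and averaging into bins of the
#' profile's `bin_width`. Envelopes are returned in dB under the package
#' convention, clamped at the profile's floor.
#'
#' @param stimulus a calibrated `stimulus`
#' @param profile a `frontend_profile`
#' @return numeric matrix, bands x time bins, in dB
#' @export
band_envelopes <- function(stimulus, profile) {
  fs <- stimulus$sample_rate
  nyq <- fs / 2
  if (any(profile$band_cfs >= nyq)) {
    stop_invalid("band CF at or above Nyquist frequency")
  }
  x <- stimulus$samples
  n_bins <- ceiling(stimulus_duration(stimulus) / profile$bin_width)
  bin_of <- pmin(
    floor((seq_along(x) - 1) / (profile$bin_width * fs)) + 1L,
    n_bins
  )
  lp <- signal::butter(2, min(150 / nyq, 0.99), type = "low")
  env <- matrix(0, nrow = profile$n_bands, ncol = n_bins)
  for (b in seq_len(profile$n_bands)) {
    cf <- profile$band_cfs[b]
    bw <- erb_bandwidth(cf)
    lo <- max(cf - bw / 2, 1) / nyq
    hi <- min(cf + bw / 2, nyq * 0.98) / nyq
    bp <- signal::butter(1, c(lo, hi), type = "pass")
    y <- signal::filtfilt(bp, x)
    e <- signal::filtfilt(lp, abs(y))
    env[b, ] <- vapply(
      split(e, bin_of), mean, numeric(1)
    )[as.character(seq_len(n_bins))]
  }
  floor_lin <- db_to_lin(profile$rate_params$floor_db)
  lin_to_db(pmax(env, floor_lin))
}

#' Instantaneous firing rate from an envelope level
#'
#' Sigmoidal rate-intensity function:
#' `rate = spont + (max - spont) / (1 + exp(-(L - threshold)/slope))`.
#'
#' @param env_db envelope level(s) in dB
#' @param rate_params the `rate_params` list of a `frontend_profile`
#' @return firing rate(s) in spikes/s
#' @export
rate_intensity <- function(env_db, rate_params) {
  rate_params$spont_rate +
    (rate_params$max_rate - rate_params$spont_rate) /
      (1 + exp(-(env_db - rate_params$threshold_db) / rate_params$slope_db))
}

#' Construct a spike train set
#'
#' The container every frontend returns: one row per spike, identified by
#' critical band, fiber index, and time in seconds. External frontends
#' construct their output with this function; [validate_spike_train_set()]
#' checks the contract.
#'
#' @param spikes data.frame with columns `band`, `fiber`, `time`
#' @param duration stimulus duration in seconds
#' @param profile the `frontend_profile` that produced the spikes
#' @param stimulus_meta metadata list (paradigm/role/intensity) copied from
#'   the source stimulus
#' @return a `spike_train_set`
#' @export
spike_train_set <- function(spikes, duration, profile, stimulus_meta = list()) {
  structure(
    list(
      spikes = spikes, duration = duration,
      profile = profile, stimulus_meta = stimulus_meta
    ),
    class = "spike_train_set"
  )
}

new_spike_train_set <- spike_train_set

#' @export
print.spike_train_set <- function(x, ...) {
  cat(sprintf(
    "<spike_train_set> %d spikes, %d band(s) x %d fiber(s), %.0f ms (%s)\n",
    nrow(x$spikes), x$profile$n_bands, x$profile$fibers_per_band,
    1000 * x$duration, x$profile$name
  ))
  invisible(x)
}

#' Generate surrogate spike trains from band envelopes
#'
#' Each fiber is an inhomogeneous point process discretised at the envelope
#' time step (at most one spike per bin): the per-bin spike probability is
#' `1 - exp(-rate * a * bin_width)`, where `rate` follows the
#' rate-intensity sigmoid and `a` is a spike-triggered adaptation state
#' that is multiplied by `1 - depression` at every spike and relaxes back
#' toward 1 with time constant `adaptation_tau`. The adaptation carries
#' over silent gaps, so a 100-ms masker measurably suppresses the response
#' to a probe 100 ms later (forward masking). Spike times are jittered
#' uniformly within `[0, bin_width - refractory)` of the bin onset, which
#' guarantees the absolute refractory period between consecutive spikes.
#' Each fiber draws from an independent counter-based substream derived
#' from `seed` and the (band, fiber) index, so changing the fiber count
#' never perturbs other fibers' spike trains.
#'
#' @param envelopes bands x bins envelope matrix in dB (from
#'   [band_envelopes()])
#' @param profile a `frontend_profile`
#' @param seed integer master seed for this simulation
#' @param stimulus_meta optional metadata list copied into the result
#' @param duration stimulus duration in seconds (default: bins x bin_width)
#' @return a `spike_train_set`; `$spikes` is a data.frame with columns
#'   `band`, `fiber`, `time` (seconds), sorted by band, fiber, time
#' @export
surrogate_spikes <- function(envelopes, profile, seed,
                             stimulus_meta = list(), duration = NULL) {
  if (!is.matrix(envelopes) || nrow(envelopes) != profile$n_bands) {
    stop_invalid("envelopes must be a bands x bins matrix matching the profile")
  }
  if (is.null(duration)) duration <- ncol(envelopes) * profile$bin_width
  rates <- rate_intensity(envelopes, profile$rate_params)
  sp <- spike_kernel(
    rates, profile$fibers_per_band, profile$bin_width,
    profile$refractory, profile$depression, profile$adaptation_tau,
    duration, as.numeric(seed)
  )
  new_spike_train_set(sp, duration, profile, stimulus_meta)
}

#' Construct the built-in surrogate frontend
#'
#' Returns an object satisfying the frontend contract
#' ([simulate_frontend()]). Band envelopes are deterministic per stimulus
#' and are memoised internally, so repeated simulations of the same
#' stimulus (as in a trial loop) only pay the filtering cost once.
#'
#' @param profile a `frontend_profile`
#' @return a `surrogate_frontend` object
#' @export
surrogate_frontend <- function(profile = frontend_profile("NH")) {
  structure(
    list(profile = profile, cache = new.env(parent = emptyenv())),
    class = c("surrogate_frontend", "frontend")
  )
}

stimulus_cache_key <- function(stimulus) {
  paste(stimulus$paradigm, stimulus$role, stimulus$intensity,
        stimulus$level_db, length(stimulus$samples), sep = "|")
}

#' Simulate a stimulus into spike trains (frontend contract)
#'
#' The single operation every frontend must provide. Implement a method for
#' your own class to plug an external auditory-nerve model into the
#' detection pipeline; use [validate_spike_train_set()] (applied
#' automatically by the trial loop) to check conformance.
#'
#' @param frontend a frontend object
#' @param stimulus a calibrated `stimulus`
#' @param seed integer seed for this simulation's randomness
#' @return a `spike_train_set`
#' @export
simulate_frontend <- function(frontend, stimulus, seed) {
  UseMethod("simulate_frontend")
}

#' @export
simulate_frontend.surrogate_frontend <- function(frontend, stimulus, seed) {
  key <- stimulus_cache_key(stimulus)
  env <- frontend$cache
  if (is.null(env[[key]])) {
    env[[key]] <- band_envelopes(stimulus, frontend$profile)
  }
  surrogate_spikes(
    env[[key]], frontend$profile, seed,
    stimulus_meta = list(
      paradigm = stimulus$paradigm, role = stimulus$role,
      intensity = stimulus$intensity, profile = frontend$profile$name
    ),
    duration = stimulus_duration(stimulus)
  )
}

#' Validate a spike train set against the frontend contract
#'
#' Checks that spike times lie in `[0, duration)`, are sorted within each
#' fiber, and respect the profile's absolute refractory period.
#'
#' @param sts a `spike_train_set`
#' @return `sts`, invisibly, if valid; otherwise an error
#' @export
validate_spike_train_set <- function(sts) {
  if (!inherits(sts, "spike_train_set")) {
    stop_invalid("not a spike_train_set")
  }
  sp <- sts$spikes
  if (!all(c("band", "fiber", "time") %in% names(sp))) {
    stop_invalid("spikes must have columns band, fiber, time")
  }
  if (nrow(sp) > 0) {
    if (any(sp$time < 0) || any(sp$time >= sts$duration)) {
      stop_invalid("spike times must lie in [0, duration)")
    }
    isi <- tapply(sp$time, interaction(sp$band, sp$fiber, drop = TRUE),
                  function(t) if (length(t) > 1) min(diff(t)) else Inf)
    if (any(unlist(isi) < 0)) stop_invalid("spike times must be sorted per fiber")
    if (any(unlist(isi) < sts$profile$refractory - 1e-12)) {
      stop_invalid("refractory period violated")
    }
  }
  invisible(sts)
}

#' Dump spike trains to CSV
#'
#' @param sts a `spike_train_set`
#' @param path output CSV path (columns: band, fiber, time_s)
#' @return `path`, invisibly
#' @export
write_spikes <- function(sts, path) {
  df <- sts$spikes
  names(df) <- c("band", "fiber", "time_s")
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
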