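# Shared fixtures: small frontend profiles (fast), a degenerate
# deterministic frontend exercising the frontend contract, and hand-built
# internal representations.

small_nh <- function(...) {
  frontend_profile("NH", n_bands = 6, f_lo = 500, f_hi = 3000,
                   fibers_per_band = 10, ...)
}

nh10 <- function(...) frontend_profile("NH", n_bands = 10, ...)

# A profile for hand-built spike trains: parameters only matter for
# validation (refractory) and binning.
toy_profile <- function(n_bands = 1) {
  frontend_profile("EH", n_bands = n_bands, fibers_per_band = 1)
}

toy_spikes <- function(times, duration, band = 1L, n_bands = 1) {
  spike_train_set(
    data.frame(band = as.integer(band), fiber = 1L, time = times),
    duration = duration, profile = toy_profile(n_bands)
  )
}

make_ir <- function(values, bin_width = 0.001, intensity = NA_real_) {
  internal_representation(
    values, bin_width, band_cfs = seq_len(nrow(values)) * 100,
    source_meta = list(intensity = intensity)
  )
}

# Degenerate contract-conforming frontend: deterministic spikes whose
# count in a late window scales with the stimulus intensity.
deterministic_frontend <- function(profile = toy_profile(2)) {
  structure(list(profile = profile), class = c("det_frontend", "frontend"))
}

simulate_frontend.det_frontend <- function(frontend, stimulus, seed) {
  dur <- stimulus_duration(stimulus)
  base <- seq(0.005, dur - 0.01, by = 0.005)
  extra <- if (identical(stimulus$role, "RT")) {
    seq(dur - 0.009, dur - 0.001, by = 0.002)
  } else {
    numeric(0)
  }
  df <- do.call(rbind, lapply(seq_len(frontend$profile$n_bands), function(b) {
    t <- if (b == 1) sort(c(base, extra)) else base
    data.frame(band = b, fiber = 1L, time = t)
  }))
  spike_train_set(df, dur, frontend$profile,
                  list(role = stimulus$role, intensity = stimulus$intensity))
}

# registerS3method so the generic dispatches from the installed namespace
registerS3method("simulate_frontend", "det_frontend",
                 simulate_frontend.det_frontend,
                 envir = asNamespace("softafc"))
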