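# Internal representations (IRs): band x time-bin spike-count matrices
# summed over fibers, the model's percept proxy. The forward-masking stage
# (FMS) is a leaky-subtraction operator that emphasises onsets and
# attenuates activity following a masker.

#' Construct an internal representation
#'
#' @param values band x time-bin matrix of (fiber-summed) spike counts
#' @param bin_width bin width in seconds
#' @param band_cfs band center frequencies in Hz
#' @param source_meta metadata list (paradigm/role/intensity/profile)
#' @param noisy whether Gaussian internal noise has been added
#' @param fms_applied whether the forward-masking stage has been applied
#' @return an `internal_representation`
#' @export
internal_representation <- function(values, bin_width, band_cfs,
                                    source_meta = list(),
                                    noisy = FALSE, fms_applied = FALSE) {
  if (!is.matrix(values)) stop_invalid("values must be a matrix")
  structure(
    list(
      values = values, bin_width = bin_width, band_cfs = band_cfs,
      source_meta = source_meta, noisy = noisy, fms_applied = fms_applied
    ),
    class = "internal_representation"
  )
}

new_internal_representation <- internal_representation

#' @export
print.internal_representation <- function(x, ...) {
  cat(sprintf(
    "<internal_representation> %d band(s) x %d bin(s) @ %.3g ms%s%s\n",
    nrow(x$values), ncol(x$values), 1000 * x$bin_width,
    if (x$noisy) ", noisy" else "",
    if (x$fms_applied) ", FMS applied" else ""
  ))
  invisible(x)
}

# Mass-conserving boxcar smoother: each source bin's kernel is renormalised
# over its in-range support, so the grand total is preserved exactly even
# at the edges.
smooth_conserve <- function(x, width) {
  n <- length(x)
  h <- (width - 1) %/% 2
  if (h < 1 || n == 1) return(x)
  idx <- seq_len(n)
  coverage <- pmin(idx + h, n) - pmax(idx - h, 1) + 1
  y <- x / coverage
  cs <- cumsum(c(0, y))
  cs[pmin(idx + h, n) + 1] - cs[pmax(idx - h, 1)]
}

#' Build an internal representation from spike trains
#'
#' Histograms all fibers' spike times into time bins per band, then
#' optionally applies a mass-conserving boxcar smoother along time.
#'
#' @param spikes a `spike_train_set`
#' @param bin_width bin width in seconds (default: the profile's bin width)
#' @param smoothing `NULL`/`"none"` for no smoothing, or a list
#'   `list(type = "boxcar", width = 5)` with an odd width in bins
#' @return an `internal_representation`
#' @export
build_ir <- function(spikes, bin_width = spikes$profile$bin_width,
                     smoothing = list(type = "boxcar", width = 5)) {
  if (!is.numeric(bin_width) || bin_width <= 0) {
    stop_invalid("bin_width must be positive")
  }
  if (bin_width > spikes$duration) {
    stop_invalid("bin_width exceeds the stimulus duration")
  }
  n_bands <- spikes$profile$n_bands
  n_bins <- ceiling(spikes$duration / bin_width)
  sp <- spikes$spikes
  values <- matrix(0, nrow = n_bands, ncol = n_bins)
  if (nrow(sp) > 0) {
    bin <- pmin(floor(sp$time / bin_width) + 1L, n_bins)
    flat <- (bin - 1L) * n_bands + sp$band
    values[] <- tabulate(flat, nbins = n_bands * n_bins)
  }
  if (!is.null(smoothing) && !identical(smoothing, "none")) {
    if (!identical(smoothing$type, "boxcar")) {
      stop_invalid("unknown smoothing type: ", smoothing$type)
    }
    w <- smoothing$width
    if (w %% 2 == 0) stop_invalid("boxcar width must be odd")
    for (b in seq_len(n_bands)) {
      values[b, ] <- smooth_conserve(values[b, ], w)
    }
  }
  new_internal_representation(
    values, bin_width, spikes$profile$band_cfs,
    source_meta = spikes$stimulus_meta
  )
}

#' Forward-masking stage configuration
#'
#' @param mode `"highpass_adaptation"` (the leaky-subtraction operator) or
#'   `"none"` (identity)
#' @param tau adaptation-state decay time constant in seconds
#' @param k subtraction strength (fraction of the accumulated state
#'   subtracted from the instantaneous input)
#' @return an `fms_config` object
#' @export
fms_config <- function(mode = c("highpass_adaptation", "none"),
                       tau = 0.050, k = 0.5) {
  mode <- match.arg(mode)
  enabled <- mode != "none"
  if (enabled && tau <= 0) stop_invalid("tau must be positive when enabled")
  structure(list(enabled = enabled, mode = mode, tau = tau, k = k),
            class = "fms_config")
}

#' Apply the forward-masking stage to an internal representation
#'
#' Per band, a leaky-subtraction recurrence:
#' `out[t] = max(0, in[t] - k * a[t])`,
#' `a[t] = d * a[t-1] + (1 - d) * in[t-1]`, `d = exp(-bin_width / tau)`,
#' `a[1] = 0`. The state `a` is a leaky average of recent activity (the
#' `1 - d` normalisation keeps it on the scale of the input, so the
#' subtraction strength `k` is a dimensionless fraction independent of the
#' bin width). Sustained input is attenuated toward `(1 - k)` of its
#' level, onsets pass through, and the response to a probe shortly after a
#' masker is suppressed relative to the probe alone. With `mode = "none"`
#' the IR is returned unchanged.
#'
#' @param ir a noiseless `internal_representation`
#' @param cfg an `fms_config`
#' @return the transformed `internal_representation` (`fms_applied` set)
#' @export
forward_masking_stage <- function(ir, cfg = fms_config()) {
  if (ir$noisy) stop_invalid("FMS applies to noiseless IRs")
  if (!cfg$enabled) return(ir)
  v <- ir$values
  n_bins <- ncol(v)
  decay <- exp(-ir$bin_width / cfg$tau)
  a <- numeric(nrow(v))
  out <- v
  for (t in seq_len(n_bins)) {
    out[, t] <- pmax(0, v[, t] - cfg$k * a)
    a <- a * decay + (1 - decay) * v[, t]
  }
  ir$values <- out
  ir$fms_applied <- TRUE
  ir
}

#' Pooled standard deviation of an internal representation
#'
#' The scalar `x` used to scale the relative internal noise: the population
#' (divide-by-N) standard deviation over all band x bin entries of the
#' reference IR, one value per frontend profile and paradigm.
#'
#' @param ir a noiseless `internal_representation` of a reference stimulus
#' @return scalar standard deviation
#' @export
ir_std <- function(ir) {
  if (ir$noisy) stop_invalid("ir_std is defined on noiseless IRs")
  v <- ir$values
  if (length(v) < 2) stop_invalid("IR must have at least 2 entries")
  sqrt(mean((v - mean(v))^2))
}

#' Export an internal representation as CSV plus JSON metadata sidecar
#'
#' @param ir an `internal_representation`
#' @param path output CSV path (rows = bands, columns = bins); a sidecar
#'   `<path>.json` carries bin width, band CFs and source metadata
#' @return `path`, invisibly
#' @export
export_ir <- function(ir, path) {
  df <- as.data.frame(ir$values)
  names(df) <- sprintf("bin%04d", seq_len(ncol(ir$values)))
  write.csv(cbind(band_cf_hz = ir$band_cfs, df), path, row.names = FALSE)
  jsonlite::write_json(
    list(
      bin_width_s = ir$bin_width, noisy = ir$noisy,
      fms_applied = ir$fms_applied, source_meta = ir$source_meta
    ),
    paste0(path, ".json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
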