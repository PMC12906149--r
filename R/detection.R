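# The detection model: an auditory-memory template (the difference between
# the internal representation at the greatest stimulus intensity and the
# reference representation), Gaussian internal noise scaled relative to
# the reference IR's standard deviation, per-critical-band zero-lag
# correlation of each noisy interval against the template, and either a
# temperature-parameterised softmax (per band, then averaged over bands
# and trials) or the legacy winner-take-all rule (the global maximum
# correlation across all bands decides).

#' Detection-model configuration
#'
#' @param sigma_rel relative internal noise: the Gaussian noise SD is
#'   `sigma_rel` times the standard deviation of the reference IR, so NH
#'   and EH frontends (whose IR amplitudes differ by the fiber-count
#'   ratio) are compared fairly
#' @param temperature softmax temperature T > 0; small T approaches
#'   winner-take-all (steep psychometric slope), large T approaches
#'   uniform guessing (shallow slope)
#' @param n_trials trials per intensity (default 100)
#' @param memory_mode `"RT_max"`: the template is built once from the
#'   highest-intensity stimulus (the auditory memory formed during
#'   practice trials); `"RT"`: the template is rebuilt each trial from the
#'   presented RT interval's own (pre-noise) representation, the legacy
#'   behaviour
#' @param decision_rule `"softmax_mean"` (per-band softmax probabilities
#'   averaged over bands) or `"argmax_legacy"` (global maximum correlation
#'   across bands and intervals)
#' @param seed integer master seed; all substreams are derived from it
#' @param band_inclusion `"all"` or `"template_energy_threshold"` (drop
#'   bands whose template energy falls below `theta` times the maximum
#'   band energy before averaging)
#' @param theta relative template-energy threshold in `[0, 1]`
#' @param normalization per-band correlation statistic: `"pearson"`
#'   (zero-lag Pearson correlation, scale-invariant) or `"dot"` (raw
#'   zero-lag dot product)
#' @param memory_reps number of frontend realisations averaged into the
#'   clean reference IR and the auditory-memory template (default 10).
#'   The memory is formed over repeated presentations, so averaging
#'   suppresses the frontend's spike noise in the stored representations;
#'   the per-trial intervals are always single fresh realisations
#' @param fms an [fms_config()]
#' @param smoothing IR smoothing spec passed to [build_ir()]
#' @return a `detection_config` object
#' @export
detection_config <- function(sigma_rel = 0.009,
                             temperature = 0.0009,
                             n_trials = 100,
                             memory_mode = c("RT_max", "RT"),
                             decision_rule = c("softmax_mean", "argmax_legacy"),
                             seed = 1L,
                             band_inclusion = c("all", "template_energy_threshold"),
                             theta = 0.01,
                             normalization = c("pearson", "dot"),
                             memory_reps = 10,
                             fms = fms_config(),
                             smoothing = list(type = "boxcar", width = 5)) {
  memory_mode <- match.arg(memory_mode)
  decision_rule <- match.arg(decision_rule)
  band_inclusion <- match.arg(band_inclusion)
  normalization <- match.arg(normalization)
  if (sigma_rel < 0) stop_invalid("sigma_rel must be >= 0")
  if (decision_rule == "softmax_mean" && temperature <= 0) {
    stop_invalid("temperature must be > 0 for the softmax decision rule")
  }
  if (n_trials < 1) stop_invalid("n_trials must be >= 1")
  if (memory_reps < 1) stop_invalid("memory_reps must be >= 1")
  structure(
    list(
      sigma_rel = sigma_rel, temperature = temperature,
      n_trials = as.integer(n_trials), memory_mode = memory_mode,
      decision_rule = decision_rule, seed = as.integer(seed),
      band_inclusion = band_inclusion, theta = theta,
      normalization = normalization, memory_reps = as.integer(memory_reps),
      fms = fms, smoothing = smoothing
    ),
    class = "detection_config"
  )
}

#' Form the auditory-memory template
#'
#' The template is the entrywise difference between the internal
#' representation of the highest-intensity stimulus and that of the
#' reference: `S_max = IR(RT_max) - IR(R)`. Under `memory_mode = "RT"` the
#' caller substitutes the current trial's IR(RT) for IR(RT_max).
#'
#' @param ir_rtmax noiseless `internal_representation` of the memory
#'   stimulus
#' @param ir_r noiseless `internal_representation` of the reference
#' @return a `template` object (`$values`: band x bin matrix,
#'   `$source_intensity`)
#' @export
make_template <- function(ir_rtmax, ir_r) {
  if (!identical(dim(ir_rtmax$values), dim(ir_r$values))) {
    stop_invalid("template inputs must have matching shapes")
  }
  if (ir_rtmax$noisy || ir_r$noisy) {
    stop_invalid("template inputs must be noiseless")
  }
  structure(
    list(
      values = ir_rtmax$values - ir_r$values,
      source_intensity = ir_rtmax$source_meta$intensity
    ),
    class = "template"
  )
}

#' Internal-noise standard deviation from the relative noise parameter
#'
#' `sigma_w = sigma_rel * x`, where `x` is the standard deviation of the
#' reference IR (per frontend profile and paradigm; see [ir_std()]).
#'
#' @param sigma_rel relative noise, >= 0
#' @param x reference-IR standard deviation, >= 0
#' @return the absolute Gaussian noise SD
#' @export
noise_std <- function(sigma_rel, x) {
  if (!is.numeric(sigma_rel) || sigma_rel < 0 || !is.numeric(x) || x < 0) {
    stop_invalid("sigma_rel and x must be non-negative")
  }
  sigma_rel * x
}

#' Add Gaussian internal noise to an internal representation
#'
#' Independent zero-mean Gaussian noise of standard deviation `sigma_w` is
#' added to every entry; the result is flagged noisy (entries may be
#' negative).
#'
#' @param ir an `internal_representation`
#' @param sigma_w noise SD (>= 0)
#' @param seed integer seed (`NULL` uses the current RNG stream)
#' @return the noisy `internal_representation`
#' @export
add_noise <- function(ir, sigma_w, seed = NULL) {
  if (sigma_w < 0) stop_invalid("sigma_w must be >= 0")
  if (sigma_w > 0) {
    noise <- if (is.null(seed)) {
      rnorm(length(ir$values), 0, sigma_w)
    } else {
      with_seed(seed, rnorm(length(ir$values), 0, sigma_w))
    }
    ir$values <- ir$values + noise
    ir$noisy <- TRUE
  }
  ir
}

#' Per-band correlation scores of the three intervals against the template
#'
#' For interval `i` and band `b`:
#' `z[b, i] = corr(NIR_i[b, ] - IR(R)[b, ], S[b, ])`, with `corr` either
#' the zero-lag Pearson correlation (default; a zero-variance template or
#' difference row scores 0) or the raw dot product.
#'
#' @param trial_nirs list of three noisy `internal_representation`s
#' @param ir_r the clean reference `internal_representation`
#' @param template a `template`
#' @param normalization `"pearson"` or `"dot"`
#' @return bands x 3 score matrix
#' @export
band_scores <- function(trial_nirs, ir_r, template,
                        normalization = c("pearson", "dot")) {
  normalization <- match.arg(normalization)
  s <- template$values
  if (!identical(dim(ir_r$values), dim(s))) {
    stop_invalid("shape mismatch between reference IR and template")
  }
  n_bands <- nrow(s)
  z <- matrix(0, nrow = n_bands, ncol = 3)
  for (i in 1:3) {
    d <- trial_nirs[[i]]$values - ir_r$values
    if (!identical(dim(d), dim(s))) {
      stop_invalid("shape mismatch between interval IR and template")
    }
    if (normalization == "dot") {
      z[, i] <- rowSums(d * s)
    } else {
      for (b in seq_len(n_bands)) {
        sb <- s[b, ] - mean(s[b, ])
        db <- d[b, ] - mean(d[b, ])
        denom <- sqrt(sum(sb^2) * sum(db^2))
        z[b, i] <- if (denom > 0) sum(sb * db) / denom else 0
      }
    }
  }
  z
}

#' Temperature-parameterised softmax
#'
#' `p_i = exp(z_i / T) / sum_j exp(z_j / T)`, computed with
#' max-subtraction so no finite score vector can overflow. The temperature
#' controls the sharpness of the distribution: as T tends to 0 the output
#' approaches the argmax indicator, as T grows it approaches uniform.
#'
#' @param z finite score vector
#' @param temperature T > 0
#' @return probability vector summing to 1
#' @export
softmax <- function(z, temperature) {
  if (!is.numeric(temperature) || length(temperature) != 1 || temperature <= 0) {
    stop_invalid("temperature must be a single value > 0")
  }
  if (any(!is.finite(z))) stop_invalid("scores must be finite")
  w <- z / temperature
  w <- w - max(w)
  e <- exp(w)
  e / sum(e)
}

#' Trial probability from per-band interval probabilities
#'
#' The probability assigned to the odd (RT) interval, averaged (unweighted)
#' over the included critical bands.
#'
#' @param band_probs bands x 3 matrix; each row sums to 1
#' @param odd_index position (1-3) of the RT interval
#' @param include logical vector of bands to include (default all)
#' @return scalar trial probability
#' @export
trial_probability <- function(band_probs, odd_index,
                              include = rep(TRUE, nrow(band_probs))) {
  if (!any(include)) stop_state("no critical bands included")
  mean(band_probs[include, odd_index])
}

#' Legacy winner-take-all decision
#'
#' The interval containing the single largest score across all bands and
#' intervals is chosen; exact ties are broken uniformly at random.
#'
#' @param band_scores bands x 3 finite score matrix
#' @param odd_index position (1-3) of the RT interval
#' @param seed integer seed for tie-breaking (`NULL` uses the current
#'   stream)
#' @return 1 if the chosen interval is the odd one, else 0
#' @export
argmax_decision <- function(band_scores, odd_index, seed = NULL) {
  if (any(!is.finite(band_scores))) stop_invalid("scores must be finite")
  hit <- which(band_scores == max(band_scores), arr.ind = TRUE)
  cols <- hit[, 2]
  chosen <- if (length(cols) == 1) {
    cols
  } else if (is.null(seed)) {
    cols[sample.int(length(cols), 1L)]
  } else {
    with_seed(seed, cols[sample.int(length(cols), 1L)])
  }
  as.integer(chosen == odd_index)
}
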