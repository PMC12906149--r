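# Orchestration of full simulated 3AFC experiments: one psychometric point
# per stimulus intensity, one curve per sweep. All randomness flows from
# the config's master seed through substreams keyed by
# (intensity, trial, interval, stage), so any component can be re-run in
# isolation and points do not depend on their position in the sweep.

paradigm_stimuli <- function(paradigm, intensity, level_db = 65,
                             sample_rate = 44100) {
  if (paradigm == "masker_probe") {
    reference <- synthesize_masker_probe(0, include_probe = FALSE,
                                         sample_rate = sample_rate)
    test <- synthesize_masker_probe(intensity, include_probe = TRUE,
                                    sample_rate = sample_rate)
  } else if (paradigm == "amplitude_modulation") {
    reference <- synthesize_am(0, is_modulated = FALSE,
                               sample_rate = sample_rate)
    test <- synthesize_am(intensity, is_modulated = TRUE,
                          sample_rate = sample_rate)
  } else {
    stop_invalid("unknown paradigm: ", paradigm)
  }
  calibrate_pair(reference, test, target_db = level_db)
}

clean_ir_once <- function(frontend, stimulus, config, seed) {
  sts <- simulate_frontend(frontend, stimulus, seed)
  validate_spike_train_set(sts)
  forward_masking_stage(
    build_ir(sts, smoothing = config$smoothing),
    config$fms
  )
}

# Memory representations are averaged over `memory_reps` independent
# frontend realisations: the listener's stored reference and template are
# built up over repeated presentations, so their spike noise is suppressed
# relative to the single-presentation trial intervals.
clean_ir <- function(frontend, stimulus, config, seed) {
  reps <- max(1L, config$memory_reps)
  ir <- clean_ir_once(frontend, stimulus, config, derive_seed(seed, 1))
  if (reps > 1) {
    acc <- ir$values
    for (j in 2:reps) {
      acc <- acc + clean_ir_once(frontend, stimulus, config,
                                 derive_seed(seed, j))$values
    }
    ir$values <- acc / reps
  }
  ir
}

band_inclusion_mask <- function(config, template) {
  if (config$band_inclusion == "all") {
    rep(TRUE, nrow(template$values))
  } else {
    energy <- rowSums(template$values^2)
    mask <- energy >= config$theta * max(energy)
    if (!any(mask)) mask[which.max(energy)] <- TRUE
    mask
  }
}

# Shared per-curve state: one clean reference IR, one noise scale, and
# (under RT_max memory) one template formed from the highest intensity in
# the sweep, mirroring the single IR(R) and S_max boxes of the pipeline.
curve_context <- function(config, frontend, paradigm, rt_max_intensity,
                          level_db = 65, sample_rate = 44100) {
  stim_max <- paradigm_stimuli(paradigm, rt_max_intensity, level_db,
                               sample_rate)
  ir_r <- clean_ir(frontend, stim_max$reference, config,
                   derive_seed(config$seed, "clean", "R", paradigm))
  x <- ir_std(ir_r)
  sigma_w <- noise_std(config$sigma_rel, x)
  ir_rtmax <- clean_ir(frontend, stim_max$test, config,
                       derive_seed(config$seed, "clean", "RTmax", paradigm))
  template <- make_template(ir_rtmax, ir_r)
  list(
    reference = stim_max$reference,
    ir_r = ir_r, x = x, sigma_w = sigma_w,
    rt_max_intensity = rt_max_intensity,
    template = template,
    include = band_inclusion_mask(config, template),
    level_db = level_db, sample_rate = sample_rate
  )
}

#' Simulate one psychometric point
#'
#' Runs `n_trials` 3AFC trials at a single stimulus intensity: synthesizes
#' and calibrates the reference and test stimuli, simulates fresh frontend
#' spike trains per interval per trial, builds internal representations,
#' applies the forward-masking stage, forms the auditory-memory template
#' (from the sweep's highest intensity under `memory_mode = "RT_max"`, or
#' from the presented RT interval under `"RT"`), adds relative internal
#' noise, correlates per critical band, and decides per the configured
#' rule. Under `softmax_mean`, `p_correct` is the mean over trials of the
#' per-trial softmax probability assigned to the odd interval; under
#' `argmax_legacy`, the mean of 0/1 correctness indicators.
#'
#' @param config a [detection_config()]
#' @param frontend a frontend object (see [simulate_frontend()])
#' @param paradigm `"masker_probe"` or `"amplitude_modulation"`
#' @param intensity probe level in dB re masker, or AM depth in `[0, 1]`
#' @param rt_max_intensity intensity of the memory stimulus RT_max
#'   (defaults to `intensity`; [run_curve()] passes the sweep maximum)
#' @param level_db calibrated reference level in dB (default 65)
#' @param sample_rate stimulus sample rate in Hz
#' @param context internal: precomputed per-curve state
#' @return a `psychometric_point`: list with `intensity`, `p_correct`,
#'   `se` (Monte Carlo standard error), `n_trials`
#' @export
run_point <- function(config, frontend, paradigm, intensity,
                      rt_max_intensity = intensity, level_db = 65,
                      sample_rate = 44100, context = NULL) {
  if (is.null(context)) {
    context <- curve_context(config, frontend, paradigm, rt_max_intensity,
                             level_db, sample_rate)
  }
  stim <- paradigm_stimuli(paradigm, intensity, context$level_db,
                           context$sample_rate)
  reference <- stim$reference
  test <- stim$test
  if (config$memory_mode == "RT") {
    # Legacy memory: the template is formed from the presented stimulus
    # itself, i.e. an independently computed clean IR at the trial's
    # intensity, rather than from the sweep's highest intensity.
    ir_rt <- clean_ir(frontend, test, config,
                      derive_seed(config$seed, "clean", "RT", intensity))
    template <- make_template(ir_rt, context$ir_r)
    include <- band_inclusion_mask(config, template)
  } else {
    template <- context$template
    include <- context$include
  }
  outcomes <- numeric(config$n_trials)
  for (tr in seq_len(config$n_trials)) {
    odd <- with_seed(derive_seed(config$seed, intensity, tr, "odd"),
                     sample.int(3L, 1L))
    nirs <- vector("list", 3L)
    for (i in 1:3) {
      s <- if (i == odd) test else reference
      sts <- simulate_frontend(
        frontend, s, derive_seed(config$seed, intensity, tr, i, "frontend")
      )
      ir <- forward_masking_stage(
        build_ir(sts, smoothing = config$smoothing), config$fms
      )
      nirs[[i]] <- add_noise(
        ir, context$sigma_w,
        seed = derive_seed(config$seed, intensity, tr, i, "noise")
      )
    }
    z <- band_scores(nirs, context$ir_r, template, config$normalization)
    if (config$decision_rule == "softmax_mean") {
      probs <- t(apply(z, 1, softmax, temperature = config$temperature))
      outcomes[tr] <- trial_probability(probs, odd, include)
    } else {
      outcomes[tr] <- argmax_decision(
        z, odd, seed = derive_seed(config$seed, intensity, tr, "tie")
      )
    }
  }
  structure(
    list(
      intensity = intensity,
      p_correct = mean(outcomes),
      se = stats::sd(outcomes) / sqrt(config$n_trials),
      n_trials = config$n_trials
    ),
    class = "psychometric_point"
  )
}

#' Simulate a full psychometric curve
#'
#' One [run_point()] per intensity, sharing a single clean reference IR,
#' noise scale, and (under RT_max memory) one template built from the
#' sweep's highest intensity. Substreams are keyed by intensity value, not
#' sweep position.
#'
#' @inheritParams run_point
#' @param intensities strictly increasing vector of at least 2 intensities
#' @return a `psychometric_curve`: list with `points` (data.frame:
#'   intensity, p_correct, se, n_trials), `config`, `profile_name`,
#'   `paradigm`
#' @export
run_curve <- function(config, frontend, paradigm, intensities,
                      level_db = 65, sample_rate = 44100) {
  if (length(intensities) < 2 || any(diff(intensities) <= 0)) {
    stop_invalid("intensities must be >= 2 strictly increasing values")
  }
  context <- curve_context(config, frontend, paradigm, max(intensities),
                           level_db, sample_rate)
  pts <- lapply(intensities, function(i) {
    run_point(config, frontend, paradigm, i, context = context)
  })
  new_psychometric_curve(pts, config, frontend, paradigm, level_db,
                         sample_rate)
}

new_psychometric_curve <- function(pts, config, frontend, paradigm,
                                   level_db, sample_rate) {
  profile_name <- if (!is.null(frontend$profile$name)) {
    frontend$profile$name
  } else {
    class(frontend)[1]
  }
  structure(
    list(
      points = data.frame(
        intensity = vapply(pts, `[[`, numeric(1), "intensity"),
        p_correct = vapply(pts, `[[`, numeric(1), "p_correct"),
        se = vapply(pts, `[[`, numeric(1), "se"),
        n_trials = vapply(pts, `[[`, numeric(1), "n_trials")
      ),
      config = config,
      profile_name = profile_name,
      paradigm = paradigm,
      level_db = level_db,
      sample_rate = sample_rate
    ),
    class = "psychometric_curve"
  )
}

#' @export
print.psychometric_curve <- function(x, ...) {
  cat(sprintf(
    "<psychometric_curve> %s / %s, %s + %s, sigma = %g, T = %g\n",
    x$paradigm, x$profile_name, x$config$decision_rule,
    x$config$memory_mode, x$config$sigma_rel, x$config$temperature
  ))
  print(x$points, row.names = FALSE)
  invisible(x)
}

#' Quick-look plot of a psychometric curve
#'
#' @param x a `psychometric_curve`
#' @param ... passed to `plot()`
#' @export
plot.psychometric_curve <- function(x, ...) {
  p <- x$points
  graphics::plot(
    p$intensity, p$p_correct, type = "b", pch = 16, ylim = c(0, 1),
    xlab = if (x$paradigm == "masker_probe") {
      "probe level (dB re masker)"
    } else {
      "modulation depth m"
    },
    ylab = "P(correct)", ...
  )
  graphics::segments(p$intensity, p$p_correct - p$se,
                     p$intensity, p$p_correct + p$se)
  graphics::abline(h = 1 / 3, lty = 2, col = "grey40")
  invisible(x)
}
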