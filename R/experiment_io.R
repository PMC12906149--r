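# Experiment configuration (YAML), curve serialization (CSV + JSON
# sidecar), and logistic summaries of simulated psychometric curves.

default_config_values <- function() {
  list(
    paradigm = "masker_probe",
    profile = list(name = "NH"),
    detection = list(
      sigma = 0.009, temperature = 0.0009, n_trials = 100,
      memory_mode = "RT_max", decision_rule = "softmax_mean", seed = 1,
      band_inclusion = "all", theta = 0.01, normalization = "pearson",
      memory_reps = 10,
      fms = list(mode = "highpass_adaptation", tau = 0.050, k = 0.5),
      smoothing = list(type = "boxcar", width = 5)
    ),
    intensities = NULL, # paradigm default grid when NULL
    level_db = 65,
    sample_rate = 44100,
    log_level = "info"
  )
}

# Default intensity grids: probe level -40..0 dB re masker in 9 steps;
# AM depth 0.01..1 log-spaced in 9 steps.
default_intensities <- function(paradigm) {
  if (paradigm == "masker_probe") {
    seq(-40, 0, length.out = 9)
  } else {
    exp(seq(log(0.01), log(1), length.out = 9))
  }
}

check_known_keys <- function(x, allowed, where) {
  unknown <- setdiff(names(x), allowed)
  if (length(unknown) > 0) {
    stop_invalid("unknown config key(s) in ", where, ": ",
                 paste(unknown, collapse = ", "))
  }
}

#' Validate and default-fill an experiment configuration
#'
#' @param cfg a named list (as parsed from YAML)
#' @return a validated `experiment_config` with all defaults filled
#' @export
validate_config <- function(cfg) {
  defaults <- default_config_values()
  check_known_keys(cfg, names(defaults), "top level")
  if (!is.null(cfg$profile)) {
    check_known_keys(
      cfg$profile,
      c("name", "n_bands", "f_lo", "f_hi", "fibers_per_band", "spont_rate",
        "max_rate", "threshold_db", "slope_db", "floor_db",
        "adaptation_tau", "depression", "refractory", "bin_width"),
      "profile"
    )
  }
  if (!is.null(cfg$detection)) {
    check_known_keys(cfg$detection, names(defaults$detection), "detection")
    if (!is.null(cfg$detection$fms)) {
      check_known_keys(cfg$detection$fms, c("mode", "tau", "k"),
                       "detection$fms")
    }
    if (!is.null(cfg$detection$smoothing)) {
      check_known_keys(cfg$detection$smoothing, c("type", "width"),
                       "detection$smoothing")
    }
  }
  out <- modifyList(defaults, cfg)
  if (!out$paradigm %in% c("masker_probe", "amplitude_modulation")) {
    stop_invalid("paradigm must be masker_probe or amplitude_modulation")
  }
  if (!out$profile$name %in% c("NH", "EH")) {
    stop_invalid("profile name must be NH or EH")
  }
  if (out$detection$decision_rule == "softmax_mean" &&
      out$detection$temperature <= 0) {
    stop_invalid("detection$temperature must be > 0 ",
                 "(softmax requires a positive temperature)")
  }
  if (out$detection$sigma < 0) stop_invalid("detection$sigma must be >= 0")
  if (out$detection$n_trials < 1) stop_invalid("detection$n_trials must be >= 1")
  if (is.null(out$intensities)) {
    out$intensities <- default_intensities(out$paradigm)
  }
  out$intensities <- as.numeric(unlist(out$intensities))
  if (length(out$intensities) < 2 || any(diff(out$intensities) <= 0)) {
    stop_invalid("intensities must be >= 2 strictly increasing values")
  }
  structure(out, class = "experiment_config")
}

#' Load an experiment configuration from YAML
#'
#' Unknown keys are rejected; missing keys receive documented defaults; the
#' result is fully validated before any simulation starts.
#'
#' @param path YAML file path
#' @return an `experiment_config`
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop_invalid("config file not found: ", path)
  validate_config(yaml::read_yaml(path))
}

#' Write an experiment configuration to YAML
#'
#' @param cfg an `experiment_config`
#' @param path output path
#' @return `path`, invisibly
#' @export
dump_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path, precision = 12)
  invisible(path)
}

#' Instantiate the simulation objects described by a configuration
#'
#' @param cfg an `experiment_config`
#' @return list with `detection` ([detection_config()]), `frontend`
#'   ([surrogate_frontend()]), `paradigm`, `intensities`, `level_db`,
#'   `sample_rate`
#' @export
build_experiment <- function(cfg) {
  cfg <- validate_config(unclass(cfg))
  d <- cfg$detection
  det <- detection_config(
    sigma_rel = d$sigma, temperature = d$temperature,
    n_trials = d$n_trials, memory_mode = d$memory_mode,
    decision_rule = d$decision_rule, seed = d$seed,
    band_inclusion = d$band_inclusion, theta = d$theta,
    normalization = d$normalization, memory_reps = d$memory_reps,
    fms = fms_config(mode = d$fms$mode, tau = d$fms$tau, k = d$fms$k),
    smoothing = d$smoothing
  )
  prof_args <- cfg$profile
  profile <- do.call(frontend_profile, prof_args)
  list(
    detection = det,
    frontend = surrogate_frontend(profile),
    paradigm = cfg$paradigm,
    intensities = cfg$intensities,
    level_db = cfg$level_db,
    sample_rate = cfg$sample_rate
  )
}

#' Run the experiment described by a configuration
#'
#' @param cfg an `experiment_config` (or path to a YAML file)
#' @return a `psychometric_curve`
#' @export
run_experiment <- function(cfg) {
  if (is.character(cfg)) cfg <- load_config(cfg)
  ex <- build_experiment(cfg)
  run_curve(ex$detection, ex$frontend, ex$paradigm, ex$intensities,
            level_db = ex$level_db, sample_rate = ex$sample_rate)
}

curve_sidecar_path <- function(path) paste0(sub("\\.csv$", "", path), ".json")

#' Write a psychometric curve to CSV with a JSON sidecar
#'
#' The CSV has exactly the columns `paradigm, profile, decision_rule,
#' memory_mode, sigma, temperature, n_trials, intensity, p_correct, se`;
#' the sidecar (`<path>.json`) records the full detection configuration and
#' master seed, sufficient for bit-exact re-simulation.
#'
#' @param curve a `psychometric_curve`
#' @param path output CSV path
#' @return `path`, invisibly
#' @export
write_curve <- function(curve, path) {
  p <- curve$points
  df <- data.frame(
    paradigm = curve$paradigm,
    profile = curve$profile_name,
    decision_rule = curve$config$decision_rule,
    memory_mode = curve$config$memory_mode,
    sigma = curve$config$sigma_rel,
    temperature = curve$config$temperature,
    n_trials = p$n_trials,
    intensity = p$intensity,
    p_correct = p$p_correct,
    se = p$se
  )
  ok <- tryCatch({
    write.csv(format(df, digits = 15, trim = TRUE, scientific = FALSE),
              path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("cannot write curve to ", path, ": ",
                        conditionMessage(ok))
  cfg <- curve$config
  cfg$fms <- unclass(cfg$fms)
  jsonlite::write_json(
    list(
      paradigm = curve$paradigm, profile = curve$profile_name,
      config = unclass(cfg), seed = curve$config$seed,
      intensities = p$intensity,
      level_db = curve$level_db, sample_rate = curve$sample_rate
    ),
    curve_sidecar_path(path),
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Read a psychometric curve back from CSV
#'
#' @param path CSV written by [write_curve()]
#' @return data.frame with the curve table
#' @export
read_curve <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}

#' Fit a 3AFC logistic function to a psychometric curve
#'
#' Least-squares fit of
#' `p(I) = 1/3 + (a - 1/3) / (1 + exp(-(I - threshold) / s))`
#' with upper asymptote `a` in `(1/3, 1]`, midpoint `threshold`, and scale
#' `s > 0`. The guess rate is fixed at the 3AFC chance level 1/3. The
#' reported `max_slope = (a - 1/3) / (4 s)` is the curve's steepest ascent
#' (probability per intensity unit), the natural summary when both the
#' asymptote and the scale react to the decision temperature. Flat or
#' degenerate curves yield `fit_ok = FALSE` rather than an error.
#'
#' @param curve a `psychometric_curve`, or a data.frame with columns
#'   `intensity` and `p_correct`
#' @return a `curve_fit`: list with `guess_rate` (1/3), `asymptote`,
#'   `lapse` (`1 - asymptote`), `threshold`, `slope` (the scale `s`),
#'   `max_slope`, `fit_ok`
#' @export
fit_logistic <- function(curve) {
  pts <- if (inherits(curve, "psychometric_curve")) curve$points else curve
  if (nrow(pts) < 4) stop_invalid("need at least 4 points to fit")
  I <- pts$intensity
  p <- pts$p_correct
  bad_fit <- function() {
    structure(
      list(guess_rate = 1 / 3, asymptote = NA_real_, lapse = NA_real_,
           threshold = NA_real_, slope = NA_real_, max_slope = NA_real_,
           fit_ok = FALSE),
      class = "curve_fit"
    )
  }
  if (diff(range(p)) < 0.02) return(bad_fit())
  a0 <- min(max(max(p), 0.4), 1)
  th0 <- I[which.min(abs(p - (1 / 3 + a0) / 2))]
  s0 <- diff(range(I)) / 6
  fit <- tryCatch(
    minpack.lm::nlsLM(
      p ~ 1 / 3 + (a - 1 / 3) / (1 + exp(-(I - th) / s)),
      start = list(a = a0, th = th0, s = s0),
      lower = c(1 / 3 + 1e-6, min(I) - diff(range(I)), 1e-9),
      upper = c(1, max(I) + diff(range(I)), diff(range(I)) * 100),
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-14,
                                           ptol = 1e-14)
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) return(bad_fit())
  cf <- coef(fit)
  if (!all(is.finite(cf)) || cf[["a"]] - 1 / 3 < 0.02) return(bad_fit())
  structure(
    list(
      guess_rate = 1 / 3,
      asymptote = cf[["a"]],
      lapse = 1 - cf[["a"]],
      threshold = cf[["th"]],
      slope = cf[["s"]],
      max_slope = (cf[["a"]] - 1 / 3) / (4 * cf[["s"]]),
      fit_ok = TRUE
    ),
    class = "curve_fit"
  )
}

#' @export
print.curve_fit <- function(x, ...) {
  if (!x$fit_ok) {
    cat("<curve_fit> degenerate (fit_ok = FALSE)\n")
  } else {
    cat(sprintf(
      "<curve_fit> asymptote %.3f, threshold %.3g, scale %.3g, max slope %.4g\n",
      x$asymptote, x$threshold, x$slope, x$max_slope
    ))
  }
  invisible(x)
}
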