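#' Stop with an invalid-argument error
#' @noRd
stop_invalid <- function(...) {
  stop(errorCondition(paste0(...), class = c("softafc_invalid_argument", "error")))
}

#' Stop with an invalid-state error
#' @noRd
stop_state <- function(...) {
  stop(errorCondition(paste0(...), class = c("softafc_invalid_state", "error")))
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so package internals never clobber the
#' caller's random stream.
#' @noRd
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' Derive a deterministic substream seed from a master seed and keys
#'
#' Keys may be integers, doubles or strings; doubles are keyed by value (to
#' 1e-9 resolution) so that, e.g., substreams keyed by stimulus intensity do
#' not depend on the position of the intensity in a sweep. FNV-1a style
#' mixing carried out in double precision below 2^31.
#'
#' @param master integer master seed
#' @param ... key components
#' @return an integer seed in `[1, 2^31 - 2]`
#' @export
derive_seed <- function(master, ...) {
  keys <- list(...)
  h <- (as.numeric(master) %% 2147483647) + 1
  mix <- function(h, v) {
    for (b in v) {
      h <- (h * 16777619 + b + 1) %% 2147483647
    }
    h
  }
  for (k in keys) {
    if (is.character(k)) {
      h <- mix(h, as.numeric(utf8ToInt(paste(k, collapse = "\r"))))
    } else {
      v <- as.numeric(k)
      v <- round(v * 1e9) %% 2147483647
      h <- mix(h, abs(v))
    }
  }
  as.integer(h %% 2147483645L + 1)
}

#' Raised-cosine on/off ramp envelope for a tone segment
#' @param n_samples segment length in samples
#' @param n_ramp ramp length in samples (each side)
#' @return multiplicative envelope of length `n_samples`
#' @noRd
raised_cosine_ramp <- function(n_samples, n_ramp) {
  env <- rep(1, n_samples)
  if (n_ramp <= 0) return(env)
  n_ramp <- min(n_ramp, floor(n_samples / 2))
  if (n_ramp < 1) return(env)
  ramp <- 0.5 * (1 - cos(pi * seq(0, 1, length.out = n_ramp)))
  env[seq_len(n_ramp)] <- ramp
  env[seq(n_samples - n_ramp + 1, n_samples)] <- rev(ramp)
  env
}

#' Polynomial rolling hash of a string, as an 8-hex-digit tag (config logging)
#' @noRd
config_hash <- function(s) {
  h <- 5381
  for (b in utf8ToInt(s)) {
    h <- (h * 33 + b) %% 2147483647
  }
  sprintf("%08x", as.integer(h))
}
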