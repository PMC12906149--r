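tiny_cfg <- function(...) {
  validate_config(modifyList(list(
    paradigm = "masker_probe",
    profile = list(name = "EH", n_bands = 4, f_lo = 500, f_hi = 2000),
    detection = list(sigma = 0.05, temperature = 0.5, n_trials = 3,
                     seed = 7, memory_reps = 2),
    intensities = c(-30, -20, -10, 0),
    sample_rate = 16000
  ), list(...)))
}

test_that("config loading fills defaults, rejects bad values and round-trips", {
  minimal <- validate_config(list(
    paradigm = "amplitude_modulation",
    detection = list(sigma = 0.02, temperature = 0.01)
  ))
  expect_equal(minimal$detection$n_trials, 100)
  expect_equal(minimal$detection$memory_mode, "RT_max")
  expect_equal(minimal$profile$name, "NH")
  expect_equal(minimal$level_db, 65)
  expect_length(minimal$intensities, 9)

  expect_error(
    validate_config(list(paradigm = "masker_probe",
                         detection = list(temperature = 0))),
    "temperature"
  )
  expect_error(validate_config(list(paradgym = "masker_probe")), "unknown")
  expect_error(
    validate_config(list(detection = list(sigmaa = 1))),
    "unknown"
  )

  path <- withr::local_tempfile(fileext = ".yaml")
  dump_config(minimal, path)
  reloaded <- load_config(path)
  expect_equal(unclass(reloaded), unclass(minimal))
})

test_that("curve CSV has the documented schema and survives a round trip", {
  cfg <- tiny_cfg()
  curve <- run_experiment(cfg)
  path <- withr::local_tempfile(fileext = ".csv")
  write_curve(curve, path)

  lines <- readLines(path)
  expect_length(lines, nrow(curve$points) + 1)
  expect_equal(
    strsplit(lines[1], ",")[[1]],
    c("paradigm", "profile", "decision_rule", "memory_mode", "sigma",
      "temperature", "n_trials", "intensity", "p_correct", "se")
  )
  back <- read_curve(path)
  expect_equal(back$p_correct, curve$points$p_correct, tolerance = 1e-12)
  expect_equal(back$intensity, curve$points$intensity)

  # the JSON sidecar allows bit-exact re-simulation
  side <- jsonlite::read_json(sub("\\.csv$", ".json", path),
                              simplifyVector = TRUE)
  cfg2 <- validate_config(list(
    paradigm = side$paradigm,
    profile = cfg$profile, # profile overrides live in the experiment config
    detection = list(sigma = side$config$sigma_rel,
                     temperature = side$config$temperature,
                     n_trials = side$config$n_trials,
                     memory_mode = side$config$memory_mode,
                     decision_rule = side$config$decision_rule,
                     seed = side$seed,
                     memory_reps = side$config$memory_reps),
    intensities = side$intensities,
    level_db = side$level_db,
    sample_rate = side$sample_rate
  ))
  curve2 <- run_experiment(cfg2)
  expect_identical(curve2$points$p_correct, curve$points$p_correct)
})

test_that("the 3AFC logistic fit recovers parameters and flags degenerate curves", {
  grid <- seq(-40, 0, length.out = 9)
  p_true <- 1 / 3 + (1 - 1 / 3) / (1 + exp(-(grid - (-20)) / 3))
  fit <- fit_logistic(data.frame(intensity = grid, p_correct = p_true))
  expect_true(fit$fit_ok)
  expect_equal(fit$asymptote, 1, tolerance = 1e-6)
  expect_equal(fit$threshold, -20, tolerance = 1e-6)
  expect_equal(fit$slope, 3, tolerance = 1e-6)

  flat <- fit_logistic(data.frame(intensity = grid, p_correct = rep(1 / 3, 9)))
  expect_false(flat$fit_ok)

  # recovery from binomial noise (n = 100/point): threshold within 2 grid
  # steps of truth in every one of 20 replicates
  step <- diff(grid)[1]
  for (s in 1:20) {
    p_obs <- withr::with_seed(s, rbinom(9, 100, p_true) / 100)
    f <- fit_logistic(data.frame(intensity = grid, p_correct = p_obs))
    expect_true(f$fit_ok)
    expect_lt(abs(f$threshold - (-20)), 2 * abs(step))
  }

  expect_error(fit_logistic(data.frame(intensity = 1:3, p_correct = rep(1, 3))),
               class = "softafc_invalid_argument")
})

test_that("the CLI runs, sweeps, compares memory modes, and rejects bad flags", {
  dir <- withr::local_tempdir()
  cfg_path <- file.path(dir, "exp.yaml")
  dump_config(tiny_cfg(), cfg_path)

  out <- file.path(dir, "curve.csv")
  status <- suppressMessages(
    softafc_cli(c("run", "--config", cfg_path, "--out", out))
  )
  expect_identical(status, 0L)
  expect_true(file.exists(out))
  expect_true(file.exists(file.path(dir, "curve.json")))

  status <- suppressMessages(softafc_cli(c(
    "sweep", "--config", cfg_path, "--out-prefix", file.path(dir, "sw"),
    "--temperatures", "0.2,0.5,1"
  )))
  expect_identical(status, 0L)
  sw <- list.files(dir, pattern = "^sw_.*\\.csv$")
  expect_length(sw, 3)

  status <- suppressMessages(softafc_cli(c(
    "compare-memory", "--config", cfg_path,
    "--out-prefix", file.path(dir, "mem")
  )))
  expect_identical(status, 0L)
  mem <- lapply(c("mem_RT_max.csv", "mem_RT.csv"), function(f) {
    read_curve(file.path(dir, f))
  })
  expect_setequal(vapply(mem, function(m) m$memory_mode[1], character(1)),
                  c("RT_max", "RT"))
  expect_equal(mem[[1]]$sigma, mem[[2]]$sigma)

  expect_identical(suppressMessages(
    softafc_cli(c("run", "--config", cfg_path, "--bogus", "1"))
  ), 1L)
  expect_identical(suppressMessages(softafc_cli(c("frobnicate"))), 1L)

  fit_status <- suppressMessages(capture.output(
    softafc_cli(c("fit", "--curve", out))
  ))
  expect_true(any(grepl("curve_fit", fit_status)))
})

test_that("WAV export writes a valid float32 RIFF file", {
  s <- calibrate_level(synthesize_am(0, FALSE, sample_rate = 8000), 65)
  path <- withr::local_tempfile(fileext = ".wav")
  write_wav(s, path)
  con <- file(path, "rb")
  on.exit(close(con))
  expect_identical(readChar(con, 4), "RIFF")
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  expect_identical(readChar(con, 4), "WAVE")
  expect_identical(readChar(con, 4), "fmt ")
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  fmt <- readBin(con, "integer", 2, 2, endian = "little")
  expect_equal(fmt[1], 3) # IEEE float
  expect_equal(fmt[2], 1) # mono
  expect_equal(readBin(con, "integer", 1, 4, endian = "little"), 8000)
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  invisible(readBin(con, "integer", 2, 2, endian = "little"))
  expect_identical(readChar(con, 4), "data")
  nbytes <- readBin(con, "integer", 1, 4, endian = "little")
  expect_equal(nbytes, 4 * length(s$samples))
  x <- readBin(con, "numeric", length(s$samples), 4, endian = "little")
  expect_equal(x, s$samples, tolerance = 1e-6)
})
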