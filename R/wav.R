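# Minimal RIFF/WAVE writer (IEEE float32, mono) for auditioning or
# debugging synthesized stimuli.

#' Export a stimulus as a float32 WAV file
#'
#' @param stimulus a `stimulus`
#' @param path output .wav path
#' @return `path`, invisibly
#' @export
write_wav <- function(stimulus, path) {
  x <- stimulus$samples
  fs <- as.integer(stimulus$sample_rate)
  con <- file(path, "wb")
  on.exit(close(con))
  data_bytes <- 4L * length(x)
  w16 <- function(v) writeBin(as.integer(v), con, size = 2, endian = "little")
  w32 <- function(v) writeBin(as.integer(v), con, size = 4, endian = "little")
  writeChar("RIFF", con, eos = NULL)
  w32(36L + data_bytes)
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  w32(16L)
  w16(3L)            # IEEE float
  w16(1L)            # mono
  w32(fs)
  w32(fs * 4L)       # byte rate
  w16(4L)            # block align
  w16(32L)           # bits per sample
  writeChar("data", con, eos = NULL)
  w32(data_bytes)
  writeBin(as.numeric(x), con, size = 4, endian = "little")
  invisible(path)
}
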