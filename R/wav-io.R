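# Minimal RIFF/WAVE reader and writer. Mono only; PCM 16/24-bit and IEEE
# float32. Chunk-walks the file so extra chunks (LIST, fact, ...) are fine.

#' Construct a waveform object
#'
#' @param samples Numeric vector of sound-pressure samples (nominally in
#'   \[-1, 1\]).
#' @param sample_rate Sampling rate in Hz.
#' @return A `si_wave` object (list with `samples`, `sample_rate`).
#' @export
si_wave <- function(samples, sample_rate) {
  stopifnot(is.numeric(samples), length(samples) > 0,
            is.numeric(sample_rate), sample_rate > 0)
  structure(list(samples = as.numeric(samples),
                 sample_rate = as.integer(round(sample_rate))),
            class = "si_wave")
}

#' @export
print.si_wave <- function(x, ...) {
  cat(sprintf("<si_wave> %d samples @ %d Hz (%.1f ms)\n",
              length(x$samples), x$sample_rate, wave_duration_ms(x)))
  invisible(x)
}

#' Duration of a waveform in milliseconds
#' @param wave A [si_wave] object.
#' @return Duration in ms (numeric scalar).
#' @export
wave_duration_ms <- function(wave) {
  stopifnot(inherits(wave, "si_wave"))
  length(wave$samples) * 1000 / wave$sample_rate
}

#' Read a mono WAV file
#'
#' Supports PCM 16- and 24-bit and IEEE float32 encodings. Multi-channel
#' files are rejected: the analysis is defined on a single sound-pressure
#' channel.
#'
#' @param path Path to a `.wav` file.
#' @return A [si_wave] with samples scaled to \[-1, 1\] for PCM input.
#' @export
read_wav <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path, call. = FALSE)
  readBin(con, "integer", 1, 4, endian = "little")  # total size, unused
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path, call. = FALSE)

  fmt <- NULL; data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    sz <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt_raw <- readBin(con, "raw", sz)
      fmt <- list(
        audio_format = readBin(fmt_raw[1:2], "integer", 1, 2,
                               signed = FALSE, endian = "little"),
        n_channels   = readBin(fmt_raw[3:4], "integer", 1, 2,
                               signed = FALSE, endian = "little"),
        sample_rate  = readBin(fmt_raw[5:8], "integer", 1, 4,
                               endian = "little"),
        bits         = readBin(fmt_raw[15:16], "integer", 1, 2,
                               signed = FALSE, endian = "little"))
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", sz)
    } else {
      readBin(con, "raw", sz + (sz %% 2L))  # skip (chunks are word-aligned)
      next
    }
    if (sz %% 2L == 1L) readBin(con, "raw", 1)
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) {
    stop("malformed WAV (missing fmt/data chunk): ", path, call. = FALSE)
  }
  if (fmt$n_channels != 1L) {
    stop("only mono WAV supported; got ", fmt$n_channels, " channels",
         call. = FALSE)
  }
  samples <- switch(
    as.character(fmt$audio_format),
    "1" = {  # integer PCM
      if (fmt$bits == 16L) {
        readBin(data_raw, "integer", length(data_raw) / 2, 2,
                signed = TRUE, endian = "little") / 32767
      } else if (fmt$bits == 24L) {
        n <- length(data_raw) / 3
        b <- matrix(as.integer(data_raw), nrow = 3)
        v <- b[1, ] + 256L * b[2, ] + 65536L * b[3, ]
        v <- ifelse(v >= 8388608, v - 16777216, v)
        v / 8388608
      } else {
        stop("unsupported PCM bit depth: ", fmt$bits, call. = FALSE)
      }
    },
    "3" = readBin(data_raw, "double", length(data_raw) / 4, 4,
                  endian = "little"),
    stop("unsupported WAV encoding (format tag ", fmt$audio_format, ")",
         call. = FALSE))
  si_wave(samples, fmt$sample_rate)
}

#' Write a mono WAV file
#'
#' @param wave A [si_wave].
#' @param path Output path.
#' @param bits Bit depth: 16 (PCM, default) or 32 (IEEE float).
#' @return `path`, invisibly.
#' @export
write_wav <- function(wave, path, bits = 16) {
  stopifnot(inherits(wave, "si_wave"), bits %in% c(16, 32))
  n <- length(wave$samples)
  bytes_per <- bits / 8
  data_sz <- n * bytes_per
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + data_sz), con, 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, 4, endian = "little")
  fmt_tag <- if (bits == 16) 1L else 3L
  writeBin(fmt_tag, con, 2, endian = "little")
  writeBin(1L, con, 2, endian = "little")  # mono
  writeBin(as.integer(wave$sample_rate), con, 4, endian = "little")
  writeBin(as.integer(wave$sample_rate * bytes_per), con, 4, endian = "little")
  writeBin(as.integer(bytes_per), con, 2, endian = "little")
  writeBin(as.integer(bits), con, 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_sz), con, 4, endian = "little")
  if (bits == 16) {
    s <- pmax(-1, pmin(1, wave$samples))
    writeBin(as.integer(round(s * 32767)), con, 2, endian = "little")
  } else {
    writeBin(wave$samples, con, 4, endian = "little")
  }
  invisible(path)
}
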