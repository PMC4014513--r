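# Multitaper spectrogram at 1 ms resolution.

.dpss_cache <- new.env(parent = emptyenv())

#' Slepian (DPSS) tapers
#'
#' Discrete prolate spheroidal sequences computed from the symmetric
#' tridiagonal eigenproblem (the classical formulation: diagonal
#' `((n-1-2t)/2)^2 cos(2*pi*W)`, off-diagonal `t(n-t)/2`). Tapers are
#' unit-energy and cached per `(n, nw, k)`.
#'
#' @param n Taper length in samples.
#' @param nw Time-bandwidth product (W = nw/n).
#' @param k Number of tapers (k <= 2*nw is the usual well-concentrated set).
#' @return An `n x k` matrix, one taper per column, `colSums(tapers^2) = 1`.
#' @export
dpss_tapers <- function(n, nw = 1.5, k = 2) {
  stopifnot(n >= 2, nw > 0, k >= 1, k < n)
  key <- paste(n, nw, k, sep = "_")
  hit <- .dpss_cache[[key]]
  if (!is.null(hit)) return(hit)
  w <- nw / n
  t_idx <- 0:(n - 1)
  diag_el <- ((n - 1 - 2 * t_idx) / 2)^2 * cos(2 * pi * w)
  off_el <- (1:(n - 1)) * (n - (1:(n - 1))) / 2
  A <- matrix(0, n, n)
  A[cbind(1:n, 1:n)] <- diag_el
  A[cbind(1:(n - 1), 2:n)] <- off_el
  A[cbind(2:n, 1:(n - 1))] <- off_el
  eg <- eigen(A, symmetric = TRUE)
  tapers <- eg$vectors[, seq_len(k), drop = FALSE]
  tapers <- sweep(tapers, 2, sqrt(colSums(tapers^2)), "/")
  # sign convention: symmetric tapers positive mean; antisymmetric tapers
  # positive initial slope
  for (j in seq_len(k)) {
    s <- sum(tapers[, j])
    if (abs(s) > 1e-8) {
      if (s < 0) tapers[, j] <- -tapers[, j]
    } else if (tapers[2, j] - tapers[1, j] < 0) {
      tapers[, j] <- -tapers[, j]
    }
  }
  .dpss_cache[[key]] <- tapers
  tapers
}

#' Multitaper power spectrogram
#'
#' Computes a Slepian-taper power spectrogram of a mono waveform on a 1 ms
#' frame grid (by default): 9 ms windows advanced in 1 ms steps, averaged
#' over `n_tapers` tapers, restricted to the analysis band. The frame count
#' is `floor((duration_ms - window_ms)/step_ms) + 1`.
#'
#' @param wave A [si_wave].
#' @param config An [si_config] (or argument list); supplies window, step,
#'   band and taper settings.
#' @return An `si_spectrogram`: list with `power` (bins-in-band x frames,
#'   nonnegative), `freq` (Hz, increasing), `power_full`/`freq_full` (full
#'   half-spectrum, used by the cepstral pitch estimate), `frame_times`
#'   (ms, window start times), plus the parameters used.
#' @examples
#' w <- si_wave(sin(2 * pi * 3000 * seq(0, 0.05, by = 1/44100)), 44100)
#' sp <- compute_spectrogram(w)
#' dim(sp$power)
#' @export
compute_spectrogram <- function(wave, config = si_config()) {
  stopifnot(inherits(wave, "si_wave"))
  config <- as_si_config(config)
  fs <- wave$sample_rate
  if (fs < 2 * config$band[2]) {
    stop(sprintf("sample rate %d Hz too low for band up to %g Hz (need >= %g)",
                 fs, config$band[2], 2 * config$band[2]), call. = FALSE)
  }
  dur_ms <- wave_duration_ms(wave)
  if (dur_ms < config$window_ms) {
    stop(sprintf("audio too short: %.2f ms < one %g ms analysis window",
                 dur_ms, config$window_ms), call. = FALSE)
  }
  win_s <- max(2L, as.integer(floor(config$window_ms * fs / 1000)))
  n_frames <- as.integer(floor((dur_ms - config$window_ms) / config$step_ms) + 1)
  starts <- floor((seq_len(n_frames) - 1) * config$step_ms * fs / 1000)  # 0-based
  # twice the next power of two: the extra zero-padding samples the taper
  # mainlobe finely enough that peak heights (hence cepstral goodness) do
  # not scallop as spectral peaks slide across the bin grid
  nfft <- 2L * 2^ceiling(log2(win_s))
  tapers <- dpss_tapers(win_s, config$nw, config$n_tapers)

  idx <- outer(seq_len(win_s), starts, "+")  # win_s x n_frames sample indices
  frames <- matrix(wave$samples[idx], nrow = win_s)
  half <- nfft %/% 2 + 1L
  pow <- matrix(0, half, n_frames)
  pad <- matrix(0, nfft, n_frames)
  for (j in seq_len(config$n_tapers)) {
    pad[seq_len(win_s), ] <- frames * tapers[, j]
    if (nfft > win_s) pad[(win_s + 1):nfft, ] <- 0
    ft <- stats::mvfft(pad)
    pow <- pow + Mod(ft[seq_len(half), , drop = FALSE])^2
  }
  pow <- pow / config$n_tapers
  freq_full <- (seq_len(half) - 1) * fs / nfft
  in_band <- freq_full >= config$band[1] & freq_full <= config$band[2]
  if (!any(in_band)) stop("no frequency bins inside the analysis band",
                          call. = FALSE)
  structure(
    list(power = pow[in_band, , drop = FALSE],
         freq = freq_full[in_band],
         power_full = pow, freq_full = freq_full,
         frame_times = (seq_len(n_frames) - 1) * config$step_ms,
         sample_rate = fs, nfft = nfft, window_samples = win_s,
         config = config),
    class = "si_spectrogram")
}

#' @export
print.si_spectrogram <- function(x, ...) {
  cat(sprintf("<si_spectrogram> %d frames x %d bins (%g-%g Hz), %g ms window\n",
              ncol(x$power), nrow(x$power), min(x$freq), max(x$freq),
              x$config$window_ms))
  invisible(x)
}
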