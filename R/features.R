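# Per-frame spectral features: Wiener entropy, frequency modulation,
# cepstral pitch + goodness, gravity center, spectral width.

#' Wiener entropy track
#'
#' Log-scale spectral flatness: per frame, the log of the ratio of the
#' geometric to the arithmetic mean of the power across bins. Zero for a
#' flat (white) spectrum, increasingly negative for concentrated spectra;
#' floored at `config$entropy_floor` where the geometric mean underflows
#' (e.g. digital silence or any zero bin).
#'
#' @param spec An `si_spectrogram`.
#' @return Numeric vector, one value per frame, all `<= 0`.
#' @export
wiener_entropy <- function(spec) {
  stopifnot(inherits(spec, "si_spectrogram"))
  p <- spec$power
  floor_v <- spec$config$entropy_floor
  am <- colMeans(p)
  gm_log <- colMeans(log(p))            # -Inf when any bin is zero
  ent <- gm_log - log(am)               # log(geometric/arithmetic)
  ent[!is.finite(ent)] <- floor_v
  pmin(pmax(ent, floor_v), 0)
}

#' Spectral gravity center track
#'
#' First moment of the power spectrum over frequency,
#' `sum(b_i * p_i) / sum(p_i)`. Zero-power frames fall back to the
#' midpoint of the analysis band.
#'
#' @inheritParams wiener_entropy
#' @return Numeric vector (Hz), one value per frame.
#' @export
gravity_center <- function(spec) {
  stopifnot(inherits(spec, "si_spectrogram"))
  tot <- colSums(spec$power)
  gc <- as.numeric(crossprod(spec$freq, spec$power)) / tot
  gc[tot <= 0] <- mean(spec$config$band)
  gc
}

#' Spectral width track
#'
#' Square root of the power-weighted second moment of frequency about the
#' gravity center. Zero when all power sits in one bin; zero-power frames
#' fall back to 0.
#'
#' @inheritParams wiener_entropy
#' @return Numeric vector (Hz), nonnegative, one value per frame.
#' @export
spectral_width <- function(spec) {
  stopifnot(inherits(spec, "si_spectrogram"))
  tot <- colSums(spec$power)
  gc <- as.numeric(crossprod(spec$freq, spec$power)) / tot
  m2 <- as.numeric(crossprod(spec$freq^2, spec$power)) / tot - gc^2
  sw <- sqrt(pmax(m2, 0))
  sw[tot <= 0] <- 0
  sw
}

#' Cepstral pitch and pitch goodness tracks
#'
#' The fundamental frequency is estimated per frame as the dominant peak of
#' the cepstrum -- the Fourier transform of the (mean-subtracted) log power
#' spectrum over the analysis band -- searched within the configured
#' fundamental range, with parabolic refinement of the peak quefrency.
#' Pitch goodness is the cepstral power at that peak: large for harmonic
#' stacks, small for noise. Both are invariant to overall amplitude
#' scaling (scaling shifts the log spectrum by a constant, which only
#' affects zero quefrency). Zero-power frames fall back to the midpoint of
#' the pitch search band with goodness 0.
#'
#' @inheritParams wiener_entropy
#' @return A list with numeric vectors `pitch` (Hz) and `pitch_goodness`.
#' @export
pitch_and_goodness <- function(spec) {
  stopifnot(inherits(spec, "si_spectrogram"))
  cfg <- spec$config
  p <- spec$power
  n_frames <- ncol(p)
  nfft <- spec$nfft
  df <- spec$sample_rate / nfft
  # quefrency index q of the padded cepstrum maps to f0 = fs / q
  q_lo <- max(2L, as.integer(ceiling(spec$sample_rate / cfg$pitch_range[2])))
  q_hi <- as.integer(floor(spec$sample_rate / cfg$pitch_range[1]))
  q_hi <- min(q_hi, nfft %/% 2 - 1L)
  fallback <- mean(cfg$pitch_range)
  if (q_lo >= q_hi) {
    return(list(pitch = rep(fallback, n_frames),
                pitch_goodness = rep(0, n_frames)))
  }
  tot <- colSums(p)
  # clamp each frame 80 dB below its peak: without a dynamic-range floor,
  # near-zero bins (log ~ -700) swamp the cepstrum of the log spectrum
  floor_p <- pmax(apply(p, 2, max) * 1e-8, 1e-300)
  lp <- log(pmax(p, rep(floor_p, each = nrow(p))))
  lp <- sweep(lp, 2, colMeans(lp))          # remove DC of the log spectrum
  padded <- matrix(0, nfft, n_frames)
  padded[seq_len(nrow(p)), ] <- lp          # zero-pad to the full FFT grid
  cep <- Mod(stats::mvfft(padded))^2 / nfft
  band <- cep[(q_lo:q_hi) + 1L, , drop = FALSE]
  pk <- max.col(t(band), ties.method = "first")
  q_pk <- q_lo + pk - 1L
  good <- band[cbind(pk, seq_len(n_frames))]
  # parabolic interpolation around the integer peak: refines both the
  # quefrency (pitch) and the peak height (goodness) -- the raw bin value
  # scallops by tens of percent as the true quefrency slides between
  # bins, which would leak artificial variability into the feature
  delta <- rep(0, n_frames)
  inner <- pk > 1 & pk < nrow(band)
  if (any(inner)) {
    i <- which(inner)
    y0 <- band[cbind(pk[i] - 1L, i)]
    y1 <- band[cbind(pk[i], i)]
    y2 <- band[cbind(pk[i] + 1L, i)]
    den <- y0 - 2 * y1 + y2
    d <- ifelse(abs(den) > 0, 0.5 * (y0 - y2) / den, 0)
    d <- pmax(-0.5, pmin(0.5, d))
    delta[i] <- d
    good[i] <- y1 - 0.25 * (y0 - y2) * d
  }
  pitch <- spec$sample_rate / (q_pk + delta)
  pitch <- pmin(pmax(pitch, cfg$pitch_range[1]), cfg$pitch_range[2])
  silent <- tot <= 0
  pitch[silent] <- fallback
  good[silent] <- 0
  list(pitch = pitch, pitch_goodness = good)
}

#' Frequency modulation track
#'
#' The angle between the temporal and spectral derivatives of the log
#' power: per frame, `atan(|dP/dt| / |dP/df|)` where each derivative
#' magnitude is the quadrature sum over frequency bins of finite
#' differences of log power (central differences; one-sided at the first
#' and last frame). Near zero for stationary sounds, large for fast
#' sweeps; 0 on silent frames.
#'
#' @inheritParams wiener_entropy
#' @return Numeric vector of angles in radians, in `[0, pi/2]`.
#' @export
frequency_modulation <- function(spec) {
  stopifnot(inherits(spec, "si_spectrogram"))
  p <- spec$power
  if (ncol(p) < 2) stop("frequency modulation needs at least 2 frames",
                        call. = FALSE)
  # clamp 80 dB below the song peak so empty bins do not dominate the
  # derivatives; a global floor keeps frames comparable over time
  floor_p <- max(p) * 1e-8
  if (floor_p <= 0) floor_p <- 1e-300
  lp <- log(pmax(p, floor_p))
  n <- ncol(lp)
  dt <- lp
  dt[, 2:(n - 1)] <- (lp[, 3:n, drop = FALSE] - lp[, 1:(n - 2), drop = FALSE]) / 2
  dt[, 1] <- lp[, 2] - lp[, 1]
  dt[, n] <- lp[, n] - lp[, n - 1]
  m <- nrow(lp)
  dfq <- lp
  if (m >= 3) {
    dfq[2:(m - 1), ] <- (lp[3:m, , drop = FALSE] - lp[1:(m - 2), , drop = FALSE]) / 2
  }
  dfq[1, ] <- lp[2, ] - lp[1, ]
  dfq[m, ] <- lp[m, ] - lp[m - 1, ]
  num <- sqrt(colSums(dt^2))
  den <- sqrt(colSums(dfq^2))
  fm <- atan2(num, den)
  fm[num == 0 & den == 0] <- 0
  fm[colSums(p) <= 0] <- 0
  fm
}

#' Compute the spectral feature table of a song
#'
#' Runs the whole feature front end: multitaper spectrogram at 1 ms
#' resolution, then all six spectral features per frame. Silent frames
#' (zero total power inside the band) are flagged so downstream users can
#' inspect fallback values.
#'
#' @param wave A [si_wave] (mono audio).
#' @param config An [si_config].
#' @return A tibble with one row per 1 ms frame: `time_ms`, `silent`, and
#'   one column per feature in [SI_FEATURES]. Attributes record the
#'   parameter signature and (un)normalized state.
#' @examples
#' w <- si_wave(sin(2 * pi * 700 * seq(0, 0.06, by = 1/44100)), 44100)
#' ft <- song_features(w)
#' head(ft)
#' @export
song_features <- function(wave, config = si_config()) {
  config <- as_si_config(config)
  spec <- compute_spectrogram(wave, config)
  pg <- pitch_and_goodness(spec)
  out <- tibble::tibble(
    time_ms = spec$frame_times,
    silent = colSums(spec$power) <= 0,
    wiener_entropy = wiener_entropy(spec),
    fm = frequency_modulation(spec),
    pitch = pg$pitch,
    pitch_goodness = pg$pitch_goodness,
    gravity_center = gravity_center(spec),
    spectral_width = spectral_width(spec))
  attr(out, "si_params") <- param_signature(config)
  attr(out, "si_normalized") <- FALSE
  out
}

#' Write a feature table with a JSON parameter sidecar
#'
#' @param features A feature tibble from [song_features()].
#' @param path CSV output path; a `.json` sidecar with the analysis
#'   parameters is written next to it.
#' @param config The [si_config] used (stored in the sidecar).
#' @return `path`, invisibly.
#' @export
write_features <- function(features, path, config = si_config()) {
  config <- as_si_config(config)
  utils::write.csv(as.data.frame(features), path, row.names = FALSE)
  side <- sub("\\.csv$", "", path)
  jsonlite::write_json(
    list(parameters = unclass(config),
         signature = param_signature(config),
         normalized = isTRUE(attr(features, "si_normalized"))),
    paste0(side, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
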