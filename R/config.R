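#' The six spectral features
#'
#' Names of the per-frame spectral features the package computes, in
#' canonical order.
#'
#' @format Character vector of length six.
#' @export
SI_FEATURES <- c("wiener_entropy", "fm", "pitch", "pitch_goodness",
                 "gravity_center", "spectral_width")

#' Analysis configuration
#'
#' Bundles every tunable parameter of the pipeline. The defaults are the
#' published operating point of the method: 9 ms analysis windows advanced
#' in 1 ms steps, a 500--8600 Hz analysis band, a two-taper Slepian
#' (DPSS) spectral estimate with time-bandwidth product 1.5, a 0.05
#' probability threshold for regions of similarity, 50 ms of sequence
#' slack, and the feature subset \{gravity center, spectral width, pitch
#' goodness, Wiener entropy\} found to maximize self/cross contrast.
#'
#' @param window_ms Analysis window length in milliseconds.
#' @param step_ms Window step (frame spacing) in milliseconds.
#' @param band Numeric length-2, analysis band in Hz.
#' @param nw Time-bandwidth product of the Slepian tapers.
#' @param n_tapers Number of Slepian tapers.
#' @param alpha Probability threshold defining regions of similarity:
#'   a matrix bin belongs to a region of similarity when the calibrated
#'   probability of its smoothed distance, `P(L) < alpha`.
#' @param slack_ms Extra width (ms) of the sequence-scoring area of
#'   interest, allowing flexible alignment of the next syllable.
#' @param features Character vector, subset of [SI_FEATURES] used for
#'   distance computation.
#' @param scale_method Feature normalization scale: `"mad"` (median
#'   absolute difference from the mean, the default) or `"sd"`.
#' @param pitch_range Numeric length-2, fundamental-frequency search band
#'   in Hz for the cepstral pitch estimate.
#' @param smooth_half_ms Half-width (ms) of the diagonal RMS smoothing
#'   window applied to the distance matrix.
#' @param entropy_floor Lower bound for Wiener entropy on (near-)silent
#'   frames, where the geometric mean underflows.
#'
#' @return An object of class `si_config` (a named list).
#' @examples
#' cfg <- si_config()
#' cfg$features
#' @export
si_config <- function(window_ms = 9, step_ms = 1, band = c(500, 8600),
                      nw = 1.5, n_tapers = 2, alpha = 0.05, slack_ms = 50,
                      features = c("gravity_center", "spectral_width",
                                   "pitch_goodness", "wiener_entropy"),
                      scale_method = c("mad", "sd"),
                      pitch_range = c(400, 3000),
                      smooth_half_ms = 25, entropy_floor = -10) {
  scale_method <- match.arg(scale_method)
  stopifnot(window_ms > 0, step_ms > 0, length(band) == 2, band[1] < band[2],
            nw > 0, n_tapers >= 1, alpha > 0, alpha < 1, slack_ms >= 0,
            length(pitch_range) == 2, pitch_range[1] < pitch_range[2],
            smooth_half_ms >= 0, entropy_floor < 0)
  bad <- setdiff(features, SI_FEATURES)
  if (length(bad) > 0) {
    stop("unknown feature name(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (length(features) < 1) stop("at least one feature required", call. = FALSE)
  structure(
    list(window_ms = window_ms, step_ms = step_ms, band = band, nw = nw,
         n_tapers = n_tapers, alpha = alpha, slack_ms = slack_ms,
         features = sort(unique(features)), scale_method = scale_method,
         pitch_range = pitch_range, smooth_half_ms = smooth_half_ms,
         entropy_floor = entropy_floor),
    class = "si_config")
}

#' @export
print.si_config <- function(x, ...) {
  cat("<si_config>\n")
  cat(sprintf("  window %g ms, step %g ms, band %g-%g Hz, NW %g, %d tapers\n",
              x$window_ms, x$step_ms, x$band[1], x$band[2], x$nw, x$n_tapers))
  cat(sprintf("  alpha %g, slack %g ms, smoothing +/-%g ms, scale '%s'\n",
              x$alpha, x$slack_ms, x$smooth_half_ms, x$scale_method))
  cat("  features:", paste(x$features, collapse = ", "), "\n")
  invisible(x)
}

as_si_config <- function(config) {
  if (is.null(config)) return(si_config())
  if (inherits(config, "si_config")) return(config)
  if (is.list(config)) return(do.call(si_config, config))
  stop("`config` must be an si_config or a list of arguments", call. = FALSE)
}

# Canonical parameter signature: everything that affects feature values and
# distance distributions. A reference built under one signature must not be
# applied to matrices computed under another.
param_signature <- function(config) {
  config <- as_si_config(config)
  paste0(
    "w", format(config$window_ms), ";s", format(config$step_ms),
    ";b", format(config$band[1]), "-", format(config$band[2]),
    ";nw", format(config$nw), ";k", config$n_tapers,
    ";pr", format(config$pitch_range[1]), "-", format(config$pitch_range[2]),
    ";sm", format(config$smooth_half_ms),
    ";ef", format(config$entropy_floor),
    ";sc", config$scale_method,
    ";f=", paste(config$features, collapse = "+"))
}

# Run code with a private RNG stream; the caller's .Random.seed is restored.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
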