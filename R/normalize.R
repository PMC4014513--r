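# Feature normalization against a reference corpus.

#' Fit feature normalization statistics from a corpus
#'
#' Pools each feature across all songs of a reference corpus and computes a
#' center (pooled mean) and scale. The default scale is the median absolute
#' difference from the mean ("mad"), so that after normalization the
#' absolute median difference of each feature from its mean is one; `"sd"`
#' uses the pooled standard deviation instead.
#'
#' @param corpus A list of feature tibbles from [song_features()], or a
#'   single feature tibble.
#' @param config An [si_config]; `config$scale_method` selects the scale
#'   convention and `config$features` has no effect here (all six features
#'   are fitted).
#' @return A tibble with columns `feature`, `center`, `scale`, carrying the
#'   scale convention as an attribute.
#' @examples
#' w <- si_wave(rnorm(4410), 44100)
#' stats <- fit_normalization(list(song_features(w)))
#' @export
fit_normalization <- function(corpus, config = si_config()) {
  config <- as_si_config(config)
  if (is.data.frame(corpus)) corpus <- list(corpus)
  if (length(corpus) == 0) stop("empty corpus", call. = FALSE)
  pooled <- dplyr::bind_rows(lapply(corpus, function(x) {
    x[, SI_FEATURES, drop = FALSE]
  }))
  if (nrow(pooled) < 2) stop("need at least 2 pooled frames", call. = FALSE)
  stats <- purrr::map_dfr(SI_FEATURES, function(f) {
    v <- pooled[[f]]
    ctr <- mean(v)
    scl <- switch(config$scale_method,
                  mad = stats::median(abs(v - ctr)),
                  sd = stats::sd(v))
    tibble::tibble(feature = f, center = ctr, scale = scl)
  })
  degenerate <- stats$feature[stats$scale <= 0 | !is.finite(stats$scale)]
  if (length(degenerate) > 0) {
    stop("zero/degenerate normalization scale for feature(s): ",
         paste(degenerate, collapse = ", "), call. = FALSE)
  }
  attr(stats, "scale_method") <- config$scale_method
  stats
}

#' Normalize a feature table
#'
#' Applies `(value - center)/scale` per feature, using statistics fitted
#' from a reference corpus with [fit_normalization()].
#'
#' @param features A feature tibble from [song_features()].
#' @param stats A statistics tibble from [fit_normalization()].
#' @return The normalized feature tibble (normalized flag set).
#' @export
normalize_features <- function(features, stats) {
  stopifnot(is.data.frame(features), is.data.frame(stats),
            all(c("feature", "center", "scale") %in% names(stats)))
  if (isTRUE(attr(features, "si_normalized"))) {
    stop("features are already normalized", call. = FALSE)
  }
  if (any(stats$scale <= 0)) {
    stop("zero normalization scale for feature(s): ",
         paste(stats$feature[stats$scale <= 0], collapse = ", "),
         call. = FALSE)
  }
  out <- features
  for (i in seq_len(nrow(stats))) {
    f <- stats$feature[i]
    if (!f %in% names(out)) next
    out[[f]] <- (out[[f]] - stats$center[i]) / stats$scale[i]
  }
  attr(out, "si_params") <- attr(features, "si_params")
  attr(out, "si_normalized") <- TRUE
  attr(out, "si_stats_sig") <- stats_signature(stats)
  out
}

#' Undo feature normalization
#'
#' @inheritParams normalize_features
#' @return The raw-scale feature tibble.
#' @export
denormalize_features <- function(features, stats) {
  stopifnot(isTRUE(attr(features, "si_normalized")))
  out <- features
  for (i in seq_len(nrow(stats))) {
    f <- stats$feature[i]
    if (!f %in% names(out)) next
    out[[f]] <- out[[f]] * stats$scale[i] + stats$center[i]
  }
  attr(out, "si_params") <- attr(features, "si_params")
  attr(out, "si_normalized") <- FALSE
  attr(out, "si_stats_sig") <- NULL
  out
}

stats_signature <- function(stats) {
  paste(sprintf("%s:%.12g:%.12g", stats$feature, stats$center, stats$scale),
        collapse = ";")
}

# Extract the active feature columns of a normalized feature table as a
# frames x features matrix, checking compatibility.
feature_matrix <- function(features, feature_names) {
  if (!isTRUE(attr(features, "si_normalized"))) {
    stop("features must be normalized before distance computation",
         call. = FALSE)
  }
  missing_f <- setdiff(feature_names, names(features))
  if (length(missing_f) > 0) {
    stop("feature(s) absent from table: ", paste(missing_f, collapse = ", "),
         call. = FALSE)
  }
  as.matrix(features[, feature_names, drop = FALSE])
}
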