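# Empirical calibration of distances against unrelated-song comparisons.
# Pooled D and L entries from all cross-source pairs are compressed to
# 1001-point quantile grids; probabilities are linear interpolations of
# the empirical cumulative distribution.

REF_GRID_POINTS <- 1001L

new_reference <- function(values_D, values_L, params, stats, provenance,
                          sample_D = NULL, sample_L = NULL) {
  probs <- seq(0, 1, length.out = REF_GRID_POINTS)
  structure(
    list(probs = probs,
         sample_D = sample_D, sample_L = sample_L,
         quantiles_D = unname(stats::quantile(values_D, probs, names = FALSE)),
         quantiles_L = unname(stats::quantile(values_L, probs, names = FALSE)),
         n_values_D = length(values_D), n_values_L = length(values_L),
         params = params, stats = stats, provenance = provenance),
    class = "si_reference")
}

#' Build reference distance distributions from an unrelated-song corpus
#'
#' Computes the raw (D) and diagonally smoothed (L) distance matrices for
#' every cross-source pair of songs in the corpus, pools all their
#' entries, and stores the empirical cumulative distributions as quantile
#' grids. Feature normalization statistics are fitted from the same corpus
#' and carried with the reference, so tutor and pupil features are always
#' normalized consistently with the null.
#'
#' @param corpus A named list mapping a source (bird) id to a list of raw
#'   feature tibbles ([song_features()] output) for that source, or a
#'   plain list of feature tibbles with `source_ids` given separately.
#' @param config An [si_config].
#' @param source_ids Optional character vector parallel to `corpus` when
#'   `corpus` is a flat list of feature tibbles.
#' @param max_pool Cap on pooled values per matrix type (default 5e6);
#'   when the pool exceeds it, a deterministic evenly spaced subsample is
#'   used before the quantile grid is computed. The grid stores 1001
#'   quantiles, so the cap costs no practical resolution.
#' @param keep_sample If positive, retain this many of the pooled D and L
#'   values (deterministic evenly spaced subsample) in the reference as
#'   `sample_D`/`sample_L`, e.g. for calibration diagnostics.
#' @return An `si_reference` object.
#' @export
build_reference <- function(corpus, config = si_config(), source_ids = NULL,
                            max_pool = 5e6, keep_sample = 0) {
  config <- as_si_config(config)
  if (!is.null(source_ids)) {
    stopifnot(length(source_ids) == length(corpus))
    flat <- corpus
    ids <- as.character(source_ids)
  } else {
    stopifnot(is.list(corpus), !is.null(names(corpus)))
    flat <- unlist(lapply(corpus, function(x) {
      if (is.data.frame(x)) list(x) else x
    }), recursive = FALSE)
    ids <- rep(names(corpus), vapply(corpus, function(x) {
      if (is.data.frame(x)) 1L else length(x)
    }, 0L))
  }
  if (length(unique(ids)) < 2) {
    stop("reference corpus needs songs from at least 2 distinct sources ",
         "(self-comparisons would bias the null)", call. = FALSE)
  }
  stats <- fit_normalization(flat, config)
  norm <- lapply(flat, normalize_features, stats = stats)

  pairs <- utils::combn(length(flat), 2)
  cross <- pairs[, ids[pairs[1, ]] != ids[pairs[2, ]], drop = FALSE]
  pool_D <- vector("list", ncol(cross))
  pool_L <- vector("list", ncol(cross))
  for (p in seq_len(ncol(cross))) {
    D <- distance_matrix(norm[[cross[1, p]]], norm[[cross[2, p]]], config)
    L <- local_distance_matrix(D, config)
    pool_D[[p]] <- as.numeric(D)
    pool_L[[p]] <- as.numeric(L)
  }
  vD <- unlist(pool_D); vL <- unlist(pool_L)
  if (is.finite(max_pool)) {
    if (length(vD) > max_pool) {
      vD <- vD[round(seq(1, length(vD), length.out = max_pool))]
    }
    if (length(vL) > max_pool) {
      vL <- vL[round(seq(1, length(vL), length.out = max_pool))]
    }
  }
  sub_sample <- function(v, n) {
    if (n <= 0 || length(v) <= n) return(if (n > 0) v else NULL)
    v[round(seq(1, length(v), length.out = n))]
  }
  new_reference(
    vD, vL, params = param_signature(config), stats = stats,
    provenance = list(n_sources = length(unique(ids)),
                      n_songs = length(flat),
                      n_cross_pairs = ncol(cross),
                      sources = sort(unique(ids))),
    sample_D = sub_sample(vD, keep_sample),
    sample_L = sub_sample(vL, keep_sample))
}

#' Convert distances to null probabilities
#'
#' Evaluates `P(reference distance < value)` by linear interpolation of
#' the stored quantile grid: 0 below the reference minimum, 1 above the
#' maximum.
#'
#' @param ref An `si_reference`.
#' @param which `"D"` (raw distances) or `"L"` (smoothed distances).
#' @param value Numeric vector or matrix of distances.
#' @return Probabilities in \[0, 1\], same shape as `value`.
#' @export
probability_of <- function(ref, which = c("D", "L"), value) {
  stopifnot(inherits(ref, "si_reference"))
  which <- match.arg(which)
  q <- if (which == "D") ref$quantiles_D else ref$quantiles_L
  p <- stats::approx(q, ref$probs, xout = as.numeric(value), rule = 2,
                     ties = max)$y
  p <- pmin(pmax(p, 0), 1)
  if (is.matrix(value)) p <- matrix(p, nrow(value), ncol(value))
  p
}

#' @export
print.si_reference <- function(x, ...) {
  cat("<si_reference>\n")
  cat(sprintf("  %d D values, %d L values from %d cross-source pairs (%d sources)\n",
              x$n_values_D, x$n_values_L, x$provenance$n_cross_pairs,
              x$provenance$n_sources))
  cat("  params:", x$params, "\n")
  invisible(x)
}

#' @method glance si_reference
#' @export
glance.si_reference <- function(x, ...) {
  tibble::tibble(n_values_D = x$n_values_D, n_values_L = x$n_values_L,
                 n_sources = x$provenance$n_sources,
                 n_cross_pairs = x$provenance$n_cross_pairs,
                 median_D = x$quantiles_D[(REF_GRID_POINTS + 1L) %/% 2L],
                 median_L = x$quantiles_L[(REF_GRID_POINTS + 1L) %/% 2L])
}

#' Serialize a reference to JSON
#' @param ref An `si_reference`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_reference <- function(ref, path) {
  stopifnot(inherits(ref, "si_reference"))
  jsonlite::write_json(
    list(probs = ref$probs, quantiles_D = ref$quantiles_D,
         quantiles_L = ref$quantiles_L, n_values_D = ref$n_values_D,
         n_values_L = ref$n_values_L, params = ref$params,
         stats = as.data.frame(ref$stats),
         scale_method = attr(ref$stats, "scale_method"),
         provenance = ref$provenance),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a reference from JSON
#' @param path Path written by [write_reference()].
#' @return An `si_reference`.
#' @export
read_reference <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  stats <- tibble::as_tibble(j$stats)
  attr(stats, "scale_method") <- j$scale_method
  structure(
    list(probs = j$probs, quantiles_D = j$quantiles_D,
         quantiles_L = j$quantiles_L, n_values_D = j$n_values_D,
         n_values_L = j$n_values_L, params = j$params, stats = stats,
         provenance = j$provenance),
    class = "si_reference")
}

check_reference_params <- function(ref, config) {
  sig <- param_signature(config)
  if (!identical(ref$params, sig)) {
    stop("reference was calibrated under different parameters\n",
         "  reference: ", ref$params, "\n  requested: ", sig, call. = FALSE)
  }
  invisible(TRUE)
}
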