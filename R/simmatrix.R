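# D, L and S matrices for one tutor x pupil comparison. Rows index tutor
# frames (i), columns pupil frames (j), both on the 1 ms frame grid.

#' Euclidean feature distance matrix
#'
#' `D[i, j]` is the Euclidean distance in normalized feature space between
#' tutor frame `i` and pupil frame `j`, over the active feature subset.
#'
#' @param tutor,pupil Normalized feature tibbles (same normalization
#'   statistics, same parameter signature).
#' @param config An [si_config]; `config$features` selects the subset.
#' @return An `M x N` nonnegative matrix (M tutor frames, N pupil frames).
#' @export
distance_matrix <- function(tutor, pupil, config = si_config()) {
  config <- as_si_config(config)
  ts <- attr(tutor, "si_stats_sig"); ps <- attr(pupil, "si_stats_sig")
  if (!identical(ts, ps)) {
    stop("tutor and pupil features were normalized with different statistics",
         call. = FALSE)
  }
  if (!identical(attr(tutor, "si_params"), attr(pupil, "si_params"))) {
    stop("tutor and pupil features were computed under different parameters",
         call. = FALSE)
  }
  Ft <- feature_matrix(tutor, config$features)
  Fp <- feature_matrix(pupil, config$features)
  d2 <- outer(rowSums(Ft^2), rowSums(Fp^2), "+") - 2 * tcrossprod(Ft, Fp)
  sqrt(pmax(d2, 0))
}

#' Diagonal RMS smoothed distance matrix
#'
#' `L[i, j]` is the RMS of `D` along the diagonal through `(i, j)`,
#' covering `smooth_half_ms` on either side (51 cells at the default 25 ms
#' and 1 ms framing). Windows are truncated at matrix borders: the RMS is
#' taken over in-bounds cells only, avoiding zero-padding bias at song
#' edges.
#'
#' @param D A distance matrix from [distance_matrix()].
#' @param config An [si_config].
#' @return A matrix of the same shape as `D`.
#' @export
local_distance_matrix <- function(D, config = si_config()) {
  config <- as_si_config(config)
  h <- as.integer(round(config$smooth_half_ms / config$step_ms))
  if (h == 0) return(D)
  M <- nrow(D); N <- ncol(D)
  D2 <- D^2
  num <- matrix(0, M, N)
  for (t in -h:h) {
    r0 <- max(1, 1 - t); r1 <- min(M, M - t)
    c0 <- max(1, 1 - t); c1 <- min(N, N - t)
    if (r0 > r1 || c0 > c1) next  # window reaches past a small matrix
    ri <- r0:r1; ci <- c0:c1
    num[ri, ci] <- num[ri, ci] + D2[ri + t, ci + t, drop = FALSE]
  }
  cnt <- outer(pmin(seq_len(M) - 1, h), pmin(seq_len(N) - 1, h), pmin) +
    outer(pmin(M - seq_len(M), h), pmin(N - seq_len(N), h), pmin) + 1
  sqrt(num / cnt)
}

#' Calibrated similarity matrix
#'
#' Converts distances to similarities via the reference null: bins where
#' `P(L) < alpha` (a distance this small would arise between unrelated
#' songs with probability below `alpha`) form regions of similarity; in
#' those bins `S = 1 - P(D)`, elsewhere `S = 0`. The inequality is
#' strict, so `P(L)` exactly at `alpha` is outside the region.
#'
#' @param D,L Matrices from [distance_matrix()] and
#'   [local_distance_matrix()].
#' @param ref An `si_reference` whose parameter signature matches
#'   `config`.
#' @param config An [si_config]; `config$alpha` is the threshold (0.05).
#' @return A matrix in \[0, 1\] of the same shape.
#' @export
similarity_from_distances <- function(D, L, ref, config = si_config()) {
  config <- as_si_config(config)
  check_reference_params(ref, config)
  stopifnot(identical(dim(D), dim(L)))
  P_L <- probability_of(ref, "L", L)
  P_D <- probability_of(ref, "D", D)
  S <- 1 - P_D
  S[P_L >= config$alpha] <- 0
  S
}

#' Compute all three matrices for one comparison
#'
#' @param tutor,pupil Normalized feature tibbles.
#' @param ref An `si_reference`.
#' @param config An [si_config].
#' @return A list with matrices `D`, `L`, `S` (class
#'   `si_similarity_matrices`).
#' @export
similarity_matrices <- function(tutor, pupil, ref, config = si_config()) {
  config <- as_si_config(config)
  D <- distance_matrix(tutor, pupil, config)
  L <- local_distance_matrix(D, config)
  S <- similarity_from_distances(D, L, ref, config)
  structure(list(D = D, L = L, S = S), class = "si_similarity_matrices")
}

#' @export
print.si_similarity_matrices <- function(x, ...) {
  cat(sprintf("<si_similarity_matrices> %d tutor x %d pupil frames; %.1f%% of S nonzero\n",
              nrow(x$S), ncol(x$S), 100 * mean(x$S > 0)))
  invisible(x)
}
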