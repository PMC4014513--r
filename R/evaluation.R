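# Self-/cross-similarity experiments, the contrast metric, and
# feature-subset sweeps.

#' Contrast between self- and cross-similarity
#'
#' `(self - cross) / (self + cross)`: a scale-invariant separation
#' measure, 0 when the two are equal and 1 when cross-similarity
#' vanishes. Undefined (`NA`) when both scores are zero.
#'
#' @param self_score,cross_score Nonnegative similarity scores (vectors
#'   recycle).
#' @return Numeric contrast in \[-1, 1\] (`NA` where `self + cross == 0`).
#' @examples
#' contrast(91, 34)  # 0.456
#' @export
contrast <- function(self_score, cross_score) {
  stopifnot(is.numeric(self_score), is.numeric(cross_score))
  tot <- self_score + cross_score
  out <- (self_score - cross_score) / tot
  out[tot == 0] <- NA_real_
  out
}

# Prepare per-bird normalized motif objects and segment feature tables.
prepare_bird <- function(bird, ref, config, n_segments, seed) {
  config <- as_si_config(config)
  motifs <- lapply(seq_along(bird$motifs), function(j) {
    m <- bird$motifs[[j]]
    ft <- normalize_features(song_features(m$wave, config), ref$stats)
    tutor_motif(ft, m$syllables, source_id = bird$bird_id)
  })
  names(motifs) <- paste0(bird$bird_id, "_motif", seq_along(motifs))
  motif_ms <- stats::median(vapply(motifs, function(m) {
    max(m$syllables$offset_ms)
  }, 0))
  segs <- list()
  for (j in seq_along(bird$bouts)) {
    bout <- bird$bouts[[j]]
    st <- segment_bout(bout$wave, motif_ms, seed = seed + 37L * j)
    for (r in seq_len(nrow(st))) {
      w <- slice_wave(bout$wave, st$start_ms[r], st$end_ms[r])
      segs[[paste0(bird$bird_id, "_b", j, "s", r)]] <-
        normalize_features(song_features(w, config), ref$stats)
    }
  }
  if (length(segs) > n_segments) {
    keep <- with_seed(seed + 1L, sort(sample(seq_along(segs), n_segments)))
    segs <- segs[keep]
  } else if (length(segs) < n_segments) {
    warning(sprintf("%s: only %d segments available (wanted %d); using all",
                    bird$bird_id, length(segs), n_segments), call. = FALSE)
  }
  list(motifs = motifs, segments = segs)
}

#' Self-/cross-similarity experiment over a colony
#'
#' For each bird: the self-similarity is the mean SI of randomly chosen
#' pupil segments of its own bouts against randomly chosen motifs of its
#' own song; the cross-similarity is the mean SI of the same segments
#' against motifs of other, randomly selected birds (without
#' replacement). The contrast summarizes the separation per bird.
#'
#' @param colony An `si_colony` from [make_colony()], or any list with the
#'   same `birds` structure.
#' @param ref An `si_reference`.
#' @param config An [si_config].
#' @param n_segments Segments sampled per bird (published protocol: 25).
#' @param n_self_motifs Own motifs compared against (published: 3).
#' @param n_cross_birds Other birds sampled (published: 10; capped at the
#'   birds available).
#' @param n_cross_motifs Motifs sampled per cross bird.
#' @param seed Integer seed; identical seeds give identical tables.
#' @return A tibble with one row per bird: `bird_id`, `self_acoustic`,
#'   `self_sequence`, `self_si`, the `cross_*` counterparts, and
#'   `contrast` (on SI), `contrast_acoustic`, `contrast_sequence`.
#' @export
self_cross_experiment <- function(colony, ref, config = si_config(),
                                  n_segments = 25, n_self_motifs = 3,
                                  n_cross_birds = 10, n_cross_motifs = 1,
                                  seed = 1L) {
  config <- as_si_config(config)
  birds <- colony$birds
  if (length(birds) < 2) stop("need at least 2 birds", call. = FALSE)
  prep <- lapply(seq_along(birds), function(i) {
    prepare_bird(birds[[i]], ref, config, n_segments, seed + 101L * i)
  })
  names(prep) <- names(birds)
  purrr::map_dfr(seq_along(birds), function(i) {
    id <- names(birds)[i]
    own <- prep[[i]]
    self_motifs <- own$motifs
    if (length(self_motifs) > n_self_motifs) {
      keep <- with_seed(seed + 11L * i,
                        sort(sample(seq_along(self_motifs), n_self_motifs)))
      self_motifs <- self_motifs[keep]
    }
    self_tab <- batch_compare(self_motifs, own$segments, ref, config)
    others <- setdiff(seq_along(birds), i)
    if (length(others) > n_cross_birds) {
      others <- with_seed(seed + 13L * i,
                          sort(sample(others, n_cross_birds)))
    }
    cross_motifs <- unlist(lapply(others, function(o) {
      m <- prep[[o]]$motifs
      if (length(m) > n_cross_motifs) {
        keep <- with_seed(seed + 17L * i + 19L * o,
                          sort(sample(seq_along(m), n_cross_motifs)))
        m <- m[keep]
      }
      m
    }), recursive = FALSE)
    cross_tab <- batch_compare(cross_motifs, own$segments, ref, config)
    s_si <- mean(self_tab$si, na.rm = TRUE)
    c_si <- mean(cross_tab$si, na.rm = TRUE)
    s_ac <- mean(self_tab$acoustic, na.rm = TRUE)
    c_ac <- mean(cross_tab$acoustic, na.rm = TRUE)
    s_sq <- mean(self_tab$sequence, na.rm = TRUE)
    c_sq <- mean(cross_tab$sequence, na.rm = TRUE)
    tibble::tibble(
      bird_id = id,
      self_acoustic = s_ac, self_sequence = s_sq, self_si = s_si,
      cross_acoustic = c_ac, cross_sequence = c_sq, cross_si = c_si,
      contrast = contrast(s_si, c_si),
      contrast_acoustic = contrast(s_ac, c_ac),
      contrast_sequence = contrast(s_sq, c_sq))
  })
}

#' Enumerate feature subsets
#'
#' @param sizes Subset sizes to enumerate (published design: 4, 5, 6 out
#'   of the six features, 22 subsets).
#' @param features Pool of feature names.
#' @return A list of character vectors (deduplicated).
#' @export
feature_subsets <- function(sizes = c(4, 5, 6), features = SI_FEATURES) {
  subsets <- unlist(lapply(sizes, function(s) {
    utils::combn(sort(features), s, simplify = FALSE)
  }), recursive = FALSE)
  unique(subsets)
}

#' Sweep feature subsets by self/cross contrast
#'
#' Re-runs the self-/cross-similarity experiment for each feature subset,
#' rebuilding the distance calibration per subset (the null distribution
#' depends on the feature space) but sharing the sampling seed, so
#' differences between rows are attributable to the features alone.
#'
#' @param subsets List of feature-name character vectors (each with >= 4
#'   features under the published design; smaller subsets allowed via
#'   `min_size`).
#' @param colony An `si_colony`.
#' @param corpus Calibration corpus: named list (source id -> list of raw
#'   feature tibbles is rebuilt internally from colony bouts when `NULL`).
#' @param config Base [si_config]; its `features` field is overridden per
#'   subset.
#' @param min_size Smallest subset size accepted.
#' @param ... Passed to [self_cross_experiment()] (`n_segments`, `seed`, ...).
#' @return A tibble: one row per (subset, bird), plus columns `subset`
#'   (label) and per-bird results; summarize with `dplyr::summarise`.
#' @export
feature_subset_sweep <- function(subsets, colony, corpus = NULL,
                                 config = si_config(), min_size = 4, ...) {
  config <- as_si_config(config)
  for (s in subsets) {
    bad <- setdiff(s, SI_FEATURES)
    if (length(bad) > 0) stop("unknown feature name(s): ",
                              paste(bad, collapse = ", "), call. = FALSE)
    if (length(s) < min_size) {
      stop("feature subsets need >= ", min_size, " features", call. = FALSE)
    }
  }
  subsets <- unique(lapply(subsets, function(s) sort(unique(s))))
  if (is.null(corpus)) {
    corpus <- lapply(colony$birds, function(b) {
      lapply(b$bouts[1], function(bt) song_features(bt$wave, config))
    })
    names(corpus) <- names(colony$birds)
  }
  purrr::map_dfr(subsets, function(s) {
    cfg <- config
    cfg$features <- s
    ref <- build_reference(corpus, cfg)
    res <- self_cross_experiment(colony, ref, cfg, ...)
    dplyr::mutate(res, subset = paste(s, collapse = "+"), .before = 1)
  })
}
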