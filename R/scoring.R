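# Greedy matching of tutor syllables onto the continuous pupil stream,
# and the acoustic, sequence, and composite SI scores.

#' Construct a tutor motif object
#'
#' Binds a (normalized or raw) feature table to manually annotated
#' syllable boundaries. Boundaries are given in ms and converted to
#' 1-based inclusive frame rows: onset rounded down (`floor(onset) + 1`),
#' offset rounded up (`ceiling(offset)`), so annotated sound is always
#' covered.
#'
#' @param features Feature tibble of the tutor motif.
#' @param syllables A data frame with `onset_ms`, `offset_ms` (one row per
#'   syllable, ordered, non-overlapping), or a two-column matrix.
#' @param source_id Identifier of the tutor.
#' @return An `si_motif` (list with `features`, `syllables` tibble holding
#'   frame rows `s_frame`, `e_frame`, `n_frames`, and `source_id`).
#' @export
tutor_motif <- function(features, syllables, source_id = "tutor") {
  stopifnot(is.data.frame(features))
  if (is.matrix(syllables)) {
    syllables <- tibble::tibble(onset_ms = syllables[, 1],
                                offset_ms = syllables[, 2])
  }
  stopifnot(all(c("onset_ms", "offset_ms") %in% names(syllables)))
  ns <- nrow(syllables)
  if (ns < 1) stop("motif must contain >= 1 syllable", call. = FALSE)
  n_frames_total <- nrow(features)
  syl <- tibble::as_tibble(syllables[, c("onset_ms", "offset_ms")])
  syl$syllable <- seq_len(ns)
  syl$s_frame <- pmax(1L, as.integer(floor(syl$onset_ms)) + 1L)
  syl$e_frame <- as.integer(ceiling(syl$offset_ms))
  for (k in seq_len(ns)) {
    if (syl$offset_ms[k] <= syl$onset_ms[k]) {
      stop(sprintf("syllable %d: offset must exceed onset", k), call. = FALSE)
    }
    if (k > 1 && syl$onset_ms[k] < syl$offset_ms[k - 1]) {
      stop(sprintf("syllable %d overlaps or precedes syllable %d", k, k - 1),
           call. = FALSE)
    }
  }
  # a trailing annotation may overhang the feature grid by up to one
  # window; clamp but reject clearly out-of-range rows
  if (any(syl$s_frame > n_frames_total)) {
    bad <- which(syl$s_frame > n_frames_total)[1]
    stop(sprintf("syllable %d lies outside the audio (%d frames)", bad,
                 n_frames_total), call. = FALSE)
  }
  syl$e_frame <- pmin(syl$e_frame, n_frames_total)
  syl$n_frames <- syl$e_frame - syl$s_frame + 1L
  structure(list(features = features,
                 syllables = syl[, c("syllable", "onset_ms", "offset_ms",
                                     "s_frame", "e_frame", "n_frames")],
                 source_id = source_id),
            class = "si_motif")
}

#' @export
print.si_motif <- function(x, ...) {
  cat(sprintf("<si_motif> '%s': %d syllables, %d frames\n", x$source_id,
              nrow(x$syllables), nrow(x$features)))
  invisible(x)
}

#' Best-matching diagonal of a tutor-syllable band
#'
#' Slides a full diagonal over the horizontal band of `S` belonging to one
#' tutor syllable (rows `s_frame..e_frame`) and returns the pupil offset
#' maximizing the diagonal sum. Only offsets where the whole diagonal fits
#' inside the matrix are admissible; ties resolve to the smallest offset.
#'
#' @param S Similarity matrix (tutor rows x pupil columns).
#' @param s_frame,e_frame Inclusive row range of the syllable band.
#' @return A list: `j1` (best pupil start column), `j2` (end column),
#'   `score` (maximal diagonal sum).
#' @export
best_diagonal <- function(S, s_frame, e_frame) {
  stopifnot(is.matrix(S), s_frame >= 1, e_frame >= s_frame,
            e_frame <= nrow(S))
  nk <- e_frame - s_frame + 1L
  N <- ncol(S)
  if (N < nk) {
    stop(sprintf("pupil segment too short: %d columns < %d-frame syllable",
                 N, nk), call. = FALSE)
  }
  n_off <- N - nk + 1L
  sums <- numeric(n_off)
  for (r in seq_len(nk)) {
    sums <- sums + S[s_frame + r - 1L, r:(r + n_off - 1L)]
  }
  j1 <- which.max(sums)  # first maximum = smallest offset on ties
  list(j1 = as.integer(j1), j2 = as.integer(j1 + nk - 1L), score = sums[j1])
}

#' Greedily match tutor syllables onto the pupil stream
#'
#' Implements the iterative matching procedure: compute each unmatched
#' syllable's best diagonal on the current matrix, pick the syllable with
#' the highest partial similarity (ties: longer syllable, then lower
#' index), zero its rows and the matched pupil columns (inclusive), then
#' recompute everything from scratch for the remaining syllables. Matched
#' pupil intervals therefore never overlap.
#'
#' Syllables with a positive best score take the literal best diagonal; a
#' syllable whose best remaining score is 0 (everything admissible was
#' zeroed) is matched at the least-conflicting offset -- minimal overlap
#' with previously matched columns, ties to the smallest offset -- and
#' flagged.
#'
#' @param S Similarity matrix.
#' @param motif An `si_motif` whose feature frame count equals `nrow(S)`.
#' @return A tibble with one row per syllable: frame bounds, matched
#'   pupil columns `j1`, `j2`, partial score `s_max`, `match_order`, and
#'   `flagged` (TRUE when the syllable was placed with score 0).
#' @export
greedy_match <- function(S, motif) {
  stopifnot(inherits(motif, "si_motif"))
  syl <- motif$syllables
  if (max(syl$e_frame) > nrow(S)) {
    stop("motif syllables extend past the similarity matrix rows",
         call. = FALSE)
  }
  if (ncol(S) < max(syl$n_frames)) {
    stop("pupil segment shorter than the longest tutor syllable",
         call. = FALSE)
  }
  work <- S
  ns <- nrow(syl)
  taken <- rep(FALSE, ncol(S))  # columns already matched
  res <- dplyr::mutate(syl, j1 = NA_integer_, j2 = NA_integer_,
                       s_max = NA_real_, match_order = NA_integer_,
                       flagged = FALSE)
  unmatched <- seq_len(ns)
  for (it in seq_len(ns)) {
    best <- NULL
    for (k in unmatched) {
      bd <- best_diagonal(work, syl$s_frame[k], syl$e_frame[k])
      better <- is.null(best) || bd$score > best$score ||
        (bd$score == best$score && syl$n_frames[k] > syl$n_frames[best$k])
      if (better) best <- c(bd, k = k)
    }
    k <- best$k
    if (best$score <= 0) {
      # nothing admissible left: place at the least-conflicting offset
      nk <- syl$n_frames[k]
      conflict <- stats::filter(as.numeric(taken), rep(1, nk), sides = 1)
      conflict <- conflict[nk:ncol(S)]  # overlap count per start offset
      j1 <- which.min(conflict)
      best$j1 <- as.integer(j1)
      best$j2 <- as.integer(j1 + nk - 1L)
      best$score <- 0
      res$flagged[k] <- TRUE
    }
    res$j1[k] <- best$j1
    res$j2[k] <- best$j2
    res$s_max[k] <- best$score
    res$match_order[k] <- it
    work[syl$s_frame[k]:syl$e_frame[k], ] <- 0
    work[, best$j1:best$j2] <- 0
    taken[best$j1:best$j2] <- TRUE
    unmatched <- setdiff(unmatched, k)
  }
  res
}

#' Acoustic similarity score
#'
#' Weighted average of the partial similarities: the sum of all syllables'
#' maximal diagonal sums normalized by the total syllable length (in
#' frames) of the tutor motif. Lies in \[0, 1\] because every similarity
#' value is at most 1.
#'
#' @param match A match tibble from [greedy_match()].
#' @return Scalar in \[0, 1\].
#' @export
acoustic_score <- function(match) {
  stopifnot(all(c("s_max", "n_frames") %in% names(match)),
            !anyNA(match$s_max))
  sum(match$s_max) / sum(match$n_frames)
}

#' Sequence similarity score
#'
#' For each tutor syllable `k` except the last, looks for an imitation of
#' syllable `k+1` immediately after the pupil fragment matched to `k`: the
#' area of interest spans the rows of syllable `k+1` and the columns from
#' the end of the matched fragment over the tutor offset-to-offset
#' interval plus `slack_ms` of flexibility. The partial score is the
#' maximal diagonal sum inside the area -- diagonals are clipped at the
#' area borders -- normalized by the length of syllable `k+1`. Syllables
#' matched so close to the segment end that the area has zero width are
#' excluded. Computed on the pristine (un-zeroed) matrix.
#'
#' @param S The pristine similarity matrix.
#' @param match A match tibble from [greedy_match()].
#' @param config An [si_config] (`slack_ms`, default 50).
#' @return A list: `score` (mean of applicable partial scores; `NA` if
#'   none, e.g. a single-syllable motif), `partials` tibble with one row
#'   per syllable and an `excluded_reason`.
#' @export
sequence_score <- function(S, match, config = si_config()) {
  config <- as_si_config(config)
  slack <- as.integer(round(config$slack_ms / config$step_ms))
  ns <- nrow(match)
  N <- ncol(S)
  rows <- vector("list", ns)
  for (k in seq_len(ns)) {
    if (k == ns) {
      rows[[k]] <- tibble::tibble(syllable = match$syllable[k],
                                  seq_partial = NA_real_,
                                  excluded_reason = "last syllable")
      next
    }
    c_lo <- match$j2[k] + 1L
    c_hi <- min(N, match$j2[k] + (match$e_frame[k + 1] - match$e_frame[k]) + slack)
    if (c_lo > N) {
      rows[[k]] <- tibble::tibble(syllable = match$syllable[k],
                                  seq_partial = NA_real_,
                                  excluded_reason = "too close to segment end")
      next
    }
    area <- S[match$s_frame[k + 1]:match$e_frame[k + 1], c_lo:c_hi,
              drop = FALSE]
    diag_sums <- tapply(area, col(area) - row(area), sum)
    rows[[k]] <- tibble::tibble(
      syllable = match$syllable[k],
      seq_partial = max(diag_sums) / match$n_frames[k + 1],
      excluded_reason = NA_character_)
  }
  partials <- dplyr::bind_rows(rows)
  applicable <- partials$seq_partial[!is.na(partials$seq_partial)]
  list(score = if (length(applicable) > 0) mean(applicable) else NA_real_,
       partials = partials)
}

#' Composite similarity index
#'
#' The product of the acoustic and sequence similarity scores. When the
#' sequence score is undefined (single-syllable motif or all syllables
#' excluded), the acoustic score is returned and the result should be
#' flagged acoustic-only by the caller.
#'
#' @param acoustic,sequence Scores in \[0, 1\] (`sequence` may be `NA`).
#' @return Scalar in \[0, 1\].
#' @export
similarity_index <- function(acoustic, sequence) {
  stopifnot(acoustic >= 0, acoustic <= 1,
            is.na(sequence) || (sequence >= 0 && sequence <= 1))
  if (is.na(sequence)) acoustic else acoustic * sequence
}

#' Score one tutor-motif x pupil-segment comparison
#'
#' Runs the full comparison: distance matrices, calibration to the
#' similarity matrix, greedy syllable matching, and the acoustic,
#' sequence and composite SI scores. Deterministic given its inputs.
#'
#' @param motif An `si_motif` (normalized features + syllable boundaries).
#' @param pupil Normalized feature tibble of the pupil segment.
#' @param ref An `si_reference` (parameter signature must match).
#' @param config An [si_config].
#' @param keep_matrices Keep D/L/S in the result (for plotting).
#' @return An `si_match` object; see [tidy.si_match()] and
#'   [glance.si_match()].
#' @export
score_pair <- function(motif, pupil, ref, config = si_config(),
                       keep_matrices = FALSE) {
  config <- as_si_config(config)
  stopifnot(inherits(motif, "si_motif"))
  mats <- similarity_matrices(motif$features, pupil, ref, config)
  match <- greedy_match(mats$S, motif)
  ac <- acoustic_score(match)
  sq <- sequence_score(mats$S, match, config)
  match <- dplyr::left_join(match, sq$partials, by = "syllable")
  structure(
    list(syllables = match,
         acoustic = ac,
         sequence = sq$score,
         si = similarity_index(ac, sq$score),
         acoustic_only = is.na(sq$score),
         source_id = motif$source_id,
         n_tutor_frames = nrow(mats$S), n_pupil_frames = ncol(mats$S),
         matrices = if (keep_matrices) mats else NULL,
         config = config),
    class = "si_match")
}

#' @export
print.si_match <- function(x, ...) {
  cat(sprintf("<si_match> tutor '%s' (%d syllables) vs %d-frame pupil segment\n",
              x$source_id, nrow(x$syllables), x$n_pupil_frames))
  cat(sprintf("  acoustic %.3f, sequence %s, SI %.3f%s\n", x$acoustic,
              ifelse(is.na(x$sequence), "NA", sprintf("%.3f", x$sequence)),
              x$si, if (x$acoustic_only) " (acoustic only)" else ""))
  invisible(x)
}
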