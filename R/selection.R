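# Automated pupil segment selection and tutor-motif ingestion.

#' Partition a song bout into comparison segments
#'
#' Splits a pupil song bout into non-overlapping adjacent segments, each
#' twice the tutor motif duration, extracting as many as fit. To sample
#' different time alignments, the first segment starts at a random offset
#' drawn uniformly from \[0, motif duration) after the bout onset; the
#' tail shorter than a full segment is discarded.
#'
#' @param bout A [si_wave], or a numeric bout duration in ms.
#' @param motif_ms Tutor motif duration in ms (> 0).
#' @param seed Integer seed for the offset draw; alternatively pass a
#'   fixed `offset_ms` to bypass the draw.
#' @param offset_ms Optional fixed offset in \[0, motif_ms).
#' @param segment_factor Segment length as a multiple of `motif_ms`
#'   (default 2, the tutor-pupil comparison setting).
#' @return A tibble with `segment`, `start_ms`, `end_ms` (possibly zero
#'   rows), with the drawn offset as attribute `offset_ms`.
#' @examples
#' segment_bout(2500, motif_ms = 500, offset_ms = 0)
#' @export
segment_bout <- function(bout, motif_ms, seed = NULL, offset_ms = NULL,
                         segment_factor = 2) {
  if (inherits(bout, "si_wave")) bout <- wave_duration_ms(bout)
  stopifnot(is.numeric(bout), bout > 0)
  if (!is.numeric(motif_ms) || motif_ms <= 0) {
    stop("motif_ms must be positive", call. = FALSE)
  }
  if (is.null(offset_ms)) {
    offset_ms <- if (is.null(seed)) stats::runif(1, 0, motif_ms) else
      with_seed(seed, stats::runif(1, 0, motif_ms))
  }
  stopifnot(offset_ms >= 0, offset_ms < motif_ms)
  seg_len <- segment_factor * motif_ms
  n_seg <- max(0L, as.integer(floor((bout - offset_ms) / seg_len)))
  out <- tibble::tibble(
    segment = seq_len(n_seg),
    start_ms = offset_ms + (seq_len(n_seg) - 1) * seg_len,
    end_ms = offset_ms + seq_len(n_seg) * seg_len)
  attr(out, "offset_ms") <- offset_ms
  out
}

#' Extract a time slice of a waveform
#'
#' @param wave A [si_wave].
#' @param start_ms,end_ms Slice bounds in ms.
#' @return A [si_wave] with the samples in `[start_ms, end_ms)`.
#' @export
slice_wave <- function(wave, start_ms, end_ms) {
  stopifnot(inherits(wave, "si_wave"), end_ms > start_ms)
  fs <- wave$sample_rate
  i0 <- max(1L, as.integer(floor(start_ms * fs / 1000)) + 1L)
  i1 <- min(length(wave$samples), as.integer(floor(end_ms * fs / 1000)))
  si_wave(wave$samples[i0:i1], fs)
}

#' Load a tutor motif from audio and a syllable annotation table
#'
#' Computes features of the tutor audio, normalizes them with the
#' reference statistics, and attaches the annotated syllable boundaries.
#' Annotations may be in seconds (`onset_s`/`offset_s`) or milliseconds
#' (`onset_ms`/`offset_ms`).
#'
#' @param wave A [si_wave] of the tutor motif.
#' @param annotation Data frame (or CSV path) with onset/offset columns
#'   and optionally `source_id`.
#' @param ref An `si_reference` supplying normalization statistics.
#' @param config An [si_config].
#' @return An `si_motif` with normalized features.
#' @export
load_tutor_motif <- function(wave, annotation, ref, config = si_config()) {
  config <- as_si_config(config)
  if (is.character(annotation)) {
    annotation <- utils::read.csv(annotation)
  }
  if (all(c("onset_s", "offset_s") %in% names(annotation))) {
    annotation$onset_ms <- annotation$onset_s * 1000
    annotation$offset_ms <- annotation$offset_s * 1000
  }
  if (!all(c("onset_ms", "offset_ms") %in% names(annotation))) {
    stop("annotation needs onset/offset columns (onset_s/offset_s or onset_ms/offset_ms)",
         call. = FALSE)
  }
  if (nrow(annotation) < 1) stop("motif must contain >= 1 syllable",
                                 call. = FALSE)
  dur <- wave_duration_ms(wave)
  bad <- which(annotation$onset_ms < 0 | annotation$onset_ms >= dur)
  if (length(bad) > 0) {
    stop(sprintf("annotation row %d lies outside the audio (0-%.1f ms)",
                 bad[1], dur), call. = FALSE)
  }
  ft <- normalize_features(song_features(wave, config), ref$stats)
  src <- if ("source_id" %in% names(annotation)) annotation$source_id[1] else
    "tutor"
  tutor_motif(ft, annotation, source_id = src)
}

#' Score many motif x segment comparisons
#'
#' Crosses every tutor motif with every pupil segment, scoring each pair;
#' failures are isolated per row (flagged with the error message) and the
#' batch continues.
#'
#' @param motifs A list of `si_motif` objects (named or not).
#' @param segments A list of normalized pupil feature tibbles.
#' @param ref An `si_reference`.
#' @param config An [si_config].
#' @return A tibble with one row per (motif, segment) pair: `motif_id`,
#'   `segment_id`, `acoustic`, `sequence`, `si`, `acoustic_only`,
#'   `error`.
#' @export
batch_compare <- function(motifs, segments, ref, config = si_config()) {
  config <- as_si_config(config)
  if (length(segments) == 0) {
    warning("no pupil segments to compare", call. = FALSE)
    return(tibble::tibble(motif_id = character(), segment_id = character(),
                          acoustic = numeric(), sequence = numeric(),
                          si = numeric(), acoustic_only = logical(),
                          error = character()))
  }
  motif_ids <- names(motifs) %||% paste0("motif", seq_along(motifs))
  segment_ids <- names(segments) %||% paste0("segment", seq_along(segments))
  grid <- tidyr::expand_grid(mi = seq_along(motifs), si_ = seq_along(segments))
  purrr::pmap_dfr(grid, function(mi, si_) {
    res <- tryCatch(score_pair(motifs[[mi]], segments[[si_]], ref, config),
                    error = function(e) e)
    if (inherits(res, "error")) {
      tibble::tibble(motif_id = motif_ids[mi], segment_id = segment_ids[si_],
                     acoustic = NA_real_, sequence = NA_real_, si = NA_real_,
                     acoustic_only = NA, error = conditionMessage(res))
    } else {
      tibble::tibble(motif_id = motif_ids[mi], segment_id = segment_ids[si_],
                     acoustic = res$acoustic, sequence = res$sequence,
                     si = res$si, acoustic_only = res$acoustic_only,
                     error = NA_character_)
    }
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
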