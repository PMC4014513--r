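#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a match result
#'
#' One row per tutor syllable: frame bounds, matched pupil interval,
#' partial acoustic score (raw and normalized by syllable length), match
#' order, and the partial sequence score with its exclusion reason.
#'
#' @param x An `si_match` from [score_pair()].
#' @param ... Unused.
#' @return A tibble.
#' @method tidy si_match
#' @export
tidy.si_match <- function(x, ...) {
  dplyr::mutate(x$syllables,
                partial_acoustic = .data$s_max / .data$n_frames)
}

#' One-row summary of a match result
#'
#' @param x An `si_match`.
#' @param ... Unused.
#' @return A tibble with `acoustic`, `sequence`, `si`, `acoustic_only`,
#'   `n_syllables`, `n_tutor_frames`, `n_pupil_frames`.
#' @method glance si_match
#' @export
glance.si_match <- function(x, ...) {
  tibble::tibble(acoustic = x$acoustic, sequence = x$sequence, si = x$si,
                 acoustic_only = x$acoustic_only,
                 n_syllables = nrow(x$syllables),
                 n_tutor_frames = x$n_tutor_frames,
                 n_pupil_frames = x$n_pupil_frames)
}

#' Write a match result to JSON
#'
#' Per-syllable matches plus the three aggregate scores and the resolved
#' configuration, for provenance.
#'
#' @param x An `si_match`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_match <- function(x, path) {
  stopifnot(inherits(x, "si_match"))
  jsonlite::write_json(
    list(source_id = x$source_id,
         scores = list(acoustic = x$acoustic, sequence = x$sequence,
                       si = x$si, acoustic_only = x$acoustic_only),
         syllables = as.data.frame(tidy(x)),
         config = unclass(x$config)),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
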