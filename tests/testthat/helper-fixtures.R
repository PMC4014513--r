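# Shared fixtures, built lazily once per test run and cached.
# Problem sizes: 11 birds with 4-syllable motifs; per bird one short
# single-rendition bout (the calibration corpus uses birds 1-10) and one
# long three-rendition bout (segment extraction); bird 11 plays the
# tutor/pupil roles.

.fx <- new.env(parent = emptyenv())

fx_config <- function() si_config()

fx_colony <- function() {
  if (is.null(.fx$colony)) {
    .fx$colony <- make_colony(n_birds = 11, motifs_per_bird = 3,
                              bouts_per_bird = 2, seed = 42,
                              n_syllables = 4,
                              renditions_per_bout = c(1, 3))
  }
  .fx$colony
}

fx_corpus <- function() {
  if (is.null(.fx$corpus)) {
    cfg <- fx_config()
    col <- fx_colony()
    .fx$corpus <- lapply(col$birds[1:10], function(b) {
      lapply(b$bouts[1], function(bt) song_features(bt$wave, cfg))
    })
  }
  .fx$corpus
}

fx_ref <- function() {
  if (is.null(.fx$ref)) {
    .fx$ref <- build_reference(fx_corpus(), fx_config(), keep_sample = 20000)
  }
  .fx$ref
}

# Tutor: clean (unperturbed) rendition of bird 11's motif, with its exact
# ground-truth annotation.
fx_tutor_render <- function() {
  if (is.null(.fx$tutor_render)) {
    .fx$tutor_render <- render_motif(fx_colony()$birds[[11]]$motif_spec)
  }
  .fx$tutor_render
}

fx_tutor_motif <- function() {
  if (is.null(.fx$tutor_motif)) {
    r <- fx_tutor_render()
    ft <- normalize_features(song_features(r$wave, fx_config()), fx_ref()$stats)
    .fx$tutor_motif <- tutor_motif(ft, r$syllables, source_id = "bird11")
  }
  .fx$tutor_motif
}

fx_features_of <- function(wave) {
  normalize_features(song_features(wave, fx_config()), fx_ref()$stats)
}

# A tiny hand-made spectrogram for closed-form feature checks.
toy_spectrogram <- function(power, freq, config = si_config()) {
  structure(list(power = power, freq = freq,
                 power_full = power, freq_full = freq,
                 frame_times = seq_len(ncol(power)) - 1,
                 sample_rate = 44100, nfft = 512,
                 window_samples = 397, config = as_si_config(config)),
            class = "si_spectrogram")
}

# Random syllable layout for toy matching problems: n_syll bands separated
# by >= 1 gap row inside M rows.
random_syllables <- function(M, n_syll) {
  repeat {
    cuts <- sort(sample(seq_len(M - 1), 2 * n_syll))
    s <- cuts[seq(1, 2 * n_syll, by = 2)]
    e <- cuts[seq(2, 2 * n_syll, by = 2)]
    if (all(e - s >= 1) && all(s[-1] - e[-n_syll] >= 2)) {
      return(tibble::tibble(onset_ms = s - 1, offset_ms = e))
    }
  }
}

# Wrap a bare similarity matrix + syllable table into an si_motif whose
# feature table only carries the frame count (greedy matching needs no
# feature values).
toy_motif <- function(M, syllables) {
  ft <- tibble::tibble(time_ms = seq_len(M) - 1)
  attr(ft, "si_normalized") <- TRUE
  tutor_motif(ft, syllables, source_id = "toy")
}
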