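# Synthetic zebra-finch-like song: motifs of 3-7 syllables (harmonic
# stacks, pure tones, linear sweeps, noise bursts) separated by silent
# gaps, with controllable rendition-to-rendition perturbations. Every
# pipeline stage is testable on this audio with known ground truth.

#' Specify one synthetic syllable
#'
#' @param kind One of `"harmonic_stack"`, `"pure_tone"`, `"sweep"`,
#'   `"noise_burst"`.
#' @param duration_ms Syllable duration in ms (> 0).
#' @param f0 Fundamental (Hz) for stacks/tones, or sweep start frequency.
#' @param f1 Sweep end frequency (Hz); ignored for other kinds.
#' @param band Length-2 band (Hz) for noise bursts (kept within 1--8 kHz).
#' @param amplitude Peak amplitude in \[0, 1\].
#' @param n_harmonics Harmonics for stacks (capped so all stay <= 8600
#'   Hz; the default 12 lets typical fundamentals fill the analysis band,
#'   as zebra finch harmonic stacks do).
#' @param noise_seed Integer seed fixing a noise burst's realization, so
#'   rendering is deterministic.
#' @return A `si_syllable_spec` list.
#' @export
syllable_spec <- function(kind = c("harmonic_stack", "pure_tone", "sweep",
                                   "noise_burst"),
                          duration_ms, f0 = NULL, f1 = NULL,
                          band = c(1500, 6000), amplitude = 0.4,
                          n_harmonics = 12, noise_seed = 1L) {
  kind <- match.arg(kind)
  stopifnot(duration_ms > 0, amplitude > 0, amplitude <= 1)
  freqs <- switch(kind,
                  harmonic_stack = f0, pure_tone = f0,
                  sweep = c(f0, f1), noise_burst = band)
  if (kind != "noise_burst" && (is.null(f0) || any(freqs < 500) ||
                                any(freqs > 8600))) {
    stop("syllable frequencies must lie within [500, 8600] Hz", call. = FALSE)
  }
  if (kind == "noise_burst" &&
      (band[1] < 1000 || band[2] > 8000 || band[1] >= band[2])) {
    stop("noise burst band must lie within [1000, 8000] Hz", call. = FALSE)
  }
  structure(list(kind = kind, duration_ms = duration_ms, f0 = f0, f1 = f1,
                 band = band, amplitude = amplitude,
                 n_harmonics = n_harmonics,
                 noise_seed = as.integer(noise_seed)),
            class = "si_syllable_spec")
}

#' Specify a synthetic motif
#'
#' @param syllables List of [syllable_spec()] objects (3--7 in typical
#'   zebra finch song; at least 1 accepted).
#' @param gaps_ms Silent gap durations between consecutive syllables
#'   (length `length(syllables) - 1`, all > 0).
#' @return A `si_motif_spec` list; `motif_duration_ms(spec)` gives the
#'   derived total duration.
#' @export
motif_spec <- function(syllables, gaps_ms) {
  stopifnot(length(syllables) >= 1,
            all(vapply(syllables, inherits, TRUE, "si_syllable_spec")))
  if (length(syllables) > 1) {
    stopifnot(length(gaps_ms) == length(syllables) - 1, all(gaps_ms > 0))
  } else {
    gaps_ms <- numeric(0)
  }
  structure(list(syllables = syllables, gaps_ms = as.numeric(gaps_ms)),
            class = "si_motif_spec")
}

#' Total duration of a motif spec in ms
#' @param spec A `si_motif_spec`.
#' @return Numeric scalar (ms).
#' @export
motif_duration_ms <- function(spec) {
  stopifnot(inherits(spec, "si_motif_spec"))
  sum(vapply(spec$syllables, `[[`, 0, "duration_ms")) + sum(spec$gaps_ms)
}

#' Draw a random motif spec
#'
#' Draws 3--7 syllables of mixed kinds with integer durations of 40--120
#' ms and gaps of 30--70 ms, values typical of adult zebra finch motifs
#' (total duration roughly 0.5--1 s; integer-ms durations keep syllable
#' onsets aligned to the 1 ms analysis grid). Fundamentals are drawn from
#' `f0_range`, so colonies can give each bird a disjoint frequency
#' inventory.
#'
#' @param n_syllables Syllable count; default drawn uniformly from 3--7.
#' @param f0_range Length-2 range (Hz) for fundamentals/sweep endpoints.
#' @param kinds Syllable kinds to draw from.
#' @param f0_ranges Optional list of per-syllable f0 ranges, overriding
#'   `f0_range` (used by [make_colony()] to give each bird a disjoint
#'   frequency comb while keeping its own syllables spread apart).
#' @param distinct_kinds Cycle through a permutation of `kinds` instead of
#'   sampling independently, so consecutive syllables differ in kind.
#' @return A `si_motif_spec`. Uses the current RNG state; seed externally
#'   for reproducibility.
#' @export
random_motif_spec <- function(n_syllables = sample(3:7, 1),
                              f0_range = c(550, 2800),
                              kinds = c("harmonic_stack", "pure_tone",
                                        "sweep", "noise_burst"),
                              f0_ranges = NULL, distinct_kinds = FALSE) {
  stopifnot(n_syllables >= 1, f0_range[1] >= 500, f0_range[2] <= 3000)
  if (!is.null(f0_ranges)) stopifnot(length(f0_ranges) >= n_syllables)
  kind_seq <- if (distinct_kinds) {
    rep_len(sample(kinds), n_syllables)
  } else {
    sample(kinds, n_syllables, replace = TRUE)
  }
  sylls <- lapply(seq_len(n_syllables), function(i) {
    kind <- kind_seq[i]
    dur <- sample(40:120, 1)
    fr <- if (is.null(f0_ranges)) f0_range else f0_ranges[[i]]
    f0 <- stats::runif(1, fr[1], fr[2])
    if (kind == "sweep") {
      f1 <- min(8600, max(500, f0 * stats::runif(1, 1.3, 2.5)))
      syllable_spec("sweep", dur, f0 = f0, f1 = f1)
    } else if (kind == "noise_burst") {
      lo <- stats::runif(1, 1000, 4000)
      syllable_spec("noise_burst", dur, band = c(lo, lo + stats::runif(1, 1500, 3500)),
                    noise_seed = sample.int(.Machine$integer.max, 1))
    } else {
      syllable_spec(kind, dur, f0 = f0,
                    n_harmonics = if (kind == "pure_tone") 1 else 12)
    }
  })
  gaps <- sample(30:70, max(0, n_syllables - 1), replace = TRUE)
  motif_spec(sylls, gaps)
}

# raised-cosine on/off ramps to avoid spectral splatter
apply_envelope <- function(x, fs, ramp_ms = 5) {
  n <- length(x)
  nr <- min(n %/% 2, max(1L, round(ramp_ms * fs / 1000)))
  ramp <- 0.5 * (1 - cos(pi * seq_len(nr) / nr))
  x[seq_len(nr)] <- x[seq_len(nr)] * ramp
  x[(n - nr + 1):n] <- x[(n - nr + 1):n] * rev(ramp)
  x
}

render_syllable <- function(sp, fs) {
  n <- max(2L, round(sp$duration_ms * fs / 1000))
  t <- (seq_len(n) - 1) / fs
  x <- switch(
    sp$kind,
    pure_tone = sin(2 * pi * sp$f0 * t),
    harmonic_stack = {
      # all harmonics below Nyquist, under a smooth spectral envelope
      # rolling off near the top of the song band; a hard harmonic-count
      # cap would make the spectrum jump discontinuously under pitch
      # jitter, which real vocal-tract filtering does not do
      h <- seq_len(max(1, min(sp$n_harmonics, floor(fs / 2 / sp$f0))))
      a <- 1 / sqrt(h) / (1 + exp((h * sp$f0 - 8000) / 400))
      colSums(a * sin(2 * pi * outer(h * sp$f0, t))) / sum(a)
    },
    sweep = {
      k <- (sp$f1 - sp$f0) / (2 * max(t))
      sin(2 * pi * (sp$f0 * t + k * t^2))
    },
    noise_burst = with_seed(sp$noise_seed, {
      z <- stats::rnorm(n)
      ft <- stats::fft(z)
      fr <- (seq_len(n) - 1) * fs / n
      fr <- pmin(fr, fs - fr)  # two-sided
      ft[fr < sp$band[1] | fr > sp$band[2]] <- 0
      y <- Re(stats::fft(ft, inverse = TRUE)) / n
      y / max(abs(y))
    }))
  apply_envelope(sp$amplitude * x / max(abs(x)), fs)
}

#' Render a motif spec to audio with ground-truth annotation
#'
#' @param spec A `si_motif_spec`.
#' @param sample_rate Sampling rate in Hz (default 44100).
#' @return A list: `wave` ([si_wave]) and `syllables`, a tibble with
#'   `syllable`, `kind`, `onset_ms`, `offset_ms` matching the rendered
#'   audio exactly.
#' @examples
#' m <- motif_spec(list(syllable_spec("pure_tone", 100, f0 = 2000)), numeric(0))
#' r <- render_motif(m)
#' r$syllables
#' @export
render_motif <- function(spec, sample_rate = 44100) {
  stopifnot(inherits(spec, "si_motif_spec"))
  fs <- sample_rate
  pieces <- list()
  ann <- vector("list", length(spec$syllables))
  cursor <- 0L  # samples
  for (i in seq_along(spec$syllables)) {
    syl <- render_syllable(spec$syllables[[i]], fs)
    ann[[i]] <- tibble::tibble(
      syllable = i, kind = spec$syllables[[i]]$kind,
      onset_ms = cursor * 1000 / fs,
      offset_ms = (cursor + length(syl)) * 1000 / fs)
    pieces[[length(pieces) + 1]] <- syl
    cursor <- cursor + length(syl)
    if (i < length(spec$syllables)) {
      gap <- numeric(round(spec$gaps_ms[i] * fs / 1000))
      pieces[[length(pieces) + 1]] <- gap
      cursor <- cursor + length(gap)
    }
  }
  list(wave = si_wave(unlist(pieces), fs),
       syllables = dplyr::bind_rows(ann))
}

#' Perturbation settings for pupil renditions
#'
#' @param pitch_jitter_frac Fractional jitter of each syllable's
#'   fundamental (uniform in `+/- frac`); sweeps scale both endpoints.
#' @param onset_jitter_ms Uniform jitter (`+/- ms`) of each gap duration
#'   (gaps floored at 5 ms).
#' @param shuffle Permute syllable order.
#' @param delete_k Number of randomly chosen syllables to delete (must be
#'   `< n_syllables`).
#' @param noise_snr_db Additive white-noise SNR (dB, relative to syllable
#'   RMS) applied at bout rendering; `Inf` for none.
#' @param seed Integer seed making the perturbation draw reproducible.
#' @return A `si_perturbation` list.
#' @export
perturbation_spec <- function(pitch_jitter_frac = 0, onset_jitter_ms = 0,
                              shuffle = FALSE, delete_k = 0,
                              noise_snr_db = Inf, seed = 1L) {
  stopifnot(pitch_jitter_frac >= 0, onset_jitter_ms >= 0, delete_k >= 0)
  structure(list(pitch_jitter_frac = pitch_jitter_frac,
                 onset_jitter_ms = onset_jitter_ms, shuffle = shuffle,
                 delete_k = as.integer(delete_k),
                 noise_snr_db = noise_snr_db, seed = as.integer(seed)),
            class = "si_perturbation")
}

#' Apply a perturbation to a motif spec
#'
#' Jitters pitch and gap timing, optionally shuffles or deletes syllables,
#' reproducibly under `pert$seed`. A zero perturbation returns an
#' identical spec.
#'
#' @param spec A `si_motif_spec`.
#' @param pert A [perturbation_spec()].
#' @return A perturbed `si_motif_spec`.
#' @export
perturb_motif <- function(spec, pert) {
  stopifnot(inherits(spec, "si_motif_spec"), inherits(pert, "si_perturbation"))
  ns <- length(spec$syllables)
  if (pert$delete_k >= ns) {
    stop("delete_k must be smaller than the syllable count", call. = FALSE)
  }
  with_seed(pert$seed, {
    sylls <- spec$syllables
    gaps <- spec$gaps_ms
    # pitch jitter: one draw per syllable, consumed regardless of magnitude
    # so nested jitter levels share the same realization under one seed
    u <- stats::runif(ns, -1, 1)
    if (pert$pitch_jitter_frac > 0) {
      for (i in seq_len(ns)) {
        fac <- 1 + pert$pitch_jitter_frac * u[i]
        s <- sylls[[i]]
        if (s$kind %in% c("pure_tone", "harmonic_stack", "sweep")) {
          s$f0 <- min(8600, max(500, s$f0 * fac))
          if (!is.null(s$f1)) s$f1 <- min(8600, max(500, s$f1 * fac))
          sylls[[i]] <- s
        }
      }
    }
    ug <- stats::runif(length(gaps), -1, 1)
    if (pert$onset_jitter_ms > 0 && length(gaps) > 0) {
      gaps <- pmax(5, gaps + pert$onset_jitter_ms * ug)
    }
    keep <- seq_len(ns)
    if (pert$delete_k > 0) keep <- sort(sample(keep, ns - pert$delete_k))
    if (isTRUE(pert$shuffle)) keep <- sample(keep)
    sylls <- sylls[keep]
    if (length(sylls) > 1) {
      gaps <- if (length(gaps) >= length(sylls) - 1) {
        gaps[seq_len(length(sylls) - 1)]
      } else {
        rep_len(c(gaps, 50), length(sylls) - 1)
      }
    } else {
      gaps <- numeric(0)
    }
    motif_spec(sylls, gaps)
  })
}

#' Render a song bout: repeated perturbed motif renditions
#'
#' @param spec Base `si_motif_spec`.
#' @param n_renditions Number of motif renditions in the bout.
#' @param pert A [perturbation_spec()]; each rendition gets an independent
#'   draw (seeds derived from `pert$seed`).
#' @param inter_motif_gap_ms Silence between renditions.
#' @param sample_rate Hz.
#' @return A list: `wave` and `syllables` (annotation across the bout).
#' @export
render_bout <- function(spec, n_renditions = 2,
                        pert = perturbation_spec(),
                        inter_motif_gap_ms = 80, sample_rate = 44100) {
  stopifnot(n_renditions >= 1)
  fs <- sample_rate
  waves <- list(); anns <- list(); cursor_ms <- 0
  for (r in seq_len(n_renditions)) {
    p <- pert
    p$seed <- pert$seed + 7919L * r
    sp <- perturb_motif(spec, p)
    rd <- render_motif(sp, fs)
    anns[[r]] <- dplyr::mutate(rd$syllables,
                               rendition = r,
                               onset_ms = .data$onset_ms + cursor_ms,
                               offset_ms = .data$offset_ms + cursor_ms)
    waves[[length(waves) + 1]] <- rd$wave$samples
    cursor_ms <- cursor_ms + wave_duration_ms(rd$wave)
    if (r < n_renditions) {
      waves[[length(waves) + 1]] <- numeric(round(inter_motif_gap_ms * fs / 1000))
      cursor_ms <- cursor_ms + inter_motif_gap_ms
    }
  }
  x <- unlist(waves)
  if (is.finite(pert$noise_snr_db)) {
    voiced_rms <- sqrt(mean(x[x != 0]^2))
    if (!is.finite(voiced_rms) || voiced_rms == 0) voiced_rms <- 0.1
    sigma <- voiced_rms / 10^(pert$noise_snr_db / 20)
    x <- x + with_seed(pert$seed + 104729L, stats::rnorm(length(x), sd = sigma))
  }
  list(wave = si_wave(x, fs), syllables = dplyr::bind_rows(anns))
}

#' Generate a synthetic colony
#'
#' Builds `n_birds` birds with distinct syllable inventories: the
#' 550--2800 Hz fundamental range is divided into an interleaved comb of
#' narrow slots, and syllable `k` of bird `b` draws its fundamental from
#' slot `(k-1)*n_birds + b`, so no two birds ever share a fundamental
#' while each bird's own syllables stay hundreds of Hz apart (motifs of
#' real colonies are similarly diverse within and across birds). Each
#' bird gets several motif renditions (mildly jittered, emulating natural
#' rendition-to-rendition variability) and several song bouts (repeated
#' perturbed renditions over a recording noise floor). Optionally writes
#' WAVs, annotation CSVs and a manifest CSV.
#'
#' @param n_birds Number of birds (>= 2).
#' @param motifs_per_bird Motif renditions kept as "tutor-style" samples.
#' @param bouts_per_bird Song bouts per bird.
#' @param seed Integer seed; the whole colony is deterministic given it.
#' @param n_syllables Syllables per motif (default random 3--7 per bird).
#' @param syllable_kinds Kinds to draw from.
#' @param renditions_per_bout Motif renditions per bout; a vector is
#'   recycled over bouts, e.g. `c(1, 3)` for one short and one long bout.
#' @param noise_snr_db Bout noise floor SNR in dB (30 dB emulates a clean
#'   laboratory recording).
#' @param pitch_jitter_frac,onset_jitter_ms Natural rendition variability.
#' @param sample_rate Hz.
#' @param dir If non-`NULL`, write `bird<k>_motif<j>.wav`,
#'   `bird<k>_bout<j>.wav`, per-motif annotation CSVs and `manifest.csv`
#'   there.
#' @return An `si_colony`: list with `birds` (per bird: `motif_spec`,
#'   `motifs` = list of rendered motifs with annotations, `bouts` = list
#'   of rendered bouts) and a `manifest` tibble.
#' @export
make_colony <- function(n_birds = 10, motifs_per_bird = 3, bouts_per_bird = 2,
                        seed = 1L, n_syllables = NULL,
                        syllable_kinds = c("harmonic_stack", "pure_tone",
                                           "sweep", "noise_burst"),
                        renditions_per_bout = 2, noise_snr_db = 30,
                        pitch_jitter_frac = 0.01, onset_jitter_ms = 3,
                        sample_rate = 44100, dir = NULL) {
  stopifnot(n_birds >= 2)
  # interleaved fundamental comb: slot width for up to 7 syllables/bird,
  # with a small guard band so cross-bird fundamentals never collide
  max_syll <- 7
  slot <- (2800 - 550) / (n_birds * max_syll)
  guard <- min(4, slot / 4)
  birds <- with_seed(seed, {
    lapply(seq_len(n_birds), function(b) {
      ns <- if (is.null(n_syllables)) sample(3:7, 1) else n_syllables
      f0_ranges <- lapply(seq_len(ns), function(k) {
        lo <- 550 + ((k - 1) * n_birds + (b - 1)) * slot
        c(lo + guard, lo + slot - guard)
      })
      spec <- random_motif_spec(
        n_syllables = ns, f0_ranges = f0_ranges,
        kinds = syllable_kinds, distinct_kinds = TRUE)
      motifs <- lapply(seq_len(motifs_per_bird), function(j) {
        # motif samples are "recordings" too: same noise floor as bouts
        p <- perturbation_spec(pitch_jitter_frac = pitch_jitter_frac,
                               onset_jitter_ms = onset_jitter_ms,
                               noise_snr_db = noise_snr_db,
                               seed = seed + 1000L * b + j)
        render_bout(spec, n_renditions = 1, pert = p,
                    sample_rate = sample_rate)
      })
      n_rend <- rep_len(renditions_per_bout, bouts_per_bird)
      bouts <- lapply(seq_len(bouts_per_bird), function(j) {
        p <- perturbation_spec(pitch_jitter_frac = pitch_jitter_frac,
                               onset_jitter_ms = onset_jitter_ms,
                               noise_snr_db = noise_snr_db,
                               seed = seed + 1000L * b + 100L * j)
        render_bout(spec, n_renditions = n_rend[j], pert = p,
                    sample_rate = sample_rate)
      })
      list(bird_id = paste0("bird", b), motif_spec = spec,
           motifs = motifs, bouts = bouts)
    })
  })
  names(birds) <- vapply(birds, `[[`, "", "bird_id")
  manifest <- purrr::map_dfr(birds, function(b) {
    tibble::tibble(
      bird_id = b$bird_id,
      item = c(paste0("motif", seq_along(b$motifs)),
               paste0("bout", seq_along(b$bouts))),
      kind = rep(c("motif", "bout"), c(length(b$motifs), length(b$bouts))),
      duration_ms = c(vapply(b$motifs, function(m) wave_duration_ms(m$wave), 0),
                      vapply(b$bouts, function(m) wave_duration_ms(m$wave), 0)))
  })
  colony <- structure(list(birds = birds, manifest = manifest, seed = seed,
                           sample_rate = sample_rate),
                      class = "si_colony")
  if (!is.null(dir)) write_colony(colony, dir)
  colony
}

#' Write a colony to disk (WAV + annotation CSV + manifest CSV)
#' @param colony An `si_colony`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_colony <- function(colony, dir) {
  stopifnot(inherits(colony, "si_colony"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  for (b in colony$birds) {
    for (j in seq_along(b$motifs)) {
      base <- file.path(dir, sprintf("%s_motif%d", b$bird_id, j))
      write_wav(b$motifs[[j]]$wave, paste0(base, ".wav"))
      ann <- dplyr::mutate(b$motifs[[j]]$syllables,
                           source_id = b$bird_id, .before = 1)
      utils::write.csv(as.data.frame(ann), paste0(base, ".csv"),
                       row.names = FALSE)
      rows[[length(rows) + 1]] <- tibble::tibble(
        bird_id = b$bird_id, kind = "motif", file = paste0(base, ".wav"))
    }
    for (j in seq_along(b$bouts)) {
      base <- file.path(dir, sprintf("%s_bout%d", b$bird_id, j))
      write_wav(b$bouts[[j]]$wave, paste0(base, ".wav"))
      rows[[length(rows) + 1]] <- tibble::tibble(
        bird_id = b$bird_id, kind = "bout", file = paste0(base, ".wav"))
    }
  }
  utils::write.csv(as.data.frame(dplyr::bind_rows(rows)),
                   file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(dir)
}
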