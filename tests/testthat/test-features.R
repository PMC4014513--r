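# Closed-form checks use hand-made spectra via toy_spectrogram(); audio
# checks use the synthetic generator.

test_that("Wiener entropy matches its closed form and is never positive", {
  # flat spectrum: geometric = arithmetic mean
  sp <- toy_spectrogram(matrix(2, nrow = 4, ncol = 3), c(1, 2, 3, 4) * 1000)
  expect_equal(wiener_entropy(sp), c(0, 0, 0))
  # bins {1, 4}: log(geometric 2 / arithmetic 2.5)
  sp2 <- toy_spectrogram(matrix(c(1, 4), 2, 1), c(1000, 2000))
  expect_equal(wiener_entropy(sp2), log(2 / 2.5), tolerance = 1e-12)
  # near-degenerate two-bin frame: large negative
  sp3 <- toy_spectrogram(matrix(c(1, 1e-8), 2, 1), c(1000, 2000))
  expect_lt(wiener_entropy(sp3), -5)
  # zero frame floors at the configured value
  sp4 <- toy_spectrogram(matrix(0, 2, 1), c(1000, 2000))
  expect_equal(wiener_entropy(sp4), si_config()$entropy_floor)
})

test_that("gravity center is the power-weighted first moment", {
  sp <- toy_spectrogram(matrix(c(0, 1, 0), 3, 1), c(1000, 2000, 3000))
  expect_equal(gravity_center(sp), 2000)
  sp2 <- toy_spectrogram(matrix(c(1, 0, 1), 3, 1), c(1000, 2000, 3000))
  expect_equal(gravity_center(sp2), 2000)
  sp3 <- toy_spectrogram(matrix(c(1, 3), 2, 1), c(1000, 2000))
  expect_equal(gravity_center(sp3), 1750)
  # invariant to uniform power scaling
  expect_equal(gravity_center(toy_spectrogram(matrix(c(7, 21), 2, 1),
                                              c(1000, 2000))), 1750)
  # zero power falls back to band midpoint
  expect_equal(gravity_center(toy_spectrogram(matrix(0, 2, 1), c(1000, 2000))),
               mean(si_config()$band))
})

test_that("spectral width is the root second moment about the gravity center", {
  sp <- toy_spectrogram(matrix(c(0, 5, 0), 3, 1), c(1000, 2000, 3000))
  expect_equal(spectral_width(sp), 0)
  sp2 <- toy_spectrogram(matrix(c(1, 0, 1), 3, 1), c(1500, 2000, 2500))
  expect_equal(spectral_width(sp2), 500)
  sp3 <- toy_spectrogram(matrix(c(1, 3), 2, 1), c(1000, 2000))
  expect_equal(spectral_width(sp3), sqrt(0.25 * 750^2 + 0.75 * 250^2),
               tolerance = 1e-12)
})

test_that("cepstral pitch locates a harmonic stack fundamental", {
  fs <- 44100
  spec <- motif_spec(list(syllable_spec("harmonic_stack", 120, f0 = 700)),
                     numeric(0))
  ft <- song_features(render_motif(spec, fs)$wave)
  voiced <- !ft$silent & ft$time_ms > 10 & ft$time_ms < 100
  est <- median(ft$pitch[voiced])
  # within one quefrency bin of 700 Hz (bins are fs/q for integer q)
  q <- round(fs / 700)
  expect_gt(est, fs / (q + 1))
  expect_lt(est, fs / (q - 1))
})

test_that("pitch goodness separates harmonic stacks from white noise", {
  stack <- render_motif(motif_spec(list(
    syllable_spec("harmonic_stack", 120, f0 = 700)), numeric(0)))$wave
  set.seed(3)
  white <- si_wave(rnorm(round(0.12 * 44100), sd = 0.1), 44100)
  g_stack <- median(song_features(stack)$pitch_goodness[10:100])
  g_noise <- median(song_features(white)$pitch_goodness[10:100])
  expect_gt(g_stack, 10 * g_noise)
})

test_that("pitch and goodness are invariant to amplitude scaling", {
  base <- render_motif(motif_spec(list(
    syllable_spec("harmonic_stack", 100, f0 = 900)), numeric(0)))$wave
  doubled <- si_wave(2 * base$samples, base$sample_rate)
  f1 <- song_features(base); f2 <- song_features(doubled)
  mid <- 20:80
  expect_equal(f1$pitch[mid], f2$pitch[mid], tolerance = 1e-8)
  expect_equal(f1$pitch_goodness[mid], f2$pitch_goodness[mid],
               tolerance = 1e-6)
})

test_that("frequency modulation is ~0 for steady tones and constant for sweeps", {
  tone <- render_motif(motif_spec(list(
    syllable_spec("pure_tone", 150, f0 = 2000)), numeric(0)))$wave
  fm_tone <- song_features(tone)$fm[30:120]
  expect_lt(median(fm_tone), 0.1)
  chirp <- render_motif(motif_spec(list(
    syllable_spec("sweep", 150, f0 = 1000, f1 = 4000)), numeric(0)))$wave
  fm_chirp <- song_features(chirp)$fm[30:120]
  expect_gt(median(fm_chirp), median(fm_tone))
  expect_lt(diff(range(fm_chirp)), 0.6)  # roughly constant over the sweep
})

test_that("normalization statistics follow the MAD-about-mean convention", {
  ft <- tibble::tibble(time_ms = 0:3, silent = FALSE)
  for (f in SI_FEATURES) ft[[f]] <- c(1, 2, 3, 6)
  stats <- fit_normalization(list(ft))
  expect_true(all(stats$center == 3))
  expect_true(all(stats$scale == 1.5))  # median{2,1,0,3}
  stats2 <- fit_normalization(list(ft), si_config(scale_method = "sd"))
  expect_true(all(abs(stats2$scale - sd(c(1, 2, 3, 6))) < 1e-12))
  # {0, 2}: center 1, MAD-scale 1
  ft2 <- ft[1:2, ]
  for (f in SI_FEATURES) ft2[[f]] <- c(0, 2)
  s2 <- fit_normalization(list(ft2))
  expect_true(all(s2$center == 1 & s2$scale == 1))
})

test_that("constant features give a zero-scale error naming the feature", {
  ft <- tibble::tibble(time_ms = 0:3, silent = FALSE)
  for (f in SI_FEATURES) ft[[f]] <- c(1, 2, 3, 6)
  ft$pitch <- 5
  expect_error(fit_normalization(list(ft)), "pitch")
})

test_that("normalize then denormalize recovers raw values", {
  w <- render_motif(motif_spec(list(
    syllable_spec("harmonic_stack", 80, f0 = 800),
    syllable_spec("sweep", 80, f0 = 1500, f1 = 3000)), 40))$wave
  raw <- song_features(w)
  stats <- fit_normalization(list(raw))
  norm <- normalize_features(raw, stats)
  expect_true(isTRUE(attr(norm, "si_normalized")))
  # applying stats to their own corpus centers each feature at ~0
  expect_true(all(abs(colMeans(norm[, SI_FEATURES])) < 1e-9))
  back <- denormalize_features(norm, stats)
  for (f in SI_FEATURES) expect_equal(back[[f]], raw[[f]], tolerance = 1e-9)
  # arithmetic: center 5, scale 2, value 9 -> 2
  expect_equal((9 - 5) / 2, 2)
  expect_error(normalize_features(norm, stats), "already normalized")
})

test_that("feature extraction is bit-reproducible on a synthetic motif", {
  set.seed(11)
  spec <- random_motif_spec(n_syllables = 3)
  w <- render_motif(spec)$wave
  f1 <- song_features(w); f2 <- song_features(w)
  expect_true(all(vapply(SI_FEATURES, function(f) {
    all(is.finite(f1[[f]])) && identical(f1[[f]], f2[[f]])
  }, TRUE)))
})
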