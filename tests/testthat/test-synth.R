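test_that("rendering is deterministic and annotations align with the audio", {
  set.seed(61)
  spec <- random_motif_spec(n_syllables = 4)
  r1 <- render_motif(spec)
  r2 <- render_motif(spec)
  expect_identical(r1$wave$samples, r2$wave$samples)
  expect_equal(nrow(r1$syllables), 4)
  # gaps are quieter than syllable peaks by >= 40 dB
  fs <- r1$wave$sample_rate
  peak <- max(abs(r1$wave$samples))
  for (k in 1:3) {
    g0 <- round(r1$syllables$offset_ms[k] * fs / 1000) + 10
    g1 <- round(r1$syllables$onset_ms[k + 1] * fs / 1000) - 10
    gap_amp <- max(abs(r1$wave$samples[g0:g1]))
    expect_lt(gap_amp, peak * 10^(-40 / 20))
  }
  # annotated syllables actually contain sound
  for (k in 1:4) {
    s0 <- round(r1$syllables$onset_ms[k] * fs / 1000) + 1
    s1 <- round(r1$syllables$offset_ms[k] * fs / 1000)
    expect_gt(max(abs(r1$wave$samples[s0:s1])), 0.05)
  }
})

test_that("frequency constraints are enforced", {
  expect_error(syllable_spec("pure_tone", 50, f0 = 300), "500")
  expect_error(syllable_spec("noise_burst", 50, band = c(500, 9000)), "8000")
})

test_that("zero perturbation is the identity and jitters are bounded", {
  set.seed(62)
  spec <- random_motif_spec(n_syllables = 4)
  same <- perturb_motif(spec, perturbation_spec(seed = 5))
  expect_identical(same, spec)
  jit <- perturb_motif(spec, perturbation_spec(pitch_jitter_frac = 0.05,
                                               seed = 5))
  for (i in seq_along(spec$syllables)) {
    s0 <- spec$syllables[[i]]; s1 <- jit$syllables[[i]]
    if (!is.null(s0$f0)) {
      expect_lte(abs(s1$f0 - s0$f0), 0.05 * s0$f0 + 1e-9)
    }
  }
  # shuffle with a seed is a fixed reproducible permutation
  sh1 <- perturb_motif(spec, perturbation_spec(shuffle = TRUE, seed = 9))
  sh2 <- perturb_motif(spec, perturbation_spec(shuffle = TRUE, seed = 9))
  expect_identical(sh1, sh2)
  expect_error(perturb_motif(spec, perturbation_spec(delete_k = 4)),
               "delete_k")
  del <- perturb_motif(spec, perturbation_spec(delete_k = 2, seed = 3))
  expect_equal(length(del$syllables), 2)
})

test_that("colonies are reproducible with disjoint per-bird inventories", {
  c1 <- make_colony(n_birds = 3, motifs_per_bird = 1, bouts_per_bird = 1,
                    seed = 77, n_syllables = 3, renditions_per_bout = 1)
  c2 <- make_colony(n_birds = 3, motifs_per_bird = 1, bouts_per_bird = 1,
                    seed = 77, n_syllables = 3, renditions_per_bout = 1)
  expect_identical(c1$birds$bird1$bouts[[1]]$wave$samples,
                   c2$birds$bird1$bouts[[1]]$wave$samples)
  expect_equal(nrow(c1$manifest), 3 * (1 + 1))
  # no two birds share a fundamental (interleaved disjoint slots)
  f0s <- lapply(c1$birds, function(b) {
    unlist(lapply(b$motif_spec$syllables, function(s) {
      if (s$kind %in% c("pure_tone", "harmonic_stack", "sweep")) s$f0
      else NULL
    }))
  })
  present <- which(lengths(f0s) > 0)
  for (i in present) for (j in present) {
    if (i < j) {
      expect_gt(min(abs(outer(f0s[[i]], f0s[[j]], "-"))), 2)
    }
  }
})

test_that("a written colony round-trips through WAV and manifest files", {
  dir <- withr::local_tempdir()
  col <- make_colony(n_birds = 2, motifs_per_bird = 1, bouts_per_bird = 1,
                     seed = 5, n_syllables = 3, renditions_per_bout = 1,
                     dir = dir)
  man <- utils::read.csv(file.path(dir, "manifest.csv"))
  expect_equal(nrow(man), 2 * 2)
  expect_true(all(file.exists(man$file)))
  w <- read_wav(man$file[man$kind == "motif"][1])
  orig <- col$birds$bird1$motifs[[1]]$wave
  expect_equal(w$sample_rate, orig$sample_rate)
  expect_lt(max(abs(w$samples - pmax(-1, pmin(1, orig$samples)))), 1 / 32000)
  ann <- utils::read.csv(file.path(dir, "bird1_motif1.csv"))
  expect_equal(nrow(ann), 3)
})
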