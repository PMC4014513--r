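test_that("best_diagonal agrees with the exhaustive offset scan", {
  set.seed(31)
  for (i in 1:25) {
    S <- matrix(runif(10 * 40), 10, 40)
    bd <- best_diagonal(S, 1, 10)
    sums <- oracle_diag_sums(S, 1, 10)
    expect_equal(bd$score, max(sums))
    expect_equal(bd$j1, which.max(sums))
    expect_equal(bd$j2, bd$j1 + 9)
  }
})

test_that("best_diagonal tie-breaks to the smallest offset and flags short segments", {
  S <- matrix(0, 5, 20)
  bd <- best_diagonal(S, 2, 4)
  expect_equal(bd$j1, 1)        # all-zero band: smallest admissible offset
  expect_equal(bd$score, 0)
  S2 <- matrix(0, 5, 20)
  S2[cbind(2:4, 7:9)] <- 1      # unit diagonal at offset 7
  bd2 <- best_diagonal(S2, 2, 4)
  expect_equal(bd2$j1, 7)
  expect_equal(bd2$score, 3)    # band height
  expect_error(best_diagonal(matrix(0, 5, 3), 1, 5), "too short")
})

test_that("greedy matching equals the literal step-by-step oracle", {
  set.seed(33)
  for (i in 1:50) {
    n_syll <- sample(2:4, 1)
    M <- sample(20:30, 1)
    N <- sample(35:60, 1)
    syl <- random_syllables(M, n_syll)
    S <- matrix(runif(M * N), M, N)
    motif <- toy_motif(M, syl)
    got <- greedy_match(S, motif)
    want <- oracle_greedy(S, got)  # uses only s_frame/e_frame columns
    expect_equal(got$j1, want$j1)
    expect_equal(got$j2, want$j2)
    expect_equal(got$s_max, want$s_max, tolerance = 1e-12)
    expect_equal(got$match_order, want$match_order)
  }
})

test_that("perfect block-diagonal similarity matches each syllable to its block", {
  M <- 30; N <- 60
  syl <- tibble::tibble(onset_ms = c(0, 10, 20), offset_ms = c(8, 18, 28))
  S <- matrix(0, M, N)
  offs <- c(5, 25, 45)
  for (k in 1:3) {
    rows <- (syl$onset_ms[k] + 1):syl$offset_ms[k]
    S[cbind(rows, offs[k] + seq_along(rows) - 1)] <- 1
  }
  res <- greedy_match(S, toy_motif(M, syl))
  expect_equal(res$j1, offs)
  expect_equal(res$s_max, res$n_frames)
  expect_equal(acoustic_score(res), 1)
  # matched intervals are disjoint on block-structured data
  o <- order(res$j1)
  expect_true(all(res$j1[o][-1] > res$j2[o][-3]))
})

test_that("equally imitated syllables match longest-first", {
  M <- 20; N <- 50
  syl <- tibble::tibble(onset_ms = c(0, 8), offset_ms = c(4, 16))
  S <- matrix(0, M, N)
  S[cbind(1:4, 10:13)] <- 1     # short syllable, raw sum 4
  S[cbind(9:16, 30:37)] <- 0.5  # long syllable, raw sum 4: same score
  res <- greedy_match(S, toy_motif(M, syl))
  expect_equal(res$match_order, c(2, 1))  # longer (syllable 2) first
})

test_that("overlapping best matches resolve by re-matching on the zeroed matrix", {
  # two syllables whose best diagonals sit on the same pupil columns; the
  # higher-sum one keeps the fragment, the other re-matches elsewhere
  M <- 20; N <- 40
  syl <- tibble::tibble(onset_ms = c(0, 10), offset_ms = c(5, 15))
  S <- matrix(0, M, N)
  S[cbind(1:5, 11:15)] <- 1.0      # syllable 1 best at cols 11-15
  S[cbind(11:15, 11:15)] <- 0.9    # syllable 2 best also at cols 11-15
  S[cbind(11:15, 25:29)] <- 0.4    # syllable 2 fallback at cols 25-29
  res <- greedy_match(S, toy_motif(M, syl))
  expect_equal(res$match_order, c(1, 2))
  expect_equal(res$j1, c(11, 25))
  expect_equal(res$s_max, c(5, 2))
})

test_that("acoustic score is the length-weighted average of partials", {
  match <- tibble::tibble(s_max = c(80, 10), n_frames = c(100, 50))
  expect_equal(acoustic_score(match), 0.6)
  expect_equal(acoustic_score(tibble::tibble(s_max = c(0, 0),
                                             n_frames = c(10, 20))), 0)
})

test_that("sequence scoring clips diagonals to the area of interest", {
  # two syllables; matched fragment of syllable 1 at cols 11-15; a perfect
  # copy of syllable 2 follows immediately
  M <- 25; N <- 60
  syl <- tibble::tibble(onset_ms = c(0, 10), offset_ms = c(5, 15))
  S <- matrix(0, M, N)
  S[cbind(1:5, 11:15)] <- 1
  S[cbind(11:15, 21:25)] <- 1
  motif <- toy_motif(M, syl)
  res <- greedy_match(S, motif)
  sq <- sequence_score(S, res, si_config())
  expect_equal(sq$partials$seq_partial[1], 1)  # full diagonal inside area
  expect_true(is.na(sq$partials$seq_partial[2]))
  expect_match(sq$partials$excluded_reason[2], "last")
  expect_equal(sq$score, 1)
  # all-zero area of interest: partial 0
  S2 <- matrix(0, M, N)
  S2[cbind(1:5, 11:15)] <- 1
  res2 <- greedy_match(S2, motif)
  sq2 <- sequence_score(S2, res2, si_config())
  expect_equal(sq2$partials$seq_partial[1], 0)
})

test_that("similarity index is the product of acoustic and sequence scores", {
  expect_equal(similarity_index(1, 1), 1)
  expect_equal(similarity_index(0.5, 0.8), 0.4)
  expect_equal(similarity_index(0.7, 0), 0)
  # undefined sequence: acoustic-only
  expect_equal(similarity_index(0.6, NA), 0.6)
})

test_that("single-syllable motifs are scored acoustic-only with a flag", {
  ref <- fx_ref()
  cfg <- fx_config()
  spec <- motif_spec(list(syllable_spec("harmonic_stack", 100, f0 = 950)),
                     numeric(0))
  r <- render_motif(spec)
  ft <- fx_features_of(r$wave)
  motif <- tutor_motif(ft, r$syllables)
  m <- score_pair(motif, ft, ref, cfg)
  expect_true(m$acoustic_only)
  expect_true(is.na(m$sequence))
  expect_equal(m$si, m$acoustic)
})

test_that("scores stay in [0, 1] on randomized toy problems", {
  set.seed(35)
  for (i in 1:20) {
    M <- sample(20:30, 1); N <- sample(30:50, 1)
    syl <- random_syllables(M, sample(2:4, 1))
    S <- matrix(runif(M * N), M, N)
    motif <- toy_motif(M, syl)
    res <- greedy_match(S, motif)
    ac <- acoustic_score(res)
    sq <- sequence_score(S, res, si_config())$score
    expect_true(ac >= 0 && ac <= 1)
    expect_true(is.na(sq) || (sq >= 0 && sq <= 1))
    if (!is.na(sq)) {
      si <- similarity_index(ac, sq)
      expect_true(si >= 0 && si <= 1)
    }
  }
})

test_that("score_pair is deterministic and tidies cleanly", {
  ref <- fx_ref()
  motif <- fx_tutor_motif()
  m1 <- score_pair(motif, motif$features, ref, fx_config())
  m2 <- score_pair(motif, motif$features, ref, fx_config())
  expect_identical(glance(m1), glance(m2))
  td <- tidy(m1)
  expect_equal(nrow(td), 4)
  expect_true(all(c("j1", "j2", "s_max", "seq_partial",
                    "partial_acoustic") %in% names(td)))
  gl <- glance(m1)
  expect_equal(gl$si, m1$acoustic * m1$sequence)
})
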