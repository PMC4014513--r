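make_norm_features <- function(mat, features = si_config()$features) {
  ft <- tibble::as_tibble(as.data.frame(mat))
  names(ft) <- features[seq_len(ncol(mat))]
  attr(ft, "si_normalized") <- TRUE
  attr(ft, "si_params") <- "toy"
  attr(ft, "si_stats_sig") <- "toy-stats"
  ft
}

test_that("distance matrix is the Euclidean distance in feature space", {
  cfg <- si_config(features = c("gravity_center", "spectral_width"))
  tut <- make_norm_features(cbind(c(3, 0), c(0, 0)), cfg$features)
  pup <- make_norm_features(cbind(c(1, 3), c(0, 4)), cfg$features)
  D <- distance_matrix(tut, pup, cfg)
  expect_equal(D[1, 1], 2)   # one differing feature: |3-1|
  expect_equal(D[2, 2], 5)   # differences (3,4)
  expect_equal(D[1, 2], 4)  # dist((3,0),(3,4))
  # identical frames -> 0
  expect_equal(distance_matrix(tut, tut, cfg)[1, 1], 0)
})

test_that("distance matrix transposes under swapping tutor and pupil", {
  set.seed(9)
  cfg <- si_config()
  a <- make_norm_features(matrix(rnorm(40 * 4), 40))
  b <- make_norm_features(matrix(rnorm(25 * 4), 25))
  expect_equal(distance_matrix(a, b, cfg), t(distance_matrix(b, a, cfg)),
               tolerance = 1e-12)
})

test_that("mismatched normalization statistics are rejected", {
  cfg <- si_config()
  a <- make_norm_features(matrix(rnorm(10 * 4), 10))
  b <- make_norm_features(matrix(rnorm(10 * 4), 10))
  attr(b, "si_stats_sig") <- "other-stats"
  expect_error(distance_matrix(a, b, cfg), "different statistics")
})

test_that("diagonal RMS smoothing equals the brute-force per-cell oracle", {
  set.seed(21)
  D <- matrix(runif(60 * 60, 0, 5), 60)
  L <- local_distance_matrix(D, si_config())
  expect_lt(max(abs(L - oracle_local_rms(D, 25))), 1e-12)
  # non-square case
  D2 <- matrix(runif(40 * 70, 0, 5), 40)
  L2 <- local_distance_matrix(D2, si_config())
  expect_lt(max(abs(L2 - oracle_local_rms(D2, 25))), 1e-12)
})

test_that("smoothing a constant matrix returns the constant", {
  D <- matrix(3.7, 50, 50)
  expect_equal(local_distance_matrix(D, si_config()), D, tolerance = 1e-12)
})

test_that("an interior unit impulse spreads as 1/sqrt(window length)", {
  D <- matrix(0, 60, 60)
  D[30, 30] <- 1
  L <- local_distance_matrix(D, si_config())
  expect_equal(L[30, 30], sqrt(1 / 51))  # full 25+1+25 window
  # corner cell: truncated window of 26 cells
  D0 <- matrix(0, 60, 60); D0[1, 1] <- 1
  expect_equal(local_distance_matrix(D0, si_config())[1, 1], sqrt(1 / 26))
})

test_that("similarity gating follows the strict alpha threshold", {
  # reference with known quantiles: distances uniform on [0, 1]
  vals <- seq(0, 1, length.out = 2001)
  ref <- songsim:::new_reference(vals, vals, params = "toy", stats = NULL,
                                 provenance = list())
  cfg <- si_config()
  cfg_sig <- songsim:::param_signature(cfg)
  ref$params <- cfg_sig
  D <- matrix(c(0.02, 0.3), 1)       # P(D) = 0.02, 0.3
  L <- matrix(c(0.01, 0.5), 1)       # P(L) = 0.01 (inside), 0.5 (outside)
  S <- similarity_from_distances(D, L, ref, cfg)
  expect_equal(S[1, 1], 1 - 0.02, tolerance = 1e-3)
  expect_equal(S[1, 2], 0)
  # P(L) exactly at alpha is outside the region of similarity: query the
  # stored quantile whose probability is the threshold itself
  cfg$alpha <- ref$probs[51]
  L2 <- matrix(rep(ref$quantiles_L[51], 2), 1)
  S2 <- similarity_from_distances(D, L2, ref, cfg)
  expect_true(all(S2 == 0))
})

test_that("self-comparison has a zero D diagonal and S-dominant diagonal", {
  ref <- fx_ref()
  ft <- fx_tutor_motif()$features
  mats <- similarity_matrices(ft, ft, ref, fx_config())
  expect_true(all(abs(diag(mats$D)) < 1e-5))  # sqrt of fp cancellation
  on_diag <- diag(mats$S)
  for (i in seq(10, nrow(mats$S) - 10, by = 25)) {
    expect_true(all(on_diag[i] >= mats$S[i, ]))
  }
  expect_true(all(mats$S >= 0 & mats$S <= 1))
})
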