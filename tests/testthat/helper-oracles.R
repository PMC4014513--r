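# Independent brute-force oracles, written as literal loops so they share
# no code path with the implementation they check.

# Sum along the full diagonal of the band rows s..e starting at pupil
# column j, for every admissible j.
oracle_diag_sums <- function(S, s, e) {
  nk <- e - s + 1
  n_off <- ncol(S) - nk + 1
  sums <- numeric(n_off)
  for (j in seq_len(n_off)) {
    acc <- 0
    for (r in 0:(nk - 1)) acc <- acc + S[s + r, j + r]
    sums[j] <- acc
  }
  sums
}

# Literal greedy matching: at each iteration recompute every unmatched
# syllable's partial similarity from scratch on the current matrix, pick
# the highest (ties: longer syllable, then lower index; offset ties:
# smallest j), zero matched rows and columns inclusive, repeat. Zero-score
# syllables are placed at the offset overlapping the fewest already-taken
# columns (ties: smallest j).
oracle_greedy <- function(S, syl) {
  ns <- nrow(syl)
  taken <- rep(FALSE, ncol(S))
  out <- data.frame(syllable = seq_len(ns), j1 = NA, j2 = NA, s_max = NA,
                    match_order = NA)
  work <- S
  remaining <- seq_len(ns)
  for (it in seq_len(ns)) {
    best_k <- NA; best_j <- NA; best_score <- -Inf
    for (k in remaining) {
      sums <- oracle_diag_sums(work, syl$s_frame[k], syl$e_frame[k])
      j <- which.max(sums)
      sc <- sums[j]
      nk_k <- syl$e_frame[k] - syl$s_frame[k] + 1
      nk_b <- if (is.na(best_k)) -1 else
        syl$e_frame[best_k] - syl$s_frame[best_k] + 1
      if (sc > best_score || (sc == best_score && nk_k > nk_b)) {
        best_k <- k; best_j <- j; best_score <- sc
      }
    }
    nk <- syl$e_frame[best_k] - syl$s_frame[best_k] + 1
    if (best_score <= 0) {
      n_off <- ncol(S) - nk + 1
      conf <- integer(n_off)
      for (j in seq_len(n_off)) conf[j] <- sum(taken[j:(j + nk - 1)])
      best_j <- which.min(conf)
      best_score <- 0
    }
    out$j1[best_k] <- best_j
    out$j2[best_k] <- best_j + nk - 1
    out$s_max[best_k] <- best_score
    out$match_order[best_k] <- it
    work[syl$s_frame[best_k]:syl$e_frame[best_k], ] <- 0
    work[, out$j1[best_k]:out$j2[best_k]] <- 0
    taken[out$j1[best_k]:out$j2[best_k]] <- TRUE
    remaining <- setdiff(remaining, best_k)
  }
  out
}

# Per-cell diagonal RMS with explicit window truncation at borders.
oracle_local_rms <- function(D, h) {
  M <- nrow(D); N <- ncol(D)
  L <- matrix(0, M, N)
  for (i in seq_len(M)) {
    for (j in seq_len(N)) {
      acc <- 0; cnt <- 0
      for (t in -h:h) {
        if (i + t >= 1 && i + t <= M && j + t >= 1 && j + t <= N) {
          acc <- acc + D[i + t, j + t]^2
          cnt <- cnt + 1
        }
      }
      L[i, j] <- sqrt(acc / cnt)
    }
  }
  L
}

# Strict-less empirical probability.
oracle_prob_less <- function(values, q) mean(values < q)
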