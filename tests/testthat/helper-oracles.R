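# Exhaustive enumeration oracle for the local profile alignment: the best
# score over every order-preserving set of matched index pairs, charging the
# linear gap penalty for positions skipped strictly between consecutive
# matches. Independent of the DP implementation; feasible for profiles of
# length <= 6 (at most choose(12, 6) = 924 chains).
bf_local_align_score <- function(a, b, s_max = 1, m0 = 1, gap = 0.5) {
  n <- length(a)
  m <- length(b)
  sigma <- function(i, j) s_max - abs(a[i] - b[j]) / m0
  best <- 0
  rec <- function(i, j, score) {
    best <<- max(best, score)
    if (i < n && j < m) {
      for (ii in (i + 1):n) {
        for (jj in (j + 1):m) {
          g <- gap * ((ii - i - 1) + (jj - j - 1))
          rec(ii, jj, score + sigma(ii, jj) - g)
        }
      }
    }
  }
  for (i in seq_len(n)) for (j in seq_len(m)) rec(i, j, sigma(i, j))
  best
}

# Recompute an alignment's score from its aligned pairs (integrity check
# that the DP's reported score is achieved by the pairs it returns).
score_from_pairs <- function(a, b, pairs, s_max = 1, m0 = 1, gap = 0.5) {
  if (nrow(pairs) == 0L) return(0)
  sub <- sum(s_max - abs(a[pairs[, 1L]] - b[pairs[, 2L]]) / m0)
  skips <- 0L
  if (nrow(pairs) > 1L) {
    skips <- sum(diff(pairs[, 1L]) - 1L) + sum(diff(pairs[, 2L]) - 1L)
  }
  sub - gap * skips
}
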