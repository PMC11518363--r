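# Independent brute-force running-sum oracle: explicit loop over ranks,
# tracking the maximum absolute deviation with the positive-then-earlier
# tie-break.  Deliberately scalar so it shares no code with the package's
# vectorized implementations.
bruteEs <- function(hits) {
  N <- length(hits)
  G <- sum(hits)
  s <- 0
  best <- 0
  bestRank <- NA_integer_
  for (r in seq_len(N)) {
    s <- s + if (hits[r]) 1 / G else -1 / (N - G)
    better <- abs(s) > abs(best) + 1e-12 ||
      (abs(abs(s) - abs(best)) <= 1e-12 && s > 0 && best <= 0)
    if (better) {
      best <- s
      bestRank <- r
    }
  }
  list(es = best, peakRank = bestRank, final = s)
}

# a ranked list over n generic miRNA names with strictly decreasing scores
toyRanked <- function(n) RankedList(paste0("hsa-mir-", seq_len(n)), n:1)
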