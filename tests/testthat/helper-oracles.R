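# Independent oracles used to cross-check the package's estimators on
# small instances.  These deliberately use different algorithms
# (1-D optimize, dense grid search, exhaustive enumeration) from the
# implementation they check.

# Penalized Bradley-Terry objective for an ability vector `a` indexed
# like `ids`.
bt_penalized_loglik <- function(a, records, ids, lambda) {
  w <- match(records$winner_id, ids)
  l <- match(records$loser_id, ids)
  sum(plogis(a[w] - a[l], log.p = TRUE)) - lambda * sum(a^2)
}

# Two-player oracle: abilities are (a, -a); maximize over scalar a by
# stats::optimize.
bt_oracle_2 <- function(records, ids, lambda) {
  f <- function(a) bt_penalized_loglik(c(a, -a), records, ids, lambda)
  opt <- optimize(f, c(-20, 20), maximum = TRUE, tol = 1e-10)
  c(opt$maximum, -opt$maximum)
}

# Three-player oracle: dense grid over (a1, a2) with a3 = -a1 - a2
# (the penalized optimum always sums to zero), coarse pass then local
# refinement.
bt_oracle_3 <- function(records, ids, lambda) {
  eval_grid <- function(a1s, a2s) {
    best <- c(-Inf, NA, NA)
    for (a1 in a1s) {
      for (a2 in a2s) {
        v <- bt_penalized_loglik(c(a1, a2, -a1 - a2), records, ids, lambda)
        if (v > best[1]) best <- c(v, a1, a2)
      }
    }
    best
  }
  coarse <- eval_grid(seq(-4, 4, by = 0.05), seq(-4, 4, by = 0.05))
  fine <- eval_grid(seq(coarse[2] - 0.05, coarse[2] + 0.05, by = 5e-4),
                    seq(coarse[3] - 0.05, coarse[3] + 0.05, by = 5e-4))
  c(fine[2], fine[3], -fine[2] - fine[3])
}

# Exhaustive capture oracle: smallest cutoff c whose top-c set contains
# all of true_top.
capture_oracle <- function(candidate_ranks, true_top) {
  ids <- names(candidate_ranks)
  for (c_cut in seq_along(candidate_ranks)) {
    top_set <- ids[candidate_ranks <= c_cut]
    if (all(true_top %in% top_set)) return(c_cut)
  }
  stop("true_top not contained in the candidate id set")
}

# All-pairs round robin resolved by dominance, one record per pair.
round_robin_records <- function(ids, dominance, round = 1L) {
  pairs <- t(combn(ids, 2))
  recs <- lapply(seq_len(nrow(pairs)), function(k) {
    resolve_contest(pairs[k, ], dominance, round = round)
  })
  do.call(rbind, recs)
}
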