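#' Form random contest pairs without replacement
#'
#' Randomly partitions a set of identifiers into unordered pairs.  With
#' an even number of ids every individual appears in exactly one pair;
#' with an odd number exactly one uniformly chosen individual sits the
#' round out.
#'
#' @param ids Character vector of at least 2 identifiers.
#' @return A two-column character matrix, one row per pair.
#' @export
#' @examples
#' set.seed(1)
#' random_pairing(sprintf("M%02d", 1:10))
random_pairing <- function(ids) {
  if (length(ids) < 2L) {
    stop("need at least 2 ids to form a pair", call. = FALSE)
  }
  perm <- sample(ids)
  n_pairs <- length(perm) %/% 2L
  # with odd length the last permuted id (uniform over ids) sits out
  matrix(perm[seq_len(2L * n_pairs)], ncol = 2L, byrow = TRUE,
         dimnames = list(NULL, c("a", "b")))
}

#' Resolve one contest deterministically by true dominance
#'
#' The member of the pair with the strictly larger dominance value wins.
#' Equal dominance is surfaced as an error: it cannot occur in continuous
#' simulations and must not be silently broken.
#'
#' @param pair Character vector of two distinct identifiers.
#' @param dominance Named numeric vector mapping ids to dominance values.
#' @param round Round number attached to the record.
#' @return A one-row `data.frame` with columns `round`, `winner_id`,
#'   `loser_id`.
#' @export
#' @examples
#' resolve_contest(c("A", "B"), c(A = 1.2, B = 0.3), round = 1)
resolve_contest <- function(pair, dominance, round = 1L) {
  if (length(pair) != 2L || pair[1] == pair[2]) {
    stop("`pair` must hold two distinct identifiers", call. = FALSE)
  }
  if (!all(pair %in% names(dominance))) {
    stop("both ids must be present in the dominance map", call. = FALSE)
  }
  d <- dominance[pair]
  if (d[1] == d[2]) {
    stop("tied dominance values for ", pair[1], " and ", pair[2],
         "; contests are resolved deterministically and ties must not occur",
         call. = FALSE)
  }
  w <- if (d[1] > d[2]) 1L else 2L
  data.frame(round = as.integer(round),
             winner_id = pair[w], loser_id = pair[3L - w],
             stringsAsFactors = FALSE)
}

#' Pair individuals by adjacent ranks
#'
#' Pairs the best-ranked with the second best, the third with the
#' fourth, and so on (rank 1 vs 2, 3 vs 4, ...).  With an odd number of
#' identifiers the last (worst-ranked) sits out.  Used for a final
#' refinement round that pits closely matched individuals against each
#' other.
#'
#' @param ranking Character vector of identifiers ordered best to worst.
#' @return A two-column character matrix of pairs.
#' @export
#' @examples
#' rank_adjacent_pairing(c("A", "B", "C", "D"))
rank_adjacent_pairing <- function(ranking) {
  if (length(ranking) < 2L) {
    stop("need at least 2 ranked identifiers to form a pair", call. = FALSE)
  }
  n_pairs <- length(ranking) %/% 2L
  matrix(ranking[seq_len(2L * n_pairs)], ncol = 2L, byrow = TRUE,
         dimnames = list(NULL, c("a", "b")))
}

#' Simulate rounds of randomly paired deterministic contests
#'
#' Stages `n_rounds` rounds.  Each round the (non-excluded) individuals
#' are paired at random without replacement and every contest is won by
#' the member with the higher true dominance.
#'
#' @param ids Identifiers of the competing individuals.
#' @param dominance Named numeric vector of true dominance values
#'   covering `ids`.
#' @param n_rounds Number of rounds to simulate.
#' @param n_pairs Optional cap on the number of pairs fought per round
#'   (defaults to as many as the cohort allows, `floor(n/2)`).
#' @param exclude Optional named list mapping round numbers (as names)
#'   to identifiers excluded from that round (e.g. injured animals).
#' @param start_round Round number of the first simulated round.
#' @return A `data.frame` of contest records: `round`, `winner_id`,
#'   `loser_id`.
#' @export
#' @examples
#' pop <- generate_population(10, male_params(), seed = 1)
#' simulate_contests(pop$id, setNames(pop$true_dominance, pop$id), 2)
simulate_contests <- function(ids, dominance, n_rounds, n_pairs = NULL,
                              exclude = NULL, start_round = 1L) {
  if (!all(ids %in% names(dominance))) {
    stop("all `ids` must be present in the dominance map", call. = FALSE)
  }
  if (n_rounds < 1L) stop("`n_rounds` must be >= 1", call. = FALSE)
  rounds <- seq.int(start_round, length.out = n_rounds)
  out <- vector("list", n_rounds)
  for (i in seq_along(rounds)) {
    r <- rounds[i]
    active <- ids
    if (!is.null(exclude)) {
      off <- exclude[[as.character(r)]]
      if (!is.null(off)) active <- setdiff(active, off)
    }
    pairs <- random_pairing(active)
    if (!is.null(n_pairs) && n_pairs < nrow(pairs)) {
      pairs <- pairs[seq_len(n_pairs), , drop = FALSE]
    }
    recs <- lapply(seq_len(nrow(pairs)), function(k) {
      resolve_contest(pairs[k, ], dominance, round = r)
    })
    out[[i]] <- do.call(rbind, recs)
  }
  do.call(rbind, out)
}
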