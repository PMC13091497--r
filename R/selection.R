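#' Combine trait and contest ranks into a hybrid ranking
#'
#' Scores every individual with the convex combination
#' `h = alpha * trait_rank + (1 - alpha) * contest_rank` and re-ranks by
#' ascending score (smaller h = better, rank 1).  `alpha = 1` reproduces
#' the trait ranking exactly and `alpha = 0` the contest ranking; ties
#' in h are broken by trait rank, then by id.
#'
#' @param trait_ranks Named integer vector mapping ids to trait ranks.
#' @param contest_ranks Named integer vector mapping the same ids to
#'   contest ranks.
#' @param alpha Weight on trait information, in `[0, 1]`.
#' @return Named integer vector of hybrid ranks over the same ids.
#' @export
#' @examples
#' hybrid_rank(c(A = 1, B = 2, C = 3), c(A = 3, B = 1, C = 2), 0.5)
hybrid_rank <- function(trait_ranks, contest_ranks, alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) ||
      alpha < 0 || alpha > 1) {
    stop("`alpha` must be a single number in [0, 1]", call. = FALSE)
  }
  ids <- names(trait_ranks)
  if (is.null(ids) || is.null(names(contest_ranks)) ||
      !setequal(ids, names(contest_ranks)) ||
      length(trait_ranks) != length(contest_ranks)) {
    stop("`trait_ranks` and `contest_ranks` must be named over the same id set",
         call. = FALSE)
  }
  cr <- contest_ranks[ids]
  h <- alpha * as.numeric(trait_ranks) + (1 - alpha) * as.numeric(cr)
  ord <- order(h, trait_ranks, ids)
  ranks <- integer(length(h))
  ranks[ord] <- seq_along(h)
  setNames(ranks, ids)
}

#' Minimum selection cutoff that captures the true top set
#'
#' Given a candidate ranking, returns the smallest cutoff `c` such that
#' the top-`c` candidates contain every member of `true_top` — i.e. the
#' worst (largest) candidate rank held by a true-top member.  This is
#' the cost, in individuals retained, of guaranteeing that no true top
#' performer is missed.
#'
#' @param candidate_ranks Named integer vector mapping ids to candidate
#'   ranks (a permutation of `1:N`).
#' @param true_top Character vector of ids forming the true top set.
#' @return A single integer between `length(true_top)` and `N`.
#' @export
#' @examples
#' min_selected_to_capture(c(A = 2, B = 3, C = 1, D = 5, E = 4), c("A", "B"))
min_selected_to_capture <- function(candidate_ranks, true_top) {
  if (length(true_top) == 0L) {
    stop("`true_top` must be non-empty", call. = FALSE)
  }
  if (!all(true_top %in% names(candidate_ranks))) {
    stop("every member of `true_top` must appear in `candidate_ranks`",
         call. = FALSE)
  }
  as.integer(max(candidate_ranks[true_top]))
}

#' Restrict a population to its best trait ranks before contests
#'
#' Emulates squad pre-selection: only the `keep_n` individuals with the
#' best (smallest) trait ranks are admitted to contests; the rest are
#' removed before any contest takes place.  Because trait rank is a
#' noisy predictor of true dominance, pre-cutting can discard true top
#' performers, making full capture impossible for that cohort.
#'
#' @param population A `population_table` from [generate_population()].
#' @param keep_n Number of individuals to retain.
#' @param k Optional size of the true top set; if supplied and
#'   `keep_n < k`, a warning flags that capture may become impossible.
#' @return The retained subset, original ids and ranks preserved.
#' @export
apply_precut <- function(population, keep_n, k = NULL) {
  n <- nrow(population)
  if (!is.numeric(keep_n) || length(keep_n) != 1L || keep_n < 1 || keep_n > n) {
    stop("`keep_n` must be between 1 and the population size (", n, ")",
         call. = FALSE)
  }
  if (!is.null(k) && keep_n < k) {
    warning("keep_n (", keep_n, ") is smaller than the true top set (", k,
            "); capture may be impossible")
  }
  out <- population[population$trait_rank <= keep_n, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Sweep the hybrid weight grid over contest rounds
#'
#' For every fitted round and every alpha on the grid, combines the
#' trait and contest rankings with [hybrid_rank()] and computes the
#' capture cutoff with [min_selected_to_capture()].  If any member of
#' `true_top` is absent from the ranked id set (possible after a
#' pre-cut), the statistic is undefined and recorded as `NA` for every
#' cell of this sweep.
#'
#' @param trait_ranks Named integer vector of trait ranks over the
#'   competing ids.
#' @param contest_ranks_by_round Named list mapping round numbers (as
#'   names) to named contest-rank vectors over the same ids.
#' @param true_top Ids of the true top performers (defined on the full
#'   population).
#' @param alpha_grid Numeric grid of weights in `[0, 1]`.
#' @return A `data.frame` with columns `round`, `alpha`, `min_selected`
#'   (one row per round x alpha; `min_selected` is `NA` when capture is
#'   impossible).
#' @export
alpha_sweep <- function(trait_ranks, contest_ranks_by_round, true_top,
                        alpha_grid = seq(0, 1, by = 0.1)) {
  if (length(alpha_grid) == 0L) {
    stop("`alpha_grid` must be non-empty", call. = FALSE)
  }
  if (any(alpha_grid < 0 | alpha_grid > 1)) {
    stop("`alpha_grid` values must lie in [0, 1]", call. = FALSE)
  }
  capturable <- all(true_top %in% names(trait_ranks))
  rounds <- as.integer(names(contest_ranks_by_round))
  grid <- expand.grid(alpha = alpha_grid, round = rounds,
                      KEEP.OUT.ATTRS = FALSE)[, c("round", "alpha")]
  grid$min_selected <- NA_integer_
  for (i in seq_len(nrow(grid))) {
    if (!capturable) next
    cr <- contest_ranks_by_round[[as.character(grid$round[i])]]
    hr <- hybrid_rank(trait_ranks, cr, grid$alpha[i])
    grid$min_selected[i] <- min_selected_to_capture(hr, true_top)
  }
  grid
}
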