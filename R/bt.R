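#' Fit a ridge-penalized Bradley-Terry model to win/loss records
#'
#' Estimates per-individual latent abilities from pairwise contest
#' outcomes under the Bradley-Terry model, where the probability that
#' individual i beats individual j is `plogis(a_i - a_j)`.  Abilities
#' maximize the penalized log-likelihood
#'
#'   sum over contests of log plogis(a_winner - a_loser) - lambda * sum(a^2)
#'
#' by Newton ascent with step halving, to a gradient max-norm below
#' `tol`.  The ridge term both fixes the additive-constant
#' non-identifiability (the penalized optimum sums to zero) and keeps
#' estimates finite when the data are separable — i.e. perfectly
#' consistent with a total order, as deterministic contests always are —
#' a situation in which the unpenalized maximum-likelihood estimate
#' diverges.
#'
#' Individuals that appear in no contest are assigned ability exactly 0
#' and are ranked after contested individuals with equal ability.
#'
#' @param records A `data.frame` of contest records with columns
#'   `winner_id` and `loser_id` (a `round` column, if present, is
#'   ignored here; subset the records first for cumulative fits).
#' @param ids Identifiers of all individuals in the cohort, contested or
#'   not.
#' @param penalty Ridge weight lambda >= 0.  The default 0.1 keeps
#'   estimates finite on separable data while preserving their order.
#'   With `penalty = 0` a fit on separable data is aborted with an
#'   error.
#' @param round Round number recorded in the output (the cumulative
#'   round the fitted records extend to); informational only.
#' @param tie_break Identifier vector in priority order used to break
#'   exact ability ties (earlier wins).  Defaults to `ids` order.
#' @param max_iter,tol Newton iteration cap and convergence tolerance on
#'   the gradient max-norm.
#'
#' @return A `data.frame` of class `"ability_table"` with columns `id`,
#'   `ability`, `contest_rank`, `n_contests`, `round`.  Abilities sum to
#'   zero; `contest_rank` is a permutation of `1:length(ids)` with rank
#'   1 for the largest ability.
#' @seealso [contest_ranks()] to re-rank an ability table under a
#'   different tie-break order.
#' @export
#' @examples
#' rec <- data.frame(winner_id = c("A", "B"), loser_id = c("B", "C"))
#' fit_bradley_terry(rec, ids = c("A", "B", "C"))
fit_bradley_terry <- function(records, ids, penalty = 0.1,
                              round = NA_integer_, tie_break = ids,
                              max_iter = 200L, tol = 1e-8) {
  if (is.null(records) || nrow(records) == 0L) {
    stop("cannot fit a Bradley-Terry model to an empty record set",
         call. = FALSE)
  }
  if (anyDuplicated(ids)) stop("`ids` must be unique", call. = FALSE)
  if (!is.numeric(penalty) || length(penalty) != 1L || penalty < 0) {
    stop("`penalty` must be a single number >= 0", call. = FALSE)
  }
  w <- match(records$winner_id, ids)
  l <- match(records$loser_id, ids)
  if (anyNA(w) || anyNA(l)) {
    stop("records reference ids not present in `ids`", call. = FALSE)
  }
  if (any(w == l)) {
    stop("records contain a self-contest (winner_id == loser_id)",
         call. = FALSE)
  }
  n <- length(ids)
  n_contests <- tabulate(c(w, l), nbins = n)

  obj <- function(a) {
    sum(plogis(a[w] - a[l], log.p = TRUE)) - penalty * sum(a^2)
  }

  a <- numeric(n)
  f <- obj(a)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    p <- plogis(a[w] - a[l])
    res <- 1 - p
    g <- numeric(n)
    gs <- rowsum(c(res, -res), c(w, l))
    g[as.integer(rownames(gs))] <- gs[, 1L]
    g <- g - 2 * penalty * a
    if (max(abs(g)) < tol) {
      converged <- TRUE
      break
    }
    # negative Hessian, accumulated contest-wise: O(m) per iteration
    v <- p * res
    H <- matrix(0, n, n)
    dv <- rowsum(c(v, v), c(w, l))
    diag(H)[as.integer(rownames(dv))] <- dv[, 1L]
    off <- rowsum(c(v, v), c(w + (l - 1L) * n, l + (w - 1L) * n))
    H[as.integer(rownames(off))] <- H[as.integer(rownames(off))] - off[, 1L]
    diag(H) <- diag(H) + 2 * penalty + 1e-12
    step <- solve(H, g)
    # step halving keeps the ascent monotone
    t_step <- 1
    repeat {
      a_new <- a + t_step * step
      f_new <- obj(a_new)
      if (is.finite(f_new) && f_new >= f - 1e-12) break
      t_step <- t_step / 2
      if (t_step < 1e-10) break
    }
    a <- a_new
    f <- f_new
    if (penalty == 0 && max(abs(a)) > 30) {
      stop("abilities diverged: the records are separable (perfectly ",
           "consistent with a total order) and the unpenalized ",
           "likelihood has no finite maximum; refit with `penalty` > 0",
           call. = FALSE)
    }
  }
  if (penalty == 0 && (!converged || max(abs(a)) > 15)) {
    # separable data: the likelihood keeps improving as abilities run
    # off to +/- infinity, so either the gradient never reaches the
    # tolerance or it does only because every fitted probability has
    # saturated at extreme abilities
    stop("no finite maximum-likelihood estimate at penalty = 0: the ",
         "records are separable (perfectly consistent with a total ",
         "order) — refit with `penalty` > 0", call. = FALSE)
  }
  if (!converged) {
    warning("Bradley-Terry fit stopped after ", max_iter,
            " iterations before reaching the gradient tolerance")
  }
  # the penalized optimum sums to zero; enforce exactly, keeping
  # uncontested individuals pinned at 0
  contested <- n_contests > 0L
  a[!contested] <- 0
  if (any(contested)) a[contested] <- a[contested] - mean(a[contested])

  out <- data.frame(id = ids, ability = a, contest_rank = NA_integer_,
                    n_contests = n_contests, round = as.integer(round),
                    stringsAsFactors = FALSE)
  out$contest_rank <- contest_ranks(out, tie_break = tie_break)
  class(out) <- c("ability_table", "data.frame")
  out
}

#' Fit a Bradley-Terry model by (unpenalized) maximum likelihood
#'
#' The classical maximum-likelihood Bradley-Terry fit, computed as a
#' logistic regression on the winner-minus-loser incidence design with
#' [stats::glm.fit()] (the computation standard Bradley-Terry software
#' performs), with the first individual as the reference.
#'
#' Deterministically resolved contests are always *separable* — the
#' records are perfectly consistent with a total order — so the
#' likelihood has no finite maximum and the iteratively reweighted
#' least-squares estimates grow until the iteration cap stops them.  The
#' returned abilities are then the finite-iteration estimates: their
#' magnitudes are meaningless and depend on `maxit`, but their *order*
#' is the ranking such software reports, and ranks are the quantity this
#' package consumes.  `attr(result, "converged")` records whether the
#' IRLS converged.  For abilities with stable magnitudes use
#' [fit_bradley_terry()] with a positive penalty.
#'
#' @inheritParams fit_bradley_terry
#' @param maxit IRLS iteration cap (the conventional default is 25).
#' @return An `"ability_table"` like [fit_bradley_terry()]'s.
#' @export
fit_bradley_terry_ml <- function(records, ids, round = NA_integer_,
                                 tie_break = ids, maxit = 25L) {
  if (is.null(records) || nrow(records) == 0L) {
    stop("cannot fit a Bradley-Terry model to an empty record set",
         call. = FALSE)
  }
  if (anyDuplicated(ids)) stop("`ids` must be unique", call. = FALSE)
  w <- match(records$winner_id, ids)
  l <- match(records$loser_id, ids)
  if (anyNA(w) || anyNA(l)) {
    stop("records reference ids not present in `ids`", call. = FALSE)
  }
  if (any(w == l)) {
    stop("records contain a self-contest (winner_id == loser_id)",
         call. = FALSE)
  }
  n <- length(ids)
  m <- nrow(records)
  X <- matrix(0, m, n)
  X[cbind(seq_len(m), w)] <- 1
  X[cbind(seq_len(m), l)] <- X[cbind(seq_len(m), l)] - 1
  fit <- suppressWarnings(
    glm.fit(X[, -1L, drop = FALSE], rep(1, m),
            family = binomial(), control = list(maxit = maxit))
  )
  a <- c(0, fit$coefficients)
  a[is.na(a)] <- 0                       # aliased (e.g. uncontested)
  n_contests <- tabulate(c(w, l), nbins = n)
  contested <- n_contests > 0L
  a[!contested] <- 0
  if (any(contested)) a[contested] <- a[contested] - mean(a[contested])

  out <- data.frame(id = ids, ability = a, contest_rank = NA_integer_,
                    n_contests = n_contests, round = as.integer(round),
                    stringsAsFactors = FALSE)
  out$contest_rank <- contest_ranks(out, tie_break = tie_break)
  class(out) <- c("ability_table", "data.frame")
  attr(out, "converged") <- fit$converged
  out
}

#' Convert fitted abilities to contest ranks
#'
#' Ranks individuals by descending ability (rank 1 = largest).  Exact
#' ties are broken first in favour of individuals that have actually
#' contested (over uncontested individuals pinned at ability 0), then by
#' the `tie_break` priority order.
#'
#' @param abilities An ability table as returned by
#'   [fit_bradley_terry()]: a `data.frame` with columns `id` and
#'   `ability` (and optionally `n_contests`).
#' @param tie_break Identifier vector in priority order (earlier wins
#'   ties); must cover every id.
#' @return A named integer vector of ranks (names are ids), a
#'   permutation of `1:nrow(abilities)`.
#' @export
contest_ranks <- function(abilities, tie_break = abilities$id) {
  if (anyNA(abilities$ability)) {
    stop("every individual must have a fitted ability", call. = FALSE)
  }
  priority <- match(abilities$id, tie_break)
  if (anyNA(priority)) {
    stop("`tie_break` must contain every id in `abilities`", call. = FALSE)
  }
  uncontested <- if ("n_contests" %in% names(abilities)) {
    abilities$n_contests == 0L
  } else {
    rep(FALSE, nrow(abilities))
  }
  ord <- order(-abilities$ability, uncontested, priority)
  ranks <- integer(nrow(abilities))
  ranks[ord] <- seq_len(nrow(abilities))
  setNames(ranks, abilities$id)
}
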