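#' Configuration for a replicate contest-selection experiment
#'
#' Collects every tunable of the simulation study.  The defaults
#' reproduce the reference design: populations of 100 per sex, 20
#' replicate simulations, 20 rounds of 50 random pairs, Bradley-Terry
#' fits on cumulative records every second round, an 11-point alpha
#' grid, a true top set of 10% of the population, and a pre-cut scenario
#' that admits only the top 40 trait ranks to contests.
#'
#' @param n_individuals Population size per sex and replicate.
#' @param n_replicates Number of replicate simulations per sex.
#' @param n_rounds Rounds of contests per replicate.
#' @param fit_rounds Rounds at which the Bradley-Terry model is fitted
#'   to the cumulative records (must lie in `1:n_rounds`).
#' @param pairs_per_round Pairs fought per round; `NULL` means as many
#'   as the cohort allows (`floor(n/2)`).
#' @param alpha_grid Hybrid weights evaluated (each in `[0, 1]`).
#' @param true_top_fraction Fraction of the population forming the true
#'   top set; `true_top_fraction * n_individuals` must round to a
#'   positive integer.
#' @param precut_keep Cohort size retained in the pre-cut scenario.
#' @param bt_penalty Bradley-Terry estimator choice: `0` (the default)
#'   ranks by the classical maximum-likelihood fit of
#'   [fit_bradley_terry_ml()] — the computation standard Bradley-Terry
#'   software performs, and the reference estimator for this design —
#'   while a positive value ranks by the ridge-penalized fit of
#'   [fit_bradley_terry()] with that penalty.
#' @param sex_params Named list of [sex_params()] objects, one per sex.
#' @param master_seed Integer master seed; per-sex, per-replicate
#'   streams are derived from it so replicates are reproducible and
#'   order-independent.
#' @return A validated list of class `"sim_config"`.
#' @export
sim_config <- function(n_individuals = 100, n_replicates = 20, n_rounds = 20,
                       fit_rounds = seq(2, n_rounds, by = 2),
                       pairs_per_round = NULL,
                       alpha_grid = seq(0, 1, by = 0.1),
                       true_top_fraction = 0.1,
                       precut_keep = 40,
                       bt_penalty = 0,
                       sex_params = list(male = male_params(),
                                         female = female_params()),
                       master_seed = 1L) {
  stopifnot(n_individuals >= 2, n_replicates >= 1, n_rounds >= 1)
  if (!all(fit_rounds %in% seq_len(n_rounds))) {
    stop("`fit_rounds` must lie within 1..n_rounds", call. = FALSE)
  }
  k <- round(true_top_fraction * n_individuals)
  if (k < 1) {
    stop("`true_top_fraction` must select at least one individual",
         call. = FALSE)
  }
  if (precut_keep > n_individuals) {
    stop("`precut_keep` cannot exceed the population size", call. = FALSE)
  }
  if (any(alpha_grid < 0 | alpha_grid > 1)) {
    stop("`alpha_grid` values must lie in [0, 1]", call. = FALSE)
  }
  if (!all(vapply(sex_params, inherits, TRUE, what = "sex_params"))) {
    stop("`sex_params` must be a named list of sex_params() objects",
         call. = FALSE)
  }
  structure(
    list(n_individuals = as.integer(n_individuals),
         n_replicates = as.integer(n_replicates),
         n_rounds = as.integer(n_rounds),
         fit_rounds = as.integer(fit_rounds),
         pairs_per_round = if (is.null(pairs_per_round)) NULL
                           else as.integer(pairs_per_round),
         alpha_grid = as.numeric(alpha_grid),
         true_top_fraction = true_top_fraction,
         true_top_k = as.integer(k),
         precut_keep = as.integer(precut_keep),
         bt_penalty = bt_penalty,
         sex_params = sex_params,
         master_seed = as.integer(master_seed)),
    class = "sim_config"
  )
}

# Rank engine used by the pipelines: penalty 0 = reference
# maximum-likelihood fit, penalty > 0 = converged ridge fit.
bt_fit_dispatch <- function(records, ids, penalty, round, tie_break) {
  if (penalty == 0) {
    fit_bradley_terry_ml(records, ids, round = round, tie_break = tie_break)
  } else {
    fit_bradley_terry(records, ids, penalty = penalty, round = round,
                      tie_break = tie_break)
  }
}

# Derive a per-(sex, replicate) stream seed from the master seed so that
# replicates are reproducible independently of execution order.
derive_seed <- function(master_seed, sex, replicate_index) {
  sex_i <- match(sex, c("male", "female"))
  if (is.na(sex_i)) sex_i <- 3L
  as.integer((as.numeric(master_seed) %% 1e6 * 1009 +
                sex_i * 97561 + replicate_index * 7919) %% 2147483647)
}

#' Run one replicate of the selection experiment
#'
#' Generates a population, simulates one stream of randomly paired
#' contests, fits the Bradley-Terry model on cumulative records at
#' every fit round, and sweeps the alpha grid.  The pre-cut scenario
#' analyses the same contest stream restricted to bouts in which both
#' contestants survived the trait-rank cut, and its capture target is
#' the true top `k` by dominance among the retained individuals (for
#' the full scenario, the population top `k`).  Emits one pre-contest
#' trait-only row (encoded as `round = 0`, `alpha = 1`: the hybrid at
#' `alpha = 1` is the trait ranking for any round, and no contest data
#' exist before round 1) plus one row per scenario x fit round x alpha.
#'
#' @param config A [sim_config()].
#' @param sex Which sex's parameters to use (must name an entry of
#'   `config$sex_params`).
#' @param replicate_index Replicate number (1-based); combined with the
#'   master seed to derive this replicate's RNG stream.
#' @param scenarios Character subset of
#'   `c("all_individuals", "precut_top40")`.
#' @return A `data.frame` with columns `replicate`, `sex`, `scenario`,
#'   `round`, `alpha`, `min_selected` (`NA` where a pre-cut removed a
#'   true-top member and capture was impossible).
#' @export
run_replicate <- function(config, sex, replicate_index,
                          scenarios = c("all_individuals", "precut_top40")) {
  stopifnot(inherits(config, "sim_config"))
  params <- config$sex_params[[sex]]
  if (is.null(params)) {
    stop("no parameters configured for sex \"", sex, "\"", call. = FALSE)
  }
  scenarios <- match.arg(scenarios, several.ok = TRUE)
  set.seed(derive_seed(config$master_seed, sex, replicate_index))

  pop <- generate_population(config$n_individuals, params)
  k <- config$true_top_k
  true_top <- pop$id[pop$true_rank <= k]
  trait_ranks <- setNames(pop$trait_rank, pop$id)
  tie_break <- pop$id[order(pop$trait_rank)]
  dominance <- setNames(pop$true_dominance, pop$id)

  rows <- list(
    data.frame(replicate = as.integer(replicate_index), sex = sex,
               scenario = "all_individuals", round = 0L, alpha = 1,
               min_selected = min_selected_to_capture(trait_ranks, true_top),
               stringsAsFactors = FALSE)
  )

  # one shared contest stream per replicate: the pre-cut scenario
  # analyses the same contests, restricted to bouts where both
  # contestants survived the cut
  records_full <- simulate_contests(pop$id, dominance, config$n_rounds,
                                    n_pairs = config$pairs_per_round)

  for (scenario in scenarios) {
    if (scenario == "precut_top40") {
      cohort <- apply_precut(pop, config$precut_keep)
    } else {
      cohort <- pop
    }
    ids_s <- cohort$id
    # the capture target is the true top k of the cohort actually in
    # play: for the full scenario the population top k, after a pre-cut
    # the top k by true dominance among the retained individuals
    true_top_s <- cohort$id[rank_values(setNames(cohort$true_dominance,
                                                 cohort$id)) <= k]
    records <- records_full[records_full$winner_id %in% ids_s &
                              records_full$loser_id %in% ids_s, ,
                            drop = FALSE]
    cr_by_round <- list()
    for (r in config$fit_rounds) {
      fit <- bt_fit_dispatch(records[records$round <= r, , drop = FALSE],
                             ids = ids_s, penalty = config$bt_penalty,
                             round = r,
                             tie_break = tie_break[tie_break %in% ids_s])
      cr_by_round[[as.character(r)]] <- setNames(fit$contest_rank, fit$id)
    }
    sweep <- alpha_sweep(trait_ranks[ids_s], cr_by_round, true_top_s,
                         config$alpha_grid)
    rows[[length(rows) + 1L]] <- data.frame(
      replicate = as.integer(replicate_index), sex = sex, scenario = scenario,
      round = sweep$round, alpha = sweep$alpha,
      min_selected = sweep$min_selected, stringsAsFactors = FALSE
    )
  }
  do.call(rbind, rows)
}

#' Run the full replicate experiment
#'
#' Loops [run_replicate()] over sexes and replicate indices and binds
#' the per-replicate selection curves.
#'
#' @inheritParams run_replicate
#' @param sexes Sexes to simulate (names into `config$sex_params`).
#' @param verbose Print one progress line per replicate.
#' @return A long-format `data.frame` of selection-curve rows.
#' @export
run_experiment <- function(config, sexes = names(config$sex_params),
                           scenarios = c("all_individuals", "precut_top40"),
                           verbose = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  out <- list()
  for (sex in sexes) {
    for (rep_i in seq_len(config$n_replicates)) {
      if (verbose) {
        message(sprintf("replicate %d/%d (%s)", rep_i,
                        config$n_replicates, sex))
      }
      out[[length(out) + 1L]] <- run_replicate(config, sex, rep_i, scenarios)
    }
  }
  do.call(rbind, out)
}

#' Aggregate selection curves across replicates
#'
#' Per (sex, scenario, round, alpha) cell: mean, standard error, and a
#' t-based confidence interval `mean +/- t(df = n-1) * sem` across the
#' replicates that produced a defined value.  Replicates whose value is
#' undefined (true-top member removed by a pre-cut) are excluded from
#' the cell and counted in `n_excluded`.
#'
#' @param rows Selection-curve rows from [run_experiment()].
#' @param conf_level Confidence level of the interval (default 0.95).
#' @return A `data.frame` with columns `sex`, `scenario`, `round`,
#'   `alpha`, `mean_min_selected`, `sem`, `ci_low`, `ci_high`,
#'   `n_effective`, `n_excluded`.
#' @export
summarize_selection <- function(rows, conf_level = 0.95) {
  key <- interaction(rows$sex, rows$scenario, rows$round, rows$alpha,
                     drop = TRUE)
  cells <- lapply(split(rows, key), function(cell) {
    vals <- cell$min_selected[!is.na(cell$min_selected)]
    n_eff <- length(vals)
    if (n_eff < 2L) {
      stop(sprintf(
        "cell (sex=%s, scenario=%s, round=%s, alpha=%s) has %d defined value(s); need >= 2",
        cell$sex[1], cell$scenario[1], cell$round[1], cell$alpha[1], n_eff),
        call. = FALSE)
    }
    m <- mean(vals)
    sem <- sd(vals) / sqrt(n_eff)
    half <- qt(1 - (1 - conf_level) / 2, df = n_eff - 1) * sem
    data.frame(sex = cell$sex[1], scenario = cell$scenario[1],
               round = cell$round[1], alpha = cell$alpha[1],
               mean_min_selected = m, sem = sem,
               ci_low = m - half, ci_high = m + half,
               n_effective = n_eff,
               n_excluded = nrow(cell) - n_eff,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, cells)
  out <- out[order(out$sex, out$scenario, out$round, out$alpha), ]
  rownames(out) <- NULL
  out
}

#' Best hybrid weight for a given round
#'
#' Returns the grid alpha minimizing the replicate-mean capture cutoff
#' for one (sex, scenario, round) cell set, with ties broken toward the
#' larger alpha (more weight on the cheap-to-measure traits).
#'
#' @param summary Output of [summarize_selection()].
#' @param sex,scenario,round Cell coordinates.
#' @param alpha_grid The grid that must be fully present (default the
#'   11-point grid).
#' @return A list with elements `alpha` and `mean`.
#' @export
find_optimal_alpha <- function(summary, sex, scenario, round,
                               alpha_grid = seq(0, 1, by = 0.1)) {
  cells <- summary[summary$sex == sex & summary$scenario == scenario &
                     summary$round == round, , drop = FALSE]
  present <- vapply(alpha_grid, function(a) {
    any(abs(cells$alpha - a) < 1e-9)
  }, TRUE)
  if (!all(present)) {
    stop("missing alpha cells for (", sex, ", ", scenario, ", round ", round,
         "): ", paste(alpha_grid[!present], collapse = ", "), call. = FALSE)
  }
  cells <- cells[order(cells$mean_min_selected, -cells$alpha), ]
  list(alpha = cells$alpha[1], mean = cells$mean_min_selected[1])
}
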