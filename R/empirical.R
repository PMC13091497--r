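#' First principal component of the claw dimensions
#'
#' Reduces the seven highly correlated claw measurements (propodus
#' widths at the carpus and dactyl joints, pollex and dactylus widths,
#' propodus, pollex and dactylus lengths) of one claw to a single size
#' score: PC1 of the column-standardized table (correlation-based PCA,
#' since widths and lengths live on different scales).  Scores are
#' oriented so that larger claws get larger scores; with well-behaved
#' claw data all loadings share one sign.
#'
#' @param dim_table Numeric matrix or data.frame, one row per
#'   individual, one column per claw dimension (at least 3 rows).
#' @return A list with `scores` (per-individual PC1 score), `loadings`
#'   (per-dimension weights), and `var_explained` (percentage of total
#'   variance carried by PC1).
#' @export
claw_size_pc1 <- function(dim_table) {
  x <- as.matrix(dim_table)
  if (nrow(x) < 3L) {
    stop("need at least 3 individuals for a PCA", call. = FALSE)
  }
  if (anyNA(x)) stop("claw dimensions must be complete", call. = FALSE)
  sds <- apply(x, 2L, sd)
  if (any(sds == 0)) {
    stop("constant claw dimension column(s): ",
         paste(colnames(x)[sds == 0], collapse = ", "),
         "; PCA on the correlation scale is degenerate", call. = FALSE)
  }
  pc <- prcomp(x, center = TRUE, scale. = TRUE)
  scores <- pc$x[, 1L]
  loadings <- pc$rotation[, 1L]
  if (sum(loadings) < 0) {          # orient: bigger claws -> bigger score
    scores <- -scores
    loadings <- -loadings
  }
  if (length(unique(sign(loadings[loadings != 0]))) > 1L) {
    warning("PC1 loadings do not share one sign; PC1 may not be a pure size axis")
  }
  list(scores = unname(scores), loadings = loadings,
       var_explained = 100 * pc$sdev[1L]^2 / sum(pc$sdev^2))
}

#' Summarize repeated strength trials into one claw-strength value
#'
#' An individual's claw strength is the mean of the maximum force (in
#' newtons) produced by the left and the right claw across all trials
#' and days: `mean(max(left), max(right))`.
#'
#' @param trials_left,trials_right Numeric vectors of force readings,
#'   at least one per claw.
#' @return A single numeric strength value.
#' @export
#' @examples
#' claw_strength_summary(c(5, 7, 6), c(8, 4, 4))  # (7 + 8) / 2 = 7.5
claw_strength_summary <- function(trials_left, trials_right) {
  if (length(trials_left) == 0L || length(trials_right) == 0L) {
    stop("need at least one strength reading per claw", call. = FALSE)
  }
  if (anyNA(trials_left) || anyNA(trials_right)) {
    stop("strength readings must not contain NA", call. = FALSE)
  }
  mean(c(max(trials_left), max(trials_right)))
}

#' Sex-specific composite trait score
#'
#' Equally weighted sum of the standardized traits that best predict
#' contest success in each sex: claw size + claw strength for males,
#' body length + claw strength for females.
#'
#' @param sex `"male"` or `"female"` (vectorized alongside the traits).
#' @param body_length,claw_size,claw_strength Standardized trait values;
#'   only the components required for the given sex need be supplied.
#' @return Numeric trait score(s).
#' @export
#' @examples
#' composite_trait_score("male", claw_size = 1, claw_strength = -0.5)
composite_trait_score <- function(sex, body_length = NULL, claw_size = NULL,
                                  claw_strength = NULL) {
  if (!all(sex %in% c("male", "female"))) {
    stop("`sex` must be \"male\" or \"female\"", call. = FALSE)
  }
  need <- function(x, nm) {
    if (is.null(x) || anyNA(x)) {
      stop("missing trait component `", nm, "` for this sex", call. = FALSE)
    }
    x
  }
  out <- numeric(length(sex))
  if (any(sex == "male")) {
    out[sex == "male"] <-
      need(claw_size, "claw_size")[sex == "male"] +
      need(claw_strength, "claw_strength")[sex == "male"]
  }
  if (any(sex == "female")) {
    out[sex == "female"] <-
      need(body_length, "body_length")[sex == "female"] +
      need(claw_strength, "claw_strength")[sex == "female"]
  }
  out
}

# standardize to mean 0, sd 1
.standardize <- function(x) as.numeric(scale(x))

#' Derive standardized traits, composite scores and trait ranks from
#' raw measurements
#'
#' Runs the raw-measurement pipeline within each sex: body length is
#' standardized; each claw's seven dimensions are reduced to a PC1 size
#' score (left and right separately, see [claw_size_pc1()]) and the two
#' sides averaged; strength trials are summarized with
#' [claw_strength_summary()].  Claw size and strength are standardized
#' within sex, the sex-specific composite score is formed, and trait
#' ranks are assigned (rank 1 = best, ties broken by id).
#'
#' @param raw A raw trait table as produced by
#'   [generate_empirical_fixture()] or read with [read_traits()]:
#'   columns `id`, `sex`, `body_length`, 7 `left_`/`right_` claw
#'   dimension columns each, and one or more `left_strength_`/
#'   `right_strength_` trial columns.
#' @return A `data.frame` with columns `id`, `sex`, `body_length_std`,
#'   `claw_size`, `claw_strength`, `trait_score`, `trait_rank` (ranks
#'   within sex); PC1 percent variance explained per sex and side is
#'   attached as attribute `"pc1_var_explained"`.
#' @export
derive_traits <- function(raw) {
  dims <- claw_dimension_names()
  left_cols <- paste0("left_", dims)
  right_cols <- paste0("right_", dims)
  sl_cols <- grep("^left_strength_", names(raw), value = TRUE)
  sr_cols <- grep("^right_strength_", names(raw), value = TRUE)
  needed <- c("id", "sex", "body_length", left_cols, right_cols)
  if (!all(needed %in% names(raw)) || length(sl_cols) == 0L ||
      length(sr_cols) == 0L) {
    stop("raw trait table is missing required columns", call. = FALSE)
  }
  pc_var <- list()
  pieces <- lapply(split(raw, raw$sex), function(chunk) {
    sex <- chunk$sex[1]
    pc_l <- claw_size_pc1(chunk[, left_cols])
    pc_r <- claw_size_pc1(chunk[, right_cols])
    pc_var[[sex]] <<- c(left = pc_l$var_explained,
                        right = pc_r$var_explained)
    strength_raw <- vapply(seq_len(nrow(chunk)), function(i) {
      claw_strength_summary(as.numeric(chunk[i, sl_cols]),
                            as.numeric(chunk[i, sr_cols]))
    }, numeric(1))
    out <- data.frame(
      id = chunk$id, sex = sex,
      body_length_std = .standardize(chunk$body_length),
      claw_size = .standardize((pc_l$scores + pc_r$scores) / 2),
      claw_strength = .standardize(strength_raw),
      stringsAsFactors = FALSE
    )
    out$trait_score <- composite_trait_score(
      out$sex, body_length = out$body_length_std,
      claw_size = out$claw_size, claw_strength = out$claw_strength
    )
    out$trait_rank <- rank_values(setNames(out$trait_score, out$id),
                                  tie_break = sort(out$id))
    out
  })
  res <- do.call(rbind, pieces)
  rownames(res) <- NULL
  attr(res, "pc1_var_explained") <- pc_var
  res
}

#' Capture trajectory of the top performers across contest rounds
#'
#' For a single-sex cohort, tracks how many individuals must be
#' selected to capture the eventual top `k` as contest evidence
#' accumulates.  The "true" top set is defined by the Bradley-Terry
#' ranking fitted to all records up to the final fit round (so the
#' final-round value equals `k` by construction — the candidate ranking
#' is then the ranking that defines the truth).  The pre-contest value
#' (round 0) uses trait ranks alone.
#'
#' @param records Contest records (`round`, `winner_id`, `loser_id`)
#'   for this cohort, covering at least `max(fit_rounds)` rounds.
#' @param derived Single-sex output of [derive_traits()].
#' @param fit_rounds Rounds at which cumulative Bradley-Terry fits are
#'   evaluated.
#' @param k Size of the top set to capture.
#' @param penalty Bradley-Terry estimator choice: `0` (default) uses
#'   the reference maximum-likelihood fit of [fit_bradley_terry_ml()],
#'   a positive value the ridge fit of [fit_bradley_terry()].
#' @return A `data.frame` with columns `round` (0 = pre-contest,
#'   trait-only) and `min_selected`.
#' @export
capture_trajectory <- function(records, derived,
                               fit_rounds = c(2, 4, 6, 8, 10, 11),
                               k = 3, penalty = 0) {
  if (length(unique(derived$sex)) != 1L) {
    stop("`derived` must hold a single-sex cohort; filter first",
         call. = FALSE)
  }
  ids <- derived$id
  if (k < 1 || k > length(ids)) {
    stop("`k` must be between 1 and the cohort size", call. = FALSE)
  }
  records <- records[records$winner_id %in% ids | records$loser_id %in% ids, ,
                     drop = FALSE]
  if (!all(c(records$winner_id, records$loser_id) %in% ids)) {
    stop("contest records mix cohorts; both contestants must be in `derived`",
         call. = FALSE)
  }
  final_round <- max(fit_rounds)
  if (max(records$round) < final_round) {
    stop("records must cover every fit round (need round ", final_round, ")",
         call. = FALSE)
  }
  tie_break <- derived$id[order(derived$trait_rank)]
  final_fit <- bt_fit_dispatch(
    records[records$round <= final_round, , drop = FALSE],
    ids = ids, penalty = penalty, round = final_round, tie_break = tie_break
  )
  true_top <- final_fit$id[final_fit$contest_rank <= k]

  trait_ranks <- setNames(derived$trait_rank, derived$id)
  vals <- integer(length(fit_rounds))
  for (i in seq_along(fit_rounds)) {
    fit <- bt_fit_dispatch(
      records[records$round <= fit_rounds[i], , drop = FALSE],
      ids = ids, penalty = penalty, round = fit_rounds[i],
      tie_break = tie_break
    )
    vals[i] <- min_selected_to_capture(setNames(fit$contest_rank, fit$id),
                                       true_top)
  }
  data.frame(
    round = c(0L, as.integer(fit_rounds)),
    min_selected = c(min_selected_to_capture(trait_ranks, true_top), vals)
  )
}

#' Canonical claw dimension names
#'
#' The seven claw measurements taken per claw, in canonical column
#' order.
#' @return Character vector of length 7.
#' @export
claw_dimension_names <- function() {
  c("propodus_width_carpus", "propodus_width_dactyl",
    "pollex_width", "dactylus_width",
    "propodus_length", "pollex_length", "dactylus_length")
}
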