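#' Rank values, largest first, with deterministic tie-breaking
#'
#' Shared ranking convention: rank 1 is assigned to the largest value
#' ("best"), and exact ties are broken deterministically so that every
#' ranking is a permutation of `1:N`.
#'
#' @param values Numeric vector to rank.
#' @param tie_break Either a numeric priority vector parallel to
#'   `values` (smaller priority wins ties; defaults to input position),
#'   or a character vector of identifiers in priority order, matched
#'   against `names(values)` (an identifier listed earlier wins ties).
#'
#' @return An integer vector of ranks, a permutation of
#'   `seq_along(values)`.
#' @export
#' @examples
#' rank_values(c(3, 1, 2))                        # 1 3 2
#' rank_values(c(A = 5, B = 5), c("A", "B"))      # A beats B on the tie
rank_values <- function(values, tie_break = seq_along(values)) {
  n <- length(values)
  if (is.character(tie_break)) {
    if (is.null(names(values))) {
      stop("`values` must be named when `tie_break` is a vector of identifiers",
           call. = FALSE)
    }
    priority <- match(names(values), tie_break)
    if (anyNA(priority)) {
      stop("every name of `values` must appear in `tie_break`", call. = FALSE)
    }
  } else {
    if (length(tie_break) != n) {
      stop("`values` and `tie_break` must have equal length", call. = FALSE)
    }
    priority <- as.numeric(tie_break)
  }
  if (anyNA(values)) stop("`values` must not contain NA", call. = FALSE)
  ord <- order(-as.numeric(values), priority)
  ranks <- integer(n)
  ranks[ord] <- seq_len(n)
  names(ranks) <- names(values)
  ranks
}

#' Generate a simulated population with traits and true dominance
#'
#' Draws a cohort of `n` individuals from the standardized trait chain:
#' body length is standard normal, claw size adds Gaussian noise to body
#' length, claw strength adds further noise to claw size.  The composite
#' trait score is the equally weighted sum of the configured trait
#' components, and true dominance — the latent value that decides every
#' simulated contest — adds one final layer of noise to the standardized
#' (mean 0, sd 1) trait predictor, so the dominance noise sd measures
#' signal dilution on a common scale across sexes and component choices.
#' Individuals are ranked by trait score (`trait_rank`) and by true
#' dominance (`true_rank`); rank 1 is best, and (probability-zero) ties
#' are broken by id order.
#'
#' Uses the R random number generator; call [set.seed()] (or pass
#' `seed`) for reproducible populations.
#'
#' @param n Number of individuals (at least 2).
#' @param params A [sex_params()] object.
#' @param seed Optional integer seed set before drawing.
#'
#' @return A `data.frame` of class `"population_table"` with columns
#'   `id`, `sex`, `body_length`, `claw_size`, `claw_strength`,
#'   `trait_score`, `trait_rank`, `true_dominance`, `true_rank`.
#' @export
#' @examples
#' pop <- generate_population(100, male_params(), seed = 1)
#' all(pop$trait_score == pop$claw_size + pop$claw_strength)
generate_population <- function(n, params, seed = NULL) {
  if (!inherits(params, "sex_params")) {
    stop("`params` must be created by sex_params()", call. = FALSE)
  }
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 2) {
    stop("`n` must be a single integer >= 2", call. = FALSE)
  }
  n <- as.integer(n)
  if (!is.null(seed)) set.seed(seed)

  body_length <- rnorm(n)
  claw_size <- body_length + rnorm(n, 0, params$claw_size_noise_sd)
  claw_strength <- claw_size + rnorm(n, 0, params$strength_noise_sd)

  traits <- cbind(body_length = body_length,
                  claw_size = claw_size,
                  claw_strength = claw_strength)
  trait_score <- rowSums(traits[, params$trait_components, drop = FALSE])
  # dominance noise is calibrated on the standardized scale of the trait
  # predictor, so the trait -> dominance signal strength is comparable
  # across sexes and trait-component choices
  predictor <- as.numeric(scale(trait_score))
  true_dominance <- predictor + rnorm(n, 0, params$dominance_noise_sd)

  id <- sprintf("%s%03d", toupper(substr(params$sex, 1L, 1L)), seq_len(n))
  pop <- data.frame(
    id = id,
    sex = params$sex,
    body_length = body_length,
    claw_size = claw_size,
    claw_strength = claw_strength,
    trait_score = trait_score,
    trait_rank = rank_values(trait_score),
    true_dominance = true_dominance,
    true_rank = rank_values(true_dominance),
    stringsAsFactors = FALSE
  )
  class(pop) <- c("population_table", "data.frame")
  pop
}
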