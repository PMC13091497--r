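#' Per-sex simulation parameters
#'
#' Bundles the Gaussian noise standard deviations of the simulated trait
#' chain (body length -> claw size -> claw strength -> true dominance)
#' together with the trait components that enter the composite trait
#' score with equal weight.  All traits live on a standardized scale:
#' body length is standard normal and each downstream trait adds only
#' residual noise around a unit-slope, zero-intercept link.
#'
#' @param sex Cohort label, `"male"` or `"female"`.
#' @param claw_size_noise_sd Standard deviation of the Gaussian noise
#'   added to body length to obtain claw size.
#' @param strength_noise_sd Standard deviation of the noise added to claw
#'   size to obtain claw strength.
#' @param dominance_noise_sd Standard deviation of the noise added to the
#'   composite trait score to obtain true dominance.
#' @param trait_components Character vector naming the traits summed
#'   (with equal weight) into the composite trait score; a non-empty
#'   subset of `"body_length"`, `"claw_size"`, `"claw_strength"`.
#'
#' @return An object of class `"sex_params"` (a named list).
#'
#' @details Noise standard deviations must be non-negative; zero values
#'   are permitted so that degenerate, perfectly deterministic chains can
#'   be constructed in tests.
#'
#' @seealso [male_params()], [female_params()] for the calibrated
#'   defaults of the two Cherax destructor cohorts.
#' @export
#' @examples
#' sex_params("male", 0.26, 0.54, 0.7, c("claw_size", "claw_strength"))
sex_params <- function(sex, claw_size_noise_sd, strength_noise_sd,
                       dominance_noise_sd, trait_components) {
  if (!is.character(sex) || length(sex) != 1L || !sex %in% c("male", "female")) {
    stop("`sex` must be \"male\" or \"female\"", call. = FALSE)
  }
  sds <- c(claw_size_noise_sd = claw_size_noise_sd,
           strength_noise_sd = strength_noise_sd,
           dominance_noise_sd = dominance_noise_sd)
  if (!is.numeric(sds) || length(sds) != 3L || anyNA(sds) ||
      any(!is.finite(sds)) || any(sds < 0)) {
    stop("noise standard deviations must be finite and >= 0", call. = FALSE)
  }
  known <- c("body_length", "claw_size", "claw_strength")
  if (length(trait_components) == 0L || !all(trait_components %in% known)) {
    stop("`trait_components` must be a non-empty subset of: ",
         paste(known, collapse = ", "), call. = FALSE)
  }
  structure(
    list(sex = sex,
         claw_size_noise_sd = as.numeric(claw_size_noise_sd),
         strength_noise_sd = as.numeric(strength_noise_sd),
         dominance_noise_sd = as.numeric(dominance_noise_sd),
         trait_components = unique(trait_components)),
    class = "sex_params"
  )
}

#' Calibrated male and female parameter sets
#'
#' Default parameterizations for the two sexes of *Cherax destructor*:
#' males have claw-size residual sd 0.26 and strength residual sd 0.54,
#' with the composite trait score the equally weighted sum of claw size
#' and claw strength; females have claw-size residual sd 0.22 and
#' strength residual sd 0.69, with the score the sum of body length and
#' claw strength.  Both sexes add dominance noise with sd 0.7.
#'
#' @return A `"sex_params"` object.
#' @export
#' @examples
#' male_params()$trait_components
male_params <- function() {
  sex_params("male", 0.26, 0.54, 0.7, c("claw_size", "claw_strength"))
}

#' @rdname male_params
#' @export
female_params <- function() {
  sex_params("female", 0.22, 0.69, 0.7, c("body_length", "claw_strength"))
}
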