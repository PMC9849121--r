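#' The EAT-R factor taxonomy
#'
#' Ten qualitative factors that shape agricultural soil exposure, grouped
#' into four classes: Environmental (natural conditions; the social/built
#' farm environment), meso-Activity (crop type, growing practices, ergonomic
#' positioning), Timing (season, day of week, time of day) and Receptor
#' (behavioral, biological). Each factor is permitted to act only on a fixed
#' set of quantitative dose-model inputs — for example, natural conditions
#' may alter the soil intake rate and the soil-to-skin adherence factor, but
#' never the receptor's body weight. [validate_modifier()] enforces this
#' mapping.
#'
#' @return A tibble with columns `class` (factor class), `factor` (factor
#'   name) and `targets` (list column of permitted dose-model parameter
#'   names).
#' @examples
#' eatr_factors()
#' @export
eatr_factors <- function() {
  tibble(
    class = c(
      "environmental", "environmental",
      "activity", "activity", "activity",
      "timing", "timing", "timing",
      "receptor", "receptor"
    ),
    factor = c(
      "natural", "social_built",
      "crop_type", "growing_practices", "ergonomic_positioning",
      "season", "day_of_week", "time_of_day",
      "behavioral", "biological"
    ),
    targets = list(
      c("intake_rate", "adherence_factor"),
      c("exposure_factor"),
      c("intake_rate", "exposure_factor", "exposure_frequency",
        "exposure_duration"),
      c("intake_rate", "exposure_frequency", "exposure_duration"),
      c("intake_rate", "surface_area"),
      c("intake_rate", "exposure_factor", "averaging_time"),
      c("exposure_factor", "averaging_time"),
      c("intake_rate", "adherence_factor"),
      c("intake_rate", "adherence_factor"),
      c("intake_rate", "surface_area", "body_weight")
    )
  )
}

eatr_classes <- c("environmental", "activity", "timing", "receptor")

factor_class <- function(factor) {
  tax <- eatr_factors()
  idx <- match(factor, tax$factor)
  if (anyNA(idx)) {
    abort(sprintf(
      "Unknown EAT-R factor `%s`. Known factors: %s.",
      factor[which(is.na(idx))[1]], paste(tax$factor, collapse = ", ")
    ), class = "eatr_validation_error")
  }
  tax$class[idx]
}

permitted_targets <- function(factor) {
  tax <- eatr_factors()
  idx <- match(factor, tax$factor)
  if (is.na(idx)) {
    abort(sprintf(
      "Unknown EAT-R factor `%s`. Known factors: %s.",
      factor, paste(tax$factor, collapse = ", ")
    ), class = "eatr_validation_error")
  }
  tax$targets[[idx]]
}
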