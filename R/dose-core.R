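#' Fraction of time in contact with the hazard
#'
#' Converts a work schedule into an exposure factor: the dimensionless
#' fraction of the averaging period a receptor spends in contact with
#' contaminated soil. It is the product of three fractions,
#' \deqn{EF = \frac{h}{24} \times \frac{d}{7} \times \frac{w}{52},}
#' where \eqn{h} is hours worked per day, \eqn{d} days per week and \eqn{w}
#' weeks per year. A grower working 10 h/day, 6 days/week, 50 weeks/year has
#' \eqn{EF = 0.34}; zero contact gives 0 and continuous contact gives 1.
#'
#' @param hours_per_day Hours of soil-contact work per 24-h day, in
#'   \eqn{[0, 24]}.
#' @param days_per_week Days worked per 7-day week, in \eqn{[0, 7]}.
#' @param weeks_per_year Weeks worked per 52-week year, in \eqn{[0, 52]}.
#'   For per-season schedules, the weeks worked within that season (still on
#'   the 52-week base, so seasonal exposure factors add up across seasons).
#'
#' @return A numeric vector of exposure factors in \eqn{[0, 1]}. Inputs are
#'   recycled following the usual vector rules.
#' @examples
#' exposure_factor(10, 6, 50) # 0.34 at two decimals
#' exposure_factor(24, 7, 52) # continuous contact: 1
#' @export
exposure_factor <- function(hours_per_day, days_per_week, weeks_per_year) {
  check_numeric_field(hours_per_day, "hours_per_day", 0, 24)
  check_numeric_field(days_per_week, "days_per_week", 0, 7)
  check_numeric_field(weeks_per_year, "weeks_per_year", 0, 52)
  (hours_per_day / 24) * (days_per_week / 7) * (weeks_per_year / 52)
}

ingestion_cols <- c("concentration", "intake_rate", "exposure_factor",
                    "body_weight")

dermal_cols <- c("concentration", "conversion_factor", "adherence_factor",
                 "absorption_fraction", "surface_area", "exposure_frequency",
                 "exposure_duration", "event_frequency", "body_weight",
                 "averaging_time")

validate_ingestion <- function(data) {
  check_columns(data, ingestion_cols, "add_ingestion")
  check_numeric_field(data$concentration, "concentration")
  check_numeric_field(data$intake_rate, "intake_rate")
  check_numeric_field(data$exposure_factor, "exposure_factor", 0, 1)
  check_numeric_field(data$body_weight, "body_weight", 0, Inf,
                      strict_lower = TRUE)
  invisible(data)
}

validate_dermal <- function(data) {
  check_columns(data, dermal_cols, "add_dermal")
  for (f in c("concentration", "conversion_factor", "adherence_factor",
              "surface_area", "exposure_frequency", "exposure_duration",
              "event_frequency")) {
    check_numeric_field(data[[f]], f)
  }
  check_numeric_field(data$absorption_fraction, "absorption_fraction", 0, 1)
  check_numeric_field(data$body_weight, "body_weight", 0, Inf,
                      strict_lower = TRUE)
  check_numeric_field(data$averaging_time, "averaging_time", 0, Inf,
                      strict_lower = TRUE)
  invisible(data)
}

#' Average daily dose via incidental soil ingestion
#'
#' Adds an average-daily-dose column to a data frame of per-cell ingestion
#' parameters:
#' \deqn{ADD = \frac{C \times IR \times EF}{BW}}
#' with soil concentration \eqn{C} (mg contaminant per mg soil), soil intake
#' rate \eqn{IR} (mg/day), exposure factor \eqn{EF} (dimensionless, see
#' [exposure_factor()]) and body weight \eqn{BW} (kg).
#'
#' @param data A data frame with numeric columns `concentration` (mg/mg),
#'   `intake_rate` (mg/day), `exposure_factor` (in \eqn{[0,1]}) and
#'   `body_weight` (kg, > 0). Extra columns (task, season, labels) pass
#'   through untouched.
#'
#' @return The input as a tibble with added columns `dose` (mg/kgBW/day) and
#'   `pathway` (`"ingestion"`).
#' @examples
#' tibble::tibble(
#'   concentration = 1e-4, intake_rate = 100,
#'   exposure_factor = 0.25, body_weight = 80
#' ) |> add_ingestion()
#' @export
add_ingestion <- function(data) {
  validate_ingestion(data)
  as_tibble(data) |>
    mutate(
      dose = .data$concentration * .data$intake_rate *
        .data$exposure_factor / .data$body_weight,
      pathway = "ingestion"
    )
}

#' Contaminant mass absorbed through skin per contact event
#'
#' Adds the per-event absorbed dose column
#' \deqn{DA_{event} = C \times CF \times AF \times ABS}
#' with soil concentration \eqn{C} (mg/kg), unit conversion factor \eqn{CF}
#' (kg/mg), soil-to-skin adherence factor \eqn{AF} (mg/cm\eqn{^2}-event) and
#' dermal absorption fraction \eqn{ABS} (dimensionless).
#'
#' @param data A data frame with numeric columns `concentration` (mg/kg),
#'   `conversion_factor` (kg/mg), `adherence_factor` (mg/cm\eqn{^2}-event)
#'   and `absorption_fraction` (in \eqn{[0,1]}).
#'
#' @return The input as a tibble with an added `dose_event` column
#'   (mg/cm\eqn{^2}-event).
#' @examples
#' tibble::tibble(
#'   concentration = 400, conversion_factor = 1e-6,
#'   adherence_factor = 0.07, absorption_fraction = 0.1
#' ) |> absorbed_dose_event()
#' @export
absorbed_dose_event <- function(data) {
  check_columns(data, c("concentration", "conversion_factor",
                        "adherence_factor", "absorption_fraction"),
                "absorbed_dose_event")
  check_numeric_field(data$concentration, "concentration")
  check_numeric_field(data$conversion_factor, "conversion_factor")
  check_numeric_field(data$adherence_factor, "adherence_factor")
  check_numeric_field(data$absorption_fraction, "absorption_fraction", 0, 1)
  as_tibble(data) |>
    mutate(dose_event = .data$concentration * .data$conversion_factor *
             .data$adherence_factor * .data$absorption_fraction)
}

#' Average daily dose via dermal contact with soil
#'
#' Adds the absorbed average-daily-dose column
#' \deqn{ADD = \frac{DA_{event} \times SA \times EF \times ED \times EV}
#'   {BW \times AT}}
#' where \eqn{DA_{event}} is the per-event absorbed dose (see
#' [absorbed_dose_event()]), \eqn{SA} the exposed skin surface area
#' (cm\eqn{^2}), \eqn{EF} the exposure frequency (days/year), \eqn{ED} the
#' exposure duration (years), \eqn{EV} the event frequency (events/day),
#' \eqn{BW} body weight (kg) and \eqn{AT} the averaging time (days). With
#' \eqn{ED} in years, \eqn{EF} in days/year and \eqn{AT} in days the result
#' is dimensionally a dose per kg body weight per day; this unit convention
#' is the standard risk-guidance parameterisation and is assumed throughout.
#'
#' @param data A data frame with the four [absorbed_dose_event()] columns
#'   plus numeric `surface_area` (cm\eqn{^2}), `exposure_frequency`
#'   (days/year), `exposure_duration` (years), `event_frequency`
#'   (events/day), `body_weight` (kg, > 0) and `averaging_time` (days, > 0).
#'
#' @return The input as a tibble with added columns `dose_event`, `dose`
#'   (mg/kgBW/day) and `pathway` (`"dermal"`).
#' @export
add_dermal <- function(data) {
  validate_dermal(data)
  absorbed_dose_event(data) |>
    mutate(
      dose = .data$dose_event * .data$surface_area *
        .data$exposure_frequency * .data$exposure_duration *
        .data$event_frequency / (.data$body_weight * .data$averaging_time),
      pathway = "dermal"
    )
}
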