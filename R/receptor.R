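#' Describe the exposed person
#'
#' A receptor profile bundles the person-specific attributes of an exposure
#' scenario: a body weight and any behavioral or biological modifiers (PPE
#' habits, produce sampling, tool use, anthropometrics). The profile's body
#' weight is applied as a biological override whenever the cascade's
#' receptor class is active; all attached modifiers must belong to the
#' receptor class.
#'
#' @param label Identifier for the receptor (e.g. `"grower_A"`).
#' @param body_weight Body weight in kg (> 0).
#' @param age_band,sex Free-text descriptors, for provenance only.
#' @param modifiers A tibble of [modifier()] rows, all of class `receptor`.
#'
#' @return An object of class `eatr_receptor`.
#' @examples
#' receptor_profile("grower_A", body_weight = 64, age_band = "20s",
#'                  sex = "female")
#' @export
receptor_profile <- function(label, body_weight, age_band = NA_character_,
                             sex = NA_character_, modifiers = NULL) {
  check_numeric_field(body_weight, "body_weight", 0, Inf, strict_lower = TRUE)
  if (!is.null(modifiers)) {
    stopifnot(is.data.frame(modifiers))
    if (nrow(modifiers) > 0 && any(modifiers$class != "receptor")) {
      abort(sprintf(
        "Receptor `%s` carries a non-receptor modifier (factor `%s`).",
        label, modifiers$factor[which(modifiers$class != "receptor")[1]]
      ), class = "eatr_validation_error")
    }
  }
  structure(list(
    label = label,
    age_band = age_band,
    sex = sex,
    body_weight = as.numeric(body_weight),
    modifiers = modifiers %||% modifier_prototype()
  ), class = "eatr_receptor")
}

`%||%` <- function(x, y) if (is.null(x)) y else x

modifier_prototype <- function() {
  tibble(
    class = character(), factor = character(), target = character(),
    action = character(), value = numeric(),
    tasks = list(), seasons = list()
  )
}

#' @export
print.eatr_receptor <- function(x, ...) {
  cat(sprintf("<eatr_receptor> %s (%s, %s), body weight %g kg, %d modifier%s\n",
              x$label, x$sex, x$age_band, x$body_weight,
              nrow(x$modifiers), if (nrow(x$modifiers) == 1) "" else "s"))
  invisible(x)
}
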