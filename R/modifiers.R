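all_dose_parameters <- function() union(ingestion_cols, dermal_cols)

#' Build a factor modifier
#'
#' A modifier records how one EAT-R factor perturbs one quantitative
#' dose-model input over a set of task-season cells: either multiplying the
#' baseline value (`action = "multiply"`) or replacing it outright
#' (`action = "override"`). Because the study of factor magnitudes is an
#' open empirical question, modifier values are always user-supplied; the
#' package enforces only *which* parameter a factor may touch (see
#' [eatr_factors()]) and elementary sign constraints.
#'
#' @param factor Name of the EAT-R factor (e.g. `"natural"`,
#'   `"biological"`); its class is looked up from the taxonomy.
#' @param target Name of the dose-model parameter the modifier acts on.
#' @param action `"multiply"` or `"override"`.
#' @param value Nonnegative number; multipliers must be strictly positive.
#' @param tasks,seasons Character vectors restricting the modifier to
#'   particular tasks/seasons; `NULL` (default) applies to all.
#'
#' @return A one-row tibble with columns `class`, `factor`, `target`,
#'   `action`, `value` and list columns `tasks`, `seasons`.
#' @examples
#' modifier("natural", "adherence_factor", "override", 0.2,
#'          seasons = c("spring", "fall"))
#' @export
modifier <- function(factor, target, action = c("multiply", "override"),
                     value, tasks = NULL, seasons = NULL) {
  action <- match.arg(action)
  cls <- factor_class(factor)
  if (!is.character(target) || length(target) != 1 ||
      !target %in% all_dose_parameters()) {
    abort(sprintf(
      "Unknown dose-model parameter `%s`. Known parameters: %s.",
      as.character(target)[1], paste(all_dose_parameters(), collapse = ", ")
    ), class = "eatr_validation_error")
  }
  check_numeric_field(value, "value", 0, Inf,
                      strict_lower = action == "multiply")
  tibble(
    class = cls, factor = factor, target = target,
    action = action, value = as.numeric(value),
    tasks = list(tasks), seasons = list(seasons)
  )
}

#' Check a modifier against the factor-to-parameter mapping
#'
#' A factor may only perturb the quantitative inputs it is mapped to in the
#' EAT-R taxonomy. This returns a verdict rather than throwing, so scenario
#' builders can collect all offending entries; on rejection the verdict
#' carries the permitted set for the factor.
#'
#' @param mod A one-row modifier tibble from [modifier()] or a parsed
#'   configuration entry with the same fields.
#'
#' @return An object of class `eatr_verdict`: a list with elements `ok`
#'   (logical), `factor`, `target`, `permitted` (character vector) and
#'   `message`.
#' @examples
#' validate_modifier(modifier("natural", "adherence_factor", "multiply", 2))
#' @export
validate_modifier <- function(mod) {
  stopifnot(is.data.frame(mod), nrow(mod) == 1)
  permitted <- permitted_targets(mod$factor)
  if (!mod$target %in% all_dose_parameters()) {
    abort(sprintf("Unknown dose-model parameter `%s`.", mod$target),
          class = "eatr_validation_error")
  }
  ok <- mod$target %in% permitted
  structure(list(
    ok = ok,
    factor = mod$factor,
    target = mod$target,
    permitted = permitted,
    message = if (ok) "ok" else sprintf(
      "Factor `%s` may not modify `%s`; permitted parameters: %s.",
      mod$factor, mod$target, paste(permitted, collapse = ", ")
    )
  ), class = "eatr_verdict")
}

#' @export
print.eatr_verdict <- function(x, ...) {
  cat(if (x$ok) "accepted:" else "rejected:", x$factor, "->", x$target, "\n")
  if (!x$ok) cat(x$message, "\n")
  invisible(x)
}

modifier_applies <- function(mod_tasks, mod_seasons, task, season) {
  (is.null(mod_tasks) || task %in% mod_tasks) &&
    (is.null(mod_seasons) || season %in% mod_seasons)
}
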