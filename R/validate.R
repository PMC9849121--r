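# Internal validation helpers. All dose inputs are plain numeric columns;
# errors always name the offending field so configuration mistakes surface
# with a usable message rather than an NaN downstream.

check_numeric_field <- function(x, field, lower = 0, upper = Inf,
                                strict_lower = FALSE) {
  if (!is.numeric(x)) {
    abort(sprintf("Field `%s` must be numeric.", field),
          class = "eatr_validation_error")
  }
  if (anyNA(x)) {
    abort(sprintf("Field `%s` contains missing values.", field),
          class = "eatr_validation_error")
  }
  bad <- if (strict_lower) x <= lower else x < lower
  bad <- bad | x > upper
  if (any(bad)) {
    cmp <- if (strict_lower) "(%s, %s]" else "[%s, %s]"
    abort(sprintf(
      "Field `%s` out of range: value %g not in %s.",
      field, x[which(bad)[1]],
      sprintf(cmp, format(lower), format(upper))
    ), class = "eatr_validation_error")
  }
  invisible(x)
}

check_columns <- function(data, cols, caller) {
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols) > 0) {
    abort(sprintf(
      "`%s()` requires column%s %s.",
      caller, if (length(missing_cols) > 1) "s" else "",
      paste0("`", missing_cols, "`", collapse = ", ")
    ), class = "eatr_validation_error")
  }
  invisible(data)
}

# Report at three significant figures (table convention); internals stay at
# full double precision.
signif3 <- function(x) signif(x, 3)
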