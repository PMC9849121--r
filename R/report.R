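#' Tidy a dose report into one row per task-season cell
#'
#' @param x An `eatr_dose_report`.
#' @param ... Unused.
#' @return A tibble with columns `level_id`, `pathway`, `receptor`, `task`,
#'   `season`, `dose` (mg/kgBW/day, full precision).
#' @method tidy eatr_dose_report
#' @export
tidy.eatr_dose_report <- function(x, ...) {
  x$cells |>
    select("task", "season", "dose") |>
    mutate(level_id = x$level_id, pathway = x$pathway,
           receptor = x$receptor_label, .before = 1)
}

#' One-row summary of a dose report
#'
#' @param x An `eatr_dose_report`.
#' @param ... Unused.
#' @return A one-row tibble: `level_id`, `pathway`, `receptor`, `n_cells`,
#'   `n_zero_cells`, `max_cell`, `annual_total`.
#' @method glance eatr_dose_report
#' @export
glance.eatr_dose_report <- function(x, ...) {
  tibble(
    level_id = x$level_id,
    pathway = x$pathway,
    receptor = x$receptor_label,
    n_cells = nrow(x$cells),
    n_zero_cells = sum(x$cells$dose == 0),
    max_cell = if (nrow(x$cells) > 0) max(x$cells$dose) else 0,
    annual_total = x$annual_total
  )
}

#' @rdname tidy.eatr_dose_report
#' @method tidy eatr_cascade
#' @export
tidy.eatr_cascade <- function(x, ...) {
  bind_rows(unname(lapply(x$reports, tidy)))
}

#' @rdname glance.eatr_dose_report
#' @method glance eatr_cascade
#' @export
glance.eatr_cascade <- function(x, ...) {
  bind_rows(unname(lapply(x$reports, glance)))
}

#' Plot a dose report as a task-by-season dose matrix
#'
#' @param object An `eatr_dose_report`.
#' @param ... Unused.
#' @return A ggplot: tiles of per-cell average daily dose, labelled at three
#'   significant figures.
#' @method autoplot eatr_dose_report
#' @export
autoplot.eatr_dose_report <- function(object, ...) {
  cells <- tidy(object) |>
    mutate(task = factor(.data$task, unique(.data$task)),
           season = factor(.data$season, unique(.data$season)))
  ggplot2::ggplot(cells, ggplot2::aes(x = .data$season, y = .data$task,
                                      fill = .data$dose)) +
    ggplot2::geom_tile(colour = "grey30") +
    ggplot2::geom_text(ggplot2::aes(label = signif3(.data$dose)),
                       size = 3) +
    ggplot2::scale_fill_viridis_c(name = "ADD\n(mg/kgBW/day)") +
    ggplot2::labs(
      title = sprintf("%s | %s | %s", object$label, object$level_id,
                      object$pathway),
      x = NULL, y = NULL
    ) +
    ggplot2::theme_minimal()
}

#' Plot cascade annual totals by level
#'
#' @param object An `eatr_cascade`.
#' @param ... Unused.
#' @return A ggplot bar chart of annual total dose per cascade level.
#' @method autoplot eatr_cascade
#' @export
autoplot.eatr_cascade <- function(object, ...) {
  g <- glance(object) |>
    mutate(level_id = factor(.data$level_id, unique(.data$level_id)))
  ggplot2::ggplot(g, ggplot2::aes(x = .data$level_id,
                                  y = .data$annual_total)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(
      title = sprintf("%s | %s cascade", object$label, object$pathway),
      x = NULL, y = "Annual total ADD (mg/kgBW/day)"
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1))
}

report_rows <- function(report) {
  cells <- report$cells |>
    mutate(row_type = "cell") |>
    select("row_type", "task", "season", "dose")
  subs <- report$seasonal_subtotals |>
    mutate(row_type = "subtotal", task = NA_character_) |>
    rename(dose = "subtotal") |>
    select("row_type", "task", "season", "dose")
  total <- tibble(row_type = "total", task = NA_character_,
                  season = NA_character_, dose = report$annual_total)
  bind_rows(cells, subs, total) |>
    mutate(
      level_id = report$level_id,
      pathway = report$pathway,
      receptor = report$receptor_label,
      scenario = report$label,
      dose_3sf = signif3(.data$dose),
      .before = 1
    )
}

#' Write cascade reports to disk
#'
#' Writes one CSV per pathway (rows flagged `cell`, `subtotal` or `total`;
#' doses given both at the three-significant-figure table convention and at
#' full precision in the `dose` column) plus a JSON summary mirroring the
#' report structure. Existing files are overwritten, so repeated runs are
#' idempotent.
#'
#' @param reports A single `eatr_dose_report`, an `eatr_cascade`, or a list
#'   of either.
#' @param dir Output directory (created if absent).
#'
#' @return Invisibly, the paths written.
#' @export
write_dose_report <- function(reports, dir) {
  if (inherits(reports, "eatr_dose_report")) reports <- list(reports)
  if (inherits(reports, "eatr_cascade")) reports <- reports$reports
  reports <- unlist(lapply(reports, function(r) {
    if (inherits(r, "eatr_cascade")) r$reports else list(r)
  }), recursive = FALSE)
  stopifnot(all(map_lgl(reports, inherits, "eatr_dose_report")))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (!dir.exists(dir)) {
    abort(sprintf("Cannot create output directory `%s`.", dir),
          class = "eatr_io_error")
  }

  proto <- tibble(
    level_id = character(), pathway = character(), receptor = character(),
    scenario = character(), dose_3sf = numeric(), row_type = character(),
    task = character(), season = character(), dose = numeric()
  )
  rows <- bind_rows(c(list(proto), unname(lapply(reports, report_rows))))
  paths <- character()
  for (pw in c("ingestion", "dermal")) {
    sub <- rows[rows$pathway %in% pw, ]
    if (nrow(sub) == 0 && length(reports) > 0) next
    path <- file.path(dir, sprintf("doses_%s.csv", pw))
    # 17 significant digits so the full-precision column re-reads
    # bit-identically
    sub$dose <- sprintf("%.17g", sub$dose)
    utils::write.csv(sub, path, row.names = FALSE)
    paths <- c(paths, path)
  }

  summary <- lapply(reports, function(r) {
    list(
      scenario = r$label,
      level_id = r$level_id,
      pathway = r$pathway,
      receptor = r$receptor_label,
      cells = r$cells |> select("task", "season", "dose"),
      seasonal_subtotals = r$seasonal_subtotals,
      annual_total = r$annual_total
    )
  })
  json_path <- file.path(dir, "dose_summary.json")
  jsonlite::write_json(summary, json_path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", na = "null")
  invisible(c(paths, json_path))
}
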