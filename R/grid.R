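#' Assemble a task-by-season exposure scenario
#'
#' A scenario grid is the unit the sensitivity cascade evaluates: an ordered
#' set of meso-activities (tasks) crossed with seasons, baseline ingestion
#' and dermal parameter sets, per-cell work schedules, EAT-R factor
#' modifiers, and optionally a receptor profile. Task-season cells that
#' appear in no schedule row are zero-exposure cells (true zero dose, not
#' missing).
#'
#' @param tasks Character vector of meso-activity names (may be empty).
#' @param seasons Character vector of season names.
#' @param baseline_ingestion Named list or one-row data frame with
#'   `concentration` (mg/mg), `intake_rate` (mg/day), `exposure_factor`,
#'   `body_weight` (kg) — the traditional single-scenario ingestion model.
#' @param baseline_dermal Named list or one-row data frame with the ten
#'   dermal parameters (see [add_dermal()]).
#' @param schedules Data frame with columns `task`, `season` and either a
#'   worked schedule (`hours_per_day`, `days_per_week`, `weeks_per_year`;
#'   weeks counted within the cell's season on the 52-week base) or direct
#'   per-cell values `exposure_factor` (ingestion) / `exposure_frequency`
#'   (dermal, days/year). At most one row per cell.
#' @param modifiers Tibble of [modifier()] rows (environmental, activity or
#'   timing class; receptor-class modifiers belong on the receptor profile).
#' @param receptor Optional [receptor_profile()].
#' @param label Scenario label used in reports.
#'
#' @return An object of class `eatr_grid`.
#' @export
scenario_grid <- function(tasks, seasons, baseline_ingestion, baseline_dermal,
                          schedules = NULL, modifiers = NULL, receptor = NULL,
                          label = "scenario") {
  tasks <- as.character(tasks)
  seasons <- as.character(seasons)
  if (anyDuplicated(tasks)) abort("Duplicate task names.",
                                  class = "eatr_config_error")
  if (anyDuplicated(seasons)) abort("Duplicate season names.",
                                    class = "eatr_config_error")

  baseline_ingestion <- as.list(baseline_ingestion)[ingestion_cols]
  names(baseline_ingestion) <- ingestion_cols
  validate_ingestion(as_tibble(baseline_ingestion))
  baseline_dermal <- as.list(baseline_dermal)[dermal_cols]
  names(baseline_dermal) <- dermal_cols
  validate_dermal(as_tibble(baseline_dermal))

  schedules <- validate_schedules(schedules, tasks, seasons)
  modifiers <- validate_grid_modifiers(modifiers, tasks, seasons)
  if (!is.null(receptor)) {
    stopifnot(inherits(receptor, "eatr_receptor"))
    check_modifier_scope(receptor$modifiers, tasks, seasons)
  }

  structure(list(
    tasks = tasks, seasons = seasons,
    baseline_ingestion = lapply(baseline_ingestion, as.numeric),
    baseline_dermal = lapply(baseline_dermal, as.numeric),
    schedules = schedules, modifiers = modifiers,
    receptor = receptor, label = label
  ), class = "eatr_grid")
}

schedule_value_cols <- c("hours_per_day", "days_per_week", "weeks_per_year",
                         "exposure_factor", "exposure_frequency")

validate_schedules <- function(schedules, tasks, seasons) {
  if (is.null(schedules) || nrow(schedules) == 0) {
    return(tibble(task = character(), season = character()))
  }
  check_columns(schedules, c("task", "season"), "scenario_grid")
  schedules <- as_tibble(schedules)
  bad_task <- setdiff(schedules$task, tasks)
  bad_season <- setdiff(schedules$season, seasons)
  if (length(bad_task) > 0 || length(bad_season) > 0) {
    abort(sprintf(
      "Schedule references unknown %s `%s`.",
      if (length(bad_task) > 0) "task" else "season",
      c(bad_task, bad_season)[1]
    ), class = "eatr_config_error")
  }
  if (anyDuplicated(schedules[c("task", "season")])) {
    abort("More than one schedule row for the same task-season cell.",
          class = "eatr_config_error")
  }
  if (all(c("hours_per_day", "days_per_week", "weeks_per_year") %in%
          names(schedules))) {
    # computed eagerly so range errors surface at build time
    exposure_factor(schedules$hours_per_day, schedules$days_per_week,
                    schedules$weeks_per_year)
  }
  if ("exposure_factor" %in% names(schedules)) {
    ef <- schedules$exposure_factor[!is.na(schedules$exposure_factor)]
    if (length(ef) > 0) check_numeric_field(ef, "exposure_factor", 0, 1)
  }
  if ("exposure_frequency" %in% names(schedules)) {
    fq <- schedules$exposure_frequency[!is.na(schedules$exposure_frequency)]
    if (length(fq) > 0) check_numeric_field(fq, "exposure_frequency", 0, 366)
  }
  if (!any(schedule_value_cols %in% names(schedules))) {
    abort("Schedules need either hours/days/weeks columns or per-cell exposure_factor / exposure_frequency.",
          class = "eatr_config_error")
  }
  schedules
}

validate_grid_modifiers <- function(modifiers, tasks, seasons) {
  if (is.null(modifiers) || nrow(modifiers) == 0) return(modifier_prototype())
  modifiers <- as_tibble(modifiers)
  for (i in seq_len(nrow(modifiers))) {
    verdict <- validate_modifier(modifiers[i, ])
    if (!verdict$ok) abort(verdict$message, class = "eatr_config_error")
  }
  if (any(modifiers$class == "receptor")) {
    abort("Receptor-class modifiers belong on the receptor profile, not the grid.",
          class = "eatr_config_error")
  }
  check_modifier_scope(modifiers, tasks, seasons)
  modifiers
}

check_modifier_scope <- function(modifiers, tasks, seasons) {
  for (i in seq_len(nrow(modifiers))) {
    sc_t <- modifiers$tasks[[i]]
    sc_s <- modifiers$seasons[[i]]
    bad <- c(setdiff(sc_t %||% character(), tasks),
             setdiff(sc_s %||% character(), seasons))
    if (length(bad) > 0) {
      abort(sprintf(
        "Modifier %d (factor `%s` on `%s`) is scoped to unknown task/season `%s`.",
        i, modifiers$factor[i], modifiers$target[i], bad[1]
      ), class = "eatr_config_error")
    }
  }
  invisible(modifiers)
}

#' @export
print.eatr_grid <- function(x, ...) {
  cat(sprintf("<eatr_grid> %s: %d task(s) x %d season(s), %d schedule cell(s), %d grid modifier(s)%s\n",
              x$label, length(x$tasks), length(x$seasons), nrow(x$schedules),
              nrow(x$modifiers),
              if (is.null(x$receptor)) "" else
                sprintf(", receptor %s", x$receptor$label)))
  invisible(x)
}

all_modifiers <- function(grid) {
  mods <- grid$modifiers
  if (!is.null(grid$receptor)) {
    rec <- grid$receptor
    mods <- bind_rows(mods, rec$modifiers)
    # the profile's body weight acts as an implicit biological override
    mods <- bind_rows(mods, modifier("biological", "body_weight", "override",
                                     rec$body_weight))
  }
  mods
}

cell_schedule_row <- function(grid, task, season) {
  sch <- grid$schedules
  if (nrow(sch) == 0) return(NULL)
  hit <- which(sch$task == task & sch$season == season)
  if (length(hit) == 0) NULL else sch[hit, ]
}

has_value <- function(row, col) {
  col %in% names(row) && !is.na(row[[col]])
}

schedule_exposure_factor <- function(row) {
  if (has_value(row, "exposure_factor")) {
    return(row$exposure_factor)
  }
  if (all(c("hours_per_day", "days_per_week", "weeks_per_year") %in%
          names(row)) && !anyNA(row[c("hours_per_day", "days_per_week",
                                      "weeks_per_year")])) {
    return(exposure_factor(row$hours_per_day, row$days_per_week,
                           row$weeks_per_year))
  }
  NA_real_
}

schedule_exposure_frequency <- function(row) {
  if (has_value(row, "exposure_frequency")) {
    return(row$exposure_frequency)
  }
  if (all(c("days_per_week", "weeks_per_year") %in% names(row)) &&
      !anyNA(row[c("days_per_week", "weeks_per_year")])) {
    return(row$days_per_week * row$weeks_per_year)
  }
  # last resort: an exposure factor alone implies contact-day equivalents
  if (has_value(row, "exposure_factor")) {
    return(row$exposure_factor * 365)
  }
  NA_real_
}

#' Resolve one task-season cell to concrete dose parameters
#'
#' Starting from the grid's baseline parameters for the requested pathway,
#' the cell's schedule sets the exposure factor (ingestion) or exposure
#' frequency (dermal); factor modifiers of the active classes are then
#' applied in fixed class order (environmental, activity, timing, receptor).
#' Within the active set, multiplicative modifiers compose commutatively and
#' overrides apply last; at most one override per parameter per cell is
#' permitted. Cells with no schedule row are zero-exposure cells. The
#' baseline is never mutated: resolving the same cell twice gives identical
#' parameters.
#'
#' @param grid An [scenario_grid()].
#' @param task,season Cell coordinates (must exist in the grid).
#' @param pathway `"ingestion"` or `"dermal"`.
#' @param classes Modifier classes to apply; defaults to all four.
#'
#' @return A one-row tibble: `task`, `season` plus the pathway's fully
#'   resolved parameter columns, satisfying all parameter invariants.
#' @export
resolve_cell <- function(grid, task, season,
                         pathway = c("ingestion", "dermal"),
                         classes = eatr_classes) {
  pathway <- match.arg(pathway)
  stopifnot(inherits(grid, "eatr_grid"))
  if (!task %in% grid$tasks || !season %in% grid$seasons) {
    abort(sprintf("Cell (%s, %s) is not in the grid.", task, season),
          class = "eatr_config_error")
  }
  classes <- match.arg(classes, eatr_classes, several.ok = TRUE)

  params <- if (pathway == "ingestion") grid$baseline_ingestion else
    grid$baseline_dermal

  row <- cell_schedule_row(grid, task, season)
  if (is.null(row)) {
    if (pathway == "ingestion") params$exposure_factor <- 0
    else params$exposure_frequency <- 0
  } else if (pathway == "ingestion") {
    ef <- schedule_exposure_factor(row)
    if (!is.na(ef)) params$exposure_factor <- ef
  } else {
    fq <- schedule_exposure_frequency(row)
    if (!is.na(fq)) params$exposure_frequency <- fq
  }

  mods <- all_modifiers(grid)
  if (nrow(mods) > 0) {
    keep_row <- mods$class %in% classes &
      mods$target %in% names(params) &
      map_lgl(seq_len(nrow(mods)), function(i) {
        modifier_applies(mods$tasks[[i]], mods$seasons[[i]], task, season)
      })
    mods <- mods[keep_row, ]
    mods <- mods[order(match(mods$class, eatr_classes)), ]

    ov <- mods[mods$action == "override", ]
    if (anyDuplicated(ov$target)) {
      abort(sprintf(
        "Cell (%s, %s): more than one override targets `%s`.",
        task, season, ov$target[duplicated(ov$target)][1]
      ), class = "eatr_config_error")
    }
    mu <- mods[mods$action == "multiply", ]
    for (i in seq_len(nrow(mu))) {
      params[[mu$target[i]]] <- params[[mu$target[i]]] * mu$value[i]
    }
    for (i in seq_len(nrow(ov))) {
      params[[ov$target[i]]] <- ov$value[i]
    }
  }

  out <- as_tibble(params)
  # resolved parameters must still satisfy the dose-model invariants
  if (pathway == "ingestion") validate_ingestion(out) else validate_dermal(out)
  bind_cols(tibble(task = task, season = season), out)
}
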