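# Scenario configuration documents: YAML or JSON with top-level keys
# label, tasks, seasons, baselines (ingestion/dermal), schedules, modifiers,
# receptor. The machine-readable schema ships in inst/schema/.

config_abort <- function(path, msg) {
  abort(sprintf("Invalid scenario configuration at `%s`: %s", path, msg),
        class = "eatr_config_error")
}

# conditions that already carry a package class pass through untouched;
# anything else gets wrapped with the document path
rewrap_config_error <- function(cnd, path) {
  if (inherits(cnd, c("eatr_config_error", "eatr_validation_error"))) {
    stop(cnd)
  }
  config_abort(path, conditionMessage(cnd))
}

as_num_list <- function(x, path, fields) {
  if (!is.list(x)) config_abort(path, "expected a mapping")
  missing_fields <- setdiff(fields, names(x))
  if (length(missing_fields) > 0) {
    config_abort(paste0(path, ".", missing_fields[1]), "field is missing")
  }
  out <- lapply(x[fields], function(v) {
    if (!is.numeric(v) || length(v) != 1) NA_real_ else as.numeric(v)
  })
  bad <- names(out)[map_lgl(out, is.na)]
  if (length(bad) > 0) {
    config_abort(paste0(path, ".", bad[1]), "must be a single number")
  }
  out
}

parse_config_modifiers <- function(entries, path) {
  if (is.null(entries) || length(entries) == 0) return(modifier_prototype())
  rows <- imap(entries, function(e, i) {
    p <- sprintf("%s[%d]", path, i)
    if (!is.list(e)) config_abort(p, "expected a mapping")
    for (f in c("factor", "target", "action", "value")) {
      if (is.null(e[[f]])) config_abort(paste0(p, ".", f), "field is missing")
    }
    tryCatch(
      modifier(e$factor, e$target, e$action, e$value,
               tasks = unlist(e$tasks) %||% NULL,
               seasons = unlist(e$seasons) %||% NULL),
      error = function(cnd) config_abort(p, conditionMessage(cnd))
    )
  })
  bind_rows(rows)
}

#' Build a scenario grid from a parsed configuration document
#'
#' Validates the document structure (reporting the path to any offending
#' entry) and constructs a fully validated [scenario_grid()]: every
#' schedule and modifier scope must reference declared tasks/seasons, and
#' every modifier must respect the EAT-R factor-to-parameter mapping.
#'
#' @param config A named list as produced by [read_scenario()] (or written
#'   by [as_scenario_config()]).
#'
#' @return An [scenario_grid()].
#' @export
build_grid_from_config <- function(config) {
  if (!is.list(config)) {
    abort("Scenario configuration must be a mapping.",
          class = "eatr_config_error")
  }
  for (f in c("tasks", "seasons", "baselines")) {
    if (is.null(config[[f]])) config_abort(f, "field is missing")
  }
  if (is.null(config$baselines$ingestion) || is.null(config$baselines$dermal)) {
    config_abort("baselines", "needs both `ingestion` and `dermal` mappings")
  }
  bi <- as_num_list(config$baselines$ingestion, "baselines.ingestion",
                    ingestion_cols)
  bd <- as_num_list(config$baselines$dermal, "baselines.dermal", dermal_cols)

  schedules <- NULL
  if (!is.null(config$schedules) && length(config$schedules) > 0) {
    schedules <- bind_rows(imap(config$schedules, function(e, i) {
      p <- sprintf("schedules[%d]", i)
      if (!is.list(e) || is.null(e$task) || is.null(e$season)) {
        config_abort(p, "needs `task` and `season`")
      }
      as_tibble(e[!map_lgl(e, is.null)])
    }))
  }
  modifiers <- parse_config_modifiers(config$modifiers, "modifiers")

  receptor <- NULL
  if (!is.null(config$receptor)) {
    r <- config$receptor
    if (is.null(r$label) || is.null(r$body_weight)) {
      config_abort("receptor", "needs `label` and `body_weight`")
    }
    receptor <- tryCatch(
      receptor_profile(
        label = r$label,
        body_weight = r$body_weight,
        age_band = r$age_band %||% NA_character_,
        sex = r$sex %||% NA_character_,
        modifiers = parse_config_modifiers(r$modifiers, "receptor.modifiers")
      ),
      error = function(cnd) rewrap_config_error(cnd, "receptor")
    )
  }

  tryCatch(
    scenario_grid(
      tasks = unlist(config$tasks) %||% character(),
      seasons = unlist(config$seasons) %||% character(),
      baseline_ingestion = bi, baseline_dermal = bd,
      schedules = schedules, modifiers = modifiers, receptor = receptor,
      label = config$label %||% "scenario"
    ),
    error = function(cnd) rewrap_config_error(cnd, "<document>")
  )
}

#' Serialise a scenario grid to a configuration list
#'
#' Inverse of [build_grid_from_config()]: the returned list round-trips
#' through [write_scenario()]/[read_scenario()] to a deep-equal grid.
#'
#' @param grid An [scenario_grid()].
#' @return A named list conforming to the published scenario schema.
#' @export
as_scenario_config <- function(grid) {
  stopifnot(inherits(grid, "eatr_grid"))
  mods_to_list <- function(m) {
    lapply(seq_len(nrow(m)), function(i) {
      e <- list(factor = m$factor[i], target = m$target[i],
                action = m$action[i], value = m$value[i])
      if (!is.null(m$tasks[[i]])) e$tasks <- as.list(m$tasks[[i]])
      if (!is.null(m$seasons[[i]])) e$seasons <- as.list(m$seasons[[i]])
      e
    })
  }
  cfg <- list(
    label = grid$label,
    tasks = as.list(grid$tasks),
    seasons = as.list(grid$seasons),
    baselines = list(ingestion = grid$baseline_ingestion,
                     dermal = grid$baseline_dermal)
  )
  if (nrow(grid$schedules) > 0) {
    cfg$schedules <- lapply(seq_len(nrow(grid$schedules)), function(i) {
      row <- as.list(grid$schedules[i, ])
      row[!map_lgl(row, function(v) is.null(v) || (length(v) == 1 && is.na(v)))]
    })
  }
  if (nrow(grid$modifiers) > 0) cfg$modifiers <- mods_to_list(grid$modifiers)
  if (!is.null(grid$receptor)) {
    r <- grid$receptor
    cfg$receptor <- list(label = r$label, body_weight = r$body_weight)
    if (!is.na(r$age_band)) cfg$receptor$age_band <- r$age_band
    if (!is.na(r$sex)) cfg$receptor$sex <- r$sex
    if (nrow(r$modifiers) > 0) {
      cfg$receptor$modifiers <- mods_to_list(r$modifiers)
    }
  }
  cfg
}

#' Read and validate a scenario configuration file
#'
#' Accepts YAML (`.yml`/`.yaml`) or JSON (`.json`). Parsing, schema
#' validation and missing-file problems raise distinct condition classes
#' (`eatr_parse_error`, `eatr_config_error`, `eatr_io_error`) so callers —
#' including the command-line interface — can map them to distinct exit
#' codes.
#'
#' @param path Path to the configuration file.
#' @param as_grid If `TRUE` (default) return the validated
#'   [scenario_grid()]; otherwise the raw parsed document.
#'
#' @return A [scenario_grid()] (or named list when `as_grid = FALSE`).
#' @export
read_scenario <- function(path, as_grid = TRUE) {
  if (!file.exists(path)) {
    abort(sprintf("Scenario file not found: `%s`.", path),
          class = "eatr_io_error")
  }
  is_json <- grepl("\\.json$", path, ignore.case = TRUE)
  config <- tryCatch(
    if (is_json) jsonlite::read_json(path, simplifyVector = FALSE)
    else yaml::read_yaml(path),
    error = function(cnd) {
      abort(sprintf("Cannot parse `%s`: %s", path, conditionMessage(cnd)),
            class = "eatr_parse_error")
    }
  )
  if (!as_grid) return(config)
  build_grid_from_config(config)
}

#' Write a scenario grid to a configuration file
#'
#' @param grid An [scenario_grid()] (or an already-built configuration
#'   list).
#' @param path Destination `.yml`/`.yaml` or `.json` path. JSON is written
#'   at full numeric precision and is the format of choice for exact
#'   round-trips.
#'
#' @return Invisibly, `path`.
#' @export
write_scenario <- function(grid, path) {
  cfg <- if (inherits(grid, "eatr_grid")) as_scenario_config(grid) else grid
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else {
    yaml::write_yaml(cfg, path, precision = 15)
  }
  invisible(path)
}
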