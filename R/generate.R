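#' Configure the synthetic scenario generator
#'
#' The generator emulates the structure of interview-derived exposure
#' scenarios: a task-by-season grid of work schedules plus a random set of
#' EAT-R factor modifiers, each respecting the factor-to-parameter mapping.
#' Schedule defaults follow the qualitative ranges growers describe —
#' roughly 1–17 h of work per day and 3–7 days per week — with up to 13
#' worked weeks per 13-week season; these are generator defaults, not
#' empirically fitted distributions.
#'
#' All draws are integer-lattice based (whole hours/days/weeks; multipliers
#' on a 0.01 grid), which keeps generated grids identical across platforms
#' for a given seed and lets configuration files round-trip exactly.
#'
#' @param seed Integer seed; one seeded stream drives the whole grid.
#' @param n_tasks,n_seasons Grid dimensions.
#' @param schedule_ranges Named list of integer `(min, max)` pairs for
#'   `hours_per_day` (within 0–24), `days_per_week` (0–7) and
#'   `weeks_per_season` (0–13).
#' @param p_cell Probability a task-season cell is worked at all; unworked
#'   cells become zero-exposure cells.
#' @param modifier_spec Data frame with columns `factor`, `prob` and
#'   `min`/`max` multiplier bounds (> 0). Defaults to probability 0.3 and
#'   multipliers in \[0.5, 2\] for every factor, except that
#'   exposure-factor multipliers are capped at 1.25 so stacked modifiers
#'   can never push an exposure factor past 1.
#' @param receptor_pool List of [receptor_profile()] templates; one is
#'   drawn per grid. `NULL` generates receptor-less grids (receptor-class
#'   factors are then skipped).
#' @param baseline_ingestion,baseline_dermal Baseline parameter sets;
#'   default to the built-in demonstration baselines.
#'
#' @return An object of class `eatr_generator_config`.
#' @export
generator_config <- function(seed,
                             n_tasks = 3,
                             n_seasons = 4,
                             schedule_ranges = list(
                               hours_per_day = c(1L, 17L),
                               days_per_week = c(3L, 7L),
                               weeks_per_season = c(0L, 13L)
                             ),
                             p_cell = 0.85,
                             modifier_spec = default_modifier_spec(),
                             receptor_pool = default_receptor_pool(),
                             baseline_ingestion = fixture_baseline_ingestion(),
                             baseline_dermal = fixture_baseline_dermal()) {
  stopifnot(is.numeric(seed), length(seed) == 1, seed == round(seed))
  check_numeric_field(n_tasks, "n_tasks", 0, 100)
  check_numeric_field(n_seasons, "n_seasons", 0, 12)
  check_numeric_field(p_cell, "p_cell", 0, 1)
  limits <- list(hours_per_day = c(0, 24), days_per_week = c(0, 7),
                 weeks_per_season = c(0, 13))
  for (f in names(limits)) {
    r <- schedule_ranges[[f]]
    if (is.null(r) || length(r) != 2 || r[1] > r[2]) {
      abort(sprintf("`schedule_ranges$%s` must be a (min, max) pair.", f),
            class = "eatr_validation_error")
    }
    check_numeric_field(r, f, limits[[f]][1], limits[[f]][2])
  }
  check_columns(modifier_spec, c("factor", "prob", "min", "max"),
                "generator_config")
  check_numeric_field(modifier_spec$prob, "prob", 0, 1)
  check_numeric_field(modifier_spec$min, "min", 0, Inf, strict_lower = TRUE)
  if (any(modifier_spec$max < modifier_spec$min)) {
    abort("modifier_spec: `max` must be >= `min`.",
          class = "eatr_validation_error")
  }
  factor_class(modifier_spec$factor) # errors on unknown factors
  structure(list(
    seed = as.integer(seed), n_tasks = as.integer(n_tasks),
    n_seasons = as.integer(n_seasons), schedule_ranges = schedule_ranges,
    p_cell = p_cell, modifier_spec = modifier_spec,
    receptor_pool = receptor_pool,
    baseline_ingestion = baseline_ingestion,
    baseline_dermal = baseline_dermal
  ), class = "eatr_generator_config")
}

#' @rdname generator_config
#' @export
default_modifier_spec <- function() {
  tax <- eatr_factors()
  tibble(
    factor = tax$factor,
    prob = 0.3,
    min = 0.5,
    # exposure-factor multipliers stay small enough that any stack of
    # factor-distinct modifiers keeps EF within [0, 1]
    max = ifelse(map_lgl(tax$targets, function(t) {
      "exposure_factor" %in% t
    }), 1.25, 2)
  )
}

#' @rdname generator_config
#' @export
default_receptor_pool <- function() {
  list(
    receptor_profile("receptor_light", body_weight = 64, age_band = "20s",
                     sex = "female"),
    receptor_profile("receptor_heavy", body_weight = 88, age_band = "40s",
                     sex = "male")
  )
}

draw_int <- function(range) {
  lo <- as.integer(range[1])
  hi <- as.integer(range[2])
  if (hi == lo) lo else lo + sample.int(hi - lo + 1L, 1L) - 1L
}

# multiplier on a 0.01 lattice so serialised configs round-trip exactly
draw_mult <- function(min, max) {
  lo <- as.integer(round(min * 100))
  hi <- as.integer(round(max * 100))
  (lo + sample.int(hi - lo + 1L, 1L) - 1L) / 100
}

#' Generate a random scenario grid
#'
#' Reproducible given the config's seed: identical configs give deeply
#' equal grids. Every emitted modifier passes [validate_modifier()] by
#' construction (the target is drawn from the factor's permitted set), and
#' every generated exposure factor lies in \[0, 1\] because schedules are
#' drawn within the type invariants and exposure-factor multipliers are
#' bounded.
#'
#' @param config An [generator_config()].
#'
#' @return An [scenario_grid()].
#' @examples
#' g <- generate_scenario(generator_config(seed = 1))
#' run_cascade(g, "ingestion")
#' @export
generate_scenario <- function(config) {
  stopifnot(inherits(config, "eatr_generator_config"))
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()))
  set.seed(config$seed)

  tasks <- sprintf("task_%d", seq_len(config$n_tasks))
  seasons <- sprintf("season_%d", seq_len(config$n_seasons))

  cells <- tidyr::expand_grid(task = tasks, season = seasons)
  schedules <- NULL
  if (nrow(cells) > 0) {
    schedules <- cells |>
      mutate(
        active = runif(n()) < config$p_cell,
        hours_per_day = map_dbl(row_number(), function(i) {
          draw_int(config$schedule_ranges$hours_per_day)
        }),
        days_per_week = map_dbl(row_number(), function(i) {
          draw_int(config$schedule_ranges$days_per_week)
        }),
        weeks_per_year = map_dbl(row_number(), function(i) {
          draw_int(config$schedule_ranges$weeks_per_season)
        })
      ) |>
      filter(.data$active) |>
      select(-"active")
    if (nrow(schedules) == 0) schedules <- NULL
  }

  receptor <- NULL
  if (!is.null(config$receptor_pool) && length(config$receptor_pool) > 0) {
    receptor <- config$receptor_pool[[
      sample.int(length(config$receptor_pool), 1L)]]
  }

  grid_mods <- list()
  receptor_mods <- list()
  spec <- config$modifier_spec
  for (i in seq_len(nrow(spec))) {
    fct <- spec$factor[i]
    cls <- factor_class(fct)
    if (cls == "receptor" && is.null(receptor)) next
    if (runif(1) >= spec$prob[i]) next
    targets <- permitted_targets(fct)
    target <- targets[draw_int(c(1L, length(targets)))]
    scope_kind <- draw_int(c(1L, 3L)) # 1 global, 2 one task, 3 one season
    scope_tasks <- if (scope_kind == 2 && length(tasks) > 0) {
      tasks[draw_int(c(1L, length(tasks)))]
    }
    scope_seasons <- if (scope_kind == 3 && length(seasons) > 0) {
      seasons[draw_int(c(1L, length(seasons)))]
    }
    mod <- modifier(fct, target, "multiply",
                    draw_mult(spec$min[i], spec$max[i]),
                    tasks = scope_tasks, seasons = scope_seasons)
    if (cls == "receptor") receptor_mods <- c(receptor_mods, list(mod))
    else grid_mods <- c(grid_mods, list(mod))
  }
  if (!is.null(receptor) && length(receptor_mods) > 0) {
    receptor <- receptor_profile(
      receptor$label, receptor$body_weight, receptor$age_band,
      receptor$sex, modifiers = bind_rows(receptor$modifiers,
                                          bind_rows(receptor_mods))
    )
  }

  scenario_grid(
    tasks = tasks, seasons = seasons,
    baseline_ingestion = config$baseline_ingestion,
    baseline_dermal = config$baseline_dermal,
    schedules = schedules,
    modifiers = if (length(grid_mods) > 0) bind_rows(grid_mods),
    receptor = receptor,
    label = sprintf("synthetic_seed%d", config$seed)
  )
}
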