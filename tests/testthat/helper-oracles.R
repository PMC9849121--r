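# Independent oracles kept deliberately naive: plain loops and scalar
# arithmetic, no reuse of package internals beyond the public constructors.

# brute-force double loop over cells: season subtotals then grand total
brute_force_aggregate <- function(cells) {
  seasons <- unique(cells$season)
  subtotals <- numeric(length(seasons))
  for (i in seq_along(seasons)) {
    members <- numeric()
    for (j in seq_len(nrow(cells))) {
      if (cells$season[j] == seasons[i]) {
        members <- c(members, cells$dose[j])
      }
    }
    subtotals[i] <- sum(members)
  }
  list(seasons = seasons, subtotals = subtotals, total = sum(subtotals))
}

# small fully-specified parameter tables for toy computations
toy_ingestion <- function(...) {
  tibble::tibble(concentration = 1e-4, intake_rate = 100,
                 exposure_factor = 0.25, body_weight = 80, ...)
}

toy_dermal <- function(...) {
  tibble::tibble(
    concentration = 400, conversion_factor = 1e-6, adherence_factor = 0.07,
    absorption_fraction = 0.1, surface_area = 3000, exposure_frequency = 200,
    exposure_duration = 1, event_frequency = 2, body_weight = 70,
    averaging_time = 365, ...
  )
}

# minimal valid grid used across structural tests
toy_grid <- function(schedules = NULL, modifiers = NULL, receptor = NULL,
                     tasks = c("planting", "weeding"),
                     seasons = c("spring", "summer")) {
  scenario_grid(
    tasks = tasks, seasons = seasons,
    baseline_ingestion = list(concentration = 1e-4, intake_rate = 100,
                              exposure_factor = 0.16, body_weight = 80),
    baseline_dermal = as.list(toy_dermal()),
    schedules = schedules, modifiers = modifiers, receptor = receptor,
    label = "toy"
  )
}
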