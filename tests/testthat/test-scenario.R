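test_that("the taxonomy has ten factors in four classes", {
  tax <- eatr_factors()
  expect_equal(nrow(tax), 10)
  expect_setequal(unique(tax$class),
                  c("environmental", "activity", "timing", "receptor"))
  expect_equal(tax$factor[tax$class == "environmental"],
               c("natural", "social_built"))
  expect_equal(tax$factor[tax$class == "timing"],
               c("season", "day_of_week", "time_of_day"))
})

test_that("modifier targets are validated against the factor mapping", {
  ok <- validate_modifier(modifier("natural", "adherence_factor",
                                   "multiply", 2))
  expect_true(ok$ok)

  # social/built conditions may only touch the exposure factor
  bad <- modifier("social_built", "adherence_factor", "multiply", 2)
  verdict <- validate_modifier(bad)
  expect_false(verdict$ok)
  expect_equal(verdict$permitted, "exposure_factor")
  expect_match(verdict$message, "permitted")

  expect_error(modifier("gravity", "intake_rate", "multiply", 2),
               "Unknown EAT-R factor", class = "eatr_validation_error")
  expect_error(modifier("natural", "shoe_size", "multiply", 2),
               "Unknown dose-model parameter",
               class = "eatr_validation_error")
  expect_error(modifier("natural", "intake_rate", "multiply", 0),
               "value", class = "eatr_validation_error")
})

test_that("an identity multiplier is accepted and is a no-op downstream", {
  id <- modifier("natural", "intake_rate", "multiply", 1)
  expect_true(validate_modifier(id)$ok)
  sch <- tibble::tibble(task = "planting", season = "spring",
                        exposure_factor = 0.1)
  with_id <- resolve_cell(toy_grid(sch, modifiers = id),
                          "planting", "spring", "ingestion")
  without <- resolve_cell(toy_grid(sch), "planting", "spring", "ingestion")
  expect_equal(with_id, without)
})

test_that("resolving a cell without modifiers returns the baseline with the schedule's exposure", {
  sch <- tibble::tibble(task = "planting", season = "spring",
                        hours_per_day = 6, days_per_week = 5,
                        weeks_per_year = 10)
  cell <- resolve_cell(toy_grid(sch), "planting", "spring", "ingestion")
  expect_equal(cell$exposure_factor, exposure_factor(6, 5, 10))
  expect_equal(cell$concentration, 1e-4)
  expect_equal(cell$intake_rate, 100)
  expect_equal(cell$body_weight, 80)
  # dermal: contact days from the schedule
  dermal <- resolve_cell(toy_grid(sch), "planting", "spring", "dermal")
  expect_equal(dermal$exposure_frequency, 5 * 10)
})

test_that("cells absent from all schedules are zero-exposure cells", {
  sch <- tibble::tibble(task = "planting", season = "spring",
                        exposure_factor = 0.1, exposure_frequency = 50)
  g <- toy_grid(sch)
  cell <- resolve_cell(g, "weeding", "summer", "ingestion")
  expect_equal(cell$exposure_factor, 0)
  expect_equal(resolve_cell(g, "weeding", "summer", "dermal")$exposure_frequency, 0)
  rep <- run_level(g, "meso_activity", "ingestion")
  zero_cells <- dplyr::filter(tidy(rep), task == "weeding")
  expect_true(all(zero_cells$dose == 0))
})

test_that("an adherence override replaces the baseline value in scope", {
  sch <- tibble::tibble(task = "planting", season = c("spring", "summer"),
                        exposure_frequency = 50)
  ov <- modifier("natural", "adherence_factor", "override", 0.2,
                 seasons = "spring")
  g <- toy_grid(sch, modifiers = ov)
  expect_equal(resolve_cell(g, "planting", "spring", "dermal")$adherence_factor, 0.2)
  expect_equal(resolve_cell(g, "planting", "summer", "dermal")$adherence_factor, 0.07)
})

test_that("multiplies compose commutatively; double resolution is idempotent", {
  sch <- tibble::tibble(task = "planting", season = "spring",
                        exposure_factor = 0.1)
  m1 <- modifier("natural", "intake_rate", "multiply", 1.5)
  m2 <- modifier("behavioral", "intake_rate", "multiply", 2)
  rec <- function(mods) receptor_profile("r", 80, modifiers = mods)
  g_ab <- toy_grid(sch, modifiers = m1, receptor = rec(m2))
  cell_ab <- resolve_cell(g_ab, "planting", "spring", "ingestion")
  expect_equal(cell_ab$intake_rate, 100 * 3)
  # same two multipliers within one class, listed in either order
  t1 <- modifier("time_of_day", "intake_rate", "multiply", 1.5)
  t2 <- modifier("time_of_day", "intake_rate", "multiply", 2)
  g1 <- toy_grid(sch, modifiers = dplyr::bind_rows(t1, t2))
  g2 <- toy_grid(sch, modifiers = dplyr::bind_rows(t2, t1))
  expect_equal(resolve_cell(g1, "planting", "spring", "ingestion"),
               resolve_cell(g2, "planting", "spring", "ingestion"))
  # resolution never mutates the grid
  expect_equal(resolve_cell(g1, "planting", "spring", "ingestion"),
               resolve_cell(g1, "planting", "spring", "ingestion"))
  expect_equal(g1$baseline_ingestion$intake_rate, 100)
})

test_that("two overrides on one parameter in one cell are rejected", {
  sch <- tibble::tibble(task = "planting", season = "spring",
                        exposure_factor = 0.1)
  ov1 <- modifier("natural", "adherence_factor", "override", 0.2)
  ov2 <- modifier("time_of_day", "adherence_factor", "override", 0.3)
  g <- toy_grid(sch, modifiers = dplyr::bind_rows(ov1, ov2))
  expect_error(resolve_cell(g, "planting", "spring", "dermal"),
               "more than one override", class = "eatr_config_error")
})

test_that("resolved parameters must satisfy the dose-model invariants", {
  sch <- tibble::tibble(task = "planting", season = "spring",
                        exposure_factor = 0.9)
  # stacked multipliers that push the exposure factor past 1 fail loudly
  boom <- modifier("season", "exposure_factor", "multiply", 2)
  g <- toy_grid(sch, modifiers = boom)
  expect_error(resolve_cell(g, "planting", "spring", "ingestion"),
               "exposure_factor", class = "eatr_validation_error")
})

test_that("grid construction rejects bad scopes and receptor misuse", {
  sch <- tibble::tibble(task = "planting", season = "spring",
                        exposure_factor = 0.1)
  misspelled <- modifier("season", "exposure_factor", "multiply", 1.1,
                         seasons = "sprang")
  expect_error(toy_grid(sch, modifiers = misspelled), "sprang",
               class = "eatr_config_error")
  rec_mod <- modifier("biological", "intake_rate", "multiply", 1.2)
  expect_error(toy_grid(sch, modifiers = rec_mod),
               "receptor profile", class = "eatr_config_error")
  expect_error(
    receptor_profile("r", 80, modifiers = modifier("natural", "intake_rate",
                                                   "multiply", 1.2)),
    "non-receptor", class = "eatr_validation_error"
  )
  expect_error(toy_grid(tibble::tibble(task = "mowing", season = "spring",
                                       exposure_factor = 0.1)),
               "mowing", class = "eatr_config_error")
})

test_that("configs build into validated grids and round-trip", {
  g <- reference_scenario("model_7")$grid
  cfg <- as_scenario_config(g)
  rebuilt <- build_grid_from_config(cfg)
  expect_equal(rebuilt, g)

  # empty tasks list: a valid grid whose every report total is 0
  empty <- build_grid_from_config(list(
    tasks = list(), seasons = list("spring"),
    baselines = list(ingestion = g$baseline_ingestion,
                     dermal = g$baseline_dermal)
  ))
  expect_equal(run_level(empty, "meso_activity", "ingestion")$annual_total, 0)

  # schema violations carry a path to the offender
  bad <- cfg
  bad$baselines$ingestion$body_weight <- -80
  expect_error(build_grid_from_config(bad), "body_weight",
               class = "eatr_validation_error")
  bad2 <- cfg
  bad2$modifiers[[1]]$factor <- "gravity"
  expect_error(build_grid_from_config(bad2), "modifiers\\[1\\]",
               class = "eatr_config_error")
  expect_error(build_grid_from_config(list(tasks = list("a"))),
               "seasons", class = "eatr_config_error")
})
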