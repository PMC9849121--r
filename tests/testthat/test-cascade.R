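test_that("the traditional level collapses to the single baseline dose", {
  g <- toy_grid(tibble::tibble(task = "planting", season = "spring",
                               exposure_factor = 0.5))
  rep <- run_level(g, "traditional", "ingestion")
  expect_equal(nrow(rep$cells), 1)
  # baseline: 1e-4 * 100 * 0.16 / 80
  expect_equal(rep$annual_total, 1e-4 * 100 * 0.16 / 80)
  expect_equal(rep$cells$dose, rep$annual_total)
})

test_that("aggregation equals a brute-force double loop and is exactly additive", {
  set.seed(11)
  for (i in 1:20) {
    cells <- tibble::tibble(
      task = sample(letters[1:4], 12, replace = TRUE),
      season = sample(c("sp", "su", "fa", "wi"), 12, replace = TRUE),
      dose = runif(12, 0, 1e-4),
      pathway = "ingestion"
    )
    oracle <- brute_force_aggregate(cells)
    agg <- aggregate_doses(cells, seasons = oracle$seasons)
    expect_identical(agg$seasonal_subtotals$subtotal, oracle$subtotals)
    expect_identical(agg$annual_total, oracle$total)
  }
})

test_that("aggregating an empty cell map gives zeros; mixed pathways error", {
  empty <- tibble::tibble(task = character(), season = character(),
                          dose = numeric(), pathway = character())
  agg <- aggregate_doses(empty, seasons = c("spring", "summer"))
  expect_equal(agg$seasonal_subtotals$subtotal, c(0, 0))
  expect_equal(agg$annual_total, 0)
  mixed <- tibble::tibble(task = "a", season = "sp", dose = c(1, 2),
                          pathway = c("ingestion", "dermal"))
  expect_error(aggregate_doses(mixed), "pathway",
               class = "eatr_validation_error")
})

test_that("report invariants hold on fixture and synthetic runs", {
  for (nm in c("model_5", "model_8", "grower_B")) {
    fx <- reference_scenario(nm)
    for (exp in fx$expected) {
      rep <- run_level(fx$grid, fx$level_id, exp$pathway)
      for (s in rep$seasonal_subtotals$season) {
        expect_identical(
          rep$seasonal_subtotals$subtotal[rep$seasonal_subtotals$season == s],
          sum(rep$cells$dose[rep$cells$season == s])
        )
      }
      expect_identical(rep$annual_total, sum(rep$seasonal_subtotals$subtotal))
      expect_true(all(rep$cells$dose >= 0))
    }
  }
})

test_that("level comparisons reproduce the reported statistics", {
  mk <- function(total, level) {
    cells <- tibble::tibble(task = "all", season = "annual", dose = total,
                            pathway = "ingestion")
    eatr:::new_dose_report(cells, level, "ingestion", NA_character_, "x")
  }
  # task-resolved vs traditional ingestion totals: about 16% greater
  cmp <- compare_levels(mk(5.08e-5, "meso_activity"), mk(4.38e-5, "traditional"))
  expect_equal(round(cmp$percent_difference), 16)
  expect_true(cmp$defined)

  same <- compare_levels(mk(1e-5, "a"), mk(1e-5, "b"))
  expect_equal(same$percent_difference, 0)
  expect_equal(same$ratio, 1)
  expect_equal(same$oom_gap, 0)

  # the two hypothetical growers' dermal totals differ two orders of magnitude
  gap <- compare_levels(mk(3.82e-7, "a"), mk(8.2e-9, "b"))
  expect_equal(gap$oom_gap, 2)

  undef <- compare_levels(mk(1e-5, "a"), mk(0, "b"))
  expect_false(undef$defined)
  expect_true(is.na(undef$ratio))
  expect_error(compare_levels(mk(1, "a"),
                              structure(list(annual_total = 1,
                                             pathway = "dermal"),
                                        class = "eatr_dose_report")),
               "pathway", class = "eatr_validation_error")
})

test_that("dropping the highest active modifier class reproduces the lower level exactly", {
  sch <- tidyr::expand_grid(task = c("planting", "weeding"),
                            season = c("spring", "summer")) |>
    dplyr::mutate(exposure_factor = c(0.1, 0.05, 0.08, 0.02),
                  exposure_frequency = c(60, 30, 45, 10))
  mods <- dplyr::bind_rows(
    modifier("natural", "intake_rate", "multiply", 1.5, seasons = "spring"),
    modifier("crop_type", "exposure_factor", "multiply", 0.8,
             tasks = "planting"),
    modifier("season", "intake_rate", "multiply", 1.2, seasons = "summer")
  )
  rec <- receptor_profile("r", 70, modifiers = modifier(
    "biological", "intake_rate", "multiply", 0.9
  ))
  # both baselines share one body weight so that a "neutral" receptor (same
  # weight, no modifiers) is exactly the absence of the receptor class
  derm80 <- as.list(toy_dermal()); derm80$body_weight <- 80
  mk_grid <- function(modifiers, receptor) {
    scenario_grid(
      tasks = c("planting", "weeding"), seasons = c("spring", "summer"),
      baseline_ingestion = list(concentration = 1e-4, intake_rate = 100,
                                exposure_factor = 0.16, body_weight = 80),
      baseline_dermal = derm80, schedules = sch,
      modifiers = modifiers, receptor = receptor, label = "toy"
    )
  }
  g_full <- mk_grid(mods, rec)

  lv <- cascade_levels()
  for (pw in c("ingestion", "dermal")) {
    casc <- run_cascade(g_full, pw)
    # the traditional level collapses the cell structure, so exact nesting
    # applies from meso_activity upward
    for (k in 3:5) {
      upper <- casc$reports[[lv$level_id[k]]]
      # strip the top class from the grid and re-run at the same level
      top <- setdiff(lv$classes[[k]], lv$classes[[k - 1]])
      stripped_mods <- mods[mods$class != top, ]
      # removing the receptor class means a neutral receptor: baseline body
      # weight, no behavioral/biological modifiers
      stripped_rec <- if (top == "receptor") receptor_profile("r", 80) else rec
      g_stripped <- mk_grid(stripped_mods, stripped_rec)
      rerun <- run_level(g_stripped, lv$level_id[k], pw)
      lower <- run_level(g_full, lv$level_id[k - 1], pw)
      expect_equal(rerun$cells$dose, lower$cells$dose)
      expect_equal(upper$level_id, lv$level_id[k])
    }
  }
})

test_that("cascade totals are monotone under adding a multiply >= 1 modifier", {
  sch <- tidyr::expand_grid(task = c("planting", "weeding"),
                            season = c("spring", "summer")) |>
    dplyr::mutate(exposure_factor = c(0.1, 0.05, 0.08, 0.02))
  base <- toy_grid(sch)
  boosted <- toy_grid(sch, modifiers = modifier("natural", "intake_rate",
                                                "multiply", 1.7))
  c0 <- run_cascade(base, "ingestion")
  c1 <- run_cascade(boosted, "ingestion")
  t0 <- glance(c0)$annual_total
  t1 <- glance(c1)$annual_total
  expect_true(all(t1 >= t0))
})

test_that("cascades are deterministic and all-zero grids give zero totals", {
  g <- toy_grid() # no schedules at all
  casc <- run_cascade(g, "dermal")
  totals <- glance(casc)$annual_total
  # the traditional level keeps its nonzero baseline; structured levels are 0
  expect_equal(totals[-1], rep(0, length(totals) - 1))
  expect_false(any(casc$comparisons$defined))

  g2 <- toy_grid(tibble::tibble(task = "planting", season = "spring",
                                exposure_factor = 0.3,
                                exposure_frequency = 100))
  expect_equal(run_cascade(g2, "ingestion"), run_cascade(g2, "ingestion"))
})

test_that("plus_receptor without a receptor profile is a configuration error", {
  g <- toy_grid(tibble::tibble(task = "planting", season = "spring",
                               exposure_factor = 0.3))
  expect_error(run_level(g, "plus_receptor", "ingestion"),
               "receptor", class = "eatr_config_error")
  expect_error(run_level(g, "imaginary_level", "ingestion"),
               "Unknown cascade level", class = "eatr_validation_error")
})

test_that("tidiers and plots expose the report structure", {
  fx <- reference_scenario("model_5")
  rep <- run_level(fx$grid, fx$level_id, "ingestion")
  td <- tidy(rep)
  expect_equal(nrow(td), 12)
  expect_named(td, c("level_id", "pathway", "receptor", "task", "season",
                     "dose"))
  gl <- glance(rep)
  expect_equal(gl$n_cells, 12)
  expect_equal(gl$annual_total, rep$annual_total)
  casc <- run_cascade(fx$grid, "ingestion")
  expect_equal(nrow(glance(casc)), 4) # no receptor on this grid
  expect_s3_class(autoplot(rep), "ggplot")
  expect_s3_class(autoplot(casc), "ggplot")
})
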