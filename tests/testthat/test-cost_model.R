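test_that("daily cost recomposes from the accounting components", {
  strategies <- paper_strategies()
  comp <- cost_components()
  # 2 teams x 608.28 + 128.59 + 92.65 + 30.82, against the printed 1,468.61
  expect_equal(daily_cost(strategies[[1]], comp, use_overrides = FALSE),
               1468.61, tolerance = 0.02 / 1468.61)
  # overrides win when enabled
  expect_cents_equal(daily_cost(strategies[[1]], comp), 1468.61)
  zero <- screening_strategy("zero", teams_day = 0, waiting_months = 1,
                             patients_3y = 1, exams_per_day = 0)
  expect_identical(daily_cost(zero, cost_components(0, 0, 0, 0)), 0)
  # homogeneity: doubling every component doubles the cost
  double <- cost_components(2 * 608.28, 2 * 128.59, 2 * 92.65, 2 * 30.82)
  expect_cents_equal(daily_cost(strategies[[1]], double, use_overrides = FALSE),
                     2 * daily_cost(strategies[[1]], comp, use_overrides = FALSE))
})

test_that("daily revenue uses the blended per-exam tariff", {
  strategies <- paper_strategies()
  tf <- tariffs()
  expect_cents_equal(daily_revenue(strategies[[1]], tf), 3986.10)  # 40 exams
  expect_cents_equal(daily_revenue(strategies[[2]], tf), 5979.15)  # 60 exams
  # blend solved from the two consistent columns: 87 + 0.35 x 36.15 per exam
  expect_cents_equal(daily_revenue(strategies[[1]], tf), 40 * 99.6525)
  # the 80-exam column is inconsistent with the blend; the printed value is
  # an override, the component model gives 80 x 99.6525
  expect_cents_equal(daily_revenue(strategies[[3]], tf, use_overrides = FALSE),
                     7972.20)
  expect_cents_equal(daily_revenue(strategies[[3]], tf), 7936.05)
  zero <- screening_strategy("zero", teams_day = 0, waiting_months = 1,
                             patients_3y = 1, exams_per_day = 0)
  expect_identical(daily_revenue(zero, tf), 0)
})

test_that("ledger identities hold exactly to the cent", {
  t3 <- table3_accounts()
  for (i in seq_len(nrow(t3)))
    expect_cents_equal(daily_margin(t3$daily_revenue[i], t3$daily_cost[i]),
                       t3$daily_margin[i])
  expect_identical(daily_margin(123.45, 123.45), 0)
  # unit screening costs, rounded to the cent
  expect_cents_equal(unit_screening_cost(2715.99, 60), 45.27)
  expect_cents_equal(unit_screening_cost(2906.40, 80), 36.33)
  expect_identical(unit_screening_cost(0, 10), 0)
  expect_error(unit_screening_cost(100, 0), "exams_per_day")
  # cost variations against the current strategy, exact
  t4 <- table4_totals()
  expect_cents_equal(cost_variation(t4$cost_3y[2], t4$cost_3y[1]), 908550.96)
  expect_cents_equal(cost_variation(t4$cost_3y[3], t4$cost_3y[1]), 1047239.40)
  expect_identical(cost_variation(5, 5), 0)
})

test_that("the 3-year horizon reproduces the projected totals", {
  # 728.37 working days back-solved from totals / daily costs
  expect_equal(screening_cost_horizon(2715.99), 1978238.64,
               tolerance = 2e-4)
  expect_equal(screening_cost_horizon(2906.40), 2116927.08,
               tolerance = 2e-4)
  expect_identical(screening_cost_horizon(0), 0)
})

test_that("the cost ledger flags printed figures that contradict the components", {
  ledger <- cost_ledger(paper_strategies())
  expect_s3_class(ledger, "cost_ledger")
  # computed current unit cost is 1468.61/40 = 36.72, not the printed 34.42
  expect_cents_equal(ledger$unit_cost[ledger$strategy == "current"], 36.72)
  # strategies whose printed daily cost does not decompose are annotated
  expect_match(ledger$note[ledger$strategy == "22-month"], "computed daily cost")
  expect_cents_equal(ledger$daily_margin,
                     table3_accounts()$daily_margin)
  expect_cents_equal(ledger$cost_variation, c(0, 908550.96, 1047239.40))
})

test_that("a ledger CSV round trip preserves every cent", {
  ledger <- cost_ledger(paper_strategies())
  path <- withr::local_tempfile(fileext = ".csv")
  write_ledger(ledger, path)
  back <- read_ledger(path)
  for (col in c("daily_revenue", "daily_cost", "daily_margin", "unit_cost",
                "cost_3y", "cost_variation"))
    expect_cents_equal(back[[col]], ledger[[col]])
})
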