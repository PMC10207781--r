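test_that("pr_met follows the Poisson zero-event complement", {
  m <- metastasis_model(P = 5e9)
  expect_identical(pr_met(0, m), 0)
  expect_equal(pr_met(5e9 * log(2), m), 0.5)
  # Table-consistent anchor: mu = 0.2231 gives a 20% probability
  expect_equal(pr_met(0.2231 * 5e9, m), 0.20, tolerance = 1e-3)
  n <- 10^seq(0, 10, by = 0.25)
  p <- pr_met(n, m)
  expect_true(all(diff(p) > 0))       # strictly increasing in cells
  expect_true(all(pr_met(10^seq(0, 15), m) < 1))  # bounded below 1
  expect_error(pr_met(-1, m), "cells")
  expect_error(metastasis_model(0), "positive")
})

test_that("calibrate_P recovers P exactly from a single informative pair", {
  bands <- stage_bands()
  obs <- data.frame(stage = "T1C", point = 0.5)
  n_t1c <- cells_from_diameter(bands$representative_mm[bands$stage == "T1C"])
  expect_equal(calibrate_P(obs, bands)$P, n_t1c / log(2))
  expect_error(calibrate_P(data.frame(stage = "T1C", point = 0)),
               "calibration failure")
})

test_that("calibrate_P recovers a known P* from a noiseless table within 1%", {
  bands <- stage_bands()
  kin <- growth_model()
  P_star <- 7e9
  truth <- metastasis_model(P_star)
  obs <- data.frame(
    stage = c("T1B", "T1C", "T2"),
    point = pr_met(cells_from_diameter(
      bands$representative_mm[match(c("T1B", "T1C", "T2"), bands$stage)]),
      truth))
  fit <- calibrate_P(obs, bands, kin)
  expect_equal(fit$P, P_star, tolerance = 0.01)
  expect_lt(max(abs(attr(fit, "residuals"))), 1e-6)
})

test_that("calibration is scale-consistent: scaling all cell counts scales P", {
  bands <- stage_bands()
  P_star <- 7e9
  for (k in c(0.1, 10)) {
    kin <- growth_model(cell_density_per_cm3 = 1e9 * k)
    truth <- metastasis_model(P_star * k)
    obs <- data.frame(
      stage = c("T1B", "T1C", "T2"),
      point = pr_met(cells_from_diameter(
        bands$representative_mm[match(c("T1B", "T1C", "T2"), bands$stage)],
        1e9 * k), truth))
    expect_equal(calibrate_P(obs, bands, kin)$P, P_star * k,
                 tolerance = 0.01)
  }
})

test_that("calibration under binomial noise at registry sample sizes brackets P*", {
  bands <- stage_bands()
  P_star <- 7e9
  truth <- metastasis_model(P_star)
  stages <- c("T1B", "T1C", "T2")
  n_stage <- c(65, 95, 59)  # registry patients per informative stage
  p_true <- pr_met(cells_from_diameter(
    bands$representative_mm[match(stages, bands$stage)]), truth)
  set.seed(20190101)
  recovered <- replicate(60, {
    obs <- data.frame(stage = stages,
                      point = stats::rbinom(3, n_stage, p_true) / n_stage)
    tryCatch(calibrate_P(obs, bands)$P, error = function(e) NA_real_)
  })
  recovered <- recovered[!is.na(recovered)]
  expect_gt(length(recovered), 50)
  ci <- stats::quantile(recovered, c(0.025, 0.975))
  expect_gt(P_star, ci[1])
  expect_lt(P_star, ci[2])
})

test_that("fit against the reference strategy column reproduces it closely", {
  fit <- calibrate_P(reference_stage_probs())
  tab <- stage_probabilities(32, fit, reference_months = 32)
  merged <- merge(tab, reference_stage_probs(), by = "stage",
                  suffixes = c("_fit", "_obs"))
  expect_lt(max(abs(merged$point_fit - merged$point_obs)), 0.02)
})

test_that("stage probabilities are monotone in waiting time, stage by stage", {
  fit <- calibrate_P(reference_stage_probs())
  cols <- lapply(c(16, 22, 32), stage_probabilities, model = fit)
  for (s in c("T1A", "T1B", "T1C", "T2")) {
    p <- vapply(cols, function(tab) tab$point[tab$stage == s], numeric(1))
    expect_true(all(diff(p) >= 0))  # shorter wait => probability no larger
  }
  # T3 sits above the palpability threshold: flagged, no probability
  for (tab in cols) {
    expect_true(tab$above_palpability[tab$stage == "T3"])
    expect_true(is.na(tab$point[tab$stage == "T3"]))
  }
  expect_error(stage_probabilities(0, fit), "waiting_months")
})

test_that("as waiting time vanishes, sub-detection bands settle at the detection threshold", {
  fit <- calibrate_P(reference_stage_probs())
  th <- tumor_thresholds()
  tab <- stage_probabilities(0.5, fit, thresholds = th)
  # T1A representative size rewound below Td is floored at Td
  expect_equal(tab$point[tab$stage == "T1A"],
               pr_met(th$detection_cells, fit))
  expect_equal(tab$point[tab$stage == "T1B"],
               pr_met(th$detection_cells, fit))
})

test_that("Wilson intervals match the score-equation roots and contain the point", {
  # independent oracle: interval endpoints are the roots p of
  # (phat - p)^2 = z^2 p (1 - p) / n
  wilson_roots <- function(phat, n, z = stats::qnorm(0.975)) {
    roots <- Re(polyroot(c(phat^2, -(2 * phat + z^2 / n), 1 + z^2 / n)))
    sort(roots)
  }
  ci <- probability_interval(0.5, 100)
  expect_equal(c(ci$lo, ci$hi), wilson_roots(0.5, 100), tolerance = 1e-9)
  expect_equal(c(ci$lo, ci$hi), c(0.404, 0.596), tolerance = 1e-2)
  for (p in c(0.03, 0.2, 0.59, 0.9)) {
    ci <- probability_interval(p, 242)
    expect_equal(c(ci$lo, ci$hi), wilson_roots(p, 242), tolerance = 1e-9)
    expect_lte(ci$lo, p)
    expect_gte(ci$hi, p)
  }
  expect_identical(probability_interval(0, 50)$lo, 0)
  # widths shrink as the effective sample size grows
  w <- vapply(c(50, 242, 1000),
              function(n) diff(unlist(probability_interval(0.2, n))),
              numeric(1))
  expect_true(all(diff(w) < 0))
  expect_error(probability_interval(0.5, 0), "n_effective")
  expect_error(probability_interval(1.2, 10), "point")
})
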