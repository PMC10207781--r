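# Published accounting / effectiveness tables rebuilt in code, used as
# expected values and as pipeline inputs throughout the suite.

table3_accounts <- function() {
  data.frame(
    strategy = c("current", "22-month", "16-month"),
    exams_per_day = c(40, 60, 80),
    daily_revenue = c(3986.10, 5979.15, 7936.05),
    daily_cost = c(1468.61, 2715.99, 2906.40),
    daily_margin = c(2517.49, 3263.16, 5029.65),
    stringsAsFactors = FALSE
  )
}

table4_totals <- function() {
  data.frame(
    strategy = c("current", "22-month", "16-month"),
    unit_cost_printed = c(34.42, 45.27, 36.33),
    cost_3y = c(1069687.68, 1978238.64, 2116927.08),
    stringsAsFactors = FALSE
  )
}

# Observed stage-wise metastasis probabilities, reference (32-month) column.
reference_stage_probs <- function() {
  data.frame(stage = c("T1A", "T1B", "T1C", "T2"),
             point = c(0.00, 0.03, 0.20, 0.59),
             stringsAsFactors = FALSE)
}

incident_patients <- function() {
  data.frame(
    strategy = rep(c("current", "22-month", "16-month"), each = 2),
    stratum = rep(c("metastatic", "non_metastatic"), 3),
    incident = c(12.8, 25.9, 14.9, 43.2, 11.2, 66.3),
    stringsAsFactors = FALSE
  )
}

qaly_strata_printed <- function() {
  data.frame(
    strategy = rep(c("current", "22-month", "16-month"), each = 2),
    stratum = rep(c("metastatic", "non_metastatic"), 3),
    qaly = c(10.3, 50.6, 12.0, 84.4, 9.0, 129.4),
    stringsAsFactors = FALSE
  )
}

paper_strategies <- function() {
  list(
    screening_strategy("current", teams_day = 2, waiting_months = 32,
                       patients_3y = 30000, mammographs = 2, ultrasounds = 3,
                       reporting_stations = 3,
                       overrides = list(daily_cost = 1468.61,
                                        cost_3y = 1069687.68)),
    screening_strategy("22-month", teams_day = 3, waiting_months = 22,
                       patients_3y = 45000,
                       overrides = list(daily_cost = 2715.99,
                                        cost_3y = 1978238.64)),
    screening_strategy("16-month", teams_day = 2, teams_afternoon = 2,
                       waiting_months = 16, patients_3y = 60000,
                       overrides = list(daily_cost = 2906.40,
                                        daily_revenue = 7936.05,
                                        cost_3y = 2116927.08))
  )
}

expect_cents_equal <- function(object, expected) {
  expect_identical(round(object * 100), round(expected * 100))
}
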