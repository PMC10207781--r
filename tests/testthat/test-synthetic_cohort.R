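test_that("cohort generation is seeded, typed and size-faithful", {
  spec <- cohort_spec(n = 0)
  expect_identical(nrow(generate_cohort(spec)), 0L)
  spec <- cohort_spec(n = 500, seed = 7)
  a <- generate_cohort(spec)
  b <- generate_cohort(spec)
  expect_identical(a, b)                       # same spec + seed => same cohort
  expect_identical(nrow(a), 500L)
  expect_true(all(a$t_stage %in% c("T1A", "T1B", "T1C", "T2", "T3")))
  expect_true(all(a$node_status %in% c("N0", "N+")))
  expect_true(all(a$grade %in% 1:3))
  # diameters respect the band of their stage
  bands <- data.frame(stage = c("T1A", "T1B", "T1C", "T2", "T3"),
                      lo = c(1, 5, 10, 20, 50), hi = c(5, 10, 20, 50, 100))
  idx <- match(a$t_stage, bands$stage)
  expect_true(all(a$diameter_mm >= bands$lo[idx] &
                    a$diameter_mm <= bands$hi[idx]))
  # serialized cohorts are byte-identical across runs
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_cohort(a, p1); write_cohort(generate_cohort(spec), p2)
  expect_identical(readLines(p1), readLines(p2))
  expect_error(cohort_spec(n = 10, stage_freqs = c(T1A = -1, T1B = 2)),
               "configuration error")
})

test_that("registry-sized cohorts land within binomial bands of the stage counts", {
  spec <- cohort_spec(n = 242, seed = 11)
  cohort <- generate_cohort(spec)
  counts <- table(factor(cohort$t_stage,
                         levels = names(spec$stage_freqs)))
  expected <- c(T1A = 20, T1B = 65, T1C = 95, T2 = 59, T3 = 3)
  # five simultaneous category checks: per-category bands at 99% so the
  # joint check keeps ~95% coverage
  for (s in names(expected)) {
    p <- expected[[s]] / 242
    expect_gte(counts[[s]], stats::qbinom(0.005, 242, p))
    expect_lte(counts[[s]], stats::qbinom(0.995, 242, p))
  }
})

test_that("generated marginals converge to the spec frequencies", {
  # chi-square goodness of fit at n = 10,000 across seeds: non-significant
  # at alpha = 0.01 in the overwhelming majority of runs
  seeds <- 1:40
  pvals <- vapply(seeds, function(s) {
    cohort <- generate_cohort(cohort_spec(n = 10000, seed = s))
    spec <- cohort_spec()
    counts <- table(factor(cohort$t_stage, levels = names(spec$stage_freqs)))
    stats::chisq.test(counts, p = spec$stage_freqs)$p.value
  }, numeric(1))
  expect_lte(sum(pvals < 0.01), 2)
})

test_that("metastasis assignment converges to the model probability", {
  model <- metastasis_model(P = 7e9)
  n <- 50000
  cohort <- data.frame(patient_id = seq_len(n), t_stage = "T1C",
                       diameter_mm = 15, node_status = "N0",
                       histology = "ductal", grade = 2, metastatic = NA)
  out <- assign_metastasis(cohort, model, seed = 3)
  p <- pr_met(cells_from_diameter(15), model)
  se <- sqrt(p * (1 - p) / n)
  expect_lt(abs(mean(out$metastatic) - p), 3 * se)
  # limit: an (effectively) infinite P produces no metastases
  none <- assign_metastasis(cohort, metastasis_model(P = 1e300), seed = 3)
  expect_identical(sum(none$metastatic), 0L)
})

test_that("expected metastatic counts shrink as the waiting list shortens", {
  fit <- calibrate_P(reference_stage_probs())
  stage_n <- c(T1A = 20, T1B = 65, T1C = 95, T2 = 59)
  expected_count <- function(months) {
    tab <- stage_probabilities(months, fit)
    sum(stage_n * tab$point[match(names(stage_n), tab$stage)])
  }
  counts <- vapply(c(16, 22, 32), expected_count, numeric(1))
  expect_true(all(diff(counts) > 0))  # 16-month < 22-month < 32-month
})

test_that("rescaling a spec to a strategy adopts its screened volume", {
  spec <- cohort_spec(n = 242)
  strategies <- paper_strategies()
  expect_identical(scale_to_strategy(spec, strategies[[1]])$n, 30000L)
  expect_identical(scale_to_strategy(spec, strategies[[3]])$n, 60000L)
  same <- screening_strategy("same", teams_day = 1, waiting_months = 32,
                             patients_3y = 242)
  expect_identical(scale_to_strategy(spec, same)$n, spec$n)
  # optional kinetic down-staging: shorter waits shift mass to smaller stages
  shifted <- scale_to_strategy(spec, strategies[[3]], shift_stage_mix = TRUE)
  small_before <- sum(spec$stage_freqs[c("T1A", "T1B", "T1C")])
  small_after <- sum(shifted$stage_freqs[c("T1A", "T1B", "T1C")])
  expect_gte(small_after, small_before)
  expect_equal(sum(shifted$stage_freqs), 1)
})
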