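#' Read a pipeline run configuration
#'
#' A single YAML file with blocks mirroring the module boundaries:
#' `tumor_model`, `costs`, `tariffs`, `strategies`, `qol`, `survival_table`,
#' `incident`, `qaly_printed`, `observed_stage_probabilities`, `cohort`,
#' plus `reference_strategy` and `use_printed_overrides`. Relative paths
#' (e.g. the survival table) are resolved against the config file's
#' directory. The packaged default reproduces the published accounting and
#' effectiveness tables.
#'
#' @param path YAML file; defaults to the packaged configuration.
#' @return A list of class `run_config` with attributes `config_dir` and
#'   `config_md5`.
#' @export
read_run_config <- function(path = default_config_path()) {
  if (!file.exists(path)) stop("I/O error: cannot read config file ", path)
  config <- yaml::read_yaml(path)
  attr(config, "config_dir") <- dirname(normalizePath(path))
  attr(config, "config_md5") <- unname(tools::md5sum(path))
  class(config) <- "run_config"
  config
}

#' @rdname read_run_config
#' @export
default_config_path <- function() {
  system.file("extdata", "config.yaml", package = "waitlineCEA")
}

resolve_path <- function(path, config) {
  if (file.exists(path)) return(path)
  candidate <- file.path(attr(config, "config_dir") %||% ".", path)
  if (file.exists(candidate)) return(candidate)
  stop("I/O error: cannot resolve path ", path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

config_strategies <- function(config) {
  lapply(config$strategies, function(s) {
    screening_strategy(
      name = s$name,
      teams_day = s$teams_day %||% 0,
      teams_afternoon = s$teams_afternoon %||% 0,
      waiting_months = s$waiting_months,
      patients_3y = s$patients_3y,
      exams_per_day = s$exams_per_day %||%
        (20 * ((s$teams_day %||% 0) + (s$teams_afternoon %||% 0))),
      mammographs = s$mammographs %||% NA_integer_,
      ultrasounds = s$ultrasounds %||% NA_integer_,
      reporting_stations = s$reporting_stations %||% NA_integer_,
      overrides = s$overrides %||% list()
    )
  })
}

config_components <- function(config) {
  args <- config$costs %||% list()
  do.call(cost_components, args[intersect(names(args),
                                          names(formals(cost_components)))])
}

config_tariffs <- function(config) {
  do.call(tariffs, config$tariffs %||% list())
}

config_kinetics <- function(config) {
  tm <- config$tumor_model %||% list()
  growth_model(doubling_time_days = tm$doubling_time_days %||% 168.5,
               cell_density_per_cm3 = tm$cell_density_per_cm3 %||% 1e9)
}

config_thresholds <- function(config) {
  tm <- config$tumor_model %||% list()
  tumor_thresholds(detection_cells = tm$detection_cells %||% 1e7,
                   palpability_cells = tm$palpability_cells %||% 1e10,
                   cell_density_per_cm3 = tm$cell_density_per_cm3 %||% 1e9)
}

#' Validate a run configuration
#'
#' Checks the whole configuration without side effects and returns every
#' violation found (frequency vectors, payer fraction, negative costs,
#' capacity identities, overlapping stage bands, unresolvable paths). An
#' empty character vector means the configuration is runnable.
#'
#' @param config A [read_run_config()] list.
#' @return Character vector of issues, empty when valid.
#' @export
validate_config <- function(config) {
  issues <- character(0)
  note <- function(...) issues <<- c(issues, paste0(...))

  if (is.null(config$strategies) || length(config$strategies) == 0) {
    note("strategies: block missing or empty")
  } else {
    for (s in config$strategies) {
      nm <- s$name %||% "<unnamed>"
      if (is.null(s$waiting_months) || s$waiting_months <= 0)
        note("strategies/", nm, ": waiting_months must be > 0")
      if (is.null(s$patients_3y) || s$patients_3y <= 0)
        note("strategies/", nm, ": patients_3y must be > 0")
      teams <- (s$teams_day %||% 0) + (s$teams_afternoon %||% 0)
      if (!is.null(s$exams_per_day) && s$exams_per_day != 20 * teams)
        note("strategies/", nm, ": exams_per_day != 20 x teams (",
             s$exams_per_day, " vs ", 20 * teams, ")")
    }
    ref <- config$reference_strategy %||% config$strategies[[1]]$name
    if (!ref %in% vapply(config$strategies, `[[`, "", "name"))
      note("reference_strategy: '", ref, "' not among strategies")
  }

  tf <- config$tariffs %||% list()
  pf <- tf$paying_fraction %||% 0.35
  if (pf < 0 || pf > 1)
    note("tariffs/paying_fraction: must lie in [0, 1], got ", pf)
  for (fee in c("paying_exam_fee", "ticket_fee"))
    if (!is.null(tf[[fee]]) && tf[[fee]] < 0)
      note("tariffs/", fee, ": must be >= 0")

  for (comp in names(config$costs %||% list()))
    if (is.numeric(config$costs[[comp]]) && any(config$costs[[comp]] < 0))
      note("costs/", comp, ": must be >= 0")

  for (w in names(config$qol %||% list()))
    if (config$qol[[w]] < 0 || config$qol[[w]] > 1)
      note("qol/", w, ": utility must lie in [0, 1]")

  for (fv in c("stage_freqs", "node_freqs", "histology_freqs", "grade_freqs")) {
    f <- config$cohort[[fv]]
    if (!is.null(f)) {
      f <- unlist(f)
      if (any(f < 0) || sum(f) <= 0)
        note("cohort/", fv, ": invalid frequency vector")
    }
  }

  for (row in config$observed_stage_probabilities %||% list())
    if (row$point < 0 || row$point > 1)
      note("observed_stage_probabilities/", row$stage,
           ": probability outside [0, 1]")

  custom_bands <- config$stage_bands
  if (!is.null(custom_bands)) {
    lo <- vapply(custom_bands, `[[`, numeric(1), "lo")
    hi <- vapply(custom_bands, `[[`, numeric(1), "hi")
    labels <- vapply(custom_bands, `[[`, character(1), "stage")
    ord <- order(lo)
    lo <- lo[ord]; hi <- hi[ord]; labels <- labels[ord]
    if (any(lo >= hi))
      for (i in which(lo >= hi))
        note("stage_bands/", labels[i], ": lo must be < hi")
    if (length(lo) > 1)
      for (i in seq_len(length(lo) - 1))
        if (hi[i] > lo[i + 1])
          note("stage_bands: bands ", labels[i], " and ", labels[i + 1],
               " overlap")
  }

  if (!is.null(config$survival_table)) {
    ok <- tryCatch({resolve_path(config$survival_table, config); TRUE},
                   error = function(e) FALSE)
    if (!ok) note("survival_table: cannot resolve path ",
                  config$survival_table)
  }
  issues
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full cost-utility pipeline
#'
#' Orchestrates cost ledger, metastasis-model calibration and stage
#' probabilities, effectiveness (LY/LYG/QALY), ICER ranking and synthetic
#' cohort generation from one configuration, writing `ledger.csv`,
#' `stage_probabilities.csv`, `effects.csv`, `icer.csv`, `cohort.csv` and a
#' Markdown `report.md` to `out_dir`. Every file's numbers are copied from
#' the stage outputs (single source of truth); the report header stamps the
#' config MD5 and the seed. Any stage failure aborts with the stage name.
#'
#' @param config A [read_run_config()] list (or a path to one).
#' @param out_dir Output directory, created if needed.
#' @param seed Integer seed used for the synthetic cohort.
#' @return Invisibly, a list with `ledger`, `stage_probabilities`,
#'   `effects`, `qaly_totals`, `icer`, `cohort`, `metastasis_model`,
#'   `seed`, `config_md5`.
#' @export
run_pipeline <- function(config = read_run_config(), out_dir, seed = 1L) {
  if (is.character(config)) config <- read_run_config(config)
  issues <- validate_config(config)
  if (length(issues))
    stop("invalid configuration:\n", paste("-", issues, collapse = "\n"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  use_overrides <- isTRUE(config$use_printed_overrides %||% TRUE)
  reference <- config$reference_strategy %||% config$strategies[[1]]$name

  strategies <- with_stage("config", config_strategies(config))
  kinetics <- with_stage("config", config_kinetics(config))
  thresholds <- with_stage("config", config_thresholds(config))

  ledger <- with_stage("cost", {
    cost_ledger(strategies, config_components(config),
                config_tariffs(config),
                working_days = config$costs$working_days_3y %||% 728.37,
                reference = reference, use_overrides = use_overrides)
  })
  write_ledger(ledger, file.path(out_dir, "ledger.csv"))

  bands <- stage_bands(thresholds)
  met_model <- with_stage("metastasis", {
    observed <- do.call(rbind, lapply(config$observed_stage_probabilities,
                                      as.data.frame))
    calibrate_P(observed, bands, kinetics)
  })
  stage_probs <- with_stage("metastasis", {
    ref_months <- strategies[[which(vapply(strategies, `[[`, "",
                                           "name") == reference)]]$waiting_months
    do.call(rbind, lapply(strategies, function(s) {
      tab <- stage_probabilities(s$waiting_months, met_model, bands,
                                 kinetics, thresholds,
                                 reference_months = ref_months)
      cbind(strategy = s$name, tab)
    }))
  })
  write_stage_probabilities(stage_probs,
                            file.path(out_dir, "stage_probabilities.csv"))

  effects <- with_stage("effectiveness", {
    incident <- do.call(rbind, lapply(config$incident, as.data.frame))
    survival <- read_survival_table(resolve_path(config$survival_table,
                                                 config))
    overrides <- NULL
    if (use_overrides && !is.null(config$qaly_printed))
      overrides <- do.call(rbind, lapply(config$qaly_printed, as.data.frame))
    effect_table(incident, survival, do.call(qol_weights, config$qol %||% list()),
                 reference = reference, qaly_overrides = overrides)
  })
  write_effects(effects, file.path(out_dir, "effects.csv"))
  qaly_totals <- strategy_qaly_table(effects, reference)

  icers <- with_stage("cea", icer_table(ledger, qaly_totals, reference))
  icers <- rank_strategies(icers, threshold = config$wtp_threshold)
  write_icer_table(icers, file.path(out_dir, "icer.csv"))

  cohort <- with_stage("cohort", {
    cfg <- config$cohort %||% list()
    spec <- cohort_spec(
      n = cfg$n %||% 242,
      stage_freqs = unlist(cfg$stage_freqs %||%
                             list(T1A = 20, T1B = 65, T1C = 95, T2 = 59, T3 = 3)),
      node_freqs = unlist(cfg$node_freqs %||% list(N0 = 154, `N+` = 88)),
      histology_freqs = unlist(cfg$histology_freqs %||%
                                 list(ductal = 189, lobular = 44,
                                      tubular = 5, mucinous = 2)),
      grade_freqs = unlist(cfg$grade_freqs %||%
                             list(`1` = 79, `2` = 109, `3` = 47)),
      seed = seed)
    assign_metastasis(generate_cohort(spec), met_model, seed = seed + 1L,
                      kinetics = kinetics)
  })
  write_cohort(cohort, file.path(out_dir, "cohort.csv"))

  result <- list(ledger = ledger, stage_probabilities = stage_probs,
                 effects = effects, qaly_totals = qaly_totals,
                 icer = icers, cohort = cohort,
                 metastasis_model = met_model, seed = seed,
                 config_md5 = attr(config, "config_md5"))
  with_stage("report", write_report(result, file.path(out_dir, "report.md")))
  invisible(result)
}

fmt_tab <- function(df, digits = 2) {
  df <- as.data.frame(df)
  for (j in seq_along(df))
    if (is.numeric(df[[j]])) df[[j]] <- format(round(df[[j]], digits),
                                               nsmall = digits,
                                               big.mark = ",", trim = TRUE)
  header <- paste("|", paste(names(df), collapse = " | "), "|")
  sep <- paste("|", paste(rep("---", ncol(df)), collapse = " | "), "|")
  body <- apply(df, 1, function(r) paste("|", paste(r, collapse = " | "), "|"))
  paste(c(header, sep, body), collapse = "\n")
}

write_report <- function(result, path) {
  lines <- c(
    "# Waiting-list cost-utility report",
    "",
    sprintf("config md5: `%s`  |  seed: %d", result$config_md5 %||% "NA",
            result$seed),
    "",
    "## Cost ledger (EUR)",
    "",
    fmt_tab(result$ledger[, c("strategy", "daily_revenue", "daily_cost",
                              "daily_margin", "unit_cost", "cost_3y",
                              "cost_variation")]),
    "",
    "## Stage-wise metastasis probabilities",
    "",
    fmt_tab(transform(result$stage_probabilities,
                      point = round(point, 4), lo = round(lo, 4),
                      hi = round(hi, 4)), 4),
    "",
    sprintf("Calibrated Poisson seeding parameter P = %.4g cells.",
            result$metastasis_model$P),
    "",
    "## Effectiveness (LY / LYG / QALY)",
    "",
    fmt_tab(result$effects[, c("strategy", "stratum", "incident", "LY",
                               "LYG", "QALY")], 1),
    "",
    "### Strategy totals",
    "",
    fmt_tab(result$qaly_totals, 1),
    "",
    "## Incremental cost-effectiveness",
    "",
    fmt_tab(result$icer),
    "",
    sprintf("Synthetic cohort: %d patients, %d metastatic.",
            nrow(result$cohort), sum(result$cohort$metastatic)),
    "")
  writeLines(lines, path)
  invisible(path)
}
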