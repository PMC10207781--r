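#' Quality-of-life utility weights
#'
#' Health-state utilities on the 0 (dead) to 1 (full health) scale used to
#' quality-adjust life years: non-metastatic disease is weighted 0.696 in
#' the first year and 0.779 in subsequent years; metastatic disease 0.685 in
#' every year.
#'
#' @param non_met_first_year,non_met_subsequent,metastatic_all_years
#'   Utilities in \[0, 1\].
#' @return An object of class `qol_weights`.
#' @export
qol_weights <- function(non_met_first_year = 0.696,
                        non_met_subsequent = 0.779,
                        metastatic_all_years = 0.685) {
  w <- c(non_met_first_year, non_met_subsequent, metastatic_all_years)
  if (any(w < 0 | w > 1)) stop("QoL weights must lie in [0, 1]")
  structure(list(non_met_first_year = non_met_first_year,
                 non_met_subsequent = non_met_subsequent,
                 metastatic_all_years = metastatic_all_years),
            class = "qol_weights")
}

#' Stage-specific life-expectancy table
#'
#' Life expectancy (years, within the 3-year analysis horizon) per
#' metastatic stratum. The packaged fixture
#' `seer_life_expectancy_synthetic.csv` is a synthetic stand-in with the
#' shape of a SEER-derived survival-by-stage table; its two values are free
#' parameters of the pipeline, calibrated once against the reference
#' life-years-gained totals, and are meant to be replaced with registry
#' values by users who have them.
#'
#' @param path CSV with columns `stratum,life_expectancy_years`; defaults to
#'   the packaged synthetic fixture.
#' @return data.frame with one row per stratum.
#' @export
read_survival_table <- function(path = system.file("extdata",
                                                   "seer_life_expectancy_synthetic.csv",
                                                   package = "waitlineCEA")) {
  tab <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("stratum", "life_expectancy_years")
  if (!all(need %in% names(tab)))
    stop("survival table must have columns: ", paste(need, collapse = ", "))
  if (any(tab$life_expectancy_years < 0))
    stop("life expectancy must be >= 0")
  nm <- tab$life_expectancy_years[tab$stratum == "non_metastatic"]
  m <- tab$life_expectancy_years[tab$stratum == "metastatic"]
  if (length(nm) == 1L && length(m) == 1L && nm < m)
    stop("non-metastatic life expectancy must not be below metastatic")
  tab
}

#' Life years from incident patients
#'
#' @param incident_patients Incident patient count (>= 0).
#' @param life_expectancy Life expectancy in years (>= 0).
#' @return Life years: the product.
#' @export
life_years <- function(incident_patients, life_expectancy) {
  if (any(incident_patients < 0) || any(life_expectancy < 0))
    stop("inputs must be >= 0")
  incident_patients * life_expectancy
}

#' Life years gained against a reference strategy
#'
#' @param strategy_ly,reference_ly Life-year totals.
#' @return Difference (may be negative).
#' @export
life_years_gained <- function(strategy_ly, reference_ly) {
  strategy_ly - reference_ly
}

#' Quality-adjust life years for one stratum
#'
#' Metastatic life years are weighted by the metastatic utility throughout.
#' Non-metastatic life years split into a first-year share at the first-year
#' utility and the remainder at the subsequent-year utility; the share is
#' `first_year_fraction`, naturally `1 / life_expectancy` when each incident
#' patient contributes one first year.
#'
#' @param ly Life years (>= 0).
#' @param weights A [qol_weights()].
#' @param stratum `"metastatic"` or `"non_metastatic"`.
#' @param first_year_fraction Fraction of non-metastatic life years lived in
#'   the first year of disease.
#' @return Quality-adjusted life years.
#' @export
qaly <- function(ly, weights = qol_weights(), stratum,
                 first_year_fraction = NULL) {
  if (any(ly < 0)) stop("ly must be >= 0")
  stopifnot(inherits(weights, "qol_weights"))
  if (stratum == "metastatic") return(ly * weights$metastatic_all_years)
  if (stratum == "non_metastatic") {
    if (is.null(first_year_fraction))
      stop("first_year_fraction required for the non-metastatic stratum")
    if (any(first_year_fraction < 0 | first_year_fraction > 1))
      stop("first_year_fraction must lie in [0, 1]")
    w <- weights$non_met_first_year * first_year_fraction +
      weights$non_met_subsequent * (1 - first_year_fraction)
    return(ly * w)
  }
  stop("unknown stratum: ", stratum)
}

#' Effect table: LY, LYG and QALY per strategy and stratum
#'
#' Multiplies incident patients by stratum life expectancy to get life years
#' (LY), differences each strategy against the reference for life years
#' gained (LYG), and quality-adjusts the LY levels with the QoL weights
#' before differencing (incremental QALYs are then differences of weighted
#' levels). Printed stratum QALYs may be supplied via `qaly_overrides` when
#' reproducing a published table whose unrounded inputs are unavailable.
#'
#' @param incident data.frame with columns `strategy`, `stratum`,
#'   `incident` (incident patients).
#' @param survival Survival table as from [read_survival_table()].
#' @param weights A [qol_weights()].
#' @param reference Name of the reference strategy.
#' @param qaly_overrides Optional data.frame `strategy`, `stratum`, `qaly`
#'   replacing the computed stratum QALYs.
#' @return data.frame of class `effect_table` with per-stratum rows.
#' @export
effect_table <- function(incident, survival = read_survival_table(),
                         weights = qol_weights(), reference,
                         qaly_overrides = NULL) {
  stopifnot(all(c("strategy", "stratum", "incident") %in% names(incident)))
  eff <- merge(incident,
               stats::setNames(survival[, c("stratum", "life_expectancy_years")],
                               c("stratum", "life_expectancy")),
               by = "stratum")
  if (nrow(eff) != nrow(incident))
    stop("survival table is missing a stratum present in the incident table")
  eff$LY <- life_years(eff$incident, eff$life_expectancy)
  eff$QALY <- mapply(function(ly, stratum, le) {
    qaly(ly, weights, stratum,
         first_year_fraction = if (stratum == "non_metastatic")
           min(1, 1 / le) else NULL)
  }, eff$LY, eff$stratum, eff$life_expectancy)
  if (!is.null(qaly_overrides)) {
    stopifnot(all(c("strategy", "stratum", "qaly") %in% names(qaly_overrides)))
    key <- paste(eff$strategy, eff$stratum)
    okey <- paste(qaly_overrides$strategy, qaly_overrides$stratum)
    hit <- match(key, okey)
    eff$QALY[!is.na(hit)] <- qaly_overrides$qaly[hit[!is.na(hit)]]
  }
  if (!reference %in% eff$strategy)
    stop("reference strategy '", reference, "' absent from incident table")
  ref <- eff[eff$strategy == reference, c("stratum", "LY")]
  eff$LYG <- eff$LY - ref$LY[match(eff$stratum, ref$stratum)]
  eff <- eff[order(eff$strategy != reference, eff$strategy, eff$stratum), ]
  rownames(eff) <- NULL
  class(eff) <- c("effect_table", "data.frame")
  eff
}

#' Per-strategy QALY totals from an effect table
#'
#' Sums the stratum rows of an effect table into one row per strategy;
#' stratum QALYs add exactly to the strategy total.
#'
#' @param effects An [effect_table()].
#' @param reference Reference strategy for incremental columns.
#' @return data.frame `strategy`, `LY`, `LYG`, `QALY`, `incremental_qaly`.
#' @export
strategy_qaly_table <- function(effects, reference = effects$strategy[1]) {
  agg <- stats::aggregate(cbind(LY, LYG, QALY) ~ strategy, data = effects,
                          FUN = sum)
  ref_q <- agg$QALY[agg$strategy == reference]
  if (length(ref_q) != 1L)
    stop("reference strategy '", reference, "' not found")
  agg$incremental_qaly <- vapply(agg$QALY, incremental_qaly, numeric(1),
                                 reference_total = ref_q)
  agg[order(agg$strategy != reference, agg$strategy), , drop = FALSE]
}

#' Incremental QALYs of a strategy against the reference
#'
#' @param strategy_total,reference_total Per-strategy QALY totals.
#' @return Difference.
#' @export
incremental_qaly <- function(strategy_total, reference_total) {
  strategy_total - reference_total
}

#' Write / read an effect table as CSV
#'
#' @param effects An [effect_table()].
#' @param path File path.
#' @return `read_effects` returns the data.frame.
#' @export
write_effects <- function(effects, path) {
  utils::write.csv(effects, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_effects
#' @export
read_effects <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
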