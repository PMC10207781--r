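#' @title Currency helpers (cent-exact arithmetic)
#' @description Ledger identities (margin = revenue - cost, variations,
#'   unit costs) must hold exactly to the cent, so all ledger arithmetic is
#'   carried out on integer cents and converted back to euros only at the
#'   edges.
#' @param euros Numeric euro amount(s).
#' @return `as_cents` returns integer cents; `as_euros` numeric euros.
#' @keywords internal
as_cents <- function(euros) {
  if (any(!is.finite(euros))) stop("currency must be finite")
  round(euros * 100)
}

#' @rdname as_cents
#' @param cents Integer cent amount(s).
#' @keywords internal
as_euros <- function(cents) cents / 100

#' Cost components of the radiology service
#'
#' Average daily cost shares (over the 5 working hours devoted to first-level
#' exams) of the four accounting lines: staff (per team and day), goods and
#' services, overheads, and equipment. Defaults are the 2019 accounting
#' figures of the modelled department. Annual totals are carried as metadata.
#'
#' @param staff_daily_per_team Daily staff cost per screening team (EUR).
#' @param goods_services_daily Daily goods-and-services share (EUR).
#' @param overheads_daily Daily overheads share (EUR).
#' @param equipment_daily Daily equipment share (EUR).
#' @param staff_annual,goods_services_annual,overheads_annual,equipment_annual
#'   Annual totals (EUR), metadata only.
#' @param working_hours_per_day Hours per day devoted to first-level exams.
#' @return An object of class `cost_components`.
#' @export
cost_components <- function(staff_daily_per_team = 608.28,
                            goods_services_daily = 128.59,
                            overheads_daily = 92.65,
                            equipment_daily = 30.82,
                            staff_annual = 856825.94,
                            goods_services_annual = 225288.23,
                            overheads_annual = 162317.13,
                            equipment_annual = 54000,
                            working_hours_per_day = 5) {
  vals <- c(staff_daily_per_team, goods_services_daily, overheads_daily,
            equipment_daily)
  if (any(is.na(vals)) || any(vals < 0))
    stop("configuration error: all daily cost components must be >= 0")
  structure(
    list(staff_daily_per_team = staff_daily_per_team,
         goods_services_daily = goods_services_daily,
         overheads_daily = overheads_daily,
         equipment_daily = equipment_daily,
         staff_annual = staff_annual,
         goods_services_annual = goods_services_annual,
         overheads_annual = overheads_annual,
         equipment_annual = equipment_annual,
         working_hours_per_day = working_hours_per_day),
    class = "cost_components"
  )
}

#' Exam tariffs and payer mix
#'
#' @param paying_exam_fee Fee paid for a first-level exam by paying patients
#'   (EUR).
#' @param ticket_fee Co-payment ticket (EUR).
#' @param paying_fraction Fraction of patients who pay (the rest are
#'   reimbursed by the regional health system).
#' @return An object of class `tariffs`.
#' @export
tariffs <- function(paying_exam_fee = 87, ticket_fee = 36.15,
                    paying_fraction = 0.35) {
  if (paying_exam_fee < 0 || ticket_fee < 0) stop("fees must be >= 0")
  if (paying_fraction < 0 || paying_fraction > 1)
    stop("paying_fraction must lie in [0, 1]")
  structure(list(paying_exam_fee = paying_exam_fee, ticket_fee = ticket_fee,
                 paying_fraction = paying_fraction),
            class = "tariffs")
}

#' A screening organizational strategy
#'
#' One waiting-list scenario: how many teams and machines run, the daily
#' exam capacity that follows (one team of doctor + technician + nurse
#' delivers 20 screening exams per day), the resulting waiting list in
#' months, and the 3-year screened volume. Printed accounting figures that
#' do not decompose cleanly from the component model can be attached as
#' overrides and take precedence in the ledger.
#'
#' @param name Strategy label.
#' @param teams_day,teams_afternoon Number of day-shift / afternoon teams.
#' @param waiting_months Waiting-list length in months (> 0).
#' @param patients_3y Patients screened over the 3-year horizon.
#' @param exams_per_day Daily exam capacity; defaults to 20 per team.
#' @param mammographs,ultrasounds,reporting_stations Equipment counts
#'   (metadata).
#' @param overrides Named list; recognized names `daily_cost`,
#'   `daily_revenue`, `cost_3y` (EUR).
#' @return An object of class `screening_strategy`.
#' @export
screening_strategy <- function(name, teams_day, teams_afternoon = 0,
                               waiting_months, patients_3y,
                               exams_per_day = 20 * (teams_day + teams_afternoon),
                               mammographs = NA_integer_,
                               ultrasounds = NA_integer_,
                               reporting_stations = NA_integer_,
                               overrides = list()) {
  if (waiting_months <= 0) stop("waiting_months must be > 0")
  if (exams_per_day < 0 || patients_3y < 0)
    stop("capacity and volume must be >= 0")
  unknown <- setdiff(names(overrides),
                     c("daily_cost", "daily_revenue", "cost_3y"))
  if (length(unknown))
    stop("unknown override(s): ", paste(unknown, collapse = ", "))
  structure(
    list(name = name, teams_day = teams_day,
         teams_afternoon = teams_afternoon,
         teams_total = teams_day + teams_afternoon,
         waiting_months = waiting_months, patients_3y = patients_3y,
         exams_per_day = exams_per_day,
         mammographs = mammographs, ultrasounds = ultrasounds,
         reporting_stations = reporting_stations,
         overrides = overrides),
    class = "screening_strategy"
  )
}

#' Daily cost of running a strategy
#'
#' Staff cost per team times the number of teams, plus the daily shares of
#' goods and services, overheads, and equipment. If the strategy carries a
#' `daily_cost` override (a printed accounting figure that does not
#' decompose into these components) and `use_overrides` is TRUE, the
#' override is returned.
#'
#' @param strategy A [screening_strategy()].
#' @param components A [cost_components()].
#' @param use_overrides Honour the strategy's printed overrides.
#' @return Daily cost in EUR, exact to the cent.
#' @export
daily_cost <- function(strategy, components = cost_components(),
                       use_overrides = TRUE) {
  stopifnot(inherits(strategy, "screening_strategy"))
  if (use_overrides && !is.null(strategy$overrides$daily_cost))
    return(as_euros(as_cents(strategy$overrides$daily_cost)))
  stopifnot(inherits(components, "cost_components"))
  cents <- strategy$teams_total * as_cents(components$staff_daily_per_team) +
    as_cents(components$goods_services_daily) +
    as_cents(components$overheads_daily) +
    as_cents(components$equipment_daily)
  as_euros(cents)
}

#' Daily hospital revenue of a strategy
#'
#' Every exam earns the first-level fee, and the paying fraction of patients
#' additionally pays the ticket, so the blended per-exam revenue is
#' `fee + paying_fraction * ticket` (EUR 99.6525 at the defaults). A
#' `daily_revenue` override takes precedence when present.
#'
#' @inheritParams daily_cost
#' @param tariffs A [tariffs()].
#' @return Daily revenue in EUR, rounded to the cent.
#' @export
daily_revenue <- function(strategy, tariffs = waitlineCEA::tariffs(),
                          use_overrides = TRUE) {
  stopifnot(inherits(strategy, "screening_strategy"),
            inherits(tariffs, "tariffs"))
  if (use_overrides && !is.null(strategy$overrides$daily_revenue))
    return(as_euros(as_cents(strategy$overrides$daily_revenue)))
  per_exam <- tariffs$paying_exam_fee +
    tariffs$paying_fraction * tariffs$ticket_fee
  as_euros(round(strategy$exams_per_day * per_exam * 100))
}

#' Daily margin
#'
#' @param revenue,cost Daily revenue and cost in EUR.
#' @return `revenue - cost`, exact to the cent.
#' @export
daily_margin <- function(revenue, cost) {
  as_euros(as_cents(revenue) - as_cents(cost))
}

#' Unit screening cost per patient
#'
#' @param daily_cost Daily cost in EUR.
#' @param exams_per_day Exams delivered per day (> 0).
#' @return Cost per exam in EUR, rounded to the cent.
#' @export
unit_screening_cost <- function(daily_cost, exams_per_day) {
  if (any(exams_per_day <= 0)) stop("exams_per_day must be > 0")
  as_euros(round(as_cents(daily_cost) / exams_per_day))
}

#' Screening cost over a working-day horizon
#'
#' @param daily_cost Daily cost in EUR.
#' @param working_days Working days in the horizon (default 728.37, the
#'   3-year equivalent of ~242.8 screening days per year).
#' @return Total cost in EUR, rounded to the cent.
#' @export
screening_cost_horizon <- function(daily_cost, working_days = 728.37) {
  if (any(working_days < 0)) stop("working_days must be >= 0")
  as_euros(round(as_cents(daily_cost) * working_days))
}

#' Cost variation of a strategy against a reference
#'
#' @param strategy_cost,reference_cost Total costs in EUR.
#' @return Difference in EUR, exact to the cent.
#' @export
cost_variation <- function(strategy_cost, reference_cost) {
  as_euros(as_cents(strategy_cost) - as_cents(reference_cost))
}

#' Build the full cost ledger for a set of strategies
#'
#' One row per strategy: daily revenue, cost and margin, unit screening
#' cost, total cost over the horizon, and the cost variation against the
#' reference strategy. When a computed figure disagrees with a printed
#' override by more than a cent the `note` column records the discrepancy
#' instead of silently adopting either side.
#'
#' @param strategies List of [screening_strategy()] objects.
#' @param components A [cost_components()].
#' @param tariffs A [tariffs()].
#' @param working_days Horizon in working days.
#' @param reference Name of the reference strategy (cost variations are
#'   taken against it). Defaults to the first strategy.
#' @param use_overrides Honour printed overrides.
#' @return A data.frame of class `cost_ledger`.
#' @export
cost_ledger <- function(strategies, components = cost_components(),
                        tariffs = waitlineCEA::tariffs(),
                        working_days = 728.37,
                        reference = strategies[[1]]$name,
                        use_overrides = TRUE) {
  stopifnot(length(strategies) >= 1)
  rows <- lapply(strategies, function(s) {
    dc <- daily_cost(s, components, use_overrides)
    dr <- daily_revenue(s, tariffs, use_overrides)
    c3 <- if (use_overrides && !is.null(s$overrides$cost_3y))
      as_euros(as_cents(s$overrides$cost_3y))
    else screening_cost_horizon(dc, working_days)
    note <- character(0)
    dc_computed <- daily_cost(s, components, use_overrides = FALSE)
    if (abs(dc_computed - dc) > 0.01)
      note <- c(note, sprintf("computed daily cost %.2f != ledger %.2f",
                              dc_computed, dc))
    data.frame(strategy = s$name,
               waiting_months = s$waiting_months,
               exams_per_day = s$exams_per_day,
               patients_3y = s$patients_3y,
               daily_revenue = dr, daily_cost = dc,
               daily_margin = daily_margin(dr, dc),
               unit_cost = unit_screening_cost(dc, s$exams_per_day),
               cost_3y = c3,
               note = paste(note, collapse = "; "),
               stringsAsFactors = FALSE)
  })
  ledger <- do.call(rbind, rows)
  ref_cost <- ledger$cost_3y[ledger$strategy == reference]
  if (length(ref_cost) != 1L)
    stop("reference strategy '", reference, "' not found in ledger")
  ledger$cost_variation <- vapply(ledger$cost_3y, cost_variation,
                                  numeric(1), reference_cost = ref_cost)
  class(ledger) <- c("cost_ledger", "data.frame")
  ledger
}

#' Write / read a cost ledger as CSV
#'
#' Currency columns are serialized as fixed two-decimal strings so that a
#' write/read round trip preserves every cent.
#'
#' @param ledger A [cost_ledger()] data.frame.
#' @param path File path.
#' @return `read_ledger` returns the ledger with numeric currency columns.
#' @export
write_ledger <- function(ledger, path) {
  out <- ledger
  money <- c("daily_revenue", "daily_cost", "daily_margin", "unit_cost",
             "cost_3y", "cost_variation")
  for (col in intersect(money, names(out)))
    out[[col]] <- sprintf("%.2f", out[[col]])
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ledger
#' @export
read_ledger <- function(path) {
  led <- utils::read.csv(path, stringsAsFactors = FALSE)
  money <- c("daily_revenue", "daily_cost", "daily_margin", "unit_cost",
             "cost_3y", "cost_variation")
  for (col in intersect(money, names(led)))
    led[[col]] <- as_euros(as_cents(as.numeric(led[[col]])))
  class(led) <- c("cost_ledger", "data.frame")
  led
}
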