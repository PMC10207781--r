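#' Incremental cost-effectiveness ratio
#'
#' Cost per QALY gained: the ratio of the cost difference to the QALY
#' difference between a strategy and its comparator. A zero QALY difference
#' leaves the ratio undefined; `NA` is returned with a warning rather than
#' an infinite or fabricated number.
#'
#' @param delta_cost Cost difference (EUR).
#' @param delta_qaly QALY difference.
#' @return EUR per QALY, rounded to the cent; `NA_real_` when
#'   `delta_qaly == 0`.
#' @export
#' @examples
#' icer(908550.96, 35.5)
icer <- function(delta_cost, delta_qaly) {
  if (length(delta_qaly) == 1L && delta_qaly == 0) {
    warning("delta_qaly is 0: ICER undefined")
    return(NA_real_)
  }
  out <- round(delta_cost / delta_qaly, 2)
  out[delta_qaly == 0] <- NA_real_
  out
}

#' Dominance classification of a strategy
#'
#' Sign conventions of the cost-effectiveness plane: more effect for less
#' (or equal) cost is dominant; less effect for more (or equal) cost is
#' dominated; everything else is a trade-off priced by the ICER.
#'
#' @param delta_cost,delta_qaly Differences against the comparator.
#' @return One of `"dominant"`, `"dominated"`, `"trade-off"`.
#' @export
dominance <- function(delta_cost, delta_qaly) {
  dominant <- (delta_qaly > 0 & delta_cost <= 0) |
    (delta_qaly >= 0 & delta_cost < 0)
  dominated <- (delta_qaly < 0 & delta_cost >= 0) |
    (delta_qaly <= 0 & delta_cost > 0)
  ifelse(dominant, "dominant", ifelse(dominated, "dominated", "trade-off"))
}

#' ICER results for a set of strategies against one comparator
#'
#' Pairwise comparison only: each strategy is set against the reference
#' strategy, exactly as in a two-way cost-utility analysis; no efficiency
#' frontier is constructed.
#'
#' @param ledger A [cost_ledger()] (supplies `cost_3y` per strategy).
#' @param qaly_totals data.frame `strategy`, `QALY` (per-strategy totals).
#' @param reference Comparator strategy name.
#' @return data.frame of class `icer_table`: `strategy`, `delta_cost`,
#'   `delta_qaly`, `icer`, `dominance`.
#' @export
icer_table <- function(ledger, qaly_totals, reference) {
  stopifnot(all(c("strategy", "cost_3y") %in% names(ledger)),
            all(c("strategy", "QALY") %in% names(qaly_totals)))
  merged <- merge(ledger[, c("strategy", "cost_3y")],
                  qaly_totals[, c("strategy", "QALY")], by = "strategy")
  ref <- merged[merged$strategy == reference, ]
  if (nrow(ref) != 1L) stop("reference strategy '", reference, "' not found")
  out <- merged[merged$strategy != reference, ]
  out <- out[order(match(out$strategy, merged$strategy)), ]
  out$delta_cost <- vapply(out$cost_3y, cost_variation, numeric(1),
                           reference_cost = ref$cost_3y)
  out$delta_qaly <- out$QALY - ref$QALY
  out$icer <- suppressWarnings(mapply(icer, out$delta_cost, out$delta_qaly))
  out$dominance <- dominance(out$delta_cost, out$delta_qaly)
  out <- out[, c("strategy", "delta_cost", "delta_qaly", "icer", "dominance")]
  rownames(out) <- NULL
  class(out) <- c("icer_table", "data.frame")
  out
}

#' Rank strategies by cost-effectiveness
#'
#' Dominant strategies rank first, then trade-off strategies by increasing
#' ICER (a lower price per QALY gained is better), then dominated ones.
#' Ties keep their input order and are flagged. When a willingness-to-pay
#' threshold is supplied, each strategy gets a verdict: dominant and
#' trade-off strategies at or under the threshold are `"cost-effective"`.
#'
#' @param results An [icer_table()].
#' @param threshold Optional willingness-to-pay (EUR per QALY).
#' @return `results` reordered, with `rank`, `tie` and (if a threshold was
#'   given) `verdict` columns.
#' @export
rank_strategies <- function(results, threshold = NULL) {
  stopifnot(nrow(results) >= 1)
  class_order <- match(results$dominance, c("dominant", "trade-off", "dominated"))
  key <- ifelse(results$dominance == "trade-off", results$icer, 0)
  ord <- order(class_order, key)  # stable: order() preserves input sequence
  out <- results[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  out$tie <- duplicated(data.frame(out$dominance, out$icer)) |
    duplicated(data.frame(out$dominance, out$icer), fromLast = TRUE)
  if (!is.null(threshold)) {
    out$verdict <- ifelse(
      out$dominance == "dominated", "not cost-effective",
      ifelse(out$dominance == "dominant" |
               (!is.na(out$icer) & out$icer <= threshold),
             "cost-effective", "above threshold"))
  }
  rownames(out) <- NULL
  out
}

#' Write / read an ICER table as CSV
#'
#' @param x An [icer_table()].
#' @param path File path.
#' @return `read_icer_table` returns the data.frame.
#' @export
write_icer_table <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_icer_table
#' @export
read_icer_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
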