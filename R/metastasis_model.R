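#' Poisson metastasis-probability model
#'
#' Metastatic seeding is modelled as a Poisson process in the accumulated
#' cell count: with P the average number of tumor cells needed to form one
#' metastasis, the expected number of seeding events at size N is mu = N/P,
#' and the probability that at least one metastasis has formed is
#' pr = 1 - exp(-N/P) (one minus the Poisson zero-event probability).
#'
#' @param P Average number of accumulated cells per expected metastatic
#'   event (> 0).
#' @return An object of class `metastasis_model`.
#' @export
metastasis_model <- function(P) {
  stopifnot(is.numeric(P), length(P) == 1L)
  if (!is.finite(P) || P <= 0) stop("P must be a positive finite number")
  structure(list(P = P), class = "metastasis_model")
}

#' Probability of metastasis at a given cell count
#'
#' @param cells Accumulated tumor cell count(s) (>= 0).
#' @param model A [metastasis_model()].
#' @return Probability in \[0, 1): `1 - exp(-cells / P)`.
#' @export
#' @examples
#' m <- metastasis_model(P = 6.9e9)
#' pr_met(cells_from_diameter(14.1), m)
pr_met <- function(cells, model) {
  stopifnot(inherits(model, "metastasis_model"))
  if (any(cells < 0)) stop("cells must be >= 0")
  # clipped a hair below 1 so the bound pr < 1 survives float saturation
  pmin(-expm1(-cells / model$P), 1 - .Machine$double.eps)
}

#' TNM T-category size bands
#'
#' Diameter bands (mm) used to band metastasis probabilities, following TNM
#' T-size conventions: T1A 1-5, T1B 5-10, T1C 10-20, T2 20-50, T3 > 50 mm.
#' The T2 band is truncated at the palpability threshold because above it
#' screening no longer detects tumors earlier than the patient would; bands
#' lying entirely above the threshold are flagged `above_palpability`.
#' The representative diameter of a band is its geometric midpoint
#' sqrt(lo * hi): cell count scales with the cube of diameter, so the
#' geometric mean is less biased than the arithmetic mean.
#'
#' @param thresholds A [tumor_thresholds()] supplying the palpability
#'   diameter used for truncation.
#' @param include_t3 Keep the T3 band (entirely above palpability under the
#'   default thresholds) as a flagged row.
#' @return A data.frame with columns `stage`, `diameter_lo_mm`,
#'   `diameter_hi_mm`, `representative_mm`, `above_palpability`.
#' @export
stage_bands <- function(thresholds = tumor_thresholds(), include_t3 = TRUE) {
  tp <- thresholds$palpability_diameter_mm
  bands <- data.frame(
    stage = c("T1A", "T1B", "T1C", "T2", "T3"),
    diameter_lo_mm = c(1, 5, 10, 20, 50),
    diameter_hi_mm = c(5, 10, 20, 50, 100),
    stringsAsFactors = FALSE
  )
  if (!include_t3) bands <- bands[bands$stage != "T3", ]
  bands$above_palpability <- bands$diameter_lo_mm >= tp
  hi <- pmin(bands$diameter_hi_mm, tp)
  hi[bands$above_palpability] <- bands$diameter_hi_mm[bands$above_palpability]
  bands$diameter_hi_mm <- hi
  if (any(bands$diameter_lo_mm >= bands$diameter_hi_mm & !bands$above_palpability))
    stop("degenerate stage band after palpability truncation")
  if (any(diff(bands$diameter_lo_mm) <= 0))
    stop("stage bands must be ordered and non-overlapping")
  bands$representative_mm <- sqrt(bands$diameter_lo_mm * bands$diameter_hi_mm)
  bands
}

#' Calibrate the Poisson seeding parameter P
#'
#' Recovers P from observed stage-wise metastasis probabilities by least
#' squares on the probability scale (kept on that scale, rather than
#' log-odds, so exact 0 entries are usable). Each band contributes the
#' squared difference between the model probability at its representative
#' diameter and the observed probability; an observed 0 contributes a
#' one-sided penalty only (the model probability is never negative, so its
#' square is the penalty). With a single informative pair the closed form
#' P = N / (-log(1 - p)) is returned exactly.
#'
#' @param observed data.frame with columns `stage` and `point` (observed
#'   probabilities as fractions) for the reference strategy.
#' @param bands Stage bands as from [stage_bands()].
#' @param kinetics A [growth_model()] supplying the cell density.
#' @return A [metastasis_model()] with attributes `residuals` (per-stage
#'   model minus observed) and `objective` (the minimized sum of squares).
#' @export
calibrate_P <- function(observed, bands = stage_bands(),
                        kinetics = growth_model()) {
  stopifnot(is.data.frame(observed),
            all(c("stage", "point") %in% names(observed)))
  obs <- merge(observed, bands[!bands$above_palpability,
                               c("stage", "representative_mm")],
               by = "stage")
  if (nrow(obs) == 0L) stop("no observed stage matches a usable band")
  if (any(obs$point < 0 | obs$point > 1))
    stop("observed probabilities must lie in [0, 1]")
  informative <- obs$point > 0 & obs$point < 1
  if (!any(informative))
    stop("calibration failure: all observed probabilities are 0 or 1")
  n_cells <- cells_from_diameter(obs$representative_mm,
                                 kinetics$cell_density_per_cm3)
  if (sum(informative) == 1L) {
    P_hat <- n_cells[informative] / (-log(1 - obs$point[informative]))
  } else {
    objective <- function(logP) {
      pr <- -expm1(-n_cells / exp(logP))
      sum((pr - obs$point)^2)
    }
    opt <- stats::optimize(objective, interval = log(c(1e4, 1e16)),
                           tol = .Machine$double.eps^0.5)
    P_hat <- exp(opt$minimum)
  }
  model <- metastasis_model(P_hat)
  fitted <- -expm1(-n_cells / P_hat)
  attr(model, "residuals") <- stats::setNames(fitted - obs$point, obs$stage)
  attr(model, "objective") <- sum((fitted - obs$point)^2)
  model
}

#' Wilson 95% score interval for a proportion
#'
#' Confidence interval attached to reported stage probabilities. The Wilson
#' score construction is used because it behaves sensibly at 0 and 1, where
#' several of the reported bands sit.
#'
#' @param point Point estimate(s) in \[0, 1\].
#' @param n_effective Effective sample size (> 0) behind the estimate.
#' @param conf_level Confidence level, default 0.95.
#' @return A data.frame with columns `lo`, `hi`; always contains `point`.
#' @export
probability_interval <- function(point, n_effective, conf_level = 0.95) {
  if (any(point < 0 | point > 1)) stop("point must lie in [0, 1]")
  if (any(n_effective <= 0)) stop("n_effective must be > 0")
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  denom <- 1 + z^2 / n_effective
  centre <- (point + z^2 / (2 * n_effective)) / denom
  half <- z * sqrt(point * (1 - point) / n_effective +
                     z^2 / (4 * n_effective^2)) / denom
  data.frame(lo = pmax(0, centre - half), hi = pmin(1, centre + half))
}

#' Stage-wise metastasis probabilities under a waiting-list strategy
#'
#' Propagates the waiting time through the growth model: relative to the
#' reference strategy, a tumor in a given T-band is detected after
#' `(waiting_months - reference_months) * wait_scale` months of extra (or
#' avoided) growth, so shorter waiting lists catch the same tumor at a
#' smaller accumulated cell count. The count is floored at the detection
#' threshold (a screen-detected tumor is at least detectable) and bands
#' whose grown size exceeds the palpability threshold are flagged: there
#' screening has lost utility as an early-diagnosis tool. This waiting-time
#' mechanism is a modelling choice of this package, not an empirical claim.
#'
#' @param waiting_months Waiting-list length of the strategy (> 0), months.
#' @param model Calibrated [metastasis_model()].
#' @param bands Stage bands from [stage_bands()].
#' @param kinetics A [growth_model()].
#' @param thresholds A [tumor_thresholds()].
#' @param reference_months Waiting time at which the model was calibrated.
#' @param wait_scale Fraction of the waiting-time difference converted into
#'   growth time (default 1).
#' @param n_effective Sample size for the Wilson intervals (default 242).
#' @param days_per_month Calendar conversion, default 30.4375.
#' @return data.frame `stage`, `point`, `lo`, `hi`, `above_palpability`.
#' @export
stage_probabilities <- function(waiting_months, model,
                                bands = stage_bands(),
                                kinetics = growth_model(),
                                thresholds = tumor_thresholds(),
                                reference_months = 32,
                                wait_scale = 1,
                                n_effective = 242,
                                days_per_month = 30.4375) {
  stopifnot(inherits(model, "metastasis_model"))
  if (waiting_months <= 0) stop("waiting_months must be > 0")
  delta_days <- (waiting_months - reference_months) * wait_scale *
    days_per_month
  n_ref <- cells_from_diameter(bands$representative_mm,
                               kinetics$cell_density_per_cm3)
  n_at_detection <- n_ref * 2^(delta_days / kinetics$doubling_time_days)
  n_at_detection <- pmax(n_at_detection, thresholds$detection_cells)
  above <- bands$above_palpability |
    n_at_detection > thresholds$palpability_cells
  point <- pmin(pr_met(n_at_detection, model), 1 - .Machine$double.eps)
  ci <- probability_interval(point, n_effective)
  out <- data.frame(stage = bands$stage, point = point,
                    lo = ci$lo, hi = ci$hi,
                    above_palpability = above,
                    stringsAsFactors = FALSE)
  out$point[above] <- NA_real_
  out$lo[above] <- NA_real_
  out$hi[above] <- NA_real_
  out
}

#' Read or write a stage-probability table
#'
#' CSV with columns `strategy,stage,point,lo,hi`; probabilities stored as
#' fractions, not percentages.
#'
#' @param x data.frame to write.
#' @param path File path.
#' @return `read_stage_probabilities` returns the data.frame.
#' @export
write_stage_probabilities <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_stage_probabilities
#' @export
read_stage_probabilities <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
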