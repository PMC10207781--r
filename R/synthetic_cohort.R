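#' Cohort specification
#'
#' Marginal frequencies of a TNM-staged breast-cancer cohort, defaulting to
#' the registry sample the package emulates: 242 patients with stage counts
#' T1A 20, T1B 65, T1C 95, T2 59, T3 3; nodal status N0 154 / N+ 88;
#' histology ductal 189, lobular 44, tubular 5, mucinous 2; grade 79/109/47.
#' Frequency vectors are renormalized over the reported categories (the
#' histology and grade counts do not reach 242 because of unreported cases).
#' Attributes are sampled independently — the registry publishes only
#' marginals — which is a documented limitation of the generator.
#'
#' @param n Cohort size (>= 0).
#' @param stage_freqs,node_freqs,histology_freqs,grade_freqs Named
#'   non-negative weight vectors; renormalized to sum to 1.
#' @param seed Integer seed making the cohort reproducible.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n = 242,
                        stage_freqs = c(T1A = 20, T1B = 65, T1C = 95,
                                        T2 = 59, T3 = 3),
                        node_freqs = c(N0 = 154, `N+` = 88),
                        histology_freqs = c(ductal = 189, lobular = 44,
                                            tubular = 5, mucinous = 2),
                        grade_freqs = c(`1` = 79, `2` = 109, `3` = 47),
                        seed = 1L) {
  if (n < 0) stop("n must be >= 0")
  norm <- function(f, what) {
    if (is.null(names(f)) || any(f < 0) || sum(f) <= 0)
      stop("configuration error: invalid frequency vector for ", what)
    f / sum(f)
  }
  structure(
    list(n = as.integer(n),
         stage_freqs = norm(stage_freqs, "stage"),
         node_freqs = norm(node_freqs, "node status"),
         histology_freqs = norm(histology_freqs, "histology"),
         grade_freqs = norm(grade_freqs, "grade"),
         seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

# Diameter bands (mm) used for sampling patient tumor sizes, full TNM
# extent (no palpability truncation: registry tumors include palpable ones).
sampling_bands <- function() {
  data.frame(stage = c("T1A", "T1B", "T1C", "T2", "T3"),
             lo = c(1, 5, 10, 20, 50),
             hi = c(5, 10, 20, 50, 100),
             stringsAsFactors = FALSE)
}

#' Generate a synthetic patient cohort
#'
#' Samples each attribute independently from the spec's marginal
#' frequencies; tumor diameters are drawn uniformly on the log scale within
#' the patient's T-band (sizes are scale-like, so log-uniform avoids piling
#' mass at the wide end of a band). Output is deterministic given the spec's
#' seed; the caller's RNG state is left untouched.
#'
#' @param spec A [cohort_spec()].
#' @return data.frame with columns `patient_id`, `t_stage`, `diameter_mm`,
#'   `node_status`, `histology`, `grade`, `metastatic` (NA until assigned).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (spec$n == 0L)
    return(data.frame(patient_id = integer(0), t_stage = character(0),
                      diameter_mm = numeric(0), node_status = character(0),
                      histology = character(0), grade = integer(0),
                      metastatic = logical(0), stringsAsFactors = FALSE))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed)
  bands <- sampling_bands()
  missing_band <- setdiff(names(spec$stage_freqs), bands$stage)
  if (length(missing_band))
    stop("no sampling band for stage(s): ", paste(missing_band, collapse = ", "))
  stage <- sample(names(spec$stage_freqs), spec$n, replace = TRUE,
                  prob = spec$stage_freqs)
  idx <- match(stage, bands$stage)
  diameter <- exp(stats::runif(spec$n, log(bands$lo[idx]), log(bands$hi[idx])))
  data.frame(
    patient_id = seq_len(spec$n),
    t_stage = stage,
    diameter_mm = diameter,
    node_status = sample(names(spec$node_freqs), spec$n, replace = TRUE,
                         prob = spec$node_freqs),
    histology = sample(names(spec$histology_freqs), spec$n, replace = TRUE,
                       prob = spec$histology_freqs),
    grade = as.integer(sample(names(spec$grade_freqs), spec$n, replace = TRUE,
                              prob = spec$grade_freqs)),
    metastatic = NA,
    stringsAsFactors = FALSE
  )
}

#' Assign metastatic status to a cohort
#'
#' Each patient's metastatic flag is drawn Bernoulli with probability
#' `pr_met` evaluated at the cell count implied by their tumor diameter, so
#' the expected stage-wise metastatic fraction equals the model probability
#' at the stage's sizes.
#'
#' @param cohort A cohort data.frame from [generate_cohort()].
#' @param model A calibrated [metastasis_model()].
#' @param seed Integer seed for the Bernoulli draws.
#' @param kinetics A [growth_model()] supplying the cell density.
#' @return The cohort with `metastatic` filled in (logical).
#' @export
assign_metastasis <- function(cohort, model, seed = 1L,
                              kinetics = growth_model()) {
  stopifnot(inherits(model, "metastasis_model"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  p <- pr_met(cells_from_diameter(cohort$diameter_mm,
                                  kinetics$cell_density_per_cm3), model)
  cohort$metastatic <- stats::runif(nrow(cohort)) < p
  cohort
}

#' Rescale a cohort spec to a strategy's screened volume
#'
#' Keeps the marginal frequencies and sets `n` to the strategy's 3-year
#' screened volume. Optionally shifts the stage mix toward smaller stages
#' for shorter waits: each stage's representative size is rewound by the
#' waiting-time difference through the growth model and reassigned to the
#' band it then falls in, so probability mass migrates down-stage.
#'
#' @param spec A [cohort_spec()].
#' @param strategy A [screening_strategy()] with `patients_3y > 0`.
#' @param shift_stage_mix Apply the kinetic down-staging shift.
#' @param reference_months Waiting time the spec's stage mix refers to.
#' @param kinetics A [growth_model()].
#' @param days_per_month Calendar conversion.
#' @return A new `cohort_spec`.
#' @export
scale_to_strategy <- function(spec, strategy, shift_stage_mix = FALSE,
                              reference_months = 32,
                              kinetics = growth_model(),
                              days_per_month = 30.4375) {
  stopifnot(inherits(spec, "cohort_spec"),
            inherits(strategy, "screening_strategy"))
  if (strategy$patients_3y <= 0) stop("patients_3y must be > 0")
  out <- spec
  out$n <- as.integer(strategy$patients_3y)
  if (shift_stage_mix) {
    bands <- sampling_bands()
    bands <- bands[match(names(spec$stage_freqs), bands$stage), ]
    rep_mm <- sqrt(bands$lo * bands$hi)
    delta_days <- (strategy$waiting_months - reference_months) * days_per_month
    new_mm <- rep_mm * 2^(delta_days / (3 * kinetics$doubling_time_days))
    # diameter scales with the cube root of cell count, hence the factor 3
    dest <- vapply(new_mm, function(d) {
      i <- which(d >= bands$lo & d < bands$hi)
      if (length(i)) i else if (d < bands$lo[1]) 1L else nrow(bands)
    }, integer(1))
    shifted <- stats::setNames(numeric(length(rep_mm)), bands$stage)
    for (k in seq_along(dest))
      shifted[dest[k]] <- shifted[dest[k]] + spec$stage_freqs[k]
    out$stage_freqs <- shifted / sum(shifted)
  }
  out
}

#' Write / read a cohort as CSV
#'
#' Serialization uses the column order
#' `patient_id,t_stage,diameter_mm,node_status,histology,grade,metastatic`.
#'
#' @param cohort Cohort data.frame.
#' @param path File path.
#' @return `read_cohort` returns the data.frame.
#' @export
write_cohort <- function(cohort, path) {
  cols <- c("patient_id", "t_stage", "diameter_mm", "node_status",
            "histology", "grade", "metastatic")
  utils::write.csv(cohort[, cols], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
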