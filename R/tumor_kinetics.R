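#' Tumor growth model
#'
#' Exponential tumor growth with a constant volume-doubling time and a fixed
#' cell-packing density. The default doubling time of 168.5 days is calibrated
#' so that growth from the mammographic detection threshold (~1e7 cells) to
#' the palpability threshold (~1e10 cells) takes about 4.6 years, the sojourn
#' window within which screening retains utility as an early-diagnosis tool.
#'
#' @param doubling_time_days Volume doubling time in days (> 0).
#' @param cell_density_per_cm3 Cells per cubic centimetre of tumor tissue
#'   (> 0). The conventional packing density is 1e9 cells/cm^3, under which a
#'   sphere of 3 mm diameter holds ~1.4e7 cells and one of ~30 mm holds
#'   ~1.4e10 cells.
#' @return An object of class `growth_model`.
#' @export
#' @examples
#' gm <- growth_model()
#' sojourn_time(tumor_thresholds(), gm) / 365.25 # about 4.6 years
growth_model <- function(doubling_time_days = 168.5,
                         cell_density_per_cm3 = 1e9) {
  stopifnot(is.numeric(doubling_time_days), length(doubling_time_days) == 1L)
  if (doubling_time_days <= 0) stop("doubling_time_days must be > 0")
  if (cell_density_per_cm3 <= 0) stop("cell_density_per_cm3 must be > 0")
  structure(
    list(doubling_time_days = doubling_time_days,
         cell_density_per_cm3 = cell_density_per_cm3),
    class = "growth_model"
  )
}

#' Detection and palpability thresholds
#'
#' The two sizes that bracket useful screening: below the detection threshold
#' (Td) mammography cannot see the tumor; above the palpability threshold
#' (Tp) the patient can find it unaided and screening loses utility as an
#' early-diagnosis tool. Cell counts are taken as primary (Td ~ 1e7, Tp ~
#' 1e10 cells) and the matching diameters are derived from the density, which
#' places Td near 3 mm and Tp in the 25-30 mm range.
#'
#' @param detection_cells Cell count at the detection threshold.
#' @param palpability_cells Cell count at the palpability threshold; must
#'   exceed `detection_cells`.
#' @param cell_density_per_cm3 Packing density used to derive diameters.
#' @return An object of class `tumor_thresholds` with cell counts and the
#'   derived diameters in mm.
#' @export
tumor_thresholds <- function(detection_cells = 1e7,
                             palpability_cells = 1e10,
                             cell_density_per_cm3 = 1e9) {
  if (detection_cells <= 0 || palpability_cells <= 0)
    stop("threshold cell counts must be > 0")
  if (detection_cells > palpability_cells)
    stop("detection_cells must not exceed palpability_cells")
  structure(
    list(detection_cells = detection_cells,
         palpability_cells = palpability_cells,
         detection_diameter_mm =
           diameter_from_cells(detection_cells, cell_density_per_cm3),
         palpability_diameter_mm =
           diameter_from_cells(palpability_cells, cell_density_per_cm3),
         cell_density_per_cm3 = cell_density_per_cm3),
    class = "tumor_thresholds"
  )
}

#' Convert tumor diameter to accumulated cell count
#'
#' Treats the tumor as a sphere of the given maximum dimension and multiplies
#' its volume by the packing density: N = (pi/6) d^3 rho, with d in cm.
#'
#' @param diameter_mm Tumor diameter(s) in millimetres (>= 0).
#' @param cell_density_per_cm3 Cells per cm^3.
#' @return Cell count(s), same length as `diameter_mm`.
#' @export
#' @examples
#' cells_from_diameter(3)  # ~1.4e7: the detection threshold
#' cells_from_diameter(30) # ~1.4e10: the palpability threshold
cells_from_diameter <- function(diameter_mm, cell_density_per_cm3 = 1e9) {
  if (any(diameter_mm < 0)) stop("diameter_mm must be >= 0")
  if (cell_density_per_cm3 <= 0) stop("cell_density_per_cm3 must be > 0")
  (pi / 6) * (diameter_mm / 10)^3 * cell_density_per_cm3
}

#' Convert accumulated cell count to tumor diameter
#'
#' Exact inverse of [cells_from_diameter()] under the same density.
#'
#' @param cells Cell count(s) (>= 0).
#' @param cell_density_per_cm3 Cells per cm^3.
#' @return Diameter(s) in millimetres.
#' @export
diameter_from_cells <- function(cells, cell_density_per_cm3 = 1e9) {
  if (any(cells < 0)) stop("cells must be >= 0")
  if (cell_density_per_cm3 <= 0) stop("cell_density_per_cm3 must be > 0")
  10 * (6 * cells / (pi * cell_density_per_cm3))^(1 / 3)
}

#' Tumor state
#'
#' A tumor size expressed simultaneously as diameter and accumulated cell
#' count; supply either and the other is derived from the model density.
#'
#' @param diameter_mm Diameter in mm, or `NULL` if `cells` is given.
#' @param cells Cell count, or `NULL` if `diameter_mm` is given.
#' @param cell_density_per_cm3 Packing density linking the two.
#' @param time_offset_days Optional days since a reference size.
#' @return An object of class `tumor_state`.
#' @export
tumor_state <- function(diameter_mm = NULL, cells = NULL,
                        cell_density_per_cm3 = 1e9, time_offset_days = 0) {
  if (is.null(diameter_mm) && is.null(cells))
    stop("supply diameter_mm or cells")
  if (is.null(cells)) cells <- cells_from_diameter(diameter_mm, cell_density_per_cm3)
  if (is.null(diameter_mm)) diameter_mm <- diameter_from_cells(cells, cell_density_per_cm3)
  if (diameter_mm < 0 || cells < 0) stop("tumor size must be >= 0")
  structure(
    list(diameter_mm = diameter_mm, cells = cells,
         cell_density_per_cm3 = cell_density_per_cm3,
         time_offset_days = time_offset_days),
    class = "tumor_state"
  )
}

#' Grow (or shrink) a tumor state over elapsed time
#'
#' Applies the exponential law N(t + dt) = N(t) * 2^(dt / doubling time).
#' Negative `elapsed_days` rewinds growth, which is how an earlier detection
#' under a shorter waiting list is modelled.
#'
#' @param state A [tumor_state()].
#' @param elapsed_days Days of growth (may be negative).
#' @param model A [growth_model()].
#' @return The grown `tumor_state`.
#' @export
grow <- function(state, elapsed_days, model = growth_model()) {
  stopifnot(inherits(state, "tumor_state"), inherits(model, "growth_model"))
  cells <- state$cells * 2^(elapsed_days / model$doubling_time_days)
  tumor_state(cells = cells,
              cell_density_per_cm3 = state$cell_density_per_cm3,
              time_offset_days = state$time_offset_days + elapsed_days)
}

#' Sojourn time between the detection and palpability thresholds
#'
#' Time for a tumor to grow from Td to Tp cells: doubling time times
#' log2(Tp/Td). Depends only on the cell-count ratio, not on the density.
#' Screening periodicity must stay below this window to be useful.
#'
#' @param thresholds A [tumor_thresholds()].
#' @param model A [growth_model()].
#' @return Sojourn time in days.
#' @export
sojourn_time <- function(thresholds = tumor_thresholds(),
                         model = growth_model()) {
  stopifnot(inherits(thresholds, "tumor_thresholds"),
            inherits(model, "growth_model"))
  if (thresholds$palpability_cells < thresholds$detection_cells)
    stop("palpability threshold must not be below the detection threshold")
  model$doubling_time_days *
    log2(thresholds$palpability_cells / thresholds$detection_cells)
}
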