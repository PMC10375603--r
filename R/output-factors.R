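# Output factors: dose ratio of a field to the 10 x 10 cm2 reference field
# at reference depth, with field-size-dependent tolerances (2% for fields
# with side <= 40 mm, 1% otherwise).

#' Output factor
#'
#' Ratio of the absorbed dose reading for a field to the reading for the
#' reference field (same depth and SSD), rounded to 3 decimals.
#'
#' @param dose_field,dose_reference Positive detector readings.
#' @return Dimensionless ratio.
#' @export
output_factor <- function(dose_field, dose_reference) {
  if (!is.numeric(dose_field) || !is.numeric(dose_reference) ||
      any(dose_field <= 0) || any(dose_reference <= 0)) {
    stop("readings must be positive")
  }
  round(dose_field / dose_reference, 3)
}

#' Tolerance applicable to an output factor
#'
#' 2% for small fields (side <= 40 mm, i.e. the 3 x 3 cm2 class), 1% for
#' 5 x 5 cm2 and larger.
#'
#' @param field_mm Nominal square-field side in mm.
#' @return Tolerance in percent.
#' @export
of_tolerance_pct <- function(field_mm) {
  stopifnot(is.numeric(field_mm), field_mm > 0)
  ifelse(field_mm <= 40, 2, 1)
}

#' Output-factor record with tolerance verdict
#'
#' @param field_mm Nominal square-field side in mm.
#' @param of_value Measured output factor (> 0).
#' @param reference_of Baseline output factor (> 0).
#' @return One-row data frame: field, values, signed `deviation_pct`
#'   (computed unrounded, displayed to 2 decimals), `tolerance_pct` and
#'   `verdict` ("pass"/"fail" on the unrounded deviation).
#' @export
output_factor_record <- function(field_mm, of_value, reference_of) {
  stopifnot(of_value > 0, reference_of > 0)
  dev <- 100 * (of_value - reference_of) / reference_of
  tol <- of_tolerance_pct(field_mm)
  data.frame(field_mm = field_mm, of_value = of_value,
             reference_of = reference_of,
             deviation_pct = round(dev, 2), tolerance_pct = tol,
             verdict = if (abs(dev) <= tol) "pass" else "fail")
}

#' Check a table of output factors against tolerance
#'
#' @param readings Data frame with columns `field_mm` and `reading`
#'   (one row per field, including the reference field).
#' @param reference_field_mm Side of the reference field (default 100 mm).
#' @param reference Optional data frame of baseline output factors with
#'   columns `field_mm`, `of`; when absent, verdicts are `NA`.
#' @return Data frame of [output_factor_record()] rows (plus `of` only,
#'   when no baseline is given), ordered by field size.
#' @export
output_factor_table <- function(readings, reference_field_mm = 100,
                                reference = NULL) {
  stopifnot(is.data.frame(readings),
            all(c("field_mm", "reading") %in% names(readings)))
  iref <- which(readings$field_mm == reference_field_mm)
  if (length(iref) != 1L) stop("exactly one reading for the reference field (",
                               reference_field_mm, " mm) is required")
  readings <- readings[order(readings$field_mm), , drop = FALSE]
  ofs <- output_factor(readings$reading, readings$reading[readings$field_mm == reference_field_mm])
  if (is.null(reference)) {
    return(data.frame(field_mm = readings$field_mm, of_value = ofs))
  }
  out <- do.call(rbind, lapply(seq_len(nrow(readings)), function(i) {
    ref_of <- reference$of[reference$field_mm == readings$field_mm[i]]
    if (!length(ref_of)) stop("no baseline output factor for field ",
                              readings$field_mm[i], " mm")
    output_factor_record(readings$field_mm[i], ofs[i], ref_of[1])
  }))
  out
}
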