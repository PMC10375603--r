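# Tolerance tables and verdicts. Two limits per parameter: the tight
# "study" criterion used for the internal audit and the looser "vendor"
# matching criterion.

#' Tolerance specification for one parameter
#'
#' @param parameter Parameter name (e.g. `"unflatness"`).
#' @param mode Units of the deviation: `"relative_pct"` (percent of
#'   baseline), `"absolute_mm"` (mm), `"absolute_pct_points"` (percent
#'   points).
#' @param study_limit,vendor_limit Positive limits; every shipped default
#'   has `study_limit <= vendor_limit`.
#' @return One-row data frame of class `tolerance_spec`.
#' @export
tolerance_spec <- function(parameter,
                           mode = c("relative_pct", "absolute_mm",
                                    "absolute_pct_points"),
                           study_limit, vendor_limit = study_limit) {
  mode <- match.arg(mode)
  if (study_limit <= 0 || vendor_limit <= 0) stop("limits must be > 0")
  if (study_limit > vendor_limit) stop("study_limit must be <= vendor_limit")
  out <- data.frame(parameter = parameter, mode = mode,
                    study_limit = study_limit, vendor_limit = vendor_limit)
  class(out) <- c("tolerance_spec", class(out))
  out
}

#' Default audit tolerance table
#'
#' Shipped defaults: PDD10 within 1% of baseline; depth of maximum dose
#' within 1 mm; profile shape parameters (flatness, unflatness, symmetry)
#' 1% study / 2% vendor; penumbra within 1 mm; output factors 1%
#' (2% below 5 x 5 cm2, handled by [of_tolerance_pct()]).
#'
#' @return Data frame with one [tolerance_spec()] row per parameter.
#' @export
default_tolerances <- function() {
  rbind(
    tolerance_spec("pdd10",      "relative_pct", 1, 1),
    tolerance_spec("dmax",       "absolute_mm",  1, 1),
    tolerance_spec("flatness",   "relative_pct", 1, 2),
    tolerance_spec("unflatness", "relative_pct", 1, 2),
    tolerance_spec("symmetry",   "relative_pct", 1, 2),
    tolerance_spec("penumbra",   "absolute_mm",  1, 1),
    tolerance_spec("output_factor", "relative_pct", 1, 2))
}

#' Evaluate a deviation against study and vendor limits
#'
#' Pass when the absolute deviation does not exceed the limit (boundary
#' passes).
#'
#' @param deviation Signed deviation, in the units of `spec$mode`.
#' @param spec A [tolerance_spec()] row.
#' @return Named character `c(study, vendor)`, each "pass" or "fail".
#' @export
evaluate_tolerance <- function(deviation, spec) {
  stopifnot(is.numeric(deviation), length(deviation) == 1L,
            all(c("study_limit", "vendor_limit") %in% names(spec)))
  c(study  = if (abs(deviation) <= spec$study_limit)  "pass" else "fail",
    vendor = if (abs(deviation) <= spec$vendor_limit) "pass" else "fail")
}
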