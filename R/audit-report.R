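# Deviation-from-baseline bookkeeping, tolerance verdicts and report
# emission for the cross-linac audit. Sign convention throughout:
# measured - reference. Deviations are computed on unrounded values and
# displayed at table precision (2 decimals); the JSON report keeps full
# precision.

#' Signed percent deviation from baseline
#'
#' `100 * (measured - reference) / reference`.
#'
#' @param measured,reference Numeric values; `reference` must be non-zero.
#' @param digits Decimals for reporting (default 2); `NULL` returns the
#'   unrounded value.
#' @return Signed deviation in percent.
#' @export
percent_deviation <- function(measured, reference, digits = 2) {
  if (any(reference == 0)) stop("zero reference value")
  dev <- 100 * (measured - reference) / reference
  if (is.null(digits)) dev else round(dev, digits)
}

#' Signed absolute deviation from baseline
#'
#' `measured - reference`, in the parameter's own units (mm or percent
#' points).
#'
#' @inheritParams percent_deviation
#' @return Signed deviation.
#' @export
absolute_deviation <- function(measured, reference, digits = 2) {
  dev <- measured - reference
  if (is.null(digits)) dev else round(dev, digits)
}

#' Record with the largest absolute deviation
#'
#' @param records Non-empty data frame of audit records with a `deviation`
#'   column (one homogeneous parameter set).
#' @return The single row with the largest `|deviation|`; ties broken by
#'   first occurrence.
#' @export
max_abs_deviation <- function(records) {
  if (!is.data.frame(records) || !nrow(records)) stop("empty record set")
  if (!"deviation" %in% names(records)) stop("records need a 'deviation' column")
  records[which.max(abs(records$deviation)), , drop = FALSE]
}

#' Average gamma passing rate over a group of plans
#'
#' Arithmetic mean of per-plan pass rates, reported to 2 decimals.
#'
#' @param rates Non-empty numeric vector of pass rates in percent (a named
#'   vector lets the names identify plans).
#' @param digits Decimals for reporting (default 2).
#' @return Mean pass rate in percent.
#' @export
aggregate_pass_rates <- function(rates, digits = 2) {
  if (!is.numeric(rates) || !length(rates)) stop("empty plan group")
  round(mean(rates), digits)
}

#' Difference between a measured penumbra and a literature value
#'
#' `measured - reported`, signed, 2 decimals. Two measurement conventions
#' are supported by passing either a single plane-specific value or both
#' the in-plane and cross-plane values (which are averaged first).
#'
#' @param measured_mm Positive measured penumbra (mm); a vector of length 2
#'   is averaged (in-plane/cross-plane mean convention).
#' @param reported_mm Positive literature value (mm).
#' @return Signed difference in mm.
#' @export
literature_diff <- function(measured_mm, reported_mm) {
  stopifnot(all(measured_mm > 0), reported_mm > 0)
  round(mean(measured_mm) - reported_mm, 2)
}

# Matching key of a curve inside a baseline set: same axis, beam type,
# nominal field and (for profiles) depth.
curve_key <- function(curve) {
  s <- curve$spec
  sprintf("%s|fff=%s|field=%g|depth=%s", s$scan_axis, s$fff,
          nominal_field_mm(curve),
          if (is.null(s$depth_mm)) "-" else format(s$depth_mm))
}

find_baseline <- function(curve, baselines) {
  key <- curve_key(curve)
  for (b in baselines$curves) if (curve_key(b) == key) return(b)
  stop("missing baseline entry for key '", key, "'")
}

audit_row <- function(curve, parameter, measured, reference, tolerances) {
  spec <- tolerances[tolerances$parameter == parameter, , drop = FALSE]
  if (!nrow(spec)) stop("no tolerance entry for parameter '", parameter, "'")
  dev <- if (spec$mode == "relative_pct") {
    percent_deviation(measured, reference, digits = NULL)
  } else {
    absolute_deviation(measured, reference, digits = NULL)
  }
  v <- evaluate_tolerance(dev, spec)
  s <- curve$spec
  data.frame(machine_id = s$machine_id, parameter = parameter,
             field_mm = nominal_field_mm(curve),
             depth_mm = if (is.null(s$depth_mm)) NA_real_ else s$depth_mm,
             axis = s$scan_axis, fff = s$fff,
             measured = measured, reference = reference,
             deviation = dev, mode = spec$mode,
             study_verdict = v[["study"]], vendor_verdict = v[["vendor"]])
}

#' Build a full beam-matching audit report
#'
#' Extracts the audit parameter set from every measured curve and its
#' matching baseline curve, computes signed deviations and study/vendor
#' verdicts, and optionally runs a per-curve 1D gamma analysis. Depth scans
#' contribute `dmax` (mm deviation) and `pdd10` (percent deviation);
#' flattened profiles contribute `flatness`, `symmetry` and `penumbra`;
#' filter-free profiles contribute `unflatness`, `symmetry` and `penumbra`
#' (average of the two sides, mm deviation).
#'
#' @param scans [scan_set()] of measured curves (any number of machines).
#' @param baselines [scan_set()] of reference curves covering every
#'   (axis, beam type, field, depth) present in `scans`.
#' @param tolerances Tolerance table (default [default_tolerances()]).
#' @param gamma A [gamma_criteria()] to also gamma-compare each curve with
#'   its baseline (both globally normalized to the baseline maximum = 100),
#'   or `NULL` to skip.
#' @return An object of class `audit_report`: list with `records` (data
#'   frame, stable ordering), `gamma` (per-curve results or `NULL`),
#'   `n_study_fail`, `all_study_pass`, `schema_version`.
#' @export
build_audit_report <- function(scans, baselines,
                               tolerances = default_tolerances(),
                               gamma = NULL) {
  stopifnot(inherits(scans, "scan_set"), inherits(baselines, "scan_set"))
  if (!length(scans$curves)) stop("empty scan set")
  rows <- list()
  gamma_rows <- list()
  for (cv in scans$curves) {
    bl <- find_baseline(cv, baselines)
    if (!is_profile(cv)) {
      mn <- normalize_pdd(cv); bn <- normalize_pdd(bl)
      rows <- c(rows, list(
        audit_row(cv, "dmax", find_dmax(mn), find_dmax(bn), tolerances),
        audit_row(cv, "pdd10", pdd_at_depth(mn, 100), pdd_at_depth(bn, 100),
                  tolerances)))
      mg <- mn; bg <- bn
    } else {
      m <- profile_metrics(cv); b <- profile_metrics(bl)
      shape <- if (cv$spec$fff) "unflatness" else "flatness"
      mv <- if (cv$spec$fff) m$unflatness else m$flatness_pct
      bv <- if (cv$spec$fff) b$unflatness else b$flatness_pct
      rows <- c(rows, list(
        audit_row(cv, shape, mv, bv, tolerances),
        audit_row(cv, "symmetry", m$symmetry_pct, b$symmetry_pct, tolerances),
        audit_row(cv, "penumbra", m$penumbra_avg_mm, b$penumbra_avg_mm,
                  tolerances)))
      mg <- cax_correction(cv)$curve; bg <- cax_correction(bl)$curve
      mg <- scan_curve(mg$spec, mg$positions, mg$doses * 100 / max(bg$doses))
      bg <- scan_curve(bg$spec, bg$positions, bg$doses * 100 / max(bg$doses))
    }
    if (!is.null(gamma)) {
      gr <- gamma_curve(bg, mg, gamma)
      gamma_rows <- c(gamma_rows, list(
        data.frame(machine_id = cv$spec$machine_id, key = curve_key(cv),
                   evaluated_n = gr$evaluated_n, passed_n = gr$passed_n,
                   pass_rate_pct = gr$pass_rate_pct)))
    }
  }
  records <- do.call(rbind, rows)
  ord <- order(records$machine_id, records$parameter, records$field_mm,
               records$depth_mm, records$axis, method = "radix")
  records <- records[ord, , drop = FALSE]
  rownames(records) <- NULL
  gamma_df <- if (length(gamma_rows)) do.call(rbind, gamma_rows) else NULL
  n_fail <- sum(records$study_verdict == "fail")
  structure(list(records = records, gamma = gamma_df,
                 n_study_fail = n_fail, all_study_pass = n_fail == 0L,
                 schema_version = "1.0"),
            class = "audit_report")
}

#' @export
print.audit_report <- function(x, ...) {
  cat(sprintf("<audit_report> %d records, %d study-criteria failure(s)\n",
              nrow(x$records), x$n_study_fail))
  df <- x$records
  df$measured <- round(df$measured, 3); df$reference <- round(df$reference, 3)
  df$deviation <- round(df$deviation, 2)
  print(df)
  invisible(x)
}

#' Write an audit report to disk
#'
#' Emits `report.json` (schema-versioned, full precision), `records.csv`
#' (one row per audit record, table precision) and `report.md` (Markdown
#' table). Regeneration from identical inputs is byte-identical: stable
#' record ordering and fixed rounding.
#'
#' @param report An [build_audit_report()] result.
#' @param dir Output directory (created if needed).
#' @return Character vector of written paths, invisibly.
#' @export
write_audit_report <- function(report, dir) {
  stopifnot(inherits(report, "audit_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jpath <- file.path(dir, "report.json")
  cpath <- file.path(dir, "records.csv")
  mpath <- file.path(dir, "report.md")
  jsonlite::write_json(
    list(schema_version = report$schema_version,
         n_study_fail = report$n_study_fail,
         all_study_pass = report$all_study_pass,
         records = report$records,
         gamma = report$gamma),
    jpath, auto_unbox = TRUE, digits = NA, null = "null", na = "null")
  disp <- report$records
  disp$measured <- sprintf("%.3f", disp$measured)
  disp$reference <- sprintf("%.3f", disp$reference)
  disp$deviation <- sprintf("%.2f", disp$deviation)
  utils::write.csv(disp, cpath, row.names = FALSE, quote = FALSE)
  hdr <- names(disp)
  md <- c("# Beam-matching audit", "",
          sprintf("Study-criteria failures: %d", report$n_study_fail), "",
          paste0("| ", paste(hdr, collapse = " | "), " |"),
          paste0("|", paste(rep("---", length(hdr)), collapse = "|"), "|"),
          apply(disp, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |")))
  writeLines(md, mpath)
  invisible(c(jpath, cpath, mpath))
}
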