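#' Scan-file dialect
#'
#' Scan curves are exchanged in a diff-able plain-text dialect: one curve per
#' block, blocks separated by a blank line. Each block is a set of
#' `# key: value` header lines followed by the column header
#' `position_mm,dose` and CSV rows `position_mm,dose`. Mandatory header keys:
#' `machine_id`, `energy_MV`, `fff`, `field_x_mm`, `field_y_mm`, `ssd_mm`,
#' `scan_axis`; `depth_mm` is mandatory for profile scans. Optional keys:
#' `detector`, `date`, `comment`. The decimal separator is `.`; positions are
#' always mm; dose values are written exactly as given (the writer never
#' normalizes).
#'
#' @name scan_dialect
NULL

.mandatory_keys <- c("machine_id", "energy_MV", "fff", "field_x_mm",
                     "field_y_mm", "ssd_mm", "scan_axis")

#' Read scan curves from a file
#'
#' Parses a file in the [scan_dialect] into a [scan_set()]. Every numeric is
#' parsed exactly as written; the parse log records the first line of each
#' curve block.
#'
#' @param path Path to an existing scan file.
#' @return A [scan_set()]; `$provenance$log` is a data frame with one row per
#'   curve block (block index and starting line number).
#' @export
read_scan_file <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  blank <- grepl("^\\s*$", lines)
  block_id <- cumsum(c(TRUE, blank[-length(blank)] & !blank[-1]))
  block_id[blank] <- NA
  blocks <- split(seq_along(lines)[!blank], block_id[!blank])

  curves <- list()
  log <- data.frame(curve = integer(), line = integer())
  for (bi in seq_along(blocks)) {
    idx <- blocks[[bi]]
    hdr_lines <- idx[grepl("^#", lines[idx])]
    dat_lines <- idx[!grepl("^#", lines[idx])]
    header <- list()
    for (i in hdr_lines) {
      m <- regmatches(lines[i], regexec("^#\\s*([A-Za-z_][A-Za-z0-9_]*)\\s*:\\s*(.*)$", lines[i]))[[1]]
      if (length(m) != 3L) {
        stop("format error: malformed header at line ", i, ": ", lines[i])
      }
      header[[m[2]]] <- trimws(m[3])
    }
    for (key in .mandatory_keys) {
      if (is.null(header[[key]])) {
        stop("format error: missing mandatory header key '", key,
             "' in curve block starting at line ", idx[1])
      }
    }
    axis <- header$scan_axis
    if (!axis %in% c("crossplane", "inplane", "depth")) {
      stop("format error: invalid scan_axis '", axis, "' at line ", idx[1])
    }
    if (axis != "depth" && is.null(header$depth_mm)) {
      stop("format error: missing mandatory header key 'depth_mm' ",
           "for profile curve block starting at line ", idx[1])
    }
    # drop the column-header row if present
    dat_lines <- dat_lines[!grepl("^\\s*position_mm\\s*,\\s*dose\\s*$", lines[dat_lines])]
    if (!length(dat_lines)) {
      stop("format error: curve block starting at line ", idx[1], " has no data rows")
    }
    parts <- strsplit(lines[dat_lines], ",", fixed = TRUE)
    if (any(lengths(parts) != 2L)) {
      bad <- dat_lines[which(lengths(parts) != 2L)[1]]
      stop("format error: expected 'position,dose' at line ", bad)
    }
    pos <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 1L)))
    dose <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 2L)))
    if (anyNA(pos) || anyNA(dose)) {
      bad <- dat_lines[which(is.na(pos) | is.na(dose))[1]]
      stop("format error: non-numeric value at line ", bad)
    }
    spec <- beam_spec(
      machine_id = header$machine_id,
      energy_MV  = as.numeric(header$energy_MV),
      fff        = tolower(header$fff) %in% c("true", "1", "yes"),
      field_x_mm = as.numeric(header$field_x_mm),
      field_y_mm = as.numeric(header$field_y_mm),
      ssd_mm     = as.numeric(header$ssd_mm),
      depth_mm   = if (axis == "depth") NULL else as.numeric(header$depth_mm),
      scan_axis  = axis,
      detector   = header$detector)
    cv <- tryCatch(scan_curve(spec, pos, dose), error = function(e) {
      stop("validation error in curve block starting at line ", idx[1], ": ",
           conditionMessage(e), call. = FALSE)
    })
    curves[[length(curves) + 1L]] <- cv
    log <- rbind(log, data.frame(curve = length(curves), line = idx[1]))
  }
  if (!length(curves)) stop("format error: no curve blocks found in ", path)
  scan_set(curves, provenance = list(path = path, log = log))
}

#' Write scan curves to a file
#'
#' Serializes a [scan_set()] in the [scan_dialect]. Round-trip guarantee:
#' re-reading the written file reproduces positions and doses to 6
#' significant digits (numbers are written with 9) and all metadata exactly.
#' Dose values are written unchanged -- the writer is not a transformer.
#'
#' @param scans A [scan_set()] with at least one curve.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_scan_file <- function(scans, path) {
  if (!inherits(scans, "scan_set")) stop("scans must be a scan_set")
  if (!length(scans$curves)) stop("empty scan set")
  blocks <- vapply(scans$curves, function(cv) {
    s <- cv$spec
    hdr <- c(
      paste0("# machine_id: ", s$machine_id),
      paste0("# energy_MV: ", fmt_num(s$energy_MV)),
      paste0("# fff: ", if (s$fff) "true" else "false"),
      paste0("# field_x_mm: ", fmt_num(s$field_x_mm)),
      paste0("# field_y_mm: ", fmt_num(s$field_y_mm)),
      paste0("# ssd_mm: ", fmt_num(s$ssd_mm)),
      if (!is.null(s$depth_mm)) paste0("# depth_mm: ", fmt_num(s$depth_mm)),
      paste0("# scan_axis: ", s$scan_axis),
      if (!is.null(s$detector)) paste0("# detector: ", s$detector))
    rows <- paste0(fmt_num(cv$positions), ",", fmt_num(cv$doses))
    paste(c(hdr, "position_mm,dose", rows), collapse = "\n")
  }, character(1))
  out <- paste(blocks, collapse = "\n\n")
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(out, con)
  invisible(path)
}

#' Read an audit configuration file
#'
#' JSON configuration holding tolerance tables, gamma criteria and baseline
#' file paths. Missing sections fall back to the shipped defaults
#' ([default_tolerances()], 1%/1mm study gamma criteria).
#'
#' @param path Path to a JSON configuration file.
#' @return A list with elements `tolerances` (data frame), `gamma`
#'   (list with `dd_pct`, `dta_mm`, `threshold_pct`), `baseline` (path or
#'   `NULL`).
#' @export
read_audit_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  tol <- if (!is.null(cfg$tolerances)) as.data.frame(cfg$tolerances)
         else default_tolerances()
  gamma <- list(dd_pct = cfg$gamma$dd_pct %||% 1,
                dta_mm = cfg$gamma$dta_mm %||% 1,
                threshold_pct = cfg$gamma$threshold_pct %||% 0)
  list(tolerances = tol, gamma = gamma, baseline = cfg$baseline %||% NULL)
}
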