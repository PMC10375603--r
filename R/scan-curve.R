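#' Beam specification for a water-phantom scan
#'
#' Metadata describing one scanned beam: machine, energy, filtration mode,
#' field size, geometry and scan axis. All lengths are millimetres; the
#' internal unit is mm everywhere (never cm).
#'
#' @param machine_id Character label of the linac (e.g. `"Linac1"`).
#' @param energy_MV Nominal photon energy in MV (positive; 6 for this study
#'   design).
#' @param fff Logical; `TRUE` for a flattening-filter-free beam.
#' @param field_x_mm,field_y_mm Nominal square-field sides in mm (positive).
#' @param ssd_mm Source-to-surface distance in mm (900 for the emulated
#'   geometry).
#' @param depth_mm Measurement depth in mm. Mandatory for lateral profiles
#'   (`scan_axis` of `"crossplane"`/`"inplane"`), must be absent for depth
#'   scans.
#' @param scan_axis One of `"crossplane"`, `"inplane"`, `"depth"`.
#' @param detector Optional detector label.
#'
#' @return An object of class `beam_spec`.
#' @examples
#' beam_spec("Linac1", 6, fff = TRUE, field_x_mm = 100, field_y_mm = 100,
#'           depth_mm = 100, scan_axis = "crossplane")
#' @export
beam_spec <- function(machine_id, energy_MV = 6, fff = FALSE,
                      field_x_mm, field_y_mm, ssd_mm = 900,
                      depth_mm = NULL,
                      scan_axis = c("crossplane", "inplane", "depth"),
                      detector = NULL) {
  scan_axis <- match.arg(scan_axis)
  stopifnot(is.character(machine_id), length(machine_id) == 1L)
  if (!is.numeric(energy_MV) || energy_MV <= 0) stop("energy_MV must be > 0")
  if (!is.numeric(field_x_mm) || field_x_mm <= 0) stop("field_x_mm must be > 0")
  if (!is.numeric(field_y_mm) || field_y_mm <= 0) stop("field_y_mm must be > 0")
  if (!is.numeric(ssd_mm) || ssd_mm <= 0) stop("ssd_mm must be > 0")
  fff <- isTRUE(as.logical(fff))
  if (scan_axis == "depth") {
    if (!is.null(depth_mm)) stop("depth_mm must be absent for depth scans")
  } else {
    if (is.null(depth_mm) || !is.numeric(depth_mm) || depth_mm <= 0) {
      stop("depth_mm is mandatory (and > 0) for profile scans")
    }
  }
  structure(
    list(machine_id = machine_id, energy_MV = as.numeric(energy_MV),
         fff = fff, field_x_mm = as.numeric(field_x_mm),
         field_y_mm = as.numeric(field_y_mm), ssd_mm = as.numeric(ssd_mm),
         depth_mm = if (is.null(depth_mm)) NULL else as.numeric(depth_mm),
         scan_axis = scan_axis, detector = detector),
    class = "beam_spec")
}

#' A single measured scan curve
#'
#' One ordered set of position--dose samples with its [beam_spec()]
#' metadata. Positions are signed off-axis mm for lateral profiles (negative
#' toward gun / A-bank) and non-negative depth mm for depth-dose scans.
#' Doses are relative (raw detector units or percent); no normalization is
#' assumed on construction.
#'
#' @param spec A [beam_spec()].
#' @param positions Strictly increasing numeric vector (mm), length >= 5.
#'   Non-uniform steps (e.g. 2 mm central / 1 mm penumbra region) are
#'   supported.
#' @param doses Non-negative numeric vector, same length as `positions`.
#' @return An object of class `scan_curve`.
#' @export
scan_curve <- function(spec, positions, doses) {
  if (!inherits(spec, "beam_spec")) stop("spec must be a beam_spec")
  positions <- as.numeric(positions); doses <- as.numeric(doses)
  if (length(positions) != length(doses)) {
    stop("validation error: positions and doses differ in length (",
         length(positions), " vs ", length(doses), ")")
  }
  if (length(positions) < 5L) stop("validation error: curve needs >= 5 samples")
  if (any(diff(positions) <= 0)) stop("validation error: non-monotonic positions")
  if (any(!is.finite(doses)) || any(doses < 0)) {
    stop("validation error: doses must be finite and >= 0")
  }
  if (spec$scan_axis == "depth") {
    if (positions[1] < 0) stop("validation error: depth positions must be >= 0")
  } else {
    if (positions[1] >= 0 || positions[length(positions)] <= 0) {
      stop("validation error: profile positions must span both sides of the axis")
    }
  }
  structure(list(spec = spec, positions = positions, doses = doses),
            class = "scan_curve")
}

#' @export
print.scan_curve <- function(x, ...) {
  s <- x$spec
  cat(sprintf("<scan_curve> %s %gMV%s %gx%g mm %s%s, %d samples [%g, %g] mm\n",
              s$machine_id, s$energy_MV, if (s$fff) " FFF" else "",
              s$field_x_mm, s$field_y_mm, s$scan_axis,
              if (!is.null(s$depth_mm)) sprintf(" @ %g mm", s$depth_mm) else "",
              length(x$positions), min(x$positions), max(x$positions)))
  invisible(x)
}

#' A collection of scan curves
#'
#' @param curves List of [scan_curve()] objects (each individually valid).
#' @param provenance Optional list recording the source path and parse log.
#' @return An object of class `scan_set`.
#' @export
scan_set <- function(curves, provenance = NULL) {
  if (!is.list(curves) || !all(vapply(curves, inherits, TRUE, "scan_curve"))) {
    stop("curves must be a list of scan_curve objects")
  }
  structure(list(curves = curves, provenance = provenance), class = "scan_set")
}

#' @export
print.scan_set <- function(x, ...) {
  cat(sprintf("<scan_set> %d curve(s)\n", length(x$curves)))
  for (cv in x$curves) print(cv)
  invisible(x)
}

#' @export
length.scan_set <- function(x) length(x$curves)

is_profile <- function(curve) curve$spec$scan_axis != "depth"

# Nominal field side along the scanned direction (mm).
nominal_field_mm <- function(curve) {
  if (curve$spec$scan_axis == "inplane") curve$spec$field_y_mm
  else curve$spec$field_x_mm
}

# Resample a curve onto a uniform grid. All profile analyses run on a
# 0.1 mm grid; the default natural-spline interpolant avoids the level-
# crossing bias that linear chords introduce on 1-2 mm measurement steps.
resample_curve <- function(curve, step_mm = 0.1, method = c("spline", "linear")) {
  method <- match.arg(method)
  p <- curve$positions
  grid <- seq(p[1], p[length(p)], by = step_mm)
  d <- if (method == "linear") {
    stats::approx(p, curve$doses, xout = grid, ties = "ordered")$y
  } else {
    stats::splinefun(p, curve$doses, method = "natural")(grid)
  }
  list(positions = grid, doses = pmax(d, 0))
}
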