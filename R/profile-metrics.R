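# Lateral dose-profile analysis: centering, field edges, flatness,
# unflatness, symmetry, penumbra for flattened (FF) and flattening-filter-
# free (FFF) beams.
#
# Conventions: profiles are analyzed centered (see cax_correction); level
# crossings use linear interpolation; FFF field edges are inflection points
# of a cubic-spline fit on a 2 mm-smoothed, 0.1 mm-resampled curve (raw
# noisy samples make derivatives unusable). Offsets for unflatness use the
# nominal header field size, not the measured width.

# Spline evaluation of a profile's dose at arbitrary positions (the same
# natural-spline interpolant that backs the 0.1 mm analysis grid).
spline_dose <- function(curve, at) {
  rng <- range(curve$positions)
  if (any(at < rng[1] - 1e-9 | at > rng[2] + 1e-9)) {
    stop("position outside sampled range [", rng[1], ", ", rng[2], "] mm",
         call. = FALSE)
  }
  pmax(stats::splinefun(curve$positions, curve$doses, method = "natural")(at), 0)
}

# Dose on the central axis (x = 0).
cax_dose <- function(curve) spline_dose(curve, 0)

#' Smooth a lateral profile
#'
#' Centered moving average of width `window_mm` applied on a 0.1 mm
#' resampled grid. A zero window is the identity (the input is returned
#' untouched, original grid included).
#'
#' @param profile A profile [scan_curve()].
#' @param window_mm Averaging window width in mm (>= 0).
#' @return A [scan_curve()]; on the 0.1 mm grid unless `window_mm = 0`.
#' @export
smooth_profile <- function(profile, window_mm) {
  stopifnot(inherits(profile, "scan_curve"))
  if (!is_profile(profile)) stop("smooth_profile expects a lateral profile")
  if (window_mm < 0) stop("window_mm must be >= 0")
  if (window_mm == 0) return(profile)
  rs <- resample_curve(profile, 0.1, method = "linear")
  n <- length(rs$doses)
  k <- max(1L, round(window_mm / 0.1 / 2))
  cs <- c(0, cumsum(rs$doses))
  i <- seq_len(n)
  lo <- pmax(1L, i - k); hi <- pmin(n, i + k)
  sm <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  scan_curve(profile$spec, rs$positions, pmax(sm, 0))
}

# First/last crossings of `level`; errors when fewer than two are found.
outer_crossings <- function(positions, doses, level, what = "field edge") {
  cr <- level_crossings(positions, doses, level)
  if (length(cr) < 2L) stop("no ", what, ": fewer than two ", level,
                            " crossings in scan range")
  c(cr[1], cr[length(cr)])
}

#' Center a profile on the beam axis
#'
#' Translates the profile so that the midpoint of its two 50%-of-CAX-dose
#' edge positions sits at zero off-axis position.
#'
#' @param profile A profile [scan_curve()] with both 50% edges in range.
#' @return A list with `curve` (the recentered [scan_curve()]) and
#'   `shift_mm` (the applied translation; a profile sitting at +1 mm gets
#'   `shift_mm = -1`).
#' @export
cax_correction <- function(profile) {
  stopifnot(inherits(profile, "scan_curve"))
  if (!is_profile(profile)) stop("cax_correction expects a lateral profile")
  cur <- profile
  total <- 0
  for (it in 1:2) {  # second pass refines D_CAX after the first translation
    dc <- cax_dose(cur)
    rs <- resample_curve(cur, 0.1)
    edges <- outer_crossings(rs$positions, rs$doses, 0.5 * dc)
    mid <- mean(edges)
    cur <- scan_curve(cur$spec, cur$positions - mid, cur$doses)
    total <- total - mid
  }
  list(curve = cur, shift_mm = round(total, 2))
}

# Penumbra-edge model fit for one side: dose = (a0 + a1 x) * Phi(+/-(x -
# x0)/s) + b0 + b1 x, i.e. an erf edge with linear in-field modulation
# (cone, tilt) and linear background. (x0, s) are optimized, the four
# linear coefficients solved by least squares. The fitted model's own
# inflection (zero second derivative) and its dose there are returned --
# far more noise-robust than differentiating the measured samples.
# `side` is -1 (left) or +1 (right). Returns NULL when the fit fails or
# does not describe the edge.
edge_fit <- function(curve, side, dcax) {
  p <- curve$positions; d <- curve$doses
  sel <- (if (side < 0) p < 0 else p > 0) & d > 0.05 * dcax & d < 0.95 * dcax
  # widen with the nearest in/out-of-field neighbours for background anchoring
  idx <- which(sel)
  if (length(idx) < 5L) return(NULL)
  idx <- unique(sort(c(idx, max(1L, min(idx) - 3L):min(length(p), max(idx) + 3L))))
  x <- p[idx]; y <- d[idx]
  sgn <- if (side < 0) 1 else -1          # dose rises with x on the left side
  design <- function(x0, s) {
    base <- stats::pnorm(sgn * (x - x0) / s)
    cbind(base, base * x, 1, x)
  }
  sse <- function(par) {
    M <- design(par[1], exp(par[2]))
    cf <- tryCatch(qr.solve(qr(M), y), error = function(e) NULL)
    if (is.null(cf)) return(sum(y^2))
    sum((y - M %*% cf)^2)
  }
  x0_init <- x[which.min(abs(y - 0.5 * dcax))]
  ft <- tryCatch(stats::optim(c(x0_init, log(3)), sse), error = function(e) NULL)
  if (is.null(ft)) return(NULL)
  x0 <- ft$par[1]; s <- exp(ft$par[2])
  M <- design(x0, s)
  cf <- tryCatch(qr.solve(qr(M), y), error = function(e) NULL)
  if (is.null(cf)) return(NULL)
  if (sqrt(mean((y - M %*% cf)^2)) > 0.03 * dcax) return(NULL)
  if (x0 < min(x) - s || x0 > max(x) + s || s <= 0.05) return(NULL)
  # inflection of the fitted model: extremum of the numeric first
  # derivative on a fine grid around x0
  g <- seq(x0 - 2 * s, x0 + 2 * s, by = 0.005)
  base <- stats::pnorm(sgn * (g - x0) / s)
  yg <- cf[1] * base + cf[2] * base * g + cf[3] + cf[4] * g
  dg <- diff(yg) / diff(g)
  j <- if (side < 0) which.max(dg) else which.min(dg)
  xi <- (g[j] + g[j + 1]) / 2
  basei <- stats::pnorm(sgn * (xi - x0) / s)
  list(x = xi, dose = cf[1] * basei + cf[2] * basei * xi + cf[3] + cf[4] * xi)
}

# Fallback inflection locator: extremum of the first derivative of a
# cubic-spline fit on the smoothed 0.1 mm grid, searched inside the
# 20-80%-of-CAX dose corridor. `side` is -1 (left) or +1 (right).
edge_inflection <- function(sm_curve, side) {
  g <- sm_curve$positions; d <- sm_curve$doses
  dc <- interp_dose(g, d, 0)
  f <- stats::splinefun(g, d, method = "natural")
  deriv <- f(g, deriv = 1)
  in_corridor <- d > 0.2 * dc & d < 0.8 * dc
  sel <- if (side < 0) in_corridor & g < 0 else in_corridor & g > 0
  if (!any(sel)) stop("no field edge: empty 20-80% corridor on ",
                      if (side < 0) "left" else "right", " side")
  idx <- which(sel)
  i <- idx[which.max(abs(deriv[idx]))]   # largest |gradient| breaks ties
  if (i > 1L && i < length(g)) {         # sub-grid refinement of the extremum
    v <- quad_vertex(g[(i - 1L):(i + 1L)], abs(deriv[(i - 1L):(i + 1L)]))
    if (v[["x"]] >= g[i - 1L] && v[["x"]] <= g[i + 1L]) return(v[["x"]])
  }
  g[i]
}

#' Field edge positions
#'
#' For flattened beams the edges are the interpolated 50%-of-CAX-dose
#' crossings. For filter-free beams the edge on each side is the inflection
#' point of the falling profile (extremal dose gradient), located by a
#' per-side erf-edge model fit (see `edge_fit`); when the model does not
#' describe the edge the fallback is the derivative extremum of a
#' cubic-spline fit of the 2 mm-smoothed, 0.1 mm-resampled curve within the
#' 20-80% dose corridor.
#'
#' @param profile A centered profile [scan_curve()].
#' @param fff Logical; use inflection-point edges. Defaults to the curve's
#'   own metadata.
#' @return Numeric `c(left, right)` edge positions in mm.
#' @export
field_edges <- function(profile, fff = profile$spec$fff) {
  stopifnot(inherits(profile, "scan_curve"))
  if (!is_profile(profile)) stop("field_edges expects a lateral profile")
  if (!fff) {
    dc <- cax_dose(profile)
    if (dc <= 0) stop("no field edge: zero central-axis dose")
    rs <- resample_curve(profile, 0.1)
    return(outer_crossings(rs$positions, rs$doses, 0.5 * dc))
  }
  fff_edges(profile)$x
}

# Both FFF edge inflections with the dose at each: erf-edge model fit
# where it describes the data, spline-derivative fallback otherwise.
fff_edges <- function(profile) {
  dc <- cax_dose(profile)
  if (dc <= 0) stop("no field edge: zero central-axis dose")
  fl <- edge_fit(profile, -1L, dc)
  fr <- edge_fit(profile, +1L, dc)
  if (!is.null(fl) && !is.null(fr)) {
    return(list(x = c(fl$x, fr$x), dose = c(fl$dose, fr$dose),
                method = "erf_fit"))
  }
  sm <- smooth_profile(profile, 2)
  if (max(sm$doses) <= 0) stop("no field edge: zero dose profile")
  xi <- c(edge_inflection(sm, -1L), edge_inflection(sm, +1L))
  list(x = xi, dose = spline_dose(sm, xi), method = "spline_derivative")
}

#' Measured field size
#'
#' Distance between the two field edges (see [field_edges()]).
#'
#' @inheritParams field_edges
#' @return Field size in mm.
#' @export
field_size <- function(profile, fff = profile$spec$fff) {
  e <- field_edges(profile, fff)
  e[2] - e[1]
}

#' Flatness of a flattened profile
#'
#' `100 * D_max / D_min` over the central `region` fraction of the measured
#' field size, evaluated on the 0.1 mm resampled grid (IEC-style ratio
#' definition; a perfectly flat top gives 100).
#'
#' @param profile A centered flattened-beam profile [scan_curve()].
#' @param region Central fraction of field size to evaluate (default 0.8).
#' @param smooth_mm Moving-average window applied before the extremum
#'   search (default 4 mm, two central sampling intervals): the max/min
#'   ratio is a worst-case statistic and measurement software smooths
#'   profiles before evaluating it. 0 disables.
#' @return Flatness in percent (>= 100), rounded to 2 decimals.
#' @export
flatness <- function(profile, region = 0.8, smooth_mm = 4) {
  stopifnot(inherits(profile, "scan_curve"), region > 0, region <= 1)
  fs <- field_size(profile, fff = FALSE)
  half <- region * fs / 2
  sm <- smooth_profile(profile, smooth_mm)
  rs <- if (smooth_mm > 0) sm else resample_curve(profile, 0.1, method = "linear")
  sel <- rs$positions >= -half & rs$positions <= half
  if (!any(sel)) stop("empty flatness window")
  round(100 * max(rs$doses[sel]) / min(rs$doses[sel]), 2)
}

# Off-axis offset for the unflatness ratio: 60% of the half field for
# fields below the 100 mm reference size, 80% at or above it.
unflatness_offset_mm <- function(field_mm) {
  field_mm / 2 * if (field_mm < 100) 0.6 else 0.8
}

#' Unflatness of a filter-free profile
#'
#' Ratio of the central-axis dose to the off-axis dose at a field-size-
#' dependent offset: 60% of the half field side for fields smaller than
#' 10 x 10 cm2, 80% at or above. The denominator averages the interpolated
#' doses at the two mirrored offsets to cancel residual asymmetry. The
#' offset uses the nominal (header) field size.
#'
#' @param profile A centered FFF profile [scan_curve()].
#' @param field_mm Nominal field side in mm; defaults to the header value
#'   along the scanned direction.
#' @return Dimensionless ratio, rounded to 3 decimals.
#' @export
unflatness <- function(profile, field_mm = nominal_field_mm(profile)) {
  stopifnot(inherits(profile, "scan_curve"))
  off <- unflatness_offset_mm(field_mm)
  rng <- range(profile$positions)
  if (-off < rng[1] || off > rng[2]) {
    stop("unflatness offset ", off, " mm outside scan range")
  }
  dc <- cax_dose(profile)
  doff <- mean(spline_dose(profile, c(-off, off)))
  round(dc / doff, 3)
}

#' Profile symmetry
#'
#' Worst-case mirrored point-dose ratio over the central `region` fraction
#' of the field size, folded to be >= 100:
#' `max_x 100 * max(D(x)/D(-x), D(-x)/D(x))` on a 0.1 mm grid.
#'
#' @param profile A centered profile [scan_curve()].
#' @param region Central fraction of field size to evaluate (default 0.8).
#' @param smooth_mm Moving-average window applied before the point-ratio
#'   search (default 4 mm; the worst-case ratio is noise-inflated on raw
#'   scans). 0 disables.
#' @return Symmetry in percent (>= 100), rounded to 2 decimals.
#' @export
symmetry <- function(profile, region = 0.8, smooth_mm = 4) {
  stopifnot(inherits(profile, "scan_curve"), region > 0, region <= 1)
  fs <- field_size(profile)
  half <- region * fs / 2
  sm <- smooth_profile(profile, smooth_mm)
  xs <- seq(0.1, half, by = 0.1)
  xs <- xs[xs <= min(-min(sm$positions), max(sm$positions))]
  if (!length(xs)) stop("empty symmetry region")
  dp <- stats::approx(sm$positions, sm$doses, xout = xs, ties = "ordered")$y
  dm <- stats::approx(sm$positions, sm$doses, xout = -xs, ties = "ordered")$y
  ok <- dp > 0 & dm > 0
  if (!any(ok)) stop("empty symmetry region")
  round(100 * max(pmax(dp[ok] / dm[ok], dm[ok] / dp[ok])), 2)
}

#' Renormalize a filter-free profile at its inflection points
#'
#' Rescales the profile so that the mean edge dose at the two inflection
#' points (from the erf-edge fit, or interpolated on the smoothed curve in
#' the fallback path) equals 50 (percent scale), putting the FFF field
#' edge at the same dose level as a flattened beam's 50% edge. Inflection
#' positions are unchanged; the operation is idempotent.
#'
#' @param profile A centered FFF profile [scan_curve()].
#' @return The rescaled [scan_curve()], with attribute `inflections_mm`.
#' @export
renormalize_fff <- function(profile) {
  stopifnot(inherits(profile, "scan_curve"))
  ed <- fff_edges(profile)
  s <- mean(ed$dose)
  if (s <= 0) stop("non-positive dose at inflection points")
  out <- scan_curve(profile$spec, profile$positions, profile$doses * (50 / s))
  attr(out, "inflections_mm") <- ed$x
  out
}

#' Penumbra widths
#'
#' Lateral 80-20% width of each field edge. Flattened beams are normalized
#' to 100 on the central axis; filter-free beams are first renormalized at
#' their inflection points (see [renormalize_fff()]) so the standard 80-20%
#' levels apply. On each side the crossing closest to the field edge is
#' used, guarding against noise-induced extra crossings.
#'
#' @param profile A centered profile [scan_curve()].
#' @param fff Logical; apply inflection-point renormalization first.
#'   Defaults to the curve's own metadata.
#' @return Named numeric `c(left_mm, right_mm, avg_mm)`, 2 decimals.
#' @export
penumbra <- function(profile, fff = profile$spec$fff) {
  stopifnot(inherits(profile, "scan_curve"))
  if (fff) {
    cur <- renormalize_fff(profile)
    edges <- attr(cur, "inflections_mm")
  } else {
    dc <- cax_dose(profile)
    if (dc <= 0) stop("zero central-axis dose")
    cur <- scan_curve(profile$spec, profile$positions, profile$doses * (100 / dc))
    edges <- field_edges(cur, fff = FALSE)
  }
  rs <- resample_curve(cur, 0.1)
  side_width <- function(side) {
    edge <- if (side < 0) edges[1] else edges[2]
    sel <- if (side < 0) rs$positions <= 0 else rs$positions >= 0
    p <- rs$positions[sel]; d <- rs$doses[sel]
    pick <- function(level) {
      cr <- level_crossings(p, d, level)
      if (!length(cr)) stop("missing ", level, "% crossing on ",
                            if (side < 0) "left" else "right", " side")
      cr[which.min(abs(cr - edge))]
    }
    abs(pick(20) - pick(80))
  }
  l <- side_width(-1L); r <- side_width(+1L)
  round(c(left_mm = l, right_mm = r, avg_mm = (l + r) / 2), 2)
}

#' All lateral-profile metrics for one curve
#'
#' Centers the profile, then extracts the parameter set appropriate to the
#' beam type: flatness for flattened beams, unflatness and inflection
#' positions for filter-free beams, plus symmetry, field size and penumbra
#' for both.
#'
#' @param curve A profile [scan_curve()] (uncentered is fine).
#' @param region Central evaluation fraction for flatness/symmetry.
#' @return A one-row data frame of class `profile_metrics`.
#' @export
profile_metrics <- function(curve, region = 0.8) {
  stopifnot(inherits(curve, "scan_curve"))
  cc <- cax_correction(curve)
  cur <- cc$curve
  fff <- cur$spec$fff
  pen <- penumbra(cur, fff)
  infl <- if (fff) field_edges(cur, TRUE) else c(NA_real_, NA_real_)
  out <- data.frame(
    machine_id = cur$spec$machine_id,
    field_mm = nominal_field_mm(cur),
    depth_mm = cur$spec$depth_mm,
    axis = cur$spec$scan_axis,
    fff = fff,
    d_cax = round(cax_dose(cur), 2),
    cax_shift_mm = cc$shift_mm,
    field_size_mm = round(field_size(cur, fff), 2),
    flatness_pct = if (fff) NA_real_ else flatness(cur, region),
    unflatness = if (fff) unflatness(cur) else NA_real_,
    symmetry_pct = symmetry(cur, region),
    penumbra_left_mm = pen[["left_mm"]],
    penumbra_right_mm = pen[["right_mm"]],
    penumbra_avg_mm = pen[["avg_mm"]],
    inflection_left_mm = round(infl[1], 2),
    inflection_right_mm = round(infl[2], 2))
  class(out) <- c("profile_metrics", class(out))
  out
}
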