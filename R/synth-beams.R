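# Synthetic water-phantom beam generator with closed-form / dense-grid
# ground truth. Emulates the audited geometry: 6 MV FF and FFF beams at
# 90 cm SSD, square fields of 30/50/100 mm, profile depths 50/100/200 mm,
# 1 mm depth-scan steps and 2 mm central / 1 mm penumbra-region profile
# steps.
#
# Depth-dose model:  P(z) = (1 - exp(-beta z)) * exp(-mu z), scaled to 100.
# Profile model:     D(x) = 50 * [erf((F/2 - x)/(sigma sqrt2)) +
#                                 erf((F/2 + x)/(sigma sqrt2))] * g(x) * t(x)
# with cone g(x) = 1 - c|x| (piecewise-linear, so the unflatness truth is
# closed-form at any offset) and tilt t(x) = 1 + a x / (F/2); the curve is
# then translated by the CAX misalignment and Gaussian noise (relative to
# the curve maximum) is added. Noise is seeded and reproducible.

#' Parameters of the synthetic depth-dose model
#'
#' @param beta_per_mm Build-up rate in 1/mm (default 0.25).
#' @param mu_per_mm Attenuation coefficient in 1/mm (default 0.005).
#'   Requires `beta > mu > 0`.
#' @param depth_range_mm Scan extent in mm (default 300).
#' @param step_mm Sampling step in mm (default 1, the emulated detector
#'   step).
#' @param noise_sd_pct Gaussian noise SD as percent of the curve maximum.
#' @param seed Integer RNG seed, or `NULL` to use the current RNG state.
#' @return An object of class `synth_pdd_params`.
#' @export
synth_pdd_params <- function(beta_per_mm = 0.25, mu_per_mm = 0.005,
                             depth_range_mm = 300, step_mm = 1,
                             noise_sd_pct = 0, seed = NULL) {
  if (!(beta_per_mm > mu_per_mm && mu_per_mm > 0)) {
    stop("invalid params: need beta > mu > 0")
  }
  if (step_mm <= 0) stop("invalid params: step_mm must be > 0")
  if (noise_sd_pct < 0) stop("invalid params: noise_sd_pct must be >= 0")
  structure(list(beta_per_mm = beta_per_mm, mu_per_mm = mu_per_mm,
                 depth_range_mm = depth_range_mm, step_mm = step_mm,
                 noise_sd_pct = noise_sd_pct, seed = seed),
            class = "synth_pdd_params")
}

pdd_model <- function(z, beta, mu) (1 - exp(-beta * z)) * exp(-mu * z)

# Closed-form depth of maximum of the two-exponential model.
pdd_model_dmax <- function(beta, mu) log(1 + beta / mu) / beta

#' Generate a synthetic depth-dose curve with ground truth
#'
#' @param params A [synth_pdd_params()].
#' @param machine_id,field_mm,fff,detector Metadata for the emitted curve.
#' @return List with `curve` (a [scan_curve()], maximum scaled to 100
#'   before noise) and `truth`: `dmax_mm` (closed form), `pdd10_pct`,
#'   `pdd20_pct`, `r80_mm` (bisection on the analytic model to 1e-6 mm)
#'   and `quality_index`.
#' @export
make_pdd <- function(params, machine_id = "Synth", field_mm = 100,
                     fff = FALSE, detector = "synthetic") {
  stopifnot(inherits(params, "synth_pdd_params"))
  b <- params$beta_per_mm; m <- params$mu_per_mm
  z <- seq(0, params$depth_range_mm, by = params$step_mm)
  dmax <- pdd_model_dmax(b, m)
  pmax_val <- pdd_model(dmax, b, m)
  doses <- 100 * pdd_model(z, b, m) / pmax_val
  if (params$noise_sd_pct > 0) {
    doses <- with_seed(params$seed,
                       doses + stats::rnorm(length(z), 0, params$noise_sd_pct))
    doses <- pmax(doses, 0)
  }
  spec <- beam_spec(machine_id, 6, fff = fff, field_x_mm = field_mm,
                    field_y_mm = field_mm, ssd_mm = 900, depth_mm = NULL,
                    scan_axis = "depth", detector = detector)
  p10 <- 100 * pdd_model(100, b, m) / pmax_val
  p20 <- 100 * pdd_model(200, b, m) / pmax_val
  r80_true <- if (pdd_model(params$depth_range_mm, b, m) < 0.8 * pmax_val) {
    stats::uniroot(function(z) pdd_model(z, b, m) - 0.8 * pmax_val,
                   c(dmax, params$depth_range_mm), tol = 1e-9)$root
  } else NA_real_   # dose never falls through 80% in range (mu -> 0 limit)
  list(curve = scan_curve(spec, z, doses),
       truth = list(dmax_mm = dmax, pdd10_pct = p10, pdd20_pct = p20,
                    r80_mm = r80_true,
                    quality_index = 1.2661 * (p20 / p10) - 0.0595))
}

#' Parameters of the synthetic lateral-profile model
#'
#' @param field_mm Nominal square-field side F in mm.
#' @param sigma_mm Edge width sigma in mm; requires `F > 6 sigma`.
#' @param cone_slope_per_mm FFF cone coefficient c in 1/mm (0 for a
#'   flattened beam); requires `c F / 2 < 1`.
#' @param tilt_fraction Asymmetry a (dose tilt reaching `a` at the field
#'   edge); requires `|a| < 0.05`.
#' @param shift_mm CAX misalignment applied to the positions.
#' @param step_central_mm,step_penumbra_mm Sampling steps: coarse in the
#'   central/out-of-field region, fine within 3 sigma (+2 mm) of each
#'   nominal edge (defaults 2 and 1 mm, the emulated scan protocol).
#' @param half_range_mm Scan half-extent; default `F/2 + max(40, 8 sigma)`.
#' @param noise_sd_pct Gaussian noise SD as percent of the curve maximum.
#' @param seed Integer RNG seed, or `NULL`.
#' @return An object of class `synth_profile_params`.
#' @export
synth_profile_params <- function(field_mm = 100, sigma_mm = 4,
                                 cone_slope_per_mm = 0, tilt_fraction = 0,
                                 shift_mm = 0, step_central_mm = 2,
                                 step_penumbra_mm = 1,
                                 half_range_mm = NULL,
                                 noise_sd_pct = 0, seed = NULL) {
  if (field_mm <= 6 * sigma_mm) stop("invalid params: need field_mm > 6*sigma_mm")
  if (cone_slope_per_mm < 0 || cone_slope_per_mm * field_mm / 2 >= 1) {
    stop("invalid params: need 0 <= cone_slope * F/2 < 1")
  }
  if (abs(tilt_fraction) >= 0.05) stop("invalid params: need |tilt_fraction| < 0.05")
  if (step_central_mm <= 0 || step_penumbra_mm <= 0) stop("invalid params: steps must be > 0")
  if (noise_sd_pct < 0) stop("invalid params: noise_sd_pct must be >= 0")
  half_range_mm <- half_range_mm %||% (field_mm / 2 + max(40, 8 * sigma_mm))
  structure(list(field_mm = field_mm, sigma_mm = sigma_mm,
                 cone_slope_per_mm = cone_slope_per_mm,
                 tilt_fraction = tilt_fraction, shift_mm = shift_mm,
                 step_central_mm = step_central_mm,
                 step_penumbra_mm = step_penumbra_mm,
                 half_range_mm = half_range_mm,
                 noise_sd_pct = noise_sd_pct, seed = seed),
            class = "synth_profile_params")
}

# Analytic profile model, noise-free and unshifted.
profile_model <- function(x, F, sigma, cone = 0, tilt = 0) {
  s2 <- sigma * sqrt(2)
  base <- 50 * (erf((F / 2 - x) / s2) + erf((F / 2 + x) / s2))
  pmax(base * (1 - cone * abs(x)) * (1 + tilt * x / (F / 2)), 0)
}

# Non-uniform measurement grid: coarse centrally, fine near the edges.
profile_grid <- function(p) {
  R <- p$half_range_mm; F <- p$field_mm
  pen_half <- 3 * p$sigma_mm + 2
  xs <- seq(-R, R, by = p$step_central_mm)
  for (edge in c(-F / 2, F / 2)) {
    xs <- c(xs, seq(edge - pen_half, edge + pen_half, by = p$step_penumbra_mm))
  }
  xs <- sort(unique(round(c(xs, 0, -R, R), 6)))
  xs[xs >= -R & xs <= R]
}

# Ground-truth metrics of the analytic model, computed on a 0.01 mm dense
# grid (an order of magnitude finer than any pipeline grid), plus closed
# forms where available.
profile_truth <- function(p) {
  F <- p$field_mm; sg <- p$sigma_mm
  cone <- p$cone_slope_per_mm; tilt <- p$tilt_fraction
  g <- seq(-p$half_range_mm, p$half_range_mm, by = 0.01)
  d <- profile_model(g, F, sg, cone, tilt)
  dc <- profile_model(0, F, sg, cone, tilt)
  fff <- cone > 0

  if (!fff) {
    edges <- outer_crossings(g, d, 0.5 * dc)
  } else {
    dd <- diff(d) / diff(g)
    gm <- (g[-1] + g[-length(g)]) / 2
    corridor <- stats::approx(g, d, xout = gm, ties = "ordered")$y
    sel_l <- gm < 0 & corridor > 0.2 * dc & corridor < 0.8 * dc
    sel_r <- gm > 0 & corridor > 0.2 * dc & corridor < 0.8 * dc
    edges <- c(gm[sel_l][which.max(dd[sel_l])], gm[sel_r][which.min(dd[sel_r])])
  }
  fs <- edges[2] - edges[1]

  # Penumbra: closed form 2*erfinv(0.6)*sigma*sqrt(2) for the pure erf edge,
  # dense-grid for cone profiles (after inflection renormalization).
  if (cone == 0 && tilt == 0) {
    pen_side <- 2 * stats::qnorm(0.8) * sg   # erfinv(0.6)*sqrt2 = qnorm(0.8)
    pen <- c(pen_side, pen_side)
  } else {
    scale <- if (fff) 50 / mean(stats::approx(g, d, xout = edges)$y) else 100 / dc
    dn <- d * scale
    pen <- vapply(1:2, function(k) {
      sel <- if (k == 1) g <= 0 else g >= 0
      cr80 <- level_crossings(g[sel], dn[sel], 80)
      cr20 <- level_crossings(g[sel], dn[sel], 20)
      abs(cr20[which.min(abs(cr20 - edges[k]))] - cr80[which.min(abs(cr80 - edges[k]))])
    }, numeric(1))
  }

  off <- unflatness_offset_mm(F)
  unfl <- dc / mean(profile_model(c(-off, off), F, sg, cone, tilt))

  # Symmetry under the pipeline's definition: recenter at the midpoint of
  # the 50%-of-CAX crossings first (a tilt moves that midpoint slightly),
  # then take the worst mirrored point ratio over the central 80%.
  c50 <- mean(outer_crossings(g, d, 0.5 * dc))
  half <- 0.8 * fs / 2
  xs <- seq(0.01, half, by = 0.01)
  dp <- profile_model(c50 + xs, F, sg, cone, tilt)
  dm <- profile_model(c50 - xs, F, sg, cone, tilt)
  sym <- 100 * max(pmax(dp / dm, dm / dp))

  win <- d[g >= -half & g <= half]
  flat <- 100 * max(win) / min(win)

  list(field_size_mm = fs, edges_mm = edges, flatness_pct = flat,
       penumbra_left_mm = pen[1], penumbra_right_mm = pen[2],
       penumbra_avg_mm = mean(pen), unflatness = unfl, symmetry_pct = sym,
       cax_shift_mm = p$shift_mm)
}

#' Generate a synthetic lateral profile with ground truth
#'
#' @param params A [synth_profile_params()].
#' @param machine_id,depth_mm,scan_axis,detector Metadata for the curve;
#'   the beam is flagged FFF when the cone slope is positive.
#' @return List with `curve` (a [scan_curve()] on the non-uniform
#'   measurement grid, shifted by `shift_mm` and noised) and `truth` (see
#'   `profile_truth`: field size, edges, per-side and average penumbra,
#'   unflatness, symmetry, applied CAX shift).
#' @export
make_profile <- function(params, machine_id = "Synth", depth_mm = 100,
                         scan_axis = c("crossplane", "inplane"),
                         detector = "synthetic") {
  stopifnot(inherits(params, "synth_profile_params"))
  scan_axis <- match.arg(scan_axis)
  xs <- profile_grid(params)
  d <- profile_model(xs, params$field_mm, params$sigma_mm,
                     params$cone_slope_per_mm, params$tilt_fraction)
  if (params$noise_sd_pct > 0) {
    d <- with_seed(params$seed,
                   d + stats::rnorm(length(d), 0,
                                    params$noise_sd_pct / 100 * max(d)))
    d <- pmax(d, 0)
  }
  spec <- beam_spec(machine_id, 6, fff = params$cone_slope_per_mm > 0,
                    field_x_mm = params$field_mm, field_y_mm = params$field_mm,
                    ssd_mm = 900, depth_mm = depth_mm, scan_axis = scan_axis,
                    detector = detector)
  list(curve = scan_curve(spec, xs + params$shift_mm, d),
       truth = profile_truth(params))
}

#' Generate a matched cohort of virtual machines
#'
#' Emulates a multi-linac audit: every machine shares the base beam model
#' and receives its own perturbation (depth-of-maximum shift via the
#' build-up rate, penumbra widening via the edge width, added tilt) plus
#' seeded measurement noise. The unperturbed noise-free model serves as the
#' baseline ("Reference") scan set.
#'
#' @param pdd_base A [synth_pdd_params()] (noise level applies per machine).
#' @param profile_base A [synth_profile_params()].
#' @param perturbations Non-empty list; each element a list with
#'   `machine_id` and optional `dmax_shift_mm`, `penumbra_shift_mm`,
#'   `tilt_add` (defaults 0).
#' @param seed Integer; machine `i` uses `seed + i` for its noise.
#' @return List with `machines` (per machine: `machine_id`, `scans`
#'   ([scan_set()] of one depth scan and one cross-plane profile), `truth`,
#'   `deltas` applied), and `baseline` (noise-free reference scan set).
#' @export
make_matched_cohort <- function(pdd_base, profile_base, perturbations,
                                seed = 1L) {
  stopifnot(inherits(pdd_base, "synth_pdd_params"),
            inherits(profile_base, "synth_profile_params"),
            is.list(perturbations), length(perturbations) >= 1L)
  base_pdd_quiet <- synth_pdd_params(pdd_base$beta_per_mm, pdd_base$mu_per_mm,
                                     pdd_base$depth_range_mm, pdd_base$step_mm,
                                     noise_sd_pct = 0)
  base_prof_quiet <- profile_base
  base_prof_quiet$noise_sd_pct <- 0; base_prof_quiet$seed <- NULL
  ref_pdd <- make_pdd(base_pdd_quiet, machine_id = "Reference")
  ref_prof <- make_profile(base_prof_quiet, machine_id = "Reference")
  baseline <- scan_set(list(ref_pdd$curve, ref_prof$curve))

  pen_per_sigma <- 2 * stats::qnorm(0.8)   # 1.6832: 80-20 width per unit sigma
  machines <- vector("list", length(perturbations))
  for (i in seq_along(perturbations)) {
    pt <- perturbations[[i]]
    mid <- pt$machine_id %||% paste0("Linac", i)
    d_dmax <- pt$dmax_shift_mm %||% 0
    d_pen <- pt$penumbra_shift_mm %||% 0
    d_tilt <- pt$tilt_add %||% 0

    beta_i <- pdd_base$beta_per_mm
    if (d_dmax != 0) {
      target <- pdd_model_dmax(pdd_base$beta_per_mm, pdd_base$mu_per_mm) + d_dmax
      beta_i <- stats::uniroot(
        function(b) pdd_model_dmax(b, pdd_base$mu_per_mm) - target,
        c(1e-3, 5), tol = 1e-10)$root
    }
    pdd_i <- synth_pdd_params(beta_i, pdd_base$mu_per_mm,
                              pdd_base$depth_range_mm, pdd_base$step_mm,
                              noise_sd_pct = pdd_base$noise_sd_pct,
                              seed = seed + i)
    prof_i <- synth_profile_params(
      field_mm = profile_base$field_mm,
      sigma_mm = profile_base$sigma_mm + d_pen / pen_per_sigma,
      cone_slope_per_mm = profile_base$cone_slope_per_mm,
      tilt_fraction = profile_base$tilt_fraction + d_tilt,
      shift_mm = profile_base$shift_mm,
      step_central_mm = profile_base$step_central_mm,
      step_penumbra_mm = profile_base$step_penumbra_mm,
      half_range_mm = profile_base$half_range_mm,
      noise_sd_pct = profile_base$noise_sd_pct, seed = seed + i)
    gp <- make_pdd(pdd_i, machine_id = mid)
    gf <- make_profile(prof_i, machine_id = mid)
    machines[[i]] <- list(
      machine_id = mid,
      scans = scan_set(list(gp$curve, gf$curve)),
      truth = list(pdd = gp$truth, profile = gf$truth),
      deltas = list(dmax_shift_mm = d_dmax, penumbra_shift_mm = d_pen,
                    tilt_add = d_tilt))
  }
  list(machines = machines, baseline = baseline)
}
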