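# Lateral-profile analysis against closed-form / dense-grid generator truth.

test_that("smooth_profile is the identity at window 0 and conserves constants", {
  g <- make_profile(synth_profile_params(100, 4))
  expect_identical(smooth_profile(g$curve, 0), g$curve)
  flat <- scan_curve(prof_spec(), seq(-60, 60, 2), rep(7, 61))
  sm <- smooth_profile(flat, 5)
  expect_equal(sm$doses, rep(7, length(sm$doses)), tolerance = 1e-12)
  expect_error(smooth_profile(flat, -1), ">= 0")
})

test_that("smoothing reduces the RMS deviation from the noise-free truth", {
  quiet <- make_profile(synth_profile_params(100, 4))$curve
  noisy <- make_profile(synth_profile_params(100, 4, noise_sd_pct = 0.5,
                                             seed = 5))$curve
  truth_at <- function(x) approx(quiet$positions, quiet$doses, xout = x)$y
  rms_raw <- sqrt(mean((noisy$doses - truth_at(noisy$positions))^2))
  sm <- smooth_profile(noisy, 2)
  rms_sm <- sqrt(mean((sm$doses - truth_at(sm$positions))^2, na.rm = TRUE))
  expect_lt(rms_sm, rms_raw)
})

test_that("cax_correction recovers an injected misalignment", {
  g <- make_profile(synth_profile_params(100, 4, shift_mm = 1.0))
  cc <- cax_correction(g$curve)
  expect_equal(cc$shift_mm, -1.0, tolerance = 0.05)
  mid <- mean(field_edges(cc$curve, fff = FALSE))
  expect_lt(abs(mid), 0.05)
  centered <- make_profile(synth_profile_params(100, 4))
  expect_equal(cax_correction(centered$curve)$shift_mm, 0.00, tolerance = 0.01)
  # only one edge in range
  half <- make_profile(synth_profile_params(100, 4))$curve
  keep <- half$positions > -30
  broken <- scan_curve(half$spec, half$positions[keep], half$doses[keep])
  expect_error(cax_correction(broken), "field edge")
})

test_that("field edges: 50% crossings for FF, inflection points for FFF", {
  ff <- make_profile(synth_profile_params(100, 4))
  expect_equal(field_edges(ff$curve, fff = FALSE), c(-50, 50), tolerance = 0.05)
  fff <- make_profile(synth_profile_params(100, 4, 0.00322))
  infl <- field_edges(fff$curve, fff = TRUE)
  expect_equal(infl, c(-50, 50), tolerance = 0.3)
  expect_equal(infl, fff$truth$edges_mm, tolerance = 0.05)
  flat <- scan_curve(prof_spec(), seq(-60, 60, 2), rep(5, 61))
  expect_error(field_edges(flat, fff = FALSE), "no field edge")
  expect_error(field_edges(flat, fff = TRUE), "no field edge")
})

test_that("field_size matches the nominal size and ignores tilt", {
  expect_equal(field_size(make_profile(synth_profile_params(100, 4))$curve),
               100, tolerance = 0.1)
  expect_equal(field_size(make_profile(synth_profile_params(30, 3))$curve),
               30, tolerance = 0.1)
  tilted <- make_profile(synth_profile_params(100, 4, tilt_fraction = 0.01))
  expect_equal(field_size(cax_correction(tilted$curve)$curve), 100,
               tolerance = 0.1)
})

test_that("flatness is the max/min ratio over the central region", {
  expect_equal(flatness(trapezoid_profile()), 100.00)
  tilted <- trapezoid_profile(tilt = 0.0125)   # +/-1% at the +/-40 mm window edge
  expect_equal(flatness(tilted), 100 * 1.01 / 0.99, tolerance = 0.1)
  # realistic flattened beam at depth sits in the published 102-106 range
  deep <- make_profile(synth_profile_params(100, 5.5))
  expect_gt(flatness(deep$curve), 102)
  expect_lt(flatness(deep$curve), 106)
  expect_equal(flatness(deep$curve, smooth_mm = 0), deep$truth$flatness_pct,
               tolerance = 0.2)
})

test_that("unflatness uses the field-size-dependent offset on the nominal size", {
  expect_equal(beamaudit:::unflatness_offset_mm(100), 40)  # >= 10x10: 80%
  expect_equal(beamaudit:::unflatness_offset_mm(30), 9)    # < 10x10: 60%
  expect_equal(unflatness(trapezoid_profile()), 1.000)
  fff <- make_profile(synth_profile_params(100, 4, 0.00322))
  u <- unflatness(fff$curve)
  expect_equal(u, fff$truth$unflatness, tolerance = 0.002)
  expect_equal(u, 1 / (1 - 0.00322 * 40), tolerance = 0.01)  # pure-cone magnitude
  narrow <- scan_curve(prof_spec(field = 100), seq(-30, 30, 2),
                       rep(1, 31))
  expect_error(unflatness(narrow), "outside scan range")
})

test_that("symmetry folds to >= 100 and matches the worst point pair", {
  expect_equal(symmetry(trapezoid_profile()), 100.00)
  # worst pair D(x)=100.5 vs D(-x)=100, no smoothing
  x <- seq(-60, 60, 1)
  d <- ifelse(abs(x) <= 50, 100, pmax(0, 100 - 20 * (abs(x) - 50)))
  d[x == 20] <- 100.5
  bump <- scan_curve(prof_spec(), x, d)
  expect_equal(symmetry(bump, smooth_mm = 0), 100.50)
  # tilt case vs the dense-grid point-wise oracle
  tl <- make_profile(synth_profile_params(100, 4, 0.00322, tilt_fraction = 0.005))
  expect_equal(symmetry(cax_correction(tl$curve)$curve), tl$truth$symmetry_pct,
               tolerance = 0.05)
})

test_that("symmetry is mirror-invariant and >= 100 on random profiles", {
  set.seed(31)
  for (k in 1:10) {
    g <- make_profile(synth_profile_params(100, runif(1, 2.5, 5),
                                           cone_slope_per_mm = runif(1, 0, 0.004),
                                           tilt_fraction = runif(1, -0.01, 0.01),
                                           noise_sd_pct = 0.2, seed = k))
    cur <- cax_correction(g$curve)$curve
    s <- symmetry(cur)
    mir <- scan_curve(cur$spec, rev(-cur$positions), rev(cur$doses))
    expect_gte(s, 100)
    expect_equal(symmetry(mir), s, tolerance = 1e-6)
  }
})

test_that("renormalize_fff pins the inflection dose at 50 and is idempotent", {
  g <- make_profile(synth_profile_params(100, 4, 0.00322))
  rn <- renormalize_fff(g$curve)
  infl <- attr(rn, "inflections_mm")
  expect_equal(mean(beamaudit:::spline_dose(rn, infl)), 50, tolerance = 0.5)
  rn2 <- renormalize_fff(rn)
  expect_equal(rn2$doses, rn$doses, tolerance = 1e-6)
  # cone -> 0 limit: inflection renormalization equals plain CAX scaling
  g0 <- make_profile(synth_profile_params(100, 4, 1e-9))
  rn0 <- renormalize_fff(g0$curve)
  cax0 <- g0$curve$doses * 100 / beamaudit:::cax_dose(g0$curve)
  expect_equal(rn0$doses, cax0, tolerance = 0.005)
})

test_that("penumbra matches the erf closed form and scales linearly in sigma", {
  g4 <- make_profile(synth_profile_params(100, 4))
  p4 <- penumbra(g4$curve)
  expect_equal(unname(p4[c("left_mm", "right_mm")]),
               rep(2 * sqrt(2) * erfinv(0.6) * 4, 2), tolerance = 0.05)
  expect_equal(p4[["avg_mm"]], 6.73, tolerance = 0.05)
  g2 <- make_profile(synth_profile_params(100, 2))
  expect_equal(penumbra(g2$curve)[["avg_mm"]], 3.37, tolerance = 0.05)
  # sigma ~ 4.5 reproduces the published 6-8 mm magnitude at depth
  g45 <- make_profile(synth_profile_params(100, 4.5, 0.00322))
  pen <- penumbra(g45$curve)[["avg_mm"]]
  expect_gt(pen, 6); expect_lt(pen, 8)
  truncated <- {
    cv <- g4$curve
    keep <- abs(cv$positions) < 48
    scan_curve(cv$spec, cv$positions[keep], cv$doses[keep])
  }
  expect_error(penumbra(truncated))
})

test_that("penumbra grows strictly with sigma; field size does not", {
  pens <- sapply(c(2, 3, 4, 5), function(s)
    penumbra(make_profile(synth_profile_params(100, s))$curve)[["avg_mm"]])
  expect_true(all(diff(pens) > 0))
  fs <- sapply(c(2, 4, 6, 8, 10), function(s)
    field_size(make_profile(synth_profile_params(100, s))$curve))
  expect_lt(max(abs(fs - 100)), 0.2)
})

test_that("noise-free pipeline metrics match ground truth at stated tolerances", {
  cases <- list(
    synth_profile_params(100, 4, 0),
    synth_profile_params(100, 4, 0.00322),
    synth_profile_params(50, 3.5, 0.0045),
    synth_profile_params(30, 3, 0.006),
    synth_profile_params(100, 4.5, 0.00322, tilt_fraction = 0.004,
                         shift_mm = 0.8))
  for (p in cases) {
    g <- make_profile(p)
    cc <- cax_correction(g$curve)
    cur <- cc$curve
    fff <- p$cone_slope_per_mm > 0
    expect_equal(field_size(cur, fff), g$truth$field_size_mm, tolerance = 0.1)
    expect_equal(penumbra(cur, fff)[["avg_mm"]], g$truth$penumbra_avg_mm,
                 tolerance = 0.05)
    expect_equal(symmetry(cur), g$truth$symmetry_pct, tolerance = 0.05)
    if (fff) {
      expect_equal(unflatness(cur), g$truth$unflatness, tolerance = 0.002)
    }
    expect_equal(cc$shift_mm, -p$shift_mm, tolerance = 0.05)
  }
})

test_that("profile_metrics dispatches by beam type", {
  ff <- profile_metrics(make_profile(synth_profile_params(100, 4))$curve)
  expect_true(is.na(ff$unflatness) && !is.na(ff$flatness_pct))
  fff <- profile_metrics(make_profile(synth_profile_params(100, 4, 0.00322))$curve)
  expect_true(is.na(fff$flatness_pct) && !is.na(fff$unflatness))
  expect_equal(fff$inflection_right_mm, 49.88, tolerance = 0.05)
  expect_gte(fff$symmetry_pct, 100)
  expect_gt(fff$penumbra_avg_mm, 0)
})
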