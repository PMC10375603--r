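# Shared fixtures and independent oracles. Everything here is built in
# code at test time; no stored data.

# Inverse error function via the normal quantile (for closed-form penumbra
# widths: the 80-20 width of an erf edge is 2*erfinv(0.6)*sigma*sqrt(2)).
erfinv <- function(y) qnorm((y + 1) / 2) / sqrt(2)

prof_spec <- function(machine = "T", fff = FALSE, field = 100, depth = 100,
                      axis = "crossplane") {
  beam_spec(machine, 6, fff = fff, field_x_mm = field, field_y_mm = field,
            ssd_mm = 900, depth_mm = depth, scan_axis = axis)
}

depth_spec <- function(machine = "T", field = 100, fff = FALSE) {
  beam_spec(machine, 6, fff = fff, field_x_mm = field, field_y_mm = field,
            ssd_mm = 900, depth_mm = NULL, scan_axis = "depth")
}

# Trapezoid profile: flat top `top` inside +/-edge, linear ramp of width
# `ramp` to zero; optional multiplicative tilt (fraction at the field edge).
trapezoid_profile <- function(edge = 50, ramp = 8, top = 100, tilt = 0,
                              step = 1, range = 80, fff = FALSE) {
  x <- seq(-range, range, by = step)
  d <- top * pmin(1, pmax(0, (edge + ramp / 2 - abs(x)) / ramp))
  d <- d * (1 + tilt * x / edge)
  scan_curve(prof_spec(fff = fff, field = 2 * edge), x, pmax(d, 0))
}

# Independent continuous 1D gamma oracle: minimize gamma^2 over each
# segment of the piecewise-linear reference inside a +/-win*DTA window
# with stats::optimize (golden section), an implementation route disjoint
# from the package's closed-form projection.
oracle_gamma_continuous <- function(reference, evaluated, dd_pct, dta_mm,
                                    win = 12) {
  rp <- reference$positions; rd <- reference$doses
  dnorm <- max(rd); dda <- dd_pct / 100 * dnorm
  vapply(seq_along(evaluated$positions), function(i) {
    r <- evaluated$positions[i]; De <- evaluated$doses[i]
    lo <- max(r - win * dta_mm, rp[1]); hi <- min(r + win * dta_mm, rp[length(rp)])
    gsq <- function(x) {
      dref <- approx(rp, rd, xout = x, ties = "ordered")$y
      ((x - r) / dta_mm)^2 + ((dref - De) / dda)^2
    }
    knots <- unique(sort(c(lo, rp[rp > lo & rp < hi], hi)))
    best <- min(gsq(knots))
    if (length(knots) > 1L) {
      for (k in seq_len(length(knots) - 1L)) {
        op <- optimize(gsq, c(knots[k], knots[k + 1L]), tol = 1e-10)
        best <- min(best, op$objective)
      }
    }
    sqrt(best)
  }, numeric(1))
}

# Dense brute-force gamma oracle: vertex minimum on a 0.001 mm grid.
oracle_gamma_grid <- function(reference, evaluated, dd_pct, dta_mm, win = 12) {
  rp <- reference$positions; rd <- reference$doses
  dnorm <- max(rd); dda <- dd_pct / 100 * dnorm
  vapply(seq_along(evaluated$positions), function(i) {
    r <- evaluated$positions[i]
    lo <- max(r - win * dta_mm, rp[1]); hi <- min(r + win * dta_mm, rp[length(rp)])
    g <- seq(lo, hi, by = 0.001)
    dref <- approx(rp, rd, xout = g, ties = "ordered")$y
    sqrt(min(((g - r) / dta_mm)^2 + ((dref - evaluated$doses[i]) / dda)^2))
  }, numeric(1))
}

# Reference/evaluated generator pair on a common dose scale (reference
# maximum = 100), reference noise-free.
gamma_pair <- function(field = 100, sigma = 4, cone = 0, noise = 0.3,
                       seed = 1) {
  ref <- make_profile(synth_profile_params(field, sigma, cone))$curve
  ev <- make_profile(synth_profile_params(field, sigma, cone,
                                          noise_sd_pct = noise,
                                          seed = seed))$curve
  sc <- 100 / max(ref$doses)
  ref$doses <- ref$doses * sc
  ev$doses <- ev$doses * sc
  list(ref = ref, ev = ev)
}
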