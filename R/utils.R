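# Internal numerical helpers shared across modules.

# Gauss error function (base R exposes only pnorm).
erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

# Run `expr` under a temporary RNG seed, restoring global state afterwards.
# seed = NULL leaves the RNG untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  expr
}

# Linear interpolation of a curve's dose at arbitrary positions.
# Errors outside the sampled range rather than extrapolating.
interp_dose <- function(positions, doses, at) {
  if (any(at < min(positions) - 1e-9 | at > max(positions) + 1e-9)) {
    stop("position outside sampled range [", min(positions), ", ",
         max(positions), "] mm", call. = FALSE)
  }
  stats::approx(positions, doses, xout = at, rule = 2, ties = "ordered")$y
}

# All x-positions where the piecewise-linear curve crosses `level`,
# by linear interpolation inside each bracketing segment.
level_crossings <- function(positions, doses, level) {
  d <- doses - level
  n <- length(d)
  hits <- positions[abs(d) < 1e-12]
  s <- d[-n] * d[-1]
  idx <- which(s < 0)
  if (length(idx)) {
    x0 <- positions[idx]; x1 <- positions[idx + 1L]
    y0 <- d[idx]; y1 <- d[idx + 1L]
    hits <- c(hits, x0 - y0 * (x1 - x0) / (y1 - y0))
  }
  sort(unique(hits))
}

# Vertex of the parabola through three points (general, non-uniform spacing).
# Returns c(x, y) of the vertex; degenerate (linear) triples error.
quad_vertex <- function(x, y) {
  stopifnot(length(x) == 3L, length(y) == 3L)
  d1 <- (y[2] - y[1]) / (x[2] - x[1])
  d2 <- (y[3] - y[2]) / (x[3] - x[2])
  a <- (d2 - d1) / (x[3] - x[1])
  if (abs(a) < 1e-15) return(c(x = x[2], y = y[2]))  # flat top: keep the sample
  b <- d1 - a * (x[1] + x[2])
  xv <- -b / (2 * a)
  cc <- y[1] - a * x[1]^2 - b * x[1]
  c(x = xv, y = a * xv^2 + b * xv + cc)
}

fmt_num <- function(x) sprintf("%.9g", x)
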