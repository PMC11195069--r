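#' Auxiliary constants for the Lambert-W extremisation
#'
#' The ratio objectives that appear in the APS condition tables,
#' `(g_syn * f_I(f) + C) / f` with `f_I` the inhibitory steady-state rate
#' under Abeta drive `g_in`, can be rewritten in the scaled variable
#' `x = g_in * f / alpha` as `(a * tanh(x - b) + c) / x` (up to a positive
#' factor).  This helper assembles the dimensionless constants.
#'
#' @param g_in Abeta-to-inhibitory coupling (mV/Hz).
#' @param g_syn Inhibitory-to-excitatory coupling (mV/Hz), weight of the
#'   `f_I` term in the objective.
#' @param C Affine constant of the objective numerator (mV); `C = 0` for
#'   the pain-inhibition upper bound, `C = -(V_rest - V_min)` for the
#'   lower-bound row.
#' @param p Inhibitory [population_params()].
#' @return Object of class `lambert_aux`: list with `a`, `b`, `c`, `C`,
#'   `g_in`, `alpha`.
#' @export
lambert_aux <- function(g_in, g_syn, C, p) {
  stopifnot(g_in >= 0, g_syn >= 0)
  b <- -(p$v_rest - p$beta) / p$alpha
  a <- 0.5 * g_syn * p$m_max
  structure(list(a = a, b = b, c = a + C, C = C, g_in = g_in, alpha = p$alpha),
            class = "lambert_aux")
}

#' Critical Abeta rates of a ratio objective, via Lambert-W branches
#'
#' For the `C = 0` case the stationary points of
#' `(a * tanh(x - b) + c) / x` have the closed form
#' `x = (c/a - W_k(-exp(1 - 2b))) / 2` on the principal (`k = 0`) and
#' lower (`k = -1`) branches.  Returned are the corresponding Abeta rates
#' `f = alpha * x / g_in` that fall inside `f_range`; branch arguments
#' outside the Lambert domain are skipped silently.
#'
#' @param aux A [lambert_aux()] object (assembled with `C = 0`).
#' @param p Inhibitory [population_params()] (used for sanity checks).
#' @param f_range Numeric length-2, the Abeta rate window (Hz).
#' @return Numeric vector (possibly empty) of candidate rates in Hz.
#' @export
lambert_critical_rates <- function(aux, p, f_range = c(10, 20)) {
  stopifnot(inherits(aux, "lambert_aux"))
  if (aux$g_in <= 0 || aux$a <= 0) return(numeric(0))
  arg <- -exp(1 - 2 * aux$b)
  if (arg < -exp(-1)) return(numeric(0))  # outside both branch domains
  xs <- c(0.5 * (aux$c / aux$a - pracma::lambertWp(arg)),
          0.5 * (aux$c / aux$a - pracma::lambertWn(arg)))
  xs <- xs[is.finite(xs) & xs > 0]
  f <- aux$alpha * xs / aux$g_in
  sort(f[f > f_range[1] & f < f_range[2]])
}

#' Critical Abeta rates of the reciprocal-rate objectives
#'
#' The remaining extremisations in the static and dynamic condition tables
#' have the form `(g * f + C) / f_I(f)` (a linear numerator over an
#' inhibitory rate).  Their stationary points also admit a Lambert-W closed
#' form: with `x = g_in * f / alpha`, `b = (beta - V_rest) / alpha` and
#' `A = C * g_in / (g * alpha)`, the critical points are
#' `x = (1 - 2A - W_k(-exp(1 - 2A - 2b))) / 2` on both branches.
#'
#' @param g Weight of the linear term (mV/Hz), must be positive.
#' @param C Affine constant (mV).
#' @param g_in Abeta drive of the inhibitory population in the denominator
#'   (mV/Hz).
#' @param p Inhibitory [population_params()].
#' @param f_range Abeta rate window (Hz).
#' @return Numeric vector (possibly empty) of candidate rates in Hz.
#' @export
reciprocal_critical_rates <- function(g, C, g_in, p, f_range = c(10, 20)) {
  if (g <= 0 || g_in <= 0) return(numeric(0))
  b <- (p$beta - p$v_rest) / p$alpha
  A <- C * g_in / (g * p$alpha)
  arg <- -exp(1 - 2 * A - 2 * b)
  if (arg < -exp(-1)) return(numeric(0))
  xs <- c(0.5 * (1 - 2 * A - pracma::lambertWp(arg)),
          0.5 * (1 - 2 * A - pracma::lambertWn(arg)))
  xs <- xs[is.finite(xs) & xs > 0]
  f <- p$alpha * xs / g_in
  sort(f[f > f_range[1] & f < f_range[2]])
}

#' Extremise a smooth objective over the Abeta rate window
#'
#' Evaluates the objective on a dense grid plus the interval endpoints plus
#' any analytic candidate points (Lambert-W stationary points where
#' available), then refines the best grid point by golden-section search in
#' its bracketing interval.  For the smooth ratio objectives of the
#' condition tables, which have at most two interior extrema, this matches
#' a 10^4-point grid scan to well below 1e-6 relative error.
#'
#' @param fn Vectorised function of the Abeta rate (Hz).
#' @param f_range Numeric length-2 window (Hz).
#' @param sense `"min"` or `"max"`.
#' @param candidates Extra candidate rates (Hz) to include.
#' @param n_grid Grid resolution (default 1001).
#' @param tol Absolute tolerance of the golden-section refinement on `f`.
#' @return List with `f` (the extremising rate) and `value`.
#' @export
extremize_over_fab <- function(fn, f_range = c(10, 20),
                               sense = c("min", "max"),
                               candidates = numeric(0),
                               n_grid = 1001, tol = 1e-10) {
  sense <- match.arg(sense)
  sgn <- if (sense == "min") 1 else -1
  f <- function(x) sgn * fn(x)
  grid <- sort(unique(c(seq(f_range[1], f_range[2], length.out = n_grid),
                        candidates[candidates >= f_range[1] & candidates <= f_range[2]])))
  vals <- f(grid)
  if (any(!is.finite(vals))) stop("objective is non-finite on the rate window")
  i <- which.min(vals)
  lo <- grid[max(i - 1L, 1L)]
  hi <- grid[min(i + 1L, length(grid))]
  # golden-section refinement
  gr <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  x1 <- b - gr * (b - a); x2 <- a + gr * (b - a)
  f1 <- f(x1); f2 <- f(x2)
  while (b - a > tol) {
    if (f1 <= f2) { b <- x2; x2 <- x1; f2 <- f1; x1 <- b - gr * (b - a); f1 <- f(x1) }
    else { a <- x1; x1 <- x2; f1 <- f2; x2 <- a + gr * (b - a); f2 <- f(x2) }
  }
  xb <- (a + b) / 2
  cand_x <- c(grid[i], xb)
  cand_v <- c(vals[i], f(xb))
  j <- which.min(cand_v)
  list(f = cand_x[j], value = sgn * cand_v[j])
}
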