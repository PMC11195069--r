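## numerator of the allodynia-surface ratio: for output population y,
## num(f) = (V_thr - V_rest) + sum of inhibitory terms - sum of upstream
## excitatory terms, so that the surface height is min_f num(f) / f
surface_numerator <- function(circuit, g_rest) {
  k <- aps_consts()
  ip <- k$ip; ep <- k$ep
  switch(circuit$name,
    simple = function(f)
      g_rest[["gIE"]] * inhibitory_rate(f, g_rest[["gAbI"]], ip) + k$e_thr,
    static = function(f)
      g_rest[["gI1E"]] * inhibitory_rate(f, g_rest[["gAbI1"]], ip) +
      g_rest[["gI2E"]] * inhibitory_rate(f, g_rest[["gAbI2"]], ip) + k$e_thr,
    dynamic = function(f) {
      fI1 <- inhibitory_rate(f, g_rest[["gAbI1"]], ip)
      fE1 <- activation_rate(ep$v_rest + g_rest[["gAbE1"]] * f -
                               g_rest[["gI1E1"]] * fI1, ep)
      g_rest[["gI2E2"]] * inhibitory_rate(f, g_rest[["gAbI2"]], ip) -
        g_rest[["gE1E2"]] * fE1 + k$e_thr
    })
}

## fast path used by the shortest-path solver: returns function(g, f) with
## g a full coupling vector in canonical order, avoiding per-call closure
## construction
surface_numerator_fn <- function(circuit) {
  k <- aps_consts()
  ip <- k$ip; ep <- k$ep
  hmI <- 0.5 * ip$m_max; hmE <- 0.5 * ep$m_max
  vI <- ip$v_rest; bI <- ip$beta; aI <- ip$alpha
  vE <- ep$v_rest; bE <- ep$beta; aE <- ep$alpha
  et <- k$e_thr
  switch(circuit$name,
    simple = function(g, f)
      g[2L] * hmI * (1 + tanh((vI + g[1L] * f - bI) / aI)) + et,
    static = function(g, f)
      g[4L] * hmI * (1 + tanh((vI + g[1L] * f - bI) / aI)) +
      g[5L] * hmI * (1 + tanh((vI + g[2L] * f - bI) / aI)) + et,
    dynamic = function(g, f) {
      fI1 <- hmI * (1 + tanh((vI + g[1L] * f - bI) / aI))
      fE1 <- hmE * (1 + tanh((vE + g[3L] * f - g[2L] * fI1 - bE) / aE))
      g[6L] * hmI * (1 + tanh((vI + g[5L] * f - bI) / aI)) -
        g[4L] * fE1 + et
    })
}

## Lambert-W candidate rates for the surface minimisation (simple circuit:
## the C = 0 ratio form; the other circuits use the dense grid)
surface_candidates <- function(circuit, g_rest) {
  if (circuit$name != "simple") return(numeric(0))
  ip <- inhibitory_params()
  lambert_critical_rates(lambert_aux(g_rest[["gAbI"]], g_rest[["gIE"]], 0, ip),
                         ip, circuit$input_rate_range)
}

#' Height of the allodynia surface above a partial coupling vector
#'
#' The allodynia surface assigns to every combination of non-output
#' couplings the critical value of the output population's Abeta weight at
#' which its steady-state voltage first reaches threshold for some
#' non-painful Abeta rate: `min over f in [10, 20] Hz` of
#' `[(V_thr - V_rest) + inhibitory terms - upstream excitatory terms] / f`.
#' Instantiations whose output Abeta weight exceeds this height can produce
#' allodynia.
#'
#' @param circuit A [circuit_spec()] object.
#' @param g_rest Named vector with every coupling except the output
#'   population's Abeta weight (extra entries are ignored).
#' @return List with `height` (mV/Hz), `f_star` (the minimising rate, Hz)
#'   and `clamped` (`TRUE` when the minimand was negative -- possible for
#'   the dynamic circuit's upstream-excitation term -- and the height was
#'   clamped to 0, since negative coupling is non-physical).
#' @examples
#' cs <- circuit_spec("simple")
#' surface_height(cs, c(gAbI = 3, gIE = 0))  # 35.1/20 = 1.755 at f = 20
#' @export
surface_height <- function(circuit, g_rest) {
  stopifnot(inherits(circuit, "circuit_spec"))
  need <- setdiff(circuit$coupling_names, circuit$output_coupling)
  if (!all(need %in% names(g_rest)))
    stop("`g_rest` must contain: ", paste(need, collapse = ", "))
  num <- surface_numerator(circuit, as.list(g_rest))
  res <- extremize_over_fab(function(f) num(f) / f, circuit$input_rate_range,
                            sense = "min",
                            candidates = surface_candidates(circuit, g_rest))
  clamped <- res$value <= 0
  list(height = max(res$value, 0), f_star = res$f, clamped = clamped)
}

#' Can a coupling vector produce allodynia?
#'
#' A full coupling vector admits allodynia exactly when its output Abeta
#' weight is at least the [surface_height()] of its remaining couplings;
#' when it does, the minimal Abeta rate at which the output population's
#' steady-state voltage reaches threshold is returned.
#'
#' @param circuit A [circuit_spec()] object.
#' @param g Full coupling vector.
#' @param tol Comparison tolerance on the height (mV/Hz).
#' @return List with `attainable` (logical) and `f_allodynia` (Hz, or `NA`
#'   when not attainable): the smallest rate in the non-painful window at
#'   which the output population fires.
#' @export
is_allodynia_attainable <- function(circuit, g, tol = 1e-9) {
  g <- coupling_vector(circuit, g)
  out <- circuit$output_coupling
  h <- surface_height(circuit, g[setdiff(names(g), out)])
  att <- g[[out]] >= h$height - tol
  f_all <- NA_real_
  if (att) {
    num <- surface_numerator(circuit, as.list(g))
    fr <- circuit$input_rate_range
    fg <- sort(unique(c(seq(fr[1], fr[2], length.out = 2001),
                        surface_candidates(circuit, g), h$f_star)))
    hit <- fg[g[[out]] * fg >= num(fg) - tol * fg]
    f_all <- if (length(hit)) min(hit) else h$f_star
  }
  list(attainable = att, f_allodynia = f_all)
}
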