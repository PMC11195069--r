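#' Derive voltage cutoffs from activation-function parameters
#'
#' The voltage bounds and firing threshold of a population are tied to its
#' activation curve: the minimum and maximum admissible average voltages sit
#' 12 slope-units below and above the half-activation voltage, and the firing
#' threshold sits one slope-unit below it.  Tying the cutoffs to the
#' activation slope this way gives excitatory and inhibitory populations
#' similar behaviour under proportional changes in input.
#'
#' @param alpha Activation slope (mV), must be positive.
#' @param beta Half-activation voltage (mV).
#' @return Named numeric vector with elements `v_min`, `v_thr`, `v_max` (mV).
#' @examples
#' derive_voltage_cutoffs(7.9, -17)   # excitatory: -111.8, -24.9, 77.8
#' derive_voltage_cutoffs(9.3, -30)   # inhibitory: -141.6, -39.3, 81.6
#' @export
derive_voltage_cutoffs <- function(alpha, beta) {
  stopifnot(is.numeric(alpha), is.numeric(beta), is.finite(alpha), is.finite(beta))
  if (alpha <= 0) stop("`alpha` must be positive")
  c(v_min = beta - 12 * alpha, v_thr = beta - alpha, v_max = beta + 12 * alpha)
}

#' Fixed biophysical parameters of one neural population
#'
#' Bundles the sigmoidal activation-curve parameters, derived voltage
#' cutoffs, resting voltage and membrane time constant of a population of
#' dorsal-horn interneurons.  Cutoffs are always derived from `alpha` and
#' `beta` via [derive_voltage_cutoffs()].
#'
#' @param alpha Activation slope (mV).
#' @param beta Half-activation voltage (mV).
#' @param m_max Maximum firing rate (Hz).
#' @param v_rest Resting voltage (mV).
#' @param tau Membrane time constant (s).
#' @return Object of class `population_params`: a list with fields `alpha`,
#'   `beta`, `m_max`, `v_rest`, `v_min`, `v_thr`, `v_max`, `tau`.
#' @seealso [inhibitory_params()], [excitatory_params()] for the standard
#'   dorsal-horn fits.
#' @export
population_params <- function(alpha, beta, m_max, v_rest, tau) {
  stopifnot(is.numeric(alpha), is.numeric(beta), is.numeric(m_max),
            is.numeric(v_rest), is.numeric(tau))
  if (alpha <= 0) stop("`alpha` must be positive")
  if (m_max <= 0) stop("`m_max` must be positive")
  if (tau <= 0) stop("`tau` must be positive")
  cut <- derive_voltage_cutoffs(alpha, beta)
  if (!(cut[["v_min"]] < v_rest && v_rest < cut[["v_thr"]]))
    stop("invalid parameters: need v_min < v_rest < v_thr")
  structure(list(alpha = alpha, beta = beta, m_max = m_max, v_rest = v_rest,
                 v_min = cut[["v_min"]], v_thr = cut[["v_thr"]],
                 v_max = cut[["v_max"]], tau = tau),
            class = "population_params")
}

#' @export
print.population_params <- function(x, ...) {
  cat(sprintf(
    "population: alpha=%.3g mV, beta=%.3g mV, m_max=%.3g Hz, v_rest=%.3g mV, tau=%.3g s\n",
    x$alpha, x$beta, x$m_max, x$v_rest, x$tau))
  cat(sprintf("  cutoffs: v_min=%.4g, v_thr=%.4g, v_max=%.4g mV\n",
              x$v_min, x$v_thr, x$v_max))
  invisible(x)
}

#' Standard inhibitory-population parameters
#'
#' Activation-curve fit to frequency-voltage relations of rat dorsal-horn
#' inhibitory interneurons (slope 9.3 mV, half-activation -30 mV, maximum
#' rate 80 Hz), resting voltage -60 mV, time constant 20 ms.
#'
#' @return A [population_params()] object.
#' @export
inhibitory_params <- function() {
  population_params(alpha = 9.3, beta = -30, m_max = 80, v_rest = -60, tau = 0.02)
}

#' Standard excitatory-population parameters
#'
#' Activation-curve fit for dorsal-horn excitatory interneurons (slope
#' 7.9 mV, half-activation -17 mV, maximum rate 50 Hz), resting voltage
#' -60 mV, time constant 10 ms.
#'
#' @return A [population_params()] object.
#' @export
excitatory_params <- function() {
  population_params(alpha = 7.9, beta = -17, m_max = 50, v_rest = -60, tau = 0.01)
}

#' Sigmoidal firing-rate activation function
#'
#' Maps average membrane voltage to average population firing rate,
#' `0.5 * m_max * (1 + tanh((V - beta) / alpha))`.  Strictly increasing in
#' `V`, bounded in `[0, m_max]`.
#'
#' @param v Average membrane voltage (mV); may be a vector or matrix.
#' @param p A [population_params()] object.
#' @return Firing rate (Hz), same shape as `v`.
#' @examples
#' activation_rate(-30, inhibitory_params())  # half-activation: 40 Hz
#' @export
activation_rate <- function(v, p) {
  if (!all(is.finite(v))) stop("`v` must be finite")
  0.5 * p$m_max * (1 + tanh((v - p$beta) / p$alpha))
}
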