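#' Steady-state population voltages under constant Abeta input
#'
#' Evaluates populations in feedforward order: each population's
#' steady-state voltage is its resting voltage plus the signed, weighted sum
#' of its presynaptic inputs, with presynaptic firing rates evaluated at the
#' presynaptic population's own steady state.  Ablation of a population
#' zeroes its output rate (equivalently its outgoing couplings), which is
#' how the condition tables remove terms from the steady-state
#' inequalities; the ablated population still receives input.
#'
#' @param circuit A [circuit_spec()] object.
#' @param g Coupling vector (see [coupling_vector()]).
#' @param f_ab Constant Abeta firing rate (Hz), non-negative scalar.
#' @param ablate Character vector of population labels whose output is
#'   silenced.
#' @return Named numeric vector of steady-state voltages (mV), one per
#'   population.
#' @examples
#' cs <- circuit_spec("simple")
#' g <- coupling_vector(cs, c(gAbI = 3, gIE = 1.5, gAbE = 4.5))
#' steady_state_voltages(cs, g, f_ab = 15)
#' @export
steady_state_voltages <- function(circuit, g, f_ab, ablate = character()) {
  stopifnot(inherits(circuit, "circuit_spec"), is.numeric(f_ab), f_ab >= 0)
  g <- coupling_vector(circuit, g)
  labels <- names(circuit$populations)
  unknown <- setdiff(ablate, labels)
  if (length(unknown)) stop("unknown ablation label(s): ", paste(unknown, collapse = ", "))
  vss <- rates <- stats::setNames(numeric(length(labels)), labels)
  for (lab in labels) {  # populations listed in feedforward order
    p <- circuit$populations[[lab]]$params
    inc <- circuit$connections[circuit$connections$target == lab, , drop = FALSE]
    total <- 0
    for (i in seq_len(nrow(inc))) {
      src <- inc$source[i]
      f_src <- if (src == "Abeta") f_ab else rates[[src]]
      total <- total + inc$sign[i] * g[[inc$coupling[i]]] * f_src
    }
    vss[[lab]] <- p$v_rest + total
    rates[[lab]] <- if (lab %in% ablate) 0 else activation_rate(vss[[lab]], p)
  }
  vss
}

#' Steady-state population firing rates under constant Abeta input
#'
#' Convenience wrapper: activation rates at [steady_state_voltages()],
#' with ablated populations reporting 0 Hz.
#'
#' @inheritParams steady_state_voltages
#' @return Named numeric vector of firing rates (Hz).
#' @export
steady_state_rates <- function(circuit, g, f_ab, ablate = character()) {
  vss <- steady_state_voltages(circuit, g, f_ab, ablate)
  out <- vapply(names(vss), function(lab)
    activation_rate(vss[[lab]], circuit$populations[[lab]]$params), numeric(1))
  out[names(out) %in% ablate] <- 0
  out
}

#' Simulate the firing-rate dynamics of a subcircuit
#'
#' Integrates `tau_x dV_x/dt = V_rest - V_x + sum_y g_yx f_y` for every
#' population with a fixed-step fourth-order Runge-Kutta scheme.  The Abeta
#' input is a piecewise-constant rate trace sampled on the simulation grid
#' (held constant within each step).  Voltages are not clipped to
#' `[v_min, v_max]`: those bounds are steady-state constraints for APS
#' membership, not dynamics.
#'
#' @param circuit A [circuit_spec()] object.
#' @param g Coupling vector.
#' @param input Numeric vector of Abeta rates (Hz), one value per time step
#'   (length determines the simulated duration), or a single constant rate
#'   together with `duration`.
#' @param dt Time step (s); must be below half the smallest membrane time
#'   constant (stability guard).
#' @param duration Total simulated time (s), only used when `input` is a
#'   scalar.
#' @param ablate Population labels whose output rate is held at zero.
#' @return Object of class `circuit_trajectory`: list with `time` (s),
#'   `voltage` and `rate` (matrices, one column per population), `input`,
#'   and `circuit` name.
#' @examples
#' cs <- circuit_spec("simple")
#' g <- coupling_vector(cs, c(gAbI = 3, gIE = 1.5, gAbE = 4.5))
#' tr <- simulate_circuit(cs, g, input = 15, dt = 1e-3, duration = 0.5)
#' tail(tr$voltage, 1)  # close to steady_state_voltages(cs, g, 15)
#' @export
simulate_circuit <- function(circuit, g, input, dt = 1e-4, duration = NULL,
                             ablate = character()) {
  stopifnot(inherits(circuit, "circuit_spec"), dt > 0)
  g <- coupling_vector(circuit, g)
  labels <- names(circuit$populations)
  unknown <- setdiff(ablate, labels)
  if (length(unknown)) stop("unknown ablation label(s): ", paste(unknown, collapse = ", "))
  taus <- vapply(circuit$populations, function(p) p$params$tau, numeric(1))
  if (dt >= min(taus) / 2)
    stop("dt must be smaller than half the smallest time constant (",
         min(taus) / 2, " s)")
  if (length(input) == 1L) {
    if (is.null(duration)) stop("`duration` required for constant input")
    input <- rep(input, ceiling(duration / dt))
  }
  n <- length(input)
  npop <- length(labels)
  v_rest <- vapply(circuit$populations, function(p) p$params$v_rest, numeric(1))
  V <- matrix(NA_real_, n + 1L, npop, dimnames = list(NULL, labels))
  R <- matrix(NA_real_, n + 1L, npop, dimnames = list(NULL, labels))
  v <- v_rest
  live <- !(labels %in% ablate)
  rate_of <- function(v) {
    r <- vapply(seq_len(npop), function(j)
      activation_rate(v[j], circuit$populations[[j]]$params), numeric(1))
    r * live
  }
  conn <- circuit$connections
  drift <- function(v, f_ab) {
    r <- rate_of(v)
    names(r) <- labels
    inp <- stats::setNames(numeric(npop), labels)
    for (i in seq_len(nrow(conn))) {
      src <- conn$source[i]
      f_src <- if (src == "Abeta") f_ab else r[[src]]
      inp[[conn$target[i]]] <- inp[[conn$target[i]]] +
        conn$sign[i] * g[[conn$coupling[i]]] * f_src
    }
    (v_rest - v + inp) / taus
  }
  V[1L, ] <- v
  R[1L, ] <- rate_of(v)
  for (t in seq_len(n)) {
    f_ab <- input[t]
    k1 <- drift(v, f_ab)
    k2 <- drift(v + dt / 2 * k1, f_ab)
    k3 <- drift(v + dt / 2 * k2, f_ab)
    k4 <- drift(v + dt * k3, f_ab)
    v <- v + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    V[t + 1L, ] <- v
    R[t + 1L, ] <- rate_of(v)
  }
  structure(list(time = seq(0, by = dt, length.out = n + 1L),
                 voltage = V, rate = R, input = input, dt = dt,
                 circuit = circuit$name),
            class = "circuit_trajectory")
}

#' @export
print.circuit_trajectory <- function(x, ...) {
  cat(sprintf("<circuit_trajectory> %s, %d steps of %g s, populations: %s\n",
              x$circuit, length(x$time) - 1L, x$dt,
              paste(colnames(x$voltage), collapse = ", ")))
  invisible(x)
}

#' Export a trajectory as a long-format data frame
#'
#' @param x A `circuit_trajectory`.
#' @param ... Unused.
#' @return Data frame with columns `time_s`, `population`, `V_mV`, `f_Hz`,
#'   suitable for CSV export.
#' @export
as.data.frame.circuit_trajectory <- function(x, ...) {
  labs <- colnames(x$voltage)
  do.call(rbind, lapply(labs, function(lab)
    data.frame(time_s = x$time, population = lab,
               V_mV = x$voltage[, lab], f_Hz = x$rate[, lab])))
}
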