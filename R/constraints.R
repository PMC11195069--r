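#' Inhibitory steady-state firing rate under constant Abeta drive
#'
#' An inhibitory population with Abeta weight `g_in` settles at voltage
#' `V_rest + g_in * f` and fires at the activation rate of that voltage.
#' Strictly increasing in both arguments.
#'
#' @param f_ab Abeta rate (Hz), vectorised.
#' @param g_in Abeta-to-inhibitory coupling (mV/Hz).
#' @param p Inhibitory [population_params()].
#' @return Firing rate (Hz).
#' @export
inhibitory_rate <- function(f_ab, g_in, p = inhibitory_params()) {
  stopifnot(all(f_ab >= 0), g_in >= 0)
  activation_rate(p$v_rest + g_in * f_ab, p)
}

## internal: shared constants of the condition tables
aps_consts <- function() {
  ip <- inhibitory_params(); ep <- excitatory_params()
  list(ip = ip, ep = ep,
       i_thr = ip$v_thr - ip$v_rest,    # 20.7 mV
       i_max = ip$v_max - ip$v_rest,    # 141.6 mV
       e_thr = ep$v_thr - ep$v_rest,    # 35.1 mV
       e_max = ep$v_max - ep$v_rest,    # 137.8 mV
       e_min = ep$v_rest - ep$v_min)    # 51.8 mV
}

## internal: constraint ids per circuit, in margin-matrix column order
constraint_ids <- function(circuit) {
  switch(circuit$name,
    simple = c("I_upper_bound", "I_fires", "pain_inhibition", "E_lower_bound",
               "E_upper_bound_I_abl", "E_fires_I_abl"),
    static = c("I1_upper_bound", "I1_fires", "I2_upper_bound", "I2_fires",
               "pain_inhibition", "E_lower_bound",
               "E_fires_I1_abl", "E_upper_bound_I1_abl",
               "E_fires_I2_abl", "E_upper_bound_I2_abl"),
    dynamic = c("I1_upper_bound", "I1_fires", "I2_upper_bound", "I2_fires",
                "E1_pain_inhibition", "E1_lower_bound",
                "E1_fires_I1_abl", "E1_upper_bound_I1_abl",
                "E2_pain_inhibition", "E2_lower_bound_E1_abl",
                "E2_fires_I1_abl", "E2_upper_bound_I1_abl",
                "E2_fires_I2_abl", "E2_upper_bound_I2_abl"))
}

## internal: worst steady-state margins (mV, >= 0 means satisfied) for a
## matrix of coupling vectors, evaluated on the Abeta rate points `fg`.
aps_margins <- function(circuit, G, fg) {
  G <- as_coupling_matrix(circuit, G)
  k <- aps_consts()
  ip <- k$ip; ep <- k$ep
  f_lo <- min(fg); f_hi <- max(fg)
  rmin <- function(M) apply(M, 1L, min)
  switch(circuit$name,
    simple = {
      FI <- activation_rate(ip$v_rest + G[, "gAbI"] %o% fg, ip)
      EF <- G[, "gAbE"] %o% fg
      TIE <- G[, "gIE"] * FI
      cbind(I_upper_bound = k$i_max - G[, "gAbI"] * f_hi,
            I_fires = G[, "gAbI"] * f_lo - k$i_thr,
            pain_inhibition = rmin(TIE - EF),
            E_lower_bound = rmin(EF - TIE + k$e_min),
            E_upper_bound_I_abl = k$e_max - G[, "gAbE"] * f_hi,
            E_fires_I_abl = G[, "gAbE"] * f_lo - k$e_thr)
    },
    static = {
      F1 <- activation_rate(ip$v_rest + G[, "gAbI1"] %o% fg, ip)
      F2 <- activation_rate(ip$v_rest + G[, "gAbI2"] %o% fg, ip)
      EF <- G[, "gAbE"] %o% fg
      T1 <- G[, "gI1E"] * F1
      T2 <- G[, "gI2E"] * F2
      cbind(I1_upper_bound = k$i_max - G[, "gAbI1"] * f_hi,
            I1_fires = G[, "gAbI1"] * f_lo - k$i_thr,
            I2_upper_bound = k$i_max - G[, "gAbI2"] * f_hi,
            I2_fires = G[, "gAbI2"] * f_lo - k$i_thr,
            pain_inhibition = rmin(T1 + T2 - EF),
            E_lower_bound = rmin(EF - T1 - T2 + k$e_min),
            E_fires_I1_abl = rmin(EF - T2 - k$e_thr),
            E_upper_bound_I1_abl = rmin(k$e_max - EF + T2),
            E_fires_I2_abl = rmin(EF - T1 - k$e_thr),
            E_upper_bound_I2_abl = rmin(k$e_max - EF + T1))
    },
    dynamic = {
      F1 <- activation_rate(ip$v_rest + G[, "gAbI1"] %o% fg, ip)
      F2 <- activation_rate(ip$v_rest + G[, "gAbI2"] %o% fg, ip)
      EF1 <- G[, "gAbE1"] %o% fg
      EF2 <- G[, "gAbE2"] %o% fg
      T11 <- G[, "gI1E1"] * F1
      T22 <- G[, "gI2E2"] * F2
      E1c <- activation_rate(ep$v_rest + EF1 - T11, ep)  # control E1 rate
      E1a <- activation_rate(ep$v_rest + EF1, ep)        # E1 rate, I1 ablated
      Tc <- G[, "gE1E2"] * E1c
      Ta <- G[, "gE1E2"] * E1a
      cbind(I1_upper_bound = k$i_max - G[, "gAbI1"] * f_hi,
            I1_fires = G[, "gAbI1"] * f_lo - k$i_thr,
            I2_upper_bound = k$i_max - G[, "gAbI2"] * f_hi,
            I2_fires = G[, "gAbI2"] * f_lo - k$i_thr,
            E1_pain_inhibition = rmin(T11 - EF1),
            E1_lower_bound = rmin(EF1 - T11 + k$e_min),
            E1_fires_I1_abl = G[, "gAbE1"] * f_lo - k$e_thr,
            E1_upper_bound_I1_abl = k$e_max - G[, "gAbE1"] * f_hi,
            E2_pain_inhibition = rmin(T22 - Tc - EF2),
            E2_lower_bound_E1_abl = rmin(EF2 - T22 + k$e_min),
            E2_fires_I1_abl = rmin(EF2 + Ta - T22 - k$e_thr),
            E2_upper_bound_I1_abl = rmin(k$e_max - EF2 - Ta + T22),
            E2_fires_I2_abl = rmin(EF2 + Tc - k$e_thr),
            E2_upper_bound_I2_abl = rmin(k$e_max - EF2 - Tc))
    })
}

#' Batch APS feasibility check
#'
#' Vectorised test of every steady-state inequality of the circuit's
#' condition table on an `n_grid`-point Abeta rate grid.  A coarse 9-point
#' screen eliminates most infeasible points before the full grid is
#' evaluated; rows are processed in chunks to bound memory.
#'
#' @param circuit A [circuit_spec()] object.
#' @param G Matrix of coupling vectors (rows = points, canonical column
#'   order or named columns), or a single coupling vector.
#' @param n_grid Rate-grid resolution (default 201).
#' @param tol Feasibility slack on the voltage margins (mV).
#' @return Logical vector, one entry per row of `G`.
#' @export
aps_feasible <- function(circuit, G, n_grid = 201, tol = 1e-9) {
  G <- as_coupling_matrix(circuit, G)
  fr <- circuit$input_rate_range
  out <- logical(nrow(G))
  chunk <- 20000L
  for (s in seq(1L, nrow(G), by = chunk)) {
    idx <- s:min(s + chunk - 1L, nrow(G))
    Gi <- G[idx, , drop = FALSE]
    keep <- seq_len(nrow(Gi))
    for (kk in c(9L, n_grid)) {
      if (!length(keep)) break
      fg <- seq(fr[1], fr[2], length.out = kk)
      M <- aps_margins(circuit, Gi[keep, , drop = FALSE], fg)
      keep <- keep[rowSums(M < -tol) == 0L]
    }
    out[idx[keep]] <- TRUE
  }
  out
}

#' Check a coupling vector against the APS condition table
#'
#' Evaluates every steady-state inequality of the circuit on an
#' `n_grid`-point Abeta grid augmented with the analytic Lambert-W
#' stationary points of the nonlinear rows, and reports the worst voltage
#' margin per constraint.
#'
#' @param circuit A [circuit_spec()] object.
#' @param g A coupling vector.
#' @param n_grid Rate-grid resolution (>= 2).
#' @param tol Feasibility slack on the margins (mV).
#' @return Object of class `constraint_report`: list with `feasible`
#'   (logical), `margins` (named numeric, mV; negative = violated) and
#'   `violations` (data frame of violated constraint ids and margins).
#' @examples
#' cs <- circuit_spec("simple")
#' is_in_aps(cs, c(gAbI = 3, gIE = 1.5, gAbE = 4.5))
#' @export
is_in_aps <- function(circuit, g, n_grid = 201, tol = 1e-9) {
  stopifnot(n_grid >= 2)
  g <- coupling_vector(circuit, g)
  fr <- circuit$input_rate_range
  fg <- seq(fr[1], fr[2], length.out = n_grid)
  ip <- inhibitory_params()
  cand <- numeric(0)
  for (nm in intersect(c("gAbI", "gAbI1", "gAbI2"), names(g))) {
    syn <- switch(nm, gAbI = "gIE", gAbI1 = if (circuit$name == "static") "gI1E" else "gI1E1",
                  gAbI2 = if (circuit$name == "static") "gI2E" else "gI2E2")
    aux <- lambert_aux(g[[nm]], g[[syn]], C = 0, p = ip)
    cand <- c(cand, lambert_critical_rates(aux, ip, fr))
  }
  fg <- sort(unique(c(fg, cand)))
  margins <- drop(aps_margins(circuit, matrix(g, nrow = 1,
                                              dimnames = list(NULL, names(g))), fg))
  bad <- margins < -tol
  structure(list(feasible = !any(bad),
                 margins = margins,
                 violations = data.frame(constraint = names(margins)[bad],
                                         margin_mV = unname(margins[bad]))),
            class = "constraint_report")
}

#' @export
print.constraint_report <- function(x, ...) {
  if (x$feasible) {
    cat("in APS; worst margin", signif(min(x$margins), 4), "mV (",
        names(x$margins)[which.min(x$margins)], ")\n")
  } else {
    cat("NOT in APS; violated constraints:\n")
    print(x$violations, row.names = FALSE)
  }
  invisible(x)
}

#' Export the circuit's constraint table as JSON
#'
#' Emits the condition identifiers and a symbolic description of each
#' steady-state inequality, for documentation and downstream tooling.
#'
#' @param circuit A [circuit_spec()] object.
#' @param path Optional file to write to.
#' @return JSON string (invisibly, if `path` given).
#' @export
constraint_table_json <- function(circuit, path = NULL) {
  ids <- constraint_ids(circuit)
  kind <- ifelse(grepl("fires", ids), "lower bound on voltage (firing)",
          ifelse(grepl("upper_bound", ids), "upper bound on voltage",
          ifelse(grepl("pain_inhibition", ids), "net Abeta-evoked input inhibitory",
                 "lower bound on voltage")))
  txt <- jsonlite::toJSON(data.frame(constraint = ids, type = kind),
                          pretty = TRUE)
  if (!is.null(path)) { writeLines(txt, path); return(invisible(txt)) }
  txt
}
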