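#' Feedforward dorsal-horn subcircuit specifications
#'
#' Builds one of the three feedforward subcircuit motifs analysed by the
#' package:
#'
#' * `"simple"` -- the canonical gate-control motif: one inhibitory
#'   population I inhibiting one excitatory population E; couplings
#'   `gAbI`, `gIE`, `gAbE`.
#' * `"static"` -- the motif implicated in static allodynia: two inhibitory
#'   populations I1 (DYN+) and I2 (PV+) both inhibiting a collective
#'   excitatory population E; couplings `gAbI1`, `gAbI2`, `gAbE`, `gI1E`,
#'   `gI2E`.
#' * `"dynamic"` -- the motif implicated in dynamic allodynia: two coupled
#'   gate units, I1 gating E1 (VGLUT3+) which excites E2 (SOM+/CR-), itself
#'   gated by I2; couplings `gAbI1`, `gI1E1`, `gAbE1`, `gE1E2`, `gAbI2`,
#'   `gI2E2`, `gAbE2`.
#'
#' Every population receives the Abeta fibre input; the output population
#' (E, E, E2 respectively) is the one presumed to target projection
#' neurons, so its sustained firing is the model's proxy for a painful
#' response.  Non-painful Abeta rates are `input_rate_range = c(10, 20)` Hz.
#'
#' @param name One of `"simple"`, `"static"`, `"dynamic"`.
#' @return Object of class `circuit_spec`: a list with fields `name`,
#'   `populations` (named list of lists with `type` and `params`),
#'   `connections` (data frame with columns `source`, `target`, `sign`,
#'   `coupling`), `coupling_names` (canonical parameter order),
#'   `sampling_order` (hierarchy order used for sequential sampling),
#'   `output_population`, `output_coupling` (the output population's Abeta
#'   weight, the "height" coordinate of the allodynia surface), and
#'   `input_rate_range` (Hz).
#' @examples
#' circuit_spec("simple")
#' @export
circuit_spec <- function(name = c("simple", "static", "dynamic")) {
  name <- match.arg(name)
  ip <- inhibitory_params()
  ep <- excitatory_params()
  pop <- function(type) list(type = type, params = if (type == "I") ip else ep)
  con <- function(source, target, sign, coupling)
    data.frame(source = source, target = target, sign = sign,
               coupling = coupling, stringsAsFactors = FALSE)
  spec <- switch(name,
    simple = list(
      populations = list(I = pop("I"), E = pop("E")),
      connections = rbind(
        con("Abeta", "I", +1, "gAbI"),
        con("Abeta", "E", +1, "gAbE"),
        con("I", "E", -1, "gIE")),
      coupling_names = c("gAbI", "gIE", "gAbE"),
      sampling_order = c("gAbI", "gIE", "gAbE"),
      output_population = "E",
      output_coupling = "gAbE"),
    static = list(
      populations = list(I1 = pop("I"), I2 = pop("I"), E = pop("E")),
      connections = rbind(
        con("Abeta", "I1", +1, "gAbI1"),
        con("Abeta", "I2", +1, "gAbI2"),
        con("Abeta", "E", +1, "gAbE"),
        con("I1", "E", -1, "gI1E"),
        con("I2", "E", -1, "gI2E")),
      coupling_names = c("gAbI1", "gAbI2", "gAbE", "gI1E", "gI2E"),
      sampling_order = c("gAbI1", "gAbI2", "gAbE", "gI1E", "gI2E"),
      output_population = "E",
      output_coupling = "gAbE"),
    dynamic = list(
      populations = list(I1 = pop("I"), E1 = pop("E"), I2 = pop("I"), E2 = pop("E")),
      connections = rbind(
        con("Abeta", "I1", +1, "gAbI1"),
        con("Abeta", "E1", +1, "gAbE1"),
        con("Abeta", "I2", +1, "gAbI2"),
        con("Abeta", "E2", +1, "gAbE2"),
        con("I1", "E1", -1, "gI1E1"),
        con("I2", "E2", -1, "gI2E2"),
        con("E1", "E2", +1, "gE1E2")),
      coupling_names = c("gAbI1", "gI1E1", "gAbE1", "gE1E2", "gAbI2", "gI2E2", "gAbE2"),
      sampling_order = c("gAbI1", "gAbI2", "gI1E1", "gAbE1", "gE1E2", "gI2E2", "gAbE2"),
      output_population = "E2",
      output_coupling = "gAbE2"))
  structure(c(list(name = name), spec, list(input_rate_range = c(10, 20))),
            class = "circuit_spec")
}

#' @export
print.circuit_spec <- function(x, ...) {
  cat(sprintf("<circuit_spec> %s subcircuit: %d populations, output %s\n",
              x$name, length(x$populations), x$output_population))
  cat("  couplings:", paste(x$coupling_names, collapse = ", "), "\n")
  cat(sprintf("  Abeta input range: [%g, %g] Hz\n",
              x$input_rate_range[1], x$input_rate_range[2]))
  invisible(x)
}

#' Construct a coupling-strength vector for a circuit
#'
#' A coupling vector is a named numeric vector in the circuit's canonical
#' parameter order; one entry per synaptic connection, including one Abeta
#' weight per population.  All strengths are in mV/Hz and must be
#' non-negative.
#'
#' @param circuit A [circuit_spec()] object.
#' @param values Named numeric vector (any order) or unnamed numeric vector
#'   already in canonical order.
#' @return Named numeric vector in `circuit$coupling_names` order.
#' @examples
#' cs <- circuit_spec("simple")
#' coupling_vector(cs, c(gIE = 1.5, gAbI = 3, gAbE = 4.5))
#' @export
coupling_vector <- function(circuit, values) {
  stopifnot(inherits(circuit, "circuit_spec"), is.numeric(values))
  nm <- circuit$coupling_names
  if (is.null(names(values))) {
    if (length(values) != length(nm))
      stop("unnamed `values` must have length ", length(nm))
    names(values) <- nm
  } else {
    if (!setequal(names(values), nm))
      stop("`values` names must be exactly: ", paste(nm, collapse = ", "))
    values <- values[nm]
  }
  if (any(values < 0)) stop("coupling strengths must be non-negative")
  values
}

## coerce a matrix (rows = points) to canonical column order
as_coupling_matrix <- function(circuit, g) {
  if (is.null(dim(g))) g <- matrix(g, nrow = 1, dimnames = list(NULL, names(g)))
  nm <- circuit$coupling_names
  if (!is.null(colnames(g))) g <- g[, nm, drop = FALSE]
  else if (ncol(g) != length(nm)) stop("wrong number of coupling columns")
  colnames(g) <- nm
  g
}
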