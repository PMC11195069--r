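#' Abeta fibre-bundle stimulus protocol
#'
#' Describes the noisy input delivered to every population: a bundle of
#' independent Poisson-spiking Abeta fibres firing at a low background rate
#' outside the stimulus window and at the stimulus rate inside it.  The
#' population input is the across-fibre average spiking rate estimated in
#' short bins.
#'
#' @param n_fibers Number of fibres in the bundle (default 300, the order of
#'   magnitude of Abeta fibres in a rodent afferent nerve).
#' @param background_rate Per-fibre rate outside the stimulus (Hz).
#' @param stimulus_rate Per-fibre rate during the stimulus (Hz); non-painful
#'   rates are 10--20 Hz.
#' @param t_on,t_off Stimulus window (s).
#' @param duration Total trace duration (s).
#' @param bin_width Rate-estimation bin (s).  The bin width is a free
#'   parameter of the rate-from-spikes conversion; 5 ms smooths single-spike
#'   granularity while keeping the stimulus onset sharp.
#' @return Object of class `stimulus_protocol`.
#' @export
stimulus_protocol <- function(n_fibers = 300, background_rate = 1,
                              stimulus_rate = 15, t_on = 0.2, t_off = 0.7,
                              duration = 1, bin_width = 0.005) {
  stopifnot(n_fibers >= 1, background_rate >= 0, stimulus_rate >= 0,
            bin_width > 0, duration > 0)
  if (!(0 <= t_on && t_on < t_off && t_off <= duration))
    stop("need 0 <= t_on < t_off <= duration")
  structure(list(n_fibers = n_fibers, background_rate = background_rate,
                 stimulus_rate = stimulus_rate, t_on = t_on, t_off = t_off,
                 duration = duration, bin_width = bin_width),
            class = "stimulus_protocol")
}

#' Generate a noisy Abeta input trace
#'
#' Draws independent Poisson spike counts per bin for the whole bundle (the
#' superposition of `n_fibers` independent Poisson processes is Poisson with
#' the summed rate), converts counts to an across-fibre average rate, and
#' resamples the piecewise-constant rate onto the simulation grid.
#' Reproducible under a fixed seed; the trace expectation equals the
#' piecewise-constant rate profile and its per-bin variance is
#' `rate / (n_fibers * bin_width)`.
#'
#' @param proto A [stimulus_protocol()].
#' @param dt Simulation time step (s); must not exceed `bin_width`.
#' @param seed Optional integer seed (local to this call).
#' @return Numeric vector of rates (Hz), one per `dt` step, of length
#'   `ceiling(duration / dt)`.
#' @examples
#' tr <- generate_abeta_trace(stimulus_protocol(), dt = 1e-3, seed = 1)
#' mean(tr[200:700])  # close to the 15 Hz stimulus rate
#' @export
generate_abeta_trace <- function(proto, dt, seed = NULL) {
  stopifnot(inherits(proto, "stimulus_protocol"), dt > 0)
  if (proto$bin_width < dt) stop("bin_width must be >= dt")
  n_bins <- ceiling(proto$duration / proto$bin_width)
  bin_start <- (seq_len(n_bins) - 1L) * proto$bin_width
  bin_mid <- bin_start + proto$bin_width / 2
  rate <- ifelse(bin_mid >= proto$t_on & bin_mid < proto$t_off,
                 proto$stimulus_rate, proto$background_rate)
  draw <- function() stats::rpois(n_bins, proto$n_fibers * rate * proto$bin_width)
  counts <- if (is.null(seed)) draw() else local_seed(seed, draw())
  bin_rate <- counts / (proto$n_fibers * proto$bin_width)
  n_steps <- ceiling(proto$duration / dt)
  idx <- pmin(floor((seq_len(n_steps) - 1L) * dt / proto$bin_width) + 1L, n_bins)
  bin_rate[idx]
}

## evaluate `code` under a temporary RNG state seeded with `seed`
local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}
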