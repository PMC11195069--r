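#' Nearest allodynia-surface point from one APS point
#'
#' Finds the minimal change of coupling strengths, measured in normalised
#' hypercube units, that moves the circuit onto the allodynia surface.
#' Rather than constructing the surface (itself defined through a
#' minimisation over the Abeta rate), the relaxed problem is solved: the
#' output Abeta weight is expressed through the surface equality at a
#' *free* rate `f` in the non-painful window, and the distance is minimised
#' over (all other couplings, f) with multi-start L-BFGS-B.  One start is
#' deterministic -- the source with its output weight lifted straight up to
#' the surface at the minimising rate -- which guarantees a feasible
#' incumbent; the rest perturb the source.  A post-hoc check re-minimises
#' the surface ratio over the rate at the returned point, so every
#' converged target satisfies the true (min-over-rate) surface equality.
#'
#' @param circuit A [circuit_spec()] object.
#' @param cube The normalising [build_hypercube()].
#' @param g_p Source coupling vector (raw units), assumed in the APS.
#' @param n_starts Number of optimisation starts.
#' @param seed Optional integer seed (local to this call).
#' @return Object of class `shortest_path_record`: list with `source`,
#'   `target`, `displacement` (normalised, named), `distance` (normalised
#'   Euclidean), `f_nearest` (Hz), `converged` (logical).
#' @export
nearest_surface_point <- function(circuit, cube, g_p, n_starts = 20,
                                  seed = NULL) {
  g_p <- coupling_vector(circuit, g_p)
  run <- function() sp_solve(circuit, cube, g_p, n_starts)
  if (is.null(seed)) run() else local_seed(seed, run())
}

## internal solver (RNG state managed by the caller)
sp_solve <- function(circuit, cube, g_p, n_starts) {
  nm <- circuit$coupling_names
  out <- circuit$output_coupling
  oi <- match(out, nm)
  free <- setdiff(seq_along(nm), oi)
  lo <- cube$lo; rng <- cube$range
  fr <- circuit$input_rate_range
  p <- as.numeric(normalize_coupling(cube, g_p))
  numf <- surface_numerator_fn(circuit)
  nfree <- length(free)
  iz <- seq_len(nfree)
  lo_f <- as.numeric(lo[free]); rng_f <- as.numeric(rng[free])
  lo_o <- as.numeric(lo[oi]); rng_o <- as.numeric(rng[oi])
  p_f <- p[free]; p_o <- p[oi]
  g_buf <- numeric(length(nm))
  clamp0 <- function(x) if (x < 0) 0 else x   # surface height is >= 0
  obj <- function(z) {
    g_buf[free] <- lo_f + z[iz] * rng_f
    f <- z[nfree + 1L]
    ny <- (clamp0(numf(g_buf, f) / f) - lo_o) / rng_o
    sum((z[iz] - p_f)^2) + (ny - p_o)^2
  }
  ## fast min-over-rate height of the surface at a full coupling buffer
  fgd <- seq(fr[1], fr[2], length.out = 401L)
  height_min <- function(g) {
    v <- numf(g, fgd) / fgd
    i <- which.min(v)
    a <- fgd[max(i - 1L, 1L)]; b <- fgd[min(i + 1L, length(fgd))]
    gr <- (sqrt(5) - 1) / 2
    x1 <- b - gr * (b - a); x2 <- a + gr * (b - a)
    f1 <- numf(g, x1) / x1; f2 <- numf(g, x2) / x2
    while (b - a > 1e-8) {
      if (f1 <= f2) { b <- x2; x2 <- x1; f2 <- f1; x1 <- b - gr * (b - a); f1 <- numf(g, x1) / x1 }
      else { a <- x1; x1 <- x2; f1 <- f2; x2 <- a + gr * (b - a); f2 <- numf(g, x2) / x2 }
    }
    fb <- (a + b) / 2
    vb <- numf(g, fb) / fb
    if (vb <= v[i]) c(clamp0(vb), fb) else c(clamp0(v[i]), fgd[i])
  }
  g_buf[free] <- as.numeric(g_p[free])
  h0 <- height_min(g_buf)
  ## deterministic starts: the source lifted at its minimising rate and at
  ## the window endpoints (the low end hosts a separate solution basin
  ## where reduced inhibitory drive makes the surface dip steeply)
  starts <- rbind(c(p_f, h0[2]), c(p_f, fr[1]), c(p_f, fr[2]))
  starts <- starts[seq_len(min(3L, max(n_starts, 1L))), , drop = FALSE]
  if (n_starts > 3) {
    for (s in seq_len(n_starts - 3L)) {
      zf <- pmin(pmax(p_f + stats::rnorm(nfree, 0, 0.2), 0), 1)
      starts <- rbind(starts, c(zf, stats::runif(1, fr[1], fr[2])))
    }
  }
  lower <- c(-lo[free] / rng[free], fr[1])   # raw couplings stay >= 0
  upper <- c(rep(2.5, length(free)), fr[2])
  best <- NULL
  for (si in seq_len(nrow(starts))) {
    r <- try(stats::optim(starts[si, ], obj, method = "L-BFGS-B",
                          lower = lower, upper = upper,
                          control = list(factr = 1e2, maxit = 500)),
             silent = TRUE)
    if (inherits(r, "try-error")) next
    if (is.null(best) || r$value < best$value) best <- r
  }
  if (is.null(best)) {
    return(structure(list(source = stats::setNames(p, nm),
                          target = rep(NA_real_, length(nm)),
                          displacement = rep(NA_real_, length(nm)),
                          distance = NA_real_, f_nearest = NA_real_,
                          converged = FALSE),
                     class = "shortest_path_record"))
  }
  ## the relaxed solution can sit above the true surface when the
  ## min-over-rate height at its couplings is attained elsewhere in the
  ## window; in that case re-solve from the plunge point until the target
  ## is self-consistent (true distance can only improve)
  true_d2 <- function(z) {
    g_buf[free] <- lo_f + z[iz] * rng_f
    ht <- height_min(g_buf)
    ny <- (ht[1] - lo_o) / rng_o
    list(d2 = sum((z[iz] - p_f)^2) + (ny - p_o)^2, ht = ht)
  }
  z <- best$par
  cur <- true_d2(z)
  for (it in 1:4) {
    g_buf[free] <- lo_f + z[iz] * rng_f
    f_z <- z[nfree + 1L]
    sval <- numf(g_buf, f_z) / f_z
    if (sval <= cur$ht[1] + 1e-8) break
    r2 <- try(stats::optim(c(z[iz], cur$ht[2]), obj, method = "L-BFGS-B",
                           lower = lower, upper = upper,
                           control = list(factr = 1e2, maxit = 500)),
              silent = TRUE)
    if (inherits(r2, "try-error")) break
    alt <- true_d2(r2$par)
    if (alt$d2 < cur$d2 - 1e-14) { z <- r2$par; cur <- alt } else break
  }
  g_t <- stats::setNames(numeric(length(nm)), nm)
  g_t[free] <- lo_f + z[iz] * rng_f
  ## enforce the true min-over-rate surface equality at the target
  ht <- cur$ht
  g_t[oi] <- ht[1]
  target <- normalize_coupling(cube, g_t)
  disp <- target - stats::setNames(p, nm)
  structure(list(source = stats::setNames(p, nm), target = target,
                 displacement = disp,
                 distance = sqrt(sum(disp^2)), f_nearest = ht[2],
                 converged = TRUE),
            class = "shortest_path_record")
}

#' @export
print.shortest_path_record <- function(x, ...) {
  cat(sprintf("<shortest_path_record> distance %.4g (normalised), f_nearest %.3g Hz\n",
              x$distance, x$f_nearest))
  cat("  displacement:\n")
  print(round(x$displacement, 4))
  invisible(x)
}

#' Shortest vectors from an APS sample to the allodynia surface
#'
#' Maps [nearest_surface_point()] over a sample of APS points (records kept
#' in input order; per-point non-convergence is flagged, not fatal).
#'
#' @param circuit A [circuit_spec()] object.
#' @param sample Matrix of coupling vectors (raw units, rows = points).
#' @param cube The normalising [build_hypercube()].
#' @param n_starts Optimisation starts per point.
#' @param seed Optional integer seed (local to this call).
#' @return Object of class `shortest_paths`: list with matrices `source`,
#'   `target`, `displacement` (normalised), vectors `distance`,
#'   `f_nearest`, `converged`, and the `cube`.
#' @export
shortest_vectors <- function(circuit, sample, cube, n_starts = 20,
                             seed = NULL) {
  sample <- as_coupling_matrix(circuit, sample)
  run <- function() {
    recs <- lapply(seq_len(nrow(sample)), function(i)
      sp_solve(circuit, cube, sample[i, ], n_starts))
    structure(list(
      source = do.call(rbind, lapply(recs, `[[`, "source")),
      target = do.call(rbind, lapply(recs, `[[`, "target")),
      displacement = do.call(rbind, lapply(recs, `[[`, "displacement")),
      distance = vapply(recs, `[[`, numeric(1), "distance"),
      f_nearest = vapply(recs, `[[`, numeric(1), "f_nearest"),
      converged = vapply(recs, `[[`, logical(1), "converged"),
      cube = cube, circuit = circuit$name),
      class = "shortest_paths")
  }
  if (is.null(seed)) run() else local_seed(seed, run())
}

#' @export
print.shortest_paths <- function(x, ...) {
  cat(sprintf("<shortest_paths> %s circuit: %d records (%d converged)\n",
              x$circuit, length(x$distance), sum(x$converged)))
  cat(sprintf("  distance: median %.3g, max %.3g (normalised units)\n",
              stats::median(x$distance, na.rm = TRUE),
              max(x$distance, na.rm = TRUE)))
  invisible(x)
}

#' @export
as.data.frame.shortest_paths <- function(x, ...) {
  src <- as.data.frame(x$source)
  names(src) <- paste0("source_", colnames(x$source))
  dsp <- as.data.frame(x$displacement)
  names(dsp) <- paste0("disp_", colnames(x$displacement))
  cbind(src, dsp,
        data.frame(distance = x$distance, f_nearest = x$f_nearest,
                   converged = x$converged))
}
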