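#' Hierarchical seed sample of the allowable parameter space
#'
#' Draws coupling vectors by walking the circuit's inequality hierarchy:
#' each coupling is drawn uniformly from its conditional interval given the
#' couplings already fixed ([coupling_bounds()]); if any interval is empty
#' the draw restarts from the top.  Every returned point satisfies the APS
#' system, but the sample is *not* spatially uniform -- it is used to bound
#' the APS (see [build_hypercube()]) and to anchor the cover, not for the
#' distributional analyses.
#'
#' @param circuit A [circuit_spec()] object.
#' @param n Number of points (the hypercube construction wants at least
#'   1000).
#' @param seed Optional integer seed (local to this call).
#' @param n_grid Rate-grid resolution for the interval evaluations.
#' @param max_restarts Abort threshold on total restarts.
#' @return Numeric matrix, `n` rows, columns in canonical coupling order.
#' @export
hierarchical_seed_sample <- function(circuit, n, seed = NULL, n_grid = 201,
                                     max_restarts = 1e6) {
  stopifnot(inherits(circuit, "circuit_spec"), n >= 1)
  draw_all <- function() {
    ord <- circuit$sampling_order
    stages <- stage_functions(circuit, n_grid)
    out <- matrix(NA_real_, n, length(ord),
                  dimnames = list(NULL, circuit$coupling_names))
    got <- 0L; restarts <- 0L
    while (got < n) {
      reset_stage_cache(stages)
      partial <- stats::setNames(numeric(0), character(0))
      ok <- TRUE
      for (nm in ord) {
        iv <- stages[[nm]](partial)
        if (is.null(iv)) { ok <- FALSE; break }
        partial <- c(partial, stats::setNames(stats::runif(1, iv[1], iv[2]), nm))
      }
      if (ok && aps_feasible(circuit, partial[circuit$coupling_names],
                             n_grid)) {
        ## the full-grid check guards the scan stages, whose intervals are
        ## resolved on a rate subgrid and can overhang by a sliver
        got <- got + 1L
        out[got, ] <- partial[circuit$coupling_names]
      } else {
        restarts <- restarts + 1L
        if (restarts > max_restarts)
          stop("seed sampling exceeded ", max_restarts, " restarts")
      }
    }
    out
  }
  if (is.null(seed)) draw_all() else local_seed(seed, draw_all())
}

#' Bounding hypercube and normalisation of an APS sample
#'
#' Component-wise minima and maxima across the sample define a rectangular
#' hypercube containing the sampled APS; couplings are normalised to
#' `[0, 1]` by their position in that box, which is how displacement
#' magnitudes in different couplings are made comparable.
#'
#' @param sample Numeric matrix of coupling vectors (rows = points).
#' @return Object of class `aps_hypercube`: list with `lo`, `hi`, `range`
#'   (named numeric vectors).
#' @export
build_hypercube <- function(sample) {
  if (is.null(dim(sample)) || nrow(sample) < 1) stop("need a non-empty sample matrix")
  lo <- apply(sample, 2L, min)
  hi <- apply(sample, 2L, max)
  if (any(hi - lo <= 0))
    stop("degenerate axis (min == max): ",
         paste(colnames(sample)[hi - lo <= 0], collapse = ", "))
  structure(list(lo = lo, hi = hi, range = hi - lo), class = "aps_hypercube")
}

#' @export
print.aps_hypercube <- function(x, ...) {
  cat("<aps_hypercube>\n")
  print(round(rbind(lo = x$lo, hi = x$hi), 4))
  invisible(x)
}

#' Map couplings to and from normalised hypercube coordinates
#'
#' @param cube An [build_hypercube()] object.
#' @param g Matrix or vector of couplings (raw mV/Hz for `normalize_coupling`,
#'   normalised units for `denormalize_coupling`).
#' @return Same shape as `g`, transformed.
#' @export
normalize_coupling <- function(cube, g) {
  if (is.null(dim(g))) (g - cube$lo) / cube$range
  else sweep(sweep(g, 2L, cube$lo), 2L, cube$range, "/")
}

#' @rdname normalize_coupling
#' @export
denormalize_coupling <- function(cube, g) {
  if (is.null(dim(g))) g * cube$range + cube$lo
  else sweep(sweep(g, 2L, cube$range, "*"), 2L, cube$lo, "+")
}

#' Hyperrectangle cover of the normalised APS
#'
#' Recursively bisects the unit hypercube (always along the currently
#' longest axis of a box).  A box all of whose random interior probes are
#' feasible is kept whole; a box with no feasible probe and no seed-sample
#' point is discarded; anything else is subdivided until `depth` bisections,
#' where boxes holding a feasible probe or a seed point are kept.  Leaves
#' are disjoint by construction, so volume-weighted box choice in
#' [sample_uniform()] is exactly uniform on the covered region.
#'
#' @param circuit A [circuit_spec()] object.
#' @param cube The bounding [build_hypercube()].
#' @param sample The seed sample (raw units) used as containment anchors.
#' @param depth Maximum number of binary bisections (default three per
#'   axis, capped at 16: beyond that the boundary-hugging frontier of the
#'   bisection tree grows faster than the resolution gain is worth).
#' @param probes Random feasibility probes per box.
#' @param seed Optional integer seed (local to this call).
#' @param n_grid Rate-grid resolution of the feasibility checks.
#' @return Object of class `aps_cover`: list with `lo`, `hi` (matrices of
#'   box corners in normalised units), `volume`, `max_volume`, `cube`.
#' @export
build_cover <- function(circuit, cube, sample,
                        depth = min(3 * length(cube$lo), 16L),
                        probes = 64, seed = NULL, n_grid = 201) {
  stopifnot(inherits(circuit, "circuit_spec"), inherits(cube, "aps_hypercube"),
            depth >= 1)
  d <- length(cube$lo)
  pts <- normalize_coupling(cube, as_coupling_matrix(circuit, sample))
  run <- function() {
    leaves <- list()
    rec <- function(lo_, hi_, pts, level) {
      P <- matrix(stats::runif(probes * d), probes, d)
      P <- sweep(sweep(P, 2L, hi_ - lo_, "*"), 2L, lo_, "+")
      nf <- sum(aps_feasible(circuit, denormalize_coupling(cube, P), n_grid))
      if (nf == probes) { leaves[[length(leaves) + 1L]] <<- c(lo_, hi_); return() }
      if (level >= depth) {
        if (nf > 0L || nrow(pts) > 0L) leaves[[length(leaves) + 1L]] <<- c(lo_, hi_)
        return()
      }
      if (nf == 0L && nrow(pts) == 0L) return()
      ax <- which.max(hi_ - lo_)
      mid <- (lo_[ax] + hi_[ax]) / 2
      sel <- pts[, ax] <= mid
      h1 <- hi_; h1[ax] <- mid
      l2 <- lo_; l2[ax] <- mid
      rec(lo_, h1, pts[sel, , drop = FALSE], level + 1L)
      rec(l2, hi_, pts[!sel, , drop = FALSE], level + 1L)
    }
    rec(rep(0, d), rep(1, d), pts, 0L)
    if (!length(leaves)) stop("cover construction produced no boxes")
    L <- t(vapply(leaves, function(b) b[seq_len(d)], numeric(d)))
    H <- t(vapply(leaves, function(b) b[d + seq_len(d)], numeric(d)))
    colnames(L) <- colnames(H) <- circuit$coupling_names
    vol <- apply(H - L, 1L, prod)
    structure(list(lo = L, hi = H, volume = vol, max_volume = max(vol),
                   cube = cube, circuit = circuit$name),
              class = "aps_cover")
  }
  if (is.null(seed)) run() else local_seed(seed, run())
}

#' @export
print.aps_cover <- function(x, ...) {
  cat(sprintf("<aps_cover> %s circuit: %d boxes, total volume %.4g of unit cube\n",
              x$circuit, nrow(x$lo), sum(x$volume)))
  invisible(x)
}

#' Spatially uniform sample of the APS
#'
#' Repeats: pick a cover box with probability proportional to its volume,
#' pick a point uniformly inside it, and keep it iff it passes the APS
#' inequality system.  Because the cover boxes are disjoint, the
#' volume-weighted box choice makes the proposal exactly uniform on the
#' cover's union, so the accepted points are exactly uniform on the APS
#' intersected with the cover; it is equivalent to choosing boxes uniformly
#' and thinning accepted points by `volume(box) / max_volume`, but wastes
#' no draws on the thinning step.  The cost is independent of the APS
#' volume fraction in the bounding box.
#'
#' @param circuit A [circuit_spec()] object.
#' @param cover An [build_cover()] object.
#' @param n Number of points to accept.
#' @param seed Optional integer seed (local to this call).
#' @param n_grid Rate-grid resolution of the feasibility checks.
#' @param batch Proposals per vectorised batch.
#' @param min_rate Abort when the empirical acceptance rate falls below
#'   this after the first batches.
#' @return List with `raw` (matrix, raw mV/Hz units), `normalized` (matrix
#'   in hypercube units) and `acceptance_rate`.
#' @export
sample_uniform <- function(circuit, cover, n, seed = NULL, n_grid = 201,
                           batch = 50000L, min_rate = 1e-6) {
  stopifnot(inherits(cover, "aps_cover"), n >= 1)
  d <- ncol(cover$lo)
  cube <- cover$cube
  run <- function() {
    acc <- matrix(numeric(0), 0L, d)
    props <- 0L
    while (nrow(acc) < n) {
      bi <- sample.int(nrow(cover$lo), batch, replace = TRUE,
                       prob = cover$volume)
      U <- matrix(stats::runif(batch * d), batch, d)
      X <- cover$lo[bi, , drop = FALSE] +
        U * (cover$hi[bi, , drop = FALSE] - cover$lo[bi, , drop = FALSE])
      props <- props + batch
      ok <- aps_feasible(circuit, denormalize_coupling(cube, X), n_grid)
      acc <- rbind(acc, X[ok, , drop = FALSE])
      if (props >= 20L * batch && nrow(acc) / props < min_rate)
        stop("sampler acceptance rate below ", min_rate)
    }
    Xn <- acc[seq_len(n), , drop = FALSE]
    colnames(Xn) <- colnames(cover$lo)
    list(raw = denormalize_coupling(cube, Xn), normalized = Xn,
         acceptance_rate = nrow(acc) / props)
  }
  if (is.null(seed)) run() else local_seed(seed, run())
}
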