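#' Density-based clustering labels
#'
#' Standard density-based spatial clustering on a set of vectors: a point
#' is a *core* point when its `eps`-neighbourhood (Euclidean, including the
#' point itself) holds at least `min_pts` points; clusters are the
#' connected components of core-point reachability, with border points
#' attached to the first core neighbour encountered.  Deterministic given
#' the input order: components are grown from the lowest-index unlabelled
#' core point.
#'
#' @param x Numeric matrix (rows = vectors) or a precomputed symmetric
#'   distance matrix (when `is_dist = TRUE`).
#' @param eps Neighbourhood radius.
#' @param min_pts Minimum neighbourhood size for a core point (self
#'   included).
#' @param is_dist Interpret `x` as a distance matrix.
#' @return Integer vector of labels; `0` marks noise.
#' @export
dbscan_labels <- function(x, eps, min_pts = 5, is_dist = FALSE) {
  dm <- if (is_dist) x else as.matrix(stats::dist(x))
  n <- nrow(dm)
  if (min_pts > n) stop("min_pts exceeds the number of points")
  ## neighbourhoods are queried against the distance matrix on demand,
  ## so no n x n logical matrix is materialised (matters at n ~ 5000)
  core <- logical(n)
  chunk <- max(1L, floor(2e7 / n))
  for (s in seq(1L, n, by = chunk)) {
    idx <- s:min(s + chunk - 1L, n)
    core[idx] <- rowSums(dm[idx, , drop = FALSE] <= eps) >= min_pts
  }
  lab <- integer(n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (lab[i] || !core[i]) next
    cl <- cl + 1L
    lab[i] <- cl
    queue <- i
    while (length(queue)) {
      j <- queue[1L]
      queue <- queue[-1L]
      nbrs <- which(dm[j, ] <= eps & lab == 0L)
      lab[nbrs] <- cl
      queue <- c(queue, nbrs[core[nbrs]])
    }
  }
  lab
}

#' Smallest no-noise neighbourhood radius
#'
#' Binary search (to `resolution`) for the smallest `eps` at which
#' density-based clustering of the displacement vectors labels no point as
#' noise.  The search bracket is the range of `min_pts`-th nearest
#' neighbour distances: at the upper end every point is core, so no noise
#' is guaranteed.
#'
#' @param vectors Numeric matrix of displacement vectors.
#' @param min_pts Core-point neighbourhood size (default 5).
#' @param resolution Search resolution on `eps`.
#' @return The selected `eps` (scalar).
#' @export
select_epsilon <- function(vectors, min_pts = 5, resolution = 1e-4) {
  vectors <- as.matrix(vectors)
  if (min_pts > nrow(vectors)) stop("min_pts exceeds the sample size")
  dm <- as.matrix(stats::dist(vectors))
  kd <- apply(dm, 1L, function(r) sort(r, partial = min_pts)[min_pts])
  lo <- min(kd)
  hi <- max(kd) * (1 + 1e-9) + resolution
  while (hi - lo > resolution) {
    mid <- (lo + hi) / 2
    if (any(dbscan_labels(dm, mid, min_pts, is_dist = TRUE) == 0L)) lo <- mid
    else hi <- mid
  }
  hi
}

#' Cluster shortest-path displacement vectors into mechanism classes
#'
#' Applies density-based clustering at the supplied radius (normally from
#' [select_epsilon()], whose contract guarantees no noise), renumbers
#' clusters by descending share (ties broken by ascending mean distance
#' when distances are supplied), and summarises each cluster by its share
#' and mean displacement.
#'
#' @param vectors Matrix of displacement vectors (rows = records), columns
#'   named by coupling.
#' @param epsilon Neighbourhood radius.
#' @param min_pts Core-point neighbourhood size.
#' @param distance Optional per-record distances used for tie-breaking and
#'   per-cluster summaries.
#' @return Object of class `cluster_result`: list with `labels`,
#'   `epsilon`, `min_pts`, `fractions`, `mean_displacements` (matrix, one
#'   row per cluster), `mean_distance`, `mechanism_tags` (filled by
#'   [tag_mechanisms()]).
#' @export
cluster_vectors <- function(vectors, epsilon, min_pts = 5, distance = NULL) {
  vectors <- as.matrix(vectors)
  lab <- dbscan_labels(vectors, epsilon, min_pts)
  if (any(lab == 0L))
    stop("noise points at the supplied epsilon; use select_epsilon()")
  shares <- table(lab) / length(lab)
  md <- if (is.null(distance)) rep(NA_real_, length(shares)) else
    vapply(names(shares), function(cl) mean(distance[lab == as.integer(cl)]),
           numeric(1))
  ord <- order(-as.numeric(shares), md)
  relab <- match(lab, as.integer(names(shares))[ord])
  k <- length(ord)
  mean_disp <- t(vapply(seq_len(k), function(cl)
    colMeans(vectors[relab == cl, , drop = FALSE]), numeric(ncol(vectors))))
  rownames(mean_disp) <- paste0("cluster_", seq_len(k))
  structure(list(labels = relab, epsilon = epsilon, min_pts = min_pts,
                 fractions = as.numeric(shares)[ord],
                 mean_displacements = mean_disp,
                 mean_distance = md[ord],
                 mechanism_tags = NULL),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  k <- length(x$fractions)
  cat(sprintf("<cluster_result> %d clusters (eps = %.4g, minPts = %d)\n",
              k, x$epsilon, x$min_pts))
  for (cl in seq_len(k)) {
    tag <- if (!is.null(x$mechanism_tags)) paste0(" [", x$mechanism_tags[cl], "]") else ""
    cat(sprintf("  cluster %d: %.1f%%%s, mean displacement: %s\n", cl,
                100 * x$fractions[cl], tag,
                paste(sprintf("%s %+0.2f", colnames(x$mean_displacements),
                              x$mean_displacements[cl, ]), collapse = ", ")))
  }
  invisible(x)
}

#' Tag clusters with their candidate allodynia mechanism
#'
#' Classifies each cluster from the dominant components of its mean
#' displacement (components whose magnitude reaches `dominance` times the
#' largest component):
#' * a dominant *decrease* of an Abeta-to-inhibitory weight means the
#'   excitatory population is **released** from that population's control
#'   (disinhibition);
#' * otherwise a dominant decrease of an inhibitory-to-excitatory weight
#'   (typically with increased Abeta drive to the same excitatory
#'   population) means that population **escapes** intact inhibition;
#' * anything else (including a null displacement) is tagged `mixed`.
#'
#' @param result A [cluster_vectors()] result.
#' @param circuit The [circuit_spec()] the displacements live on.
#' @param dominance Fraction of the largest component a component must
#'   reach to count as dominant (default 0.5).
#' @return `result` with `mechanism_tags` filled (e.g. `"release(I2)"`,
#'   `"escape(E)"`).
#' @export
tag_mechanisms <- function(result, circuit, dominance = 0.5) {
  stopifnot(inherits(result, "cluster_result"), inherits(circuit, "circuit_spec"))
  conn <- circuit$connections
  tag_one <- function(d) {
    if (max(abs(d)) < 1e-8) return("mixed")
    dom <- abs(d) >= dominance * max(abs(d))
    pops_rel <- character(0); pops_esc <- character(0)
    for (j in which(dom)) {
      cp <- colnames(result$mean_displacements)[j]
      row <- conn[conn$coupling == cp, ]
      tgt_type <- circuit$populations[[row$target]]$type
      if (d[j] < 0 && row$source == "Abeta" && tgt_type == "I")
        pops_rel <- c(pops_rel, row$target)
      if (d[j] < 0 && row$sign < 0)      # inhibitory synapse weakened
        pops_esc <- c(pops_esc, row$target)
    }
    if (length(pops_rel))
      sprintf("release(%s)", paste(sort(unique(pops_rel)), collapse = ","))
    else if (length(pops_esc))
      sprintf("escape(%s)", paste(sort(unique(pops_esc)), collapse = ","))
    else "mixed"
  }
  result$mechanism_tags <- apply(result$mean_displacements, 1L, tag_one)
  result
}
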