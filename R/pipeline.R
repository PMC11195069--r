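#' Run the full allodynia-mechanism analysis for one subcircuit
#'
#' Executes the whole chain: hierarchical seed sample, bounding hypercube,
#' hyperrectangle cover, spatially uniform APS sample, Pearson correlations
#' of the normalised couplings, shortest vectors to the allodynia surface,
#' no-noise epsilon selection, density-based clustering, mechanism tagging,
#' and one representative simulation pair per cluster (the cluster's
#' representative instantiation against its nearest surface point, driven
#' by a noisy Abeta bundle).  All randomness flows from `seed`; a fixed
#' configuration and seed reproduce the run exactly.
#'
#' @param circuit A [circuit_spec()] or its name.
#' @param n_seed Seed-sample size for the hypercube (default 2000).
#' @param n_uniform Uniform APS sample size (defaults: 5000 simple, 2000
#'   static, 2000 dynamic).
#' @param n_starts Multi-start count for the shortest-path solver.
#' @param min_pts Density-clustering neighbourhood size.
#' @param seed Integer seed for the whole run.
#' @param depth,probes Cover construction controls (see [build_cover()]).
#' @param n_grid Rate-grid resolution of feasibility checks.
#' @param simulate_clusters Run the per-cluster representative simulations.
#' @param sim_dt Time step of those simulations (s).
#' @param out_dir Optional directory; when given, all artifacts are written
#'   there (CSV/JSON) together with a run manifest.
#' @return Object of class `allodynia_pipeline`: list with fields
#'   `circuit`, `sample` (raw), `normalized`, `cube`, `cover`,
#'   `correlations`, `paths`, `epsilon`, `clusters`, `representatives`,
#'   `config`.
#' @export
run_pipeline <- function(circuit, n_seed = 2000, n_uniform = NULL,
                         n_starts = 20, min_pts = 5, seed = 1,
                         depth = NULL, probes = 64, n_grid = 201,
                         simulate_clusters = TRUE, sim_dt = 1e-3,
                         out_dir = NULL) {
  if (is.character(circuit)) circuit <- circuit_spec(circuit)
  stopifnot(inherits(circuit, "circuit_spec"))
  if (is.null(n_uniform))
    n_uniform <- switch(circuit$name, simple = 5000, static = 2000, dynamic = 2000)
  if (is.null(depth)) depth <- min(3 * length(circuit$coupling_names), 16L)
  cfg <- list(circuit = circuit$name, n_seed = n_seed, n_uniform = n_uniform,
              n_starts = n_starts, min_pts = min_pts, seed = seed,
              depth = depth, probes = probes, n_grid = n_grid,
              sim_dt = sim_dt)
  res <- local_seed(seed, {
    seedS <- hierarchical_seed_sample(circuit, n_seed, n_grid = n_grid)
    cube <- build_hypercube(seedS)
    cover <- build_cover(circuit, cube, seedS, depth = depth, probes = probes,
                         n_grid = n_grid)
    us <- sample_uniform(circuit, cover, n_uniform, n_grid = n_grid)
    corr <- stats::cor(us$normalized)
    paths <- shortest_vectors(circuit, us$raw, cube, n_starts = n_starts)
    ok <- paths$converged
    eps <- select_epsilon(paths$displacement[ok, , drop = FALSE], min_pts)
    clusters <- cluster_vectors(paths$displacement[ok, , drop = FALSE], eps,
                                min_pts, distance = paths$distance[ok])
    clusters <- tag_mechanisms(clusters, circuit)
    reps <- if (simulate_clusters)
      cluster_representatives(circuit, cube, us, paths, clusters, sim_dt)
    else NULL
    list(sample = us$raw, normalized = us$normalized, cube = cube,
         cover = cover, acceptance_rate = us$acceptance_rate,
         correlations = corr, paths = paths, epsilon = eps,
         clusters = clusters, representatives = reps)
  })
  res <- structure(c(list(circuit = circuit), res, list(config = cfg)),
                   class = "allodynia_pipeline")
  if (!is.null(out_dir)) write_pipeline_artifacts(res, out_dir)
  res
}

#' @export
print.allodynia_pipeline <- function(x, ...) {
  cat(sprintf("<allodynia_pipeline> %s circuit, %d uniform APS points (seed %d)\n",
              x$circuit$name, nrow(x$sample), x$config$seed))
  print(x$clusters)
  invisible(x)
}

## representative instantiation per cluster: cluster mean if it is in the
## APS, otherwise the medoid (needed for spatially disjoint clusters);
## simulated against its nearest surface point under a noisy Abeta bundle
cluster_representatives <- function(circuit, cube, us, paths, clusters,
                                    sim_dt = 1e-3) {
  ok <- which(paths$converged)
  lapply(seq_along(clusters$fractions), function(cl) {
    idx <- ok[clusters$labels == cl]
    gm <- colMeans(us$raw[idx, , drop = FALSE])
    kind <- "mean"
    if (!aps_feasible(circuit, gm)) {
      Xn <- us$normalized[idx, , drop = FALSE]
      dm <- as.matrix(stats::dist(Xn))
      gm <- us$raw[idx[which.min(rowSums(dm))], ]
      kind <- "medoid"
    }
    rec <- sp_solve(circuit, cube, gm, n_starts = 10)
    g_surface <- denormalize_coupling(cube, rec$target)
    g_surface[g_surface < 0] <- 0
    f_drive <- max(rec$f_nearest, circuit$input_rate_range[1])
    proto <- stimulus_protocol(stimulus_rate = f_drive)
    trace <- generate_abeta_trace(proto, dt = sim_dt)
    sim_source <- simulate_circuit(circuit, gm, trace, dt = sim_dt)
    sim_surface <- simulate_circuit(circuit, g_surface, trace, dt = sim_dt)
    list(cluster = cl, representative = gm, kind = kind,
         surface_point = g_surface, f_drive = f_drive,
         sim_source = sim_source, sim_surface = sim_surface)
  })
}

## write the artifact bundle of a pipeline run
write_pipeline_artifacts <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  nm <- colnames(res$sample)
  samp <- cbind(as.data.frame(res$sample),
                stats::setNames(as.data.frame(res$normalized),
                                paste0("norm_", nm)))
  utils::write.csv(samp, file.path(out_dir, "aps_sample.csv"), row.names = FALSE)
  jsonlite::write_json(list(lo = as.list(res$cube$lo), hi = as.list(res$cube$hi)),
                       file.path(out_dir, "hypercube.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(list(lo = res$cover$lo, hi = res$cover$hi,
                            volume = res$cover$volume),
                       file.path(out_dir, "cover.json"), digits = NA)
  pdf_ <- as.data.frame(res$paths)
  pdf_$cluster <- NA_integer_
  pdf_$cluster[res$paths$converged] <- res$clusters$labels
  utils::write.csv(pdf_, file.path(out_dir, "paths.csv"), row.names = FALSE)
  cl <- res$clusters
  utils::write.csv(
    data.frame(cluster = seq_along(cl$fractions),
               fraction = cl$fractions,
               mean_distance = cl$mean_distance,
               mechanism = cl$mechanism_tags,
               cl$mean_displacements),
    file.path(out_dir, "clusters.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(circuit = res$circuit$name,
         epsilon = cl$epsilon, min_pts = cl$min_pts,
         fractions = cl$fractions, mechanisms = cl$mechanism_tags,
         acceptance_rate = res$acceptance_rate,
         correlations = res$correlations),
    file.path(out_dir, "summary.json"), digits = NA)
  if (!is.null(res$representatives)) {
    tdir <- file.path(out_dir, "trajectories")
    dir.create(tdir, showWarnings = FALSE)
    for (r in res$representatives) {
      utils::write.csv(as.data.frame(r$sim_source),
                       file.path(tdir, sprintf("cluster%d_source.csv", r$cluster)),
                       row.names = FALSE)
      utils::write.csv(as.data.frame(r$sim_surface),
                       file.path(tdir, sprintf("cluster%d_surface.csv", r$cluster)),
                       row.names = FALSE)
    }
  }
  jsonlite::write_json(
    c(res$config, list(package_version = as.character(utils::packageVersion("dorsalhorn")),
                       r_version = R.version.string,
                       timestamp = format(Sys.time(), tz = "UTC"))),
    file.path(out_dir, "manifest.json"), auto_unbox = TRUE)
  invisible(out_dir)
}
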