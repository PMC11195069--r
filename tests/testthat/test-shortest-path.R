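test_that("a point already on the surface projects onto itself", {
  fx <- simple_aps()
  g <- fx$us$raw[3, ]
  h <- surface_height(fx$cs, g[c("gAbI", "gIE")])
  g["gAbE"] <- h$height
  rec <- nearest_surface_point(fx$cs, fx$cube, g, n_starts = 6, seed = 1)
  expect_true(rec$converged)
  expect_lt(rec$distance, 1e-4)
  expect_lt(max(abs(rec$displacement)), 1e-4)
})

test_that("converged targets satisfy the surface equality", {
  fx <- simple_aps()
  sp <- simple_paths()
  expect_true(all(sp$converged))
  expect_equal(sp$distance,
               sqrt(rowSums(sp$displacement^2)), tolerance = 1e-9)
  for (i in seq(1, 150, by = 10)) {
    g_t <- denormalize_coupling(fx$cube, sp$target[i, ])
    h <- surface_height(fx$cs, g_t[c("gAbI", "gIE")])
    expect_lt(abs(g_t[["gAbE"]] - h$height), 1e-8)
    expect_lt(abs(sp$f_nearest[i] - h$f_star), 0.3)
  }
  # sources strictly below the surface: positive distances
  expect_true(all(sp$distance > 0))
})

test_that("relaxed-problem distances match a 3-D surface-grid oracle", {
  fx <- simple_aps()
  sp <- simple_paths()
  cube <- fx$cube
  # parameterise the surface by (gAbI, gIE) on a grid and take the nearest
  # grid node as an independent upper bound with known resolution
  n1 <- 60; n2 <- 60
  ga <- seq(cube$lo[["gAbI"]] - 0.3 * cube$range[["gAbI"]],
            cube$hi[["gAbI"]] + 0.3 * cube$range[["gAbI"]], length.out = n1)
  gi <- seq(max(cube$lo[["gIE"]] - 0.3 * cube$range[["gIE"]], 0),
            cube$hi[["gIE"]] + 0.3 * cube$range[["gIE"]], length.out = n2)
  grid <- expand.grid(gAbI = ga, gIE = gi)
  hts <- vapply(seq_len(nrow(grid)), function(j)
    surface_height(fx$cs, c(gAbI = grid$gAbI[j], gIE = grid$gIE[j]))$height,
    numeric(1))
  Sn <- cbind((grid$gAbI - cube$lo[["gAbI"]]) / cube$range[["gAbI"]],
              (grid$gIE - cube$lo[["gIE"]]) / cube$range[["gIE"]],
              (hts - cube$lo[["gAbE"]]) / cube$range[["gAbE"]])
  res <- max(diff(ga)[1] / cube$range[["gAbI"]],
             diff(gi)[1] / cube$range[["gIE"]])
  for (i in seq(1, 100, by = 4)) {
    p <- sp$source[i, ]
    oracle <- sqrt(min((Sn[, 1] - p[1])^2 + (Sn[, 2] - p[2])^2 +
                         (Sn[, 3] - p[3])^2))
    expect_lte(sp$distance[i], oracle + 1e-9)        # solver at least as good
    expect_gte(sp$distance[i], oracle * 0.98 - res)  # and not spuriously short
  }
})

test_that("more starts never lengthen the path", {
  fx <- simple_aps()
  for (i in c(2, 20, 40)) {
    d1 <- nearest_surface_point(fx$cs, fx$cube, fx$us$raw[i, ],
                                n_starts = 1, seed = 5)$distance
    d8 <- nearest_surface_point(fx$cs, fx$cube, fx$us$raw[i, ],
                                n_starts = 8, seed = 5)$distance
    expect_lte(d8, d1 + 1e-10)
  }
})

test_that("each distance undercuts random points drawn on the surface", {
  fx <- simple_aps()
  sp <- simple_paths()
  set.seed(13)
  n_surf <- 500
  gs <- cbind(gAbI = runif(n_surf, fx$cube$lo[["gAbI"]], fx$cube$hi[["gAbI"]]),
              gIE = runif(n_surf, fx$cube$lo[["gIE"]], fx$cube$hi[["gIE"]]))
  hs <- vapply(seq_len(n_surf), function(j)
    surface_height(fx$cs, gs[j, ])$height, numeric(1))
  Sn <- normalize_coupling(fx$cube, cbind(gs, gAbE = hs))
  for (i in seq(1, 150, by = 15)) {
    p <- sp$source[i, ]
    ub <- sqrt(min(rowSums(sweep(Sn, 2, p)^2)))
    expect_lte(sp$distance[i], ub + 1e-9)
  }
})
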