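test_that("the hypercube bounds and normalisation behave as an inverse pair", {
  fx <- simple_aps()
  S <- fx$seed_sample
  cube <- fx$cube
  Sn <- normalize_coupling(cube, S)
  expect_true(all(Sn >= 0 & Sn <= 1))
  expect_equal(apply(Sn, 2, min), setNames(rep(0, 3), colnames(S)))
  expect_equal(apply(Sn, 2, max), setNames(rep(1, 3), colnames(S)))
  expect_equal(denormalize_coupling(cube, Sn), S, tolerance = 1e-12)
  expect_error(build_hypercube(S[1, , drop = FALSE]), "degenerate")
})

test_that("seed-sample extremes approach the analytic caps", {
  fx <- simple_aps()
  expect_gt(max(fx$seed_sample[, "gAbI"]), 7.08 - 0.15)
  expect_lt(max(fx$seed_sample[, "gAbI"]), 7.08 + 1e-9)
  expect_gt(min(fx$seed_sample[, "gAbI"]), 2.07 - 1e-9)
})

test_that("the cover contains every seed point in disjoint boxes", {
  fx <- simple_aps()
  cov <- fx$cover
  Sn <- normalize_coupling(fx$cube, fx$seed_sample)
  in_box_count <- function(x) {
    sum(vapply(seq_len(nrow(cov$lo)), function(b)
      all(x >= cov$lo[b, ] - 1e-12) && all(x <= cov$hi[b, ] + 1e-12),
      logical(1)))
  }
  counts <- vapply(seq_len(200), function(i) in_box_count(Sn[i, ]), numeric(1))
  expect_true(all(counts >= 1))          # containment
  # interior points (off box faces) lie in exactly one box: disjointness
  set.seed(9)
  U <- matrix(runif(300), 100, 3)
  cu <- vapply(seq_len(100), function(i) in_box_count(U[i, ]), numeric(1))
  expect_true(all(cu <= 1))
})

test_that("every uniform point is APS-feasible and the pipeline is seed-deterministic", {
  fx <- simple_aps()
  expect_true(all(aps_feasible(fx$cs, fx$us$raw)))
  us2 <- sample_uniform(fx$cs, fx$cover, 100, seed = 103)
  expect_identical(us2$raw[1:100, ], fx$us$raw[1:100, ])
  S2 <- hierarchical_seed_sample(fx$cs, 50, seed = 101)
  expect_identical(S2, fx$seed_sample[1:50, ])
})

test_that("cover-based sampling beats and matches plain rejection", {
  fx <- simple_aps()
  # plain rejection from the bounding hypercube
  set.seed(77)
  n_prop <- 40000
  U <- matrix(runif(n_prop * 3), n_prop, 3)
  raw <- denormalize_coupling(fx$cube, U)
  ok <- aps_feasible(fx$cs, raw)
  rej <- U[ok, , drop = FALSE]
  # acceptance rate of the cover sampler is at least plain rejection's
  expect_gt(fx$us$acceptance_rate, mean(ok))
  # distributional match: chi-square on a 3x3x3 partition of the unit cube
  bin <- function(X) {
    idx <- pmin(floor(X * 3), 2)
    factor(idx[, 1] * 9 + idx[, 2] * 3 + idx[, 3], levels = 0:26)
  }
  tab <- rbind(table(bin(fx$us$normalized)), table(bin(rej)))
  keep <- colSums(tab) > 0
  p <- suppressWarnings(chisq.test(tab[, keep]))$p.value
  expect_gt(p, 0.01)
})

test_that("static and dynamic uniform samples stay feasible", {
  fs <- static_aps()
  expect_true(all(aps_feasible(fs$cs, fs$us$raw)))
  fd <- dynamic_aps()
  expect_true(all(aps_feasible(fd$cs, fd$us$raw)))
})
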