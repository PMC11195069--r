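make_bundles <- function(seed = 1, n = 50, gap = 1, spread = 0.02) {
  set.seed(seed)
  rbind(matrix(rnorm(n * 3, 0, spread), n, 3),
        sweep(matrix(rnorm(n * 3, 0, spread), n, 3), 2, c(gap, 0, 0), "+"))
}

test_that("two well-separated bundles split at an epsilon below their gap", {
  x <- make_bundles()
  eps <- select_epsilon(x, min_pts = 5)
  expect_lt(eps, 1)                        # below the inter-bundle gap
  cl <- cluster_vectors(x, eps, 5)
  expect_length(cl$fractions, 2)
  expect_equal(cl$fractions, c(0.5, 0.5))
  expect_equal(sum(cl$fractions), 1)
  expect_true(all(cl$labels > 0))
})

test_that("degenerate inputs are handled", {
  x <- matrix(1, 20, 3)                    # identical vectors
  eps <- select_epsilon(x, 5)
  cl <- cluster_vectors(x, eps, 5)
  expect_length(cl$fractions, 1)
  expect_error(select_epsilon(matrix(0, 3, 2), min_pts = 5), "min_pts")
  # noise at a too-small epsilon violates the contract
  y <- make_bundles(n = 30)
  expect_error(cluster_vectors(y, 1e-6, 5), "noise")
})

test_that("density clustering attaches border points and is order-deterministic", {
  # a line of core points plus one border point reachable from the end
  x <- cbind(c(seq(0, 0.5, by = 0.05), 0.62), 0)
  lab <- dbscan_labels(x, eps = 0.12, min_pts = 3)
  expect_true(all(lab == 1))
  lab2 <- dbscan_labels(x, eps = 0.02, min_pts = 3)
  expect_true(all(lab2 == 0))              # all noise when radius too small
  expect_identical(dbscan_labels(x, 0.12, 3), dbscan_labels(x, 0.12, 3))
})

test_that("mechanism tagging names release and escape correctly", {
  cs <- circuit_spec("simple")
  mk <- function(center) sweep(matrix(rnorm(90, 0, 0.01), 30, 3), 2, center, "+")
  # bundle 1: dominant decrease of the Abeta->I drive (release);
  # bundle 2: decreased I->E with increased Abeta->E (escape)
  x <- rbind(mk(c(-0.3, 0, 0.05)), mk(c(0, -0.3, 0.2)))
  colnames(x) <- cs$coupling_names
  eps <- select_epsilon(x, 5)
  cl <- tag_mechanisms(cluster_vectors(x, eps, 5), cs)
  expect_setequal(cl$mechanism_tags, c("release(I)", "escape(E)"))
  # a null displacement is mixed
  z <- matrix(rnorm(60, 0, 1e-12), 20, 3,
              dimnames = list(NULL, cs$coupling_names))
  clz <- tag_mechanisms(cluster_vectors(z, select_epsilon(z, 5), 5), cs)
  expect_equal(clz$mechanism_tags[[1]], "mixed")
  # tags only ever name populations of the circuit
  expect_true(all(grepl("^(release|escape)\\((I|E)(,(I|E))*\\)$|^mixed$",
                        cl$mechanism_tags)))
})

test_that("clusters are numbered by share with distance tie-breaks", {
  x <- rbind(make_bundles(seed = 2, n = 80, gap = 2)[1:80, ],
             make_bundles(seed = 3, n = 20, gap = 2)[21:40, ])
  eps <- select_epsilon(x, 5)
  cl <- cluster_vectors(x, eps, 5, distance = rep(1, 100))
  expect_true(all(diff(cl$fractions) <= 0))
  expect_equal(cl$fractions[1], max(cl$fractions))
})
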