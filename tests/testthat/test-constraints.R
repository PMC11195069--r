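test_that("inhibitory_rate matches the steady-state composition", {
  ip <- inhibitory_params()
  # drive placing the voltage at half-activation: half the maximum rate
  g_half <- (ip$beta - ip$v_rest) / 15
  expect_equal(inhibitory_rate(15, g_half, ip), 40, tolerance = 1e-12)
  # zero drive: activation at rest
  expect_equal(inhibitory_rate(12, 0, ip), activation_rate(-60, ip))
  # the box-bound drive 20.7/10 puts V at threshold when f = 10
  expect_equal(inhibitory_rate(10, 2.07, ip), activation_rate(ip$v_thr, ip),
               tolerance = 1e-12)
  # monotone in both arguments
  f <- seq(10, 20, by = 0.5)
  expect_true(all(diff(inhibitory_rate(f, 3, ip)) > 0))
  expect_true(all(inhibitory_rate(f, 3.5, ip) > inhibitory_rate(f, 3, ip)))
})

test_that("the Abeta->I box bounds are reproduced", {
  cs <- circuit_spec("simple")
  iv <- coupling_bounds(cs, numeric(0))
  expect_equal(iv, c(2.07, 7.08), tolerance = 1e-12)
  st <- circuit_spec("static")
  expect_equal(coupling_bounds(st, numeric(0)), c(2.07, 7.08), tolerance = 1e-12)
})

test_that("clear violations are named in the constraint report", {
  cs <- circuit_spec("simple")
  r0 <- is_in_aps(cs, c(gAbI = 0, gIE = 0, gAbE = 0))
  expect_false(r0$feasible)
  expect_true("I_fires" %in% r0$violations$constraint)
  r1 <- is_in_aps(cs, c(gAbI = 2.0, gIE = 1.4, gAbE = 4.5))
  expect_false(r1$feasible)
  expect_true("I_fires" %in% r1$violations$constraint)
  # a known-good interior point
  r2 <- is_in_aps(cs, c(gAbI = 4, gIE = 1.2, gAbE = 4.2))
  expect_true(r2$feasible)
  expect_equal(nrow(r2$violations), 0)
})

test_that("is_in_aps and the batch checker agree", {
  cs <- circuit_spec("simple")
  set.seed(5)
  G <- cbind(gAbI = runif(200, 1.8, 7.5), gIE = runif(200, 0.5, 2.5),
             gAbE = runif(200, 3, 7.5))
  batch <- aps_feasible(cs, G)
  single <- vapply(seq_len(nrow(G)), function(i)
    is_in_aps(cs, G[i, ])$feasible, logical(1))
  # is_in_aps adds Lambert candidates, so it can only be stricter
  expect_true(all(single[batch] | !batch[single]))
  expect_gt(mean(batch == single), 0.99)
  expect_gt(sum(batch), 5)   # the box contains feasible points
})

test_that("hierarchical sampling lands inside the APS for every circuit", {
  expect_true(all(aps_feasible(circuit_spec("simple"), simple_aps()$seed_sample)))
  expect_true(all(aps_feasible(circuit_spec("static"), static_aps()$seed_sample)))
  expect_true(all(aps_feasible(circuit_spec("dynamic"), dynamic_aps()$seed_sample)))
  # and is_in_aps (with candidate refinement) agrees on a subset
  fx <- simple_aps()
  sub <- fx$seed_sample[seq(1, 900, by = 90), ]
  expect_true(all(vapply(seq_len(nrow(sub)), function(i)
    is_in_aps(fx$cs, sub[i, ])$feasible, logical(1))))
})

test_that("interval endpoints separate feasible from infeasible points", {
  cs <- circuit_spec("simple")
  partial <- c(gAbI = 3.2)
  ivIE <- coupling_bounds(cs, partial)
  g2 <- mean(ivIE)
  ivE <- coupling_bounds(cs, c(partial, gIE = g2))
  mid <- mean(ivE)
  expect_true(aps_feasible(cs, c(partial, gIE = g2, gAbE = mid)))
  expect_false(aps_feasible(cs, c(partial, gIE = g2, gAbE = ivE[2] + 1e-4)))
  expect_false(aps_feasible(cs, c(partial, gIE = g2, gAbE = ivE[1] - 1e-4)))
})

test_that("constraint tables export as JSON", {
  txt <- constraint_table_json(circuit_spec("static"))
  parsed <- jsonlite::fromJSON(txt)
  expect_equal(nrow(parsed), 10)
  expect_true("pain_inhibition" %in% parsed$constraint)
})
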