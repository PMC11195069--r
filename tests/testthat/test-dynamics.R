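test_that("steady-state voltages match the closed forms", {
  cs <- circuit_spec("simple")
  g <- coupling_vector(cs, c(gAbI = 3, gIE = 1.5, gAbE = 4.5))
  vss <- steady_state_voltages(cs, g, f_ab = 15)
  expect_equal(vss[["I"]], -60 + 3 * 15)                 # linear in the drive
  fI <- fI_oracle(3, 15)
  expect_equal(vss[["E"]], -60 + 4.5 * 15 - 1.5 * fI, tolerance = 1e-12)
  # zero input: I exactly at rest; E a fraction of a mV below it because the
  # activation curve transmits a tiny spontaneous rate at rest
  v0 <- steady_state_voltages(cs, g, 0)
  expect_equal(v0[["I"]], -60)
  expect_equal(v0[["E"]], -60 - 1.5 * activation_rate(-60, inhibitory_params()),
               tolerance = 1e-12)
  expect_lt(abs(v0[["E"]] + 60), 0.5)
  # I ablation removes the inhibitory term
  va <- steady_state_voltages(cs, g, 15, ablate = "I")
  expect_equal(va[["E"]], -60 + 4.5 * 15)
  expect_error(steady_state_voltages(cs, g, 15, ablate = "Z"), "unknown")
})

test_that("steady states cascade correctly through the dynamic circuit", {
  cs <- circuit_spec("dynamic")
  g <- coupling_vector(cs, c(gAbI1 = 3, gI1E1 = 1.4, gAbE1 = 4.8, gE1E2 = 2,
                             gAbI2 = 3.2, gI2E2 = 1.5, gAbE2 = 5))
  f <- 12
  vss <- steady_state_voltages(cs, g, f)
  fI1 <- fI_oracle(3, f)
  ep <- excitatory_params()
  vE1 <- -60 + 4.8 * f - 1.4 * fI1
  expect_equal(vss[["E1"]], vE1, tolerance = 1e-12)
  fE1 <- activation_rate(vE1, ep)
  fI2 <- fI_oracle(3.2, f)
  expect_equal(vss[["E2"]], -60 + 5 * f + 2 * fE1 - 1.5 * fI2, tolerance = 1e-12)
})

test_that("the integrator reaches the closed-form steady state", {
  cs <- circuit_spec("simple")
  g <- coupling_vector(cs, c(gAbI = 3.5, gIE = 1.4, gAbE = 4.6))
  tr <- simulate_circuit(cs, g, input = 15, dt = 1e-3, duration = 1)
  vss <- steady_state_voltages(cs, g, 15)
  expect_lt(abs(tail(tr$voltage[, "I"], 1) - vss[["I"]]), 1e-3)
  expect_lt(abs(tail(tr$voltage[, "E"], 1) - vss[["E"]]), 1e-3)
  # zero input: settles at the zero-input steady state (I exactly at rest)
  tr0 <- simulate_circuit(cs, g, input = 0, dt = 1e-3, duration = 0.3)
  expect_true(all(abs(tr0$voltage[, "I"] + 60) < 1e-12))
  v0 <- steady_state_voltages(cs, g, 0)
  expect_lt(abs(tail(tr0$voltage[, "E"], 1) - v0[["E"]]), 1e-3)
  # rates bounded along a noisy trajectory
  trace <- generate_abeta_trace(stimulus_protocol(), dt = 1e-3, seed = 7)
  trn <- simulate_circuit(cs, g, trace, dt = 1e-3)
  expect_true(all(trn$rate[, "I"] >= 0 & trn$rate[, "I"] <= 80))
  expect_true(all(trn$rate[, "E"] >= 0 & trn$rate[, "E"] <= 50))
})

test_that("the stability guard rejects overly long steps", {
  cs <- circuit_spec("simple")
  g <- coupling_vector(cs, c(gAbI = 3, gIE = 1.5, gAbE = 4.5))
  expect_error(simulate_circuit(cs, g, input = 15, dt = 0.005, duration = 0.1),
               "time constant")
})

test_that("silencing the inhibitory pathway of an APS point produces allodynia", {
  fx <- simple_aps()
  g <- fx$us$raw[1, ]
  g["gIE"] <- 0
  ep <- excitatory_params()
  v <- sapply(seq(10, 20, by = 0.5), function(f)
    steady_state_voltages(fx$cs, g, f)[["E"]])
  expect_true(any(v >= ep$v_thr))
  # and under ablation of I itself
  v2 <- sapply(seq(10, 20, by = 0.5), function(f)
    steady_state_voltages(fx$cs, fx$us$raw[1, ], f, ablate = "I")[["E"]])
  expect_true(any(v2 >= ep$v_thr))
})
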