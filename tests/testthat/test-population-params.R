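test_that("voltage cutoffs follow the slope-based rule", {
  expect_equal(derive_voltage_cutoffs(7.9, -17),
               c(v_min = -111.8, v_thr = -24.9, v_max = 77.8))
  expect_equal(derive_voltage_cutoffs(9.3, -30),
               c(v_min = -141.6, v_thr = -39.3, v_max = 81.6))
  expect_equal(derive_voltage_cutoffs(1, 0),
               c(v_min = -12, v_thr = -1, v_max = 12))
  expect_error(derive_voltage_cutoffs(0, -17), "positive")
  expect_error(derive_voltage_cutoffs(-1, -17), "positive")
})

test_that("standard population parameters carry consistent cutoffs", {
  for (p in list(inhibitory_params(), excitatory_params())) {
    expect_lt(p$v_min, p$v_rest)
    expect_lt(p$v_rest, p$v_thr)
    expect_lt(p$v_thr, p$v_max)
    expect_equal(p$v_thr, p$beta - p$alpha, tolerance = 1e-12)
    expect_equal(p$v_max, p$beta + 12 * p$alpha, tolerance = 1e-12)
    expect_equal(p$v_min, p$beta - 12 * p$alpha, tolerance = 1e-12)
  }
  expect_equal(inhibitory_params()$m_max, 80)
  expect_equal(excitatory_params()$m_max, 50)
  expect_error(population_params(7.9, -17, -50, -60, 0.01), "m_max")
})

test_that("activation function is a bounded increasing sigmoid", {
  ip <- inhibitory_params()
  ep <- excitatory_params()
  expect_equal(activation_rate(ip$beta, ip), 40)           # half-activation
  expect_equal(activation_rate(1e4, ep), 50, tolerance = 1e-9)  # saturates at m_max
  # closed form at the firing threshold (beta - alpha)
  expect_equal(activation_rate(ip$v_thr, ip), 40 * (1 + tanh(-1)),
               tolerance = 1e-12)
  v <- seq(-150, 80, by = 0.5)
  r <- activation_rate(v, ip)
  expect_true(all(r >= 0 & r <= ip$m_max))
  expect_true(all(diff(r) > 0))
  expect_error(activation_rate(NaN, ip), "finite")
  expect_error(activation_rate(Inf, ip), "finite")
})
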