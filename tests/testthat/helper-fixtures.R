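# Shared, lazily computed fixtures.  Heavy artefacts (APS samples, shortest
# paths) are built once per test run and reused across files.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- force(expr)
  .fixtures[[name]]
}

# simple circuit: seed sample, hypercube, cover, 800 uniform points
simple_aps <- function() fixture("simple_aps", {
  cs <- circuit_spec("simple")
  S <- hierarchical_seed_sample(cs, 1000, seed = 101)
  cube <- build_hypercube(S)
  cover <- build_cover(cs, cube, S, seed = 102)
  us <- sample_uniform(cs, cover, 800, seed = 103)
  list(cs = cs, seed_sample = S, cube = cube, cover = cover, us = us)
})

# shortest paths for a 150-point subset of the simple uniform sample
simple_paths <- function() fixture("simple_paths", {
  fx <- simple_aps()
  sp <- shortest_vectors(fx$cs, fx$us$raw[1:150, ], fx$cube,
                         n_starts = 10, seed = 104)
  sp
})

# static circuit small APS fixture
static_aps <- function() fixture("static_aps", {
  cs <- circuit_spec("static")
  S <- hierarchical_seed_sample(cs, 700, seed = 111)
  cube <- build_hypercube(S)
  cover <- build_cover(cs, cube, S, seed = 112)
  us <- sample_uniform(cs, cover, 200, seed = 113)
  list(cs = cs, seed_sample = S, cube = cube, cover = cover, us = us)
})

# dynamic circuit small APS fixture
dynamic_aps <- function() fixture("dynamic_aps", {
  cs <- circuit_spec("dynamic")
  S <- hierarchical_seed_sample(cs, 700, seed = 121)
  cube <- build_hypercube(S)
  cover <- build_cover(cs, cube, S, seed = 122)
  us <- sample_uniform(cs, cover, 200, seed = 123)
  list(cs = cs, seed_sample = S, cube = cube, cover = cover, us = us)
})

# steady-state inhibitory rate helper used by oracles
fI_oracle <- function(g_in, f) {
  p <- inhibitory_params()
  0.5 * p$m_max * (1 + tanh((p$v_rest + g_in * f - p$beta) / p$alpha))
}
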