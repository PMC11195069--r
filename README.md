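# dorsalhorn

Mechanisms of excitatory–inhibitory (E–I) dysregulation in dorsal-horn
pain-processing subcircuits.

## The problem

Allodynia — pain evoked by normally innocuous touch — is thought to arise
when the balance between excitation and inhibition in laminae I–II of the
spinal dorsal horn is disrupted, so that Aβ-fibre input (light touch) can
drive the excitatory interneurons that feed projection neurons.  Because
E–I balance can be achieved by many different combinations of synaptic
strengths, the *way* it breaks can differ from individual to individual.

`dorsalhorn` implements firing-rate population models of three feedforward
subcircuit motifs — the canonical gate-control unit (I → E), the static
allodynia motif (I1, I2 → E) and the dynamic allodynia motif
(I1 → E1 → E2 ← I2) — and the analysis pipeline that turns them into
testable hypotheses about allodynia mechanisms:

1. **Allowable parameter space (APS).**  Each population obeys
   `τ dV/dt = V_rest − V + Σ g·f`, with rates
   `f(V) = 0.5·m·(1 + tanh((V − β)/α))`.  Requiring healthy behaviour —
   inhibitory populations fire, the output population stays gated below
   rest (pain inhibition), voltages stay in bounds, and ablating any
   inhibitory population produces allodynia — for every non-painful Aβ
   rate `f ∈ [10, 20]` Hz yields a hierarchical system of inequalities on
   the coupling strengths `g` (mV/Hz).  The embedded extremisations over
   `f` are solved with Lambert-W closed forms where available and a
   refined grid elsewhere.
2. **Uniform sampling.**  The APS is non-convex and occupies a tiny
   fraction of its bounding box (≈3·10⁻⁵ for the static motif), so points
   are drawn uniformly via a disjoint hyperrectangle cover built by
   recursive bisection.
3. **Allodynia surface.**  `S = {g : g_out = min_f [ (V_thr − V_rest) +
   inhibition − upstream excitation ] / f}` separates coupling vectors
   that can produce allodynia from those that cannot.
4. **Shortest paths.**  For every sampled point, the minimal
   normalised-coordinate change reaching `S` is found by solving the
   relaxed problem over (couplings, input rate) with multi-start L-BFGS-B.
5. **Mechanism clustering.**  Displacement vectors are clustered with
   density-based scanning (minPts = 5, smallest no-noise ε) and tagged as
   **release** (disinhibition: reduced Aβ→I drive) or **escape** (reduced
   I→E efficacy with increased Aβ→E drive).

## Worked example

```r
library(dorsalhorn)

pp <- run_pipeline("simple", n_seed = 1000, n_uniform = 1000,
                   n_starts = 10, seed = 1, simulate_clusters = FALSE)
pp
#> <allodynia_pipeline> simple circuit, 1000 uniform APS points (seed 1)
#> <cluster_result> 2 clusters (eps = 0.01751, minPts = 5)
#>   cluster 1: 54.7% [release(I)], mean displacement: gAbI -0.25, gIE -0.03, gAbE +0.07
#>   cluster 2: 45.3% [escape(E)], mean displacement: gAbI -0.00, gIE -0.29, gAbE +0.21

round(apply(pp$sample, 2, range), 2)
#>      gAbI  gIE gAbE
#> [1,] 2.64 0.90 3.51
#> [2,] 7.07 1.97 6.87
```

Reading the output: about half of the healthy gate-control circuits are
most easily pushed into allodynia by *release* — lowering the Aβ drive to
the inhibitory population (`gAbI` falls by ~25% of its healthy range) —
and the other half by *escape* — weakening the inhibitory synapse while
strengthening the direct Aβ drive to E (~29% drop in `gIE`, ~21% rise in
`gAbE`).  The coupling ranges of the sample (2.6–7.1, 0.9–2.0 and
3.5–6.9 mV/Hz) delimit the healthy parameter space itself.

`run_pipeline("static", ...)` and `run_pipeline("dynamic", ...)` run the
same analysis for the five- and seven-coupling motifs; passing
`out_dir = "..."` writes `aps_sample.csv`, `paths.csv`, `clusters.csv`,
`hypercube.json`, `summary.json`, per-cluster trajectory CSVs and a run
manifest.  A thin command-line wrapper is available at
`inst/scripts/dorsalhorn-cli.R`.

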