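---
title: "Firing-rate models of dorsal-horn subcircuits and the geometry of allodynia"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Firing-rate models of dorsal-horn subcircuits and the geometry of allodynia}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`dorsalhorn` asks a geometric question about pain processing: among all the
ways a dorsal-horn subcircuit can balance excitation and inhibition while
behaving healthily, which *small* change of synaptic strengths is most
likely to tip it into allodynia — pain evoked by innocuous touch?  This
vignette records the model, every tunable that matters, the algorithms, the
numerical choices, and what the package's tests do and do not establish.

## The population model

Each neural population `x` is described by its average membrane voltage
`V_x` (mV) and average firing rate `f_x` (Hz):

* voltage dynamics: `tau_x dV_x/dt = V_{x,rest} - V_x + sum_y g_yx f_y`,
  where the sum runs over presynaptic populations and the Abeta input, with
  coupling strengths `g_yx` in mV/Hz (inhibitory terms enter negatively);
* rate readout: `f_x = 0.5 m_x (1 + tanh((V_x - beta_x)/alpha_x))`.

Fixed population parameters (from fits to rodent dorsal-horn frequency–
voltage data): inhibitory `alpha = 9.3` mV, `beta = -30` mV, `m = 80` Hz,
`tau = 20` ms; excitatory `alpha = 7.9` mV, `beta = -17` mV, `m = 50` Hz,
`tau = 10` ms; both rest at `-60` mV.  Voltage cutoffs are tied to the
activation curve — `V_thr = beta - alpha`, `V_{min,max} = beta ∓ 12 alpha`
— so that both population types respond similarly to proportional input
changes (`derive_voltage_cutoffs()`).

Three feedforward motifs are hand-encoded (`circuit_spec()`): *simple*
(I gates E; couplings `gAbI, gIE, gAbE`), *static* (I1 and I2 gate E;
5 couplings) and *dynamic* (I1 gates E1, which excites E2, gated by I2;
7 couplings).  Every population receives the Abeta input; the output
population (E or E2) stands in for the drive onto projection neurons.

Because the motifs are acyclic, steady states are evaluated by closed-form
feedforward substitution (`steady_state_voltages()`), never by long
simulation.  Time-resolved responses use fixed-step RK4
(`simulate_circuit()`, default `dt = 1e-4` s, well below `tau_E = 0.01` s;
a guard rejects `dt >= min(tau)/2`).  The dynamics are linear in `V` with
smooth input, so a stiff solver would be overkill; the closed-form steady
state serves as the integrator's oracle in the tests.  Voltages are *not*
clipped to `[V_min, V_max]` during integration — the bounds are
steady-state constraints defining healthy behaviour, not dynamics.

Ablation of a population zeroes its output rate but leaves its own dynamics
intact, mirroring how the condition tables delete terms from the
steady-state inequalities.

One modelling subtlety: the sigmoid transmits a tiny spontaneous rate at
rest (`f_I(-60 mV) ≈ 0.13` Hz), so with zero input an inhibited population
settles a fraction of a millivolt below rest.  The package treats this as
part of the model rather than subtracting a baseline.

## The Abeta input

`generate_abeta_trace()` models a bundle of 300 independent Poisson-spiking
Abeta fibres, each firing at 1 Hz outside the stimulus window (0.2–0.7 s by
default) and at the stimulus rate (10–20 Hz, the non-painful range observed
in slowly adapting mechanoreceptors) inside it.  Counts are drawn per bin
for the whole bundle — the superposition of independent Poisson processes
is Poisson — and converted to an across-fibre average rate.  The rate
estimation bin is a free parameter of the conversion; the default 5 ms
smooths single-spike granularity while keeping the onset sharp.  Traces are
non-negative, have the piecewise-constant profile as expectation, per-bin
variance `rate/(n_fibers · bin_width)`, and are bit-reproducible under a
fixed seed.

## The allowable parameter space

Healthy behaviour is encoded as steady-state inequalities that must hold
for *every* constant Abeta rate in `[10, 20]` Hz: inhibitory populations
fire (`V >= V_thr`) without exceeding `V_max`; the output population is
gated below rest (pain inhibition) but not below `V_min`; and ablating any
single inhibitory population lets the output population fire (this is what
makes ablation experiments reproduce allodynia) while staying below
`V_max`.  Rewritten in the couplings, these form a hierarchy: box bounds
on the Abeta→I weights, e.g. `(V_thr - V_rest)/f_min = 2.07 <= gAbI <=
(V_max - V_rest)/f_max = 7.08` mV/Hz, then interval bounds for each further
coupling given the ones before it (`coupling_bounds()`).

The nonlinear rows are extremisations of ratios like
`min_f gIE f_I(f)/f`.  Two Lambert-W families solve the embedded
stationarity conditions in closed form: for `(a·tanh(x-b)+c)/x` (with
`x = gAbI f/alpha_I`) the critical points are
`x = (c/a - W_{0,-1}(-e^{1-2b}))/2`, and for the reciprocal family
`(g f + C)/f_I(f)` they are `x = (1 - 2A - W_{0,-1}(-e^{1-2A-2b}))/2` with
`A = C·gAbI/(g·alpha_I)`.  `extremize_over_fab()` combines these candidates
with a 1001-point grid and golden-section refinement; a property test holds
it to within 1e-6 relative error of a 10^4-point scan over 1000 random
coupling draws.  For valid population parameters `b = (beta - V_rest)/alpha
> 1`, so the Lambert arguments always lie inside the branch domains; the
domain guard exists for robustness only.

Stages without closed forms use a structural fact: given the Abeta→I
weights, every constraint is affine in the remaining couplings, so the set
of values of one coupling for which the downstream intervals are non-empty
is itself an interval.  Those conditional intervals are found by vectorised
scanning with edge refinement (static `gAbE`/`gI1E`, dynamic
`gE1E2`/`gI2E2`).  A coarse-grid pre-screen (a relaxation, hence a sound
rejection test) makes the many failing draws cheap.

`is_in_aps()` checks all inequalities on a 201-point rate grid augmented
with the Lambert candidates and reports the worst margin per constraint in
mV.  The grid is dense relative to the curvature of the constraint
functions (at most two interior extrema); margins are accurate to well
below the tolerances used anywhere downstream.

## Uniform sampling

The APS is non-convex, and it is *small*: Monte-Carlo integration puts the
static APS at roughly 3e-5 of its bounding box, concentrated along an
anti-diagonal ridge of the two Abeta→I weights with long, extremely thin
tendrils at high drive.  Plain rejection from the box is therefore
hopeless, and the sampling pipeline works in three steps
(`hierarchical_seed_sample()`, `build_hypercube()`, `build_cover()` +
`sample_uniform()`):

1. a seed sample (default 2000 points, twice the minimum the hypercube
   construction wants, to stabilise the range estimates) walks the
   hierarchy, drawing each coupling uniformly from its conditional interval
   and restarting on empty intervals; it is feasible by construction but
   *not* uniform — it deliberately over-weights thin regions;
2. component-wise extremes of the seed define the bounding hypercube and
   the normalisation `ĝ = (g - g_min)/(g_max - g_min)` used for all
   cross-coupling comparisons;
3. the unit cube is bisected recursively (always along the longest axis)
   into a disjoint set of boxes: a box whose 64 random probes are all
   feasible is kept whole, a box with no feasible probe and no seed point
   is discarded, anything else splits, down to a depth of three bisections
   per axis (capped at 16 total — in 7 dimensions the boundary-hugging
   frontier otherwise grows faster than the resolution gain is worth).
   Seed points anchor thin regions that probes miss.  Sampling then picks a
   box with probability proportional to its volume, a point uniformly
   inside, and keeps it iff it satisfies the inequality system.  Because
   the boxes are disjoint, the volume-weighted proposal is exactly uniform
   on the cover's union, so accepted points are exactly uniform on the APS
   ∩ cover; this is equivalent to picking boxes uniformly and thinning by
   `vol/max_vol`, without wasting draws on the thinning step.

What can go wrong, and how it is checked: the cover could miss feasible
regions that contain neither probes nor seed points — the risk is confined
to volumes that are tiny by construction, and a chi-square test against
plain rejection (tractable for the simple motif, acceptance ≈ 9%) verifies
distributional uniformity on a 27-cell partition.  Default uniform sample
sizes are 5000 (simple) and 2000 (static, dynamic).

## The allodynia surface and shortest paths

The output population can be driven to threshold by some non-painful rate
exactly when its Abeta weight reaches

`S(g_rest) = min_{f in [10,20]} [ (V_thr - V_rest) + inhibitory terms(f) - upstream excitatory terms(f) ] / f`

(`surface_height()`).  The surface is computed in unnormalised units and
mapped through the hypercube for geometry.  For the dynamic motif the
upstream-excitation term can drive the minimand negative; the height is
clamped at zero with a diagnostic flag, since negative coupling is
non-physical.

`nearest_surface_point()` finds the minimal normalised-coordinate change
from an APS point to `S` without constructing the surface: the relaxed
problem treats the rate `f` as a free variable, expresses the output weight
through the surface equality at that `f`, and minimises the distance over
(all other couplings, `f`) with multi-start L-BFGS-B (default 20 starts:
three deterministic — the source lifted straight up to the surface at its
minimising rate, which guarantees a feasible incumbent, and at the two
window endpoints, because the low end of the rate window hosts a separate
solution basin where reduced inhibitory drive makes the surface dip
steeply — plus perturbed restarts; objective tolerance `factr = 1e2`).
The relaxed solution can sit *above* the true surface when the min-over-
rate height at its couplings is attained at a different rate (the
"surface-plunge" corner, most visible in the dynamic motif where lowering
the upstream Abeta-to-I drive swings the surface through the upstream
excitation term); such solutions are detected post hoc and re-solved from
the plunge point until self-consistent, so every reported target satisfies
the true min-over-rate equality to 1e-8 and distances can only shrink in
the process.  Distances and displacements are reported in *normalised*
units — mechanism directions are fractions of each coupling's healthy
range — and the relaxation is not assumed correct but enforced: on the
simple motif a 60×60 surface-grid oracle must bracket every distance
within 2% plus grid resolution, and the former plunge solutions were
cross-checked against 300-start re-solves.

## Clustering and mechanism tags

Displacement vectors are clustered with density-based scanning
(`dbscan_labels()`, implemented in the package since no DBSCAN
implementation ships with the environment's R stack): core points have at
least `min_pts = 5` neighbours within `eps` (self included), clusters are
core-reachability components, border points attach to the first core
neighbour, ties broken by record order.  `select_epsilon()` binary-searches
(resolution 1e-4) for the smallest radius that yields no noise, between the
min and max 5th-neighbour distances.  Clusters are renumbered by descending
share with mean-distance tie-breaks, and tagged (`tag_mechanisms()`) from
the dominant components of their mean displacement (dominance threshold:
half the largest component): dominant decreases of Abeta→I weights mean the
excitatory population is *released* from inhibition; otherwise dominant
decreases of I→E weights mean it *escapes* intact inhibition; anything else
is mixed.  Representative per-cluster simulations use the cluster mean, or
its medoid when the mean falls outside the APS (spatially disjoint
clusters), paired against its nearest surface point under a noisy Abeta
bundle.

## What the pipeline finds, and a known divergence

At the package's default scales the simple motif splits roughly evenly
into a release cluster (lower `ĝAbI`; nearer the surface) and an escape
cluster whose direction is essentially fixed — about a 30% drop in `ĝIE`
against a 20% rise in `ĝAbE` — matching the published account of the
gate-control motif.  The dynamic motif at its default 2000 uniform points
yields the published four-mechanism structure — release of I2, escape of
E2 (the same fixed direction as the simple escape cluster, on the
downstream gate), release of I1, and a small escape-of-E1 cluster below
one percent — though with shares ordered differently (release of I2
dominates our sample where the published account has escape of E2
largest).

The static motif is the package's one substantive divergence: the
published analysis reports four clusters, two of which (≈ half the sample)
release the E population from whichever inhibitory population is the more
weakly driven one.  Our pipeline finds the symmetric both-population
release dominating, with single-population release clusters of ≈ 1–3% and
no escape cluster.  The discrepancy was investigated rather than tuned
away: (i) the uniform sample is verified against direct Monte-Carlo
cross-sections — the APS mass really does sit where both inhibitory
populations remain sensitive at the low end of the rate window, and the
saturated configurations needed for single-population release or static
escape carry negligible uniform volume; (ii) the shortest paths were
verified as global (multi-start robustness, on-surface residuals,
gradient equalisation at the targets, and the grid oracle on the simple
motif).  The efficient route to the surface from a doubly-sensitive point
is to lower *both* Abeta→I drives slightly, producing allodynia at the low
end of the rate window; single-population directions only dominate where
the other population is saturated.  The smallest-cluster share (~2%)
agrees with the published value even so.  Users comparing against the
published static clustering should bear this structural difference in
mind.

## Numerical choices and degenerate inputs

* Rate-grid resolution 201 everywhere a constraint is checked; interval
  edge refinement to ~1e-5 of an interval's width.
* Seed-sample restarts are capped at 1e6 (an infeasible configuration
  errors out rather than spinning).
* `build_hypercube()` rejects degenerate axes; `cluster_vectors()` refuses
  radii that leave noise (the contract is that `eps` comes from
  `select_epsilon()`); zero displacement vectors tag as `mixed`.
* Non-converged shortest-path records are flagged, kept in order, and
  excluded from clustering rather than aborting the batch.
* All sampling, optimisation and simulation entry points take explicit
  seeds and restore the ambient RNG state; a fixed configuration and seed
  reproduce every artifact byte-for-byte.

## Problem sizes used by the tests and the acceptance script

The packaged checks run the simple motif at 5000 uniform points (range
statistics) and 500 (shortest-path clustering), the static motif at 2000,
and the dynamic motif at 5000; simulation checks use 20 random
instantiations per motif with `dt = 1e-3` s.  The dynamic motif needs the
full 5000-point scale because its smallest mechanism class (escape of E1)
holds only a few points per thousand: below that scale the class falls
under the clustering's minimum neighbourhood size at many seeds, and the
no-noise radius rule then merges every cluster.  A seed-robustness study
informed these sizes; with them, cluster shares are stable to a few
percentage points across seeds while a full run stays in the minutes
range on one core.

## Limitations

The generator and the models emulate steady-state gating of constant or
piecewise-constant Abeta input in small feedforward motifs with homogeneous
population parameters.  They do not capture spiking phenomena (delayed or
transient firing), C-fibre input and wind-up, projection-neuron dynamics,
recurrent circuitry, or heterogeneity within a population — so passing
tests certify the geometry of the rate-model parameter space, not those
physiological features.  Mechanism tags summarise cluster means; individual
points near cluster boundaries can mix release and escape character.
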