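# boolcpg

Threshold-logic Boolean networks for respiratory rhythm generation.

Breathing is paced by a brainstem central pattern generator whose core
populations — inspiratory pre-I (the pre-Bötzinger complex), post-I and
aug-E — fire in sequence, driven by tonic spike trains from other brainstem
regions (NTS, RTN, Pons). `boolcpg` models this circuit as a Boolean
network: every node is a bit (1 = action potential), all nodes update
simultaneously, and a node turns on exactly when at least *N* of its
activators are on and none of its inhibitors is (inhibition dominates).
Because information lives in spike *timing* only, the control parameter of
every drive is its period *p*, and the model's predictions are properties
of the logic (memory, threshold, self-excitation, inhibition) rather than
of tuned biophysical constants.

The package is for modellers of respiratory (and other bursting) neural
circuits who want exact, assumption-light dynamics: every simulated steady
state is an exactly detected cycle of a finite deterministic system, and
the two bursting motifs come with closed-form steady-state oracles that the
simulator is tested against over full parameter grids.

## What it provides

* **Engine** — `network_spec()` / `node_spec()` declare threshold-logic
  networks; `simulate_network()` runs the synchronous update (compiled
  kernel); `find_cycle()` detects the exact eventual cycle by hashing the
  full bit state plus input phase; JSON (de)serialisation and TSV export.
* **Signal generators** — `periodic_input(p, phase)` spike streams and the
  equivalent autonomous `build_generator_ring(p)`, whose output settles
  into a period-*p* spike train from any initial state.
* **Bursting motifs** — `build_net_a(k, N)`: a *k*-step memory chain whose
  output fires on *N* coincident chain spikes (steady state:
  tonic for *p* ≤ *k*/*N*; bursting with *s* = *k* − (*N*−1)*p* spikes per
  period for *k*/*N* < *p* < *k*/(*N*−1); silent beyond).
  `build_net_b(k, m, N = 2)` adds memory loss (an output spike erases the
  chain beyond position *m*) and one-step self-excitation; its six-case
  closed form (`predict_net_b()`) has the signature that the burst length
  stays *m* while only expiration stretches with *p*.
* **Pattern classifier** — `classify_pattern()` labels a cyclic pattern
  silent / tonic(*p*) / bursting / mixed-mode via the
  trailing-zero-run-vs-internal-gap criterion; `burst_timing()` measures
  per-burst inspiration (T_I), expiration (T_E) and breath period (T).
* **Composed CPG** — `build_cpg()` wires one Net A (post-I) and two Net B
  (pre-I, aug-E) motifs with cross-population inhibition; `run_cpg()`,
  `phase_timing()`, `sweep_control()` and `ensemble_variability()`
  reproduce the 3-phase → 2-phase → 1-phase regime transitions, selective
  control of inspiration/expiration times, and the phase-jitter
  variability predictions.
* **CLI** — `inst/exec/boolcpg` exposes `predict`, `simulate`, `classify`
  and `cpg run|sweep|ensemble` over JSON/TSV for shell use.

## Worked example

```r
library(boolcpg)

# Isolated pre-I motif (k = 400, m = 100, N = 2) under a period-110 drive:
predict_net_b(net_b_params(400, 100), p = 110)
#> <steady_prediction> bursting: cycle length 220, 100 spike step(s) per cycle

# The same answer by exact simulation from the feasible state:
fs <- feasible_state(net_b_params(400, 100), p = 110)
out <- steady_output(build_net_b(net_b_params(400, 100)),
                     init = fs$state, inputs = fs$inputs)
length(out); sum(out)
#> [1] 220
#> [1] 100

# The composed CPG at the reference drives (p1, p3, p4) = (5, 110, 32):
run <- run_cpg(cpg_params())
run$label
#> [1] "three_phase"
tm <- phase_timing(run)
round(sapply(tm$stats, `[[`, "mean"), 1)
#>   T_I   T_E  T_E1  T_E2     T
#>  68.4 151.6  41.6 110.0 220.0
```

Read: each 220-step breath (set by aug-E's autonomous 2·p3 cycle) splits
into ~68 steps of inspiration (X1 active until post-I fires), ~42 steps of
first expiration (post-I active until aug-E fires) and 110 steps of second
expiration; inspiration varies breath-to-breath (spike-arrival jitter)
while the breath period is locked. Raising p3 lengthens expiration at
constant inspiration; raising p1 shortens inspiration at constant breath
period; raising p4 does the reverse — the selective timing control the
architecture was built to explain.

## Notes

* The methods vignette (`vignettes/boolcpg-methods.Rmd`) documents the
  model, the closed forms, the canonical-rotation and timing conventions,
  and the composition choices in detail.
* All dynamics are exact integer arithmetic; randomness enters only
  through seeded control-phase ensembles.
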