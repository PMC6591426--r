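---
title: "Threshold-logic Boolean networks for respiratory rhythm generation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Threshold-logic Boolean networks for respiratory rhythm generation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(boolcpg)
```

## The model

`boolcpg` models neural populations of the respiratory brainstem as Boolean
networks under a synchronous threshold-logic update. Every node holds a bit
(1 = an action potential in this time step, 0 = none) and all nodes update
simultaneously from the current state by three rules:

1. a node is 1 in the next step if at least $N$ of its activators are 1 now
   and none of its inhibitors is — $N$ is the node's *threshold* and may
   differ between nodes;
2. a node is 0 in the next step if fewer than $N$ activators are 1;
3. a node is 0 in the next step if *any* inhibitor is 1, regardless of the
   activators (inhibition dominates).

Spike *amplitude* carries no information in this representation; all
signalling is in spike timing. A tonic drive of period $p$ is the stream
that emits a 1 every $p$ steps. The framework deliberately abstracts away
membrane biophysics: what remains is the logic — thresholds, memory,
self-excitation and inhibition — and every qualitative result holds for
whole parameter ranges rather than tuned values.

Because the state space is finite and the update deterministic, every
trajectory eventually repeats; `find_cycle()` detects the exact repeating
cycle by hashing the full bit vector augmented with the input phase counter
($t \bmod \mathrm{lcm}$ of the input periods). No lossy hashing is used:
keys are the packed exact bits, so a detected cycle is a theorem about the
trajectory, not an approximation. The default step cap,
$50\cdot\mathrm{lcm}(\text{input periods}) + \#\text{nodes}$, is far above
every cycle the closed-form analysis predicts (all of which divide small
multiples of the input periods); it can be overridden for pathological
inputs.

### Control signals

Control inputs are represented as periodic streams (`periodic_input(p,
phase)`, bit 1 iff $(t-\phi) \bmod p = 0$). An equivalent autonomous
construction exists: `build_generator_ring(p)` builds a ring of $p-1$ chain
nodes plus a constant drive whose output settles into the period-$p$ spike
train from *any* initial state (the suite verifies this exhaustively for
$p \le 9$). Using streams rather than embedded rings keeps the hashed state
compact; the exhaustive equivalence tests justify the substitution. The
degenerate $p = 1$ generator (output wired straight to the constant drive)
is admitted because the composed network's sweeps need period-1 controls.

## The bursting motifs

Two motifs convert a tonic drive $C_1$ into richer output at a node $X_1$.

**Net A (memory preserved).** A delay line $S_1 \ldots S_k$ carries each
drive spike for $k$ steps; $X_1$ fires while at least $N$ chain nodes are
active. Its steady state has a closed form (`predict_net_a()`): tonic for
$p \le k/N$, bursting with $s = k - (N-1)p$ spikes per period for
$k/N < p < k/(N-1)$, silent for $p \ge k/(N-1)$. At $N = 1$ the network can
never be silenced. At the upper boundary the burst degenerates to a single
spike ($s = 1$), i.e. a uniform period-$p$ train, and the regime label is
taken from the pattern classifier rather than hard-coded as bursting.

**Net B (memory loss + self-excitation).** As Net A with $N = 2$, plus: an
output spike erases the chain beyond position $m$ (inhibitory edges
$X_1 \dashv S_i$ for $i > m$), and a node $I_1$ feeds $X_1$'s own spike back
one step later, counting as one ordinary activator. `predict_net_b()`
implements the six-case closed form stated from the *feasible state* (two
chain spikes $p$ apart, output off): tonic for $p \le m$; an alternating
`10` pair at $p = m+1$ even; a three-part cycle of length $3m+3$ at
$p = m+1$ odd; the bursting pattern of $m$ spikes then $2p-m$ zeros (cycle
$2p$) for $m+2 \le p < k-1$; a sparse alternating burst at $p = k-1$; silent
for $p \ge k$. The distinguishing signature of Net B is that inspiration
time (spikes per burst) stays $m$ while only the quiescent phase stretches
with $p$ — in Net A the burst *shrinks* as $p$ grows.

Two written-pattern ambiguities were resolved from the case proofs rather
than the printed summaries: at $p = m+1$ odd, the alternation block is the
even-length run $0,1,\ldots,0,1$ over steps $p..2p-2$ followed by $m+3$
zeros (the printed block lengths are off by one but describe the same bit
sequence), and at $p = k-1$ the spikes sit at odd steps $t \le m$ of the
$2p$-cycle. Both forms are verified against direct simulation over full
parameter grids ($k \in 6..30$, $m \in 3..k-3$, $p \in 1..k+2$), not just
spot cases.

For $p \ge k$ the feasible state as literally written does not exist (the
second chain spike has no slot), so `feasible_state()` refuses it; the
silent-regime grid tests start from the all-zero chain instead, which under
a period-$p \ge k$ drive provably holds at most one chain spike at a time —
the same argument the silent case rests on.

The closed forms are stated from one initial condition, but basin lemmas
make them general: for $p < m$ every initial state ends tonic, for
$p > k+1$ every initial state ends silent, and for $m+1 < p \le k-1$ every
trajectory funnels through the feasible state. The suite checks these
exhaustively over all $2^{k+2}$ initial assignments for small motifs and
over 200 seeded random states for larger ones. Behaviour from arbitrary
initial states at $p = m$ and $p = m+1$ is not characterised by the lemmas
and is deliberately tested only from the feasible state.

## Pattern classification

A repeating cyclic pattern is decomposed by rotating it to end with its
longest zero run (wrap-aware, earliest rotation on ties). This
canonicalisation is a package choice: the underlying definition presumes a
rotation without fixing one, and ending at the longest quiescent run is the
unique choice that makes the decomposition rotation-invariant. After
rotation, with $n$ the trailing zero run and $\max(0)_m$ the longest zero
run inside the leading active segment, `classify_pattern()` labels:

* **silent** — no spikes;
* **tonic** (period $p$) — exactly one spike per minimal period: the
  uniform train $\overline{10\cdots0}$, including the all-ones train;
* **bursting** — not tonic and $n > \max(0)_m$;
* **mixed-mode** — not tonic and $n \le \max(0)_m$.

The alternating pair $\overline{10}$ is a uniform period-2 train and is
therefore labelled tonic, which keeps the classifier consistent with the
trajectory taxonomy (tonic spiking with period $p$ for every $p$); the
motif oracle reports that steady state by its literal pattern and defers
the label to the classifier.

`burst_timing()` measures inspiration/expiration on a cycle: zero runs
shorter than a gap tolerance $g$ are absorbed into the surrounding burst,
each burst span is a $T_I$, each inter-burst gap a $T_E$, and
$\sum T_I + \sum T_E$ equals the cycle length exactly. The motif-analysis
default is $g = 1$ (no merging).

## The composed central pattern generator

`build_cpg()` wires one Net A and two Net B motifs into the respiratory
network: $X_1$ (pre-I, inspiration), $X_4$ (post-I, first expiratory
phase, Net A with a higher threshold $N = 3$), $X_3$ (aug-E, second
expiratory phase). $X_3$ hears only its own drive $C_3$; $X_3$ inhibits
$X_1$, $X_4$ and their whole memory chains; $X_4$ inhibits $X_1$ and its
chain. Default parameters are $k_1 = k_3 = 400$, $N_1 = N_3 = 2$,
$m_1 = m_3 = 100$, $k_4 = 800$, $N_4 = 3$, periods $(p_1, p_3, p_4) =
(5, 110, 32)$.

Two composition choices were genuinely open:

* **Inhibition targets the whole chain, not just the output.** The
  three-phase mechanism needs the released population to *re-accumulate*
  drive spikes before firing (activation delays of order $N \cdot p$); if
  only the output were inhibited, the chain would stay charged and the
  released population would fire instantly. Whole-chain inhibition
  reproduces the mechanism's timing; the exact interior wiring is otherwise
  unobservable from the outputs.
* **Self-excitation nodes are not inhibited directly.** $I_1$ follows its
  output with one step of lag, so inhibiting the output already extinguishes
  it one step later; adding edges onto $I_1$ changes nothing observable.

No $X_1 \to X_4$ or $X_4 \to X_3$ edges exist: the first-expiratory
population is recruited by its drive once $X_3$ releases it, not by the
inspiratory population.

### Regimes and timing

`run_cpg()` simulates from the all-zero deterministic initial condition,
discards a burn-in and analyses a steady window (defaults 3000 + 4400
steps; the defaults hold roughly twenty breaths of the reference rhythm and
sit far past the measured transients, which are below ~1500 steps at the
reference parameters). Per-population regimes in the window are *silent*,
*tonic* (uninterrupted activity or a uniform spike train) or *bursting*,
and the joint label follows the decision table (3-phase, 2-phase with
either expiratory population, 1-phase, tonic, silence). Active phases of
the composed network are solid runs of 1s, so regime detection needs no gap
tolerance; the timing analysis merges at $\min(p_i + 1, 6)$ steps only to
absorb onset flicker. A tolerance as large as the control period itself —
a plausible alternative — would erase genuine quiescent phases (a Net A
population driven at $p_4 = 350$ rests for only $250$ steps) and was
rejected for that reason.

Per-breath timing is boundary-based: a breath runs from one $X_1$ onset to
the next, and within it $T_I$ ends at the $X_4$ onset, $T_{E1}$ at the
$X_3$ onset, $T_{E2}$ at the next $X_1$ onset, so
$T = T_I + T_{E1} + T_{E2}$ holds exactly. (Activity-based burst lengths
would leave the post-release activation delays unassigned to any phase.)
In the 1-phase regime, where no expiratory onset exists, $T_I$ is the
merged $X_1$ burst span itself — the count of consecutive spikes. Breaths
within one detected window differ because drive spikes arrive at varying
offsets relative to the expiratory cycle; `ensemble_variability()`
quantifies this by re-running the network from seeded random control
phases and pooling per-breath timings.

## What the synthetic inputs do and do not emulate

All inputs are constructed: periodic spike trains and parameterised motif
networks. They emulate the *timing logic* of tonic brainstem drives —
frequency coding, phase jitter, regime transitions — and nothing else. Real
respiratory networks have noisy, frequency-modulated drives, heterogeneous
neurons, within-burst spike-rate changes and analog coupling to lungs and
heart; none of that is modelled, and passing tests say nothing about those
features. In particular, within-burst rate modulation is explicitly out of
scope, and the early-inspiratory population is deliberately absent from the
composed network (it is not needed to generate or control the rhythm here).

## Numerical and size choices

* All arithmetic is exact integer/bit arithmetic; there are no tolerances
  in the dynamics, only in timing *summaries* (means over breaths).
* Oracle-equivalence grids: Net A $k \in 4..40$, $N \in 1..4$,
  $p \in 1..k+3$; Net B $k \in 6..30$, $m \in 3..k-3$, $p \in 1..k+2$ —
  several thousand exact pattern comparisons each, covering every regime
  boundary.
* Sweep probes hold the composed network inside the intended regime:
  $p_3 \in 104..150$ keeps $X_3$ bursting ($p_3 \ge m+2 = 102$), and
  $p_4 \le 56$ keeps the three-phase label — beyond $p_4 \approx 55$ the
  post-I population cannot collect $N_4 = 3$ drive spikes inside the
  120-step expiratory window and the system genuinely leaves the 3-phase
  regime (that boundary is itself a model prediction, not an artefact).
* Scaled-down composed networks ($k = 60/120$) are used in unit tests for
  speed; the full reference network is exercised in the acceptance suite.

## Known limitations

* The closed-form Net B oracle covers $N = 2$, $m \ge 3$ only; outside
  that range `predict_net_b()` refuses rather than extrapolates, and
  simulation is the fallback.
* Regime labels are read from a finite steady window; a rhythm whose joint
  period exceeds the window would be classified from incomplete evidence
  (the window default is sized to avoid this at the parameters studied).
* The boundaries of the "medium" $C_3$ band that admits a three-phase
  label in the composed network are scanned empirically, not derived in
  closed form.
* Asynchronous or stochastic update schemes and continuous-time semantics
  are out of scope.
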