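---
title: "Modeling aging as loss of morphogenetic goal-directedness: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling aging as loss of morphogenetic goal-directedness: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(ncaging)
```

# The model

`ncaging` simulates multicellular morphogenesis and its long-term decay with
a Neural Cellular Automaton (NCA): a fixed `N_x x N_y` grid of cells, each
carrying a continuous state vector of `N_C = N_G + N_H` channels. The first
`N_G` channels are *indicators*: a cell's expressed type is the index of the
largest indicator (ties break to the lowest index — the rule must be fixed
because evolved states can tie exactly at the clip bounds). The remaining
`N_H` channels are hidden, available for unconstrained intercellular
communication.

Every cell runs the *same* controller. One perception-action cycle:

1. **Perception.** The cell reads its own state and the states of its 8
   Moore neighbors. Out-of-grid neighbors (fixed boundary conditions) and
   neighbors behind a closed gap junction are read as the zero vector.
2. **Sensor embedding.** Each perceived state is mapped separately through a
   one-layer tanh embedding of dimension `sensor_dim`.
3. **Mean pooling.** The 9 embeddings are averaged into one context vector.
   Pooling makes the dynamics invariant to any relabeling of the neighbors —
   cells have no compass.
4. **Recurrent control.** A minimally gated recurrent layer of dimension
   `hidden_dim` (a forget gate and a candidate update, both fed by the
   context and the cell's private memory) advances the cell's working
   memory; a tanh head proposes an action of length `N_C`, clipped to
   `l_a = [-1, 1]`.
5. **Update.** All cells update synchronously:
   `c(t+1) = clip(c(t) + a(t) + xi, l_c)` with `l_c = [-3, 3]` and `xi`
   i.i.d. Gaussian noise of standard deviation `xi_c` per channel.

The reference system is a 16 x 16 grid, `N_G = 3`, `N_H = 1`,
`xi_c = 0.125`, and a developmental horizon of `t_D = 35` steps; the shipped
target is the canonical smiley-face pattern (`make_smiley()`,
`inst/extdata/smiley.json`) with `LeftEye`, `RightEye` and `Mouth` organ
masks. The smiley's exact pixel layout is a versioned package decision (a
circular face, two 2 x 2 eyes, a one-cell-thick mouth arc): every experiment
the platform supports is pattern-agnostic, so determinism of the fixture
matters more than any particular pixel choice.

Noise is applied *whether or not* the action survives the competency gate
(below): residual noise is precisely what erodes tissue that has stopped
correcting itself, so silencing it alongside the action would remove the
phenomenon under study.

## Genome and neuroevolution

The genome is the flat vector CMA-ES searches: *structural genes* — the
initial cell states, clipped to `l_c` at decoding — followed by *functional
genes* — the controller parameters shared by all cells. Development runs
`t_D` steps from the structural genes with zeroed memories; the phenotype is
the final type grid. Fitness:

    r = (2 n_G - N_j) + r_T * n_T - r_S * n_S

with `n_G` the correctly typed cells at `t_D`, `n_T` the steps at which the
whole target is realized (premature-completion bonus), and `n_S` the pairs
of successive steps without any type change (stagnation penalty). The
pattern term `2 n_G - N_j` reaching `N_j` defines "solved"; this keeps the
solved criterion independent of `r_T`, `r_S`, whose numeric values
(defaults 0.1/0.1) are secondary shaping terms. When scoring whole
lifespans, the stagnation term accumulates over the entire scored window,
which is why even perfectly maintained tissue scores below the developmental
maximum on long horizons.

CMA-ES runs with mean zero, initial step size 0.5, and the standard
rank-based covariance updates. Two implementation choices matter on this
noisy, integer-valued objective:

* every candidate is evaluated as the mean of `repetitions = 3` rollouts,
  each with an RNG stream derived from `(seed, generation, candidate,
  repetition)`, so ranking noise is controlled and runs are bit-reproducible;
* if the best-ever score improves by less than 0.5 over 40 consecutive
  generations the strategy restarts from scratch (fresh sampling stream,
  same budget accounting) — the usual remedy for premature covariance
  collapse; the total generation budget is never exceeded.

## Aging mechanisms

Four lifetime perturbations can be attached to a deployment, each with its
own derived RNG stream so that enabling one never changes another's draws
(paired comparisons stay paired):

* **Misdifferentiation noise** — a schedule replaces the constant `xi_c`;
  the reference ramp is linear from 0 to 1 over the lifespan.
* **Competency** — each cell's proposed action is applied only with
  probability `P_D(t)` (kept iff `u <= P_D`, one uniform draw per cell per
  step); the reference schedule is `sin^4((pi/2)(1 - t/t_A))`, falling from
  1 to 0.
* **Gap-junction closure** — per cell, while the open fraction of its
  incoming in-grid links exceeds `P_GJ(t)`, one uniformly chosen open link
  closes permanently. Closure is directed (it blocks what the perceiving
  cell reads); symmetric closure is not modeled. The reference schedule is
  linear from 1 to 0.
* **Genetic damage** — i.i.d. `N(0, sigma_x)` increments (reference
  `sigma_x = 0.01`) are added to the functional genes at every step and the
  controller is re-decoded, identically in every cell; structural genes are
  never mutated during life. After `t` steps the per-parameter variance is
  `t * sigma_x^2` — the `t_A = 1000` reference run accumulates 0.1.

Schedules are evaluated at the pre-update time of each step. The noise
schedule *replaces* the baseline 0.125 rather than adding to it, following
the declared endpoint `xi_c(0) = 0`.

## Information dynamics

Active information storage (AIS), transfer entropy (TE) and spatial entropy
(SE) are computed on discrete symbol series. The default discretization is
the expressed cell type: with a three-type system this is the only
self-consistent discrete reading; a per-channel uniform binning of the
continuous states over `l_c` is provided as an option. All estimators are
plug-in (maximum-likelihood) over the analyzed window, with no bias
correction: at alphabet size 3 and the window sizes used, reproducibility
and exact checkability against brute-force histogram oracles were judged
more valuable than small-sample bias. Consequences worth knowing: local
values can be negative, means cannot; plug-in AIS/TE of short i.i.d. series
have a positive bias of order `(alphabet^k) / n`.

The semi-infinite past is truncated at history length `k`; there is no
canonical value, so `k` is a mandatory, logged parameter (default 2).
Per-cell maps average TE over the cell's *open* incoming links only, so maps
remain meaningful under gap-junction closure. Time-resolved series use
sliding windows (default width 100, stride 10).

## Organ monitoring and rejuvenation

Every organ has a score `r_o(t)`: the fraction of its cells expressing their
target type, optionally over the organ plus its one-cell Moore boundary
ring. An intervention triggers when `r_o < r_th` strictly (default
`r_th = 0.6`) and the organ's refractory period (default 25 steps) has
elapsed; organs are independent. Two modes: reset the whole organ, or only
its wrongly expressed cells; either can be boundary-augmented. The payload
is the cell's primordial initial state from the structural genes (default)
or an indicator encoding of the target type (+1 target channel, -1 other
indicators, hidden 0 — an artifact decision, recorded in the run config).
Reset cells always have their recurrent memory erased. Scores are computed
every step; interventions apply after expression and scoring, before the
next dynamics step (the ordering is a fixed package decision). Monitoring
can be deferred (`start`), and the default experiments start it at `t_D` so
development itself is never treated. In the smiley and toy-face policies the
mouth's boundary is excluded by default: the mouth is the most stable organ
and already occupies a large fraction of the face.

# Scaled-down study conditions

Evolving the 16 x 16 reference system is a multi-hour computation, so the
package's experiments and tests run on two fixed toy organisms
(`toy_study_conditions()`), with all cell-level constants (noise 0.125,
clip bounds, Moore neighborhood) identical to the reference system:

* **stripe** — a 4 x 4 two-type vertical stripe; population 24, at most 200
  generations, `t_D = 20`, sensor/recurrent dimensions 2/2 (genome length
  85). This is the evolution smoke task: it is reliably solved within the
  budget in about a minute.
* **face** — an 8 x 8 miniature of the smiley: background ring, 6 x 6 face,
  two 2 x 2 eyes and a 4-cell mouth of a third type, with organ masks and
  boundary rings. Population 24, at most 300 generations, `t_D = 35` (the
  reference developmental horizon), lifespan `t_A = 1000` for perturbation
  and rejuvenation experiments; unperturbed aging is read off at
  `20 t_D = 700`.

Why a second toy: the aging phenomenology of the reference system is *organ
loss* — small regions of a distinct type embedded in host tissue blur and
disappear first. A two-type stripe has no such structure, and evolved stripe
solutions often find genuinely stable majority-vote attractors that never
age; embedded 2 x 2 organs are exactly the structures that decay. The face
toy also supplies the organ masks the rejuvenation protocols need, including
a mouth that is larger and more stable than the eyes. Evolution stops as
soon as the developmental task is first solved: like the reference
organisms, the toys are selected for development only, never refined for
long-term robustness.

Choices made once for these conditions: the stripe develops over
`t_D = 20` steps (enough for noise-exposed development on a 4-cell-wide
grid while keeping a CMA-ES candidate evaluation cheap) while the face keeps
the reference `t_D = 35`; architecture dimensions 2/2 (genome lengths
85-298, comfortably inside CMA-ES's reliable regime at population 24);
deployment ensembles of 20-25 seeds; perturbation and rejuvenation horizons
of `t_A = 1000` matching the reference experiments.

What the toys do and do not show: they reproduce the *directions* of the
reference phenomena — emergent post-developmental decay, acceleration under
each of the four mechanisms, fewer interventions needed for targeted and
boundary-augmented resets — at 1-2 orders of magnitude smaller scale. They
do not reproduce the reference system's absolute numbers (fitness 256,
specific loss times), and individual evolved toys can achieve genuine
morphostasis and not age at all within the measured horizon, just as the
most robust reference individuals maintain their pattern for exceptionally
long times. Stochastic comparisons are therefore made on ensemble medians
with paired seeds, and an occasional tie between a stable organism's
developmental and end-of-life medians is an honest outcome, not a defect.

One protocol contrast does not always transfer to toy scale: in the
reference system, whole-organ resets to primordial states are the *least*
sustainable intervention (the organ dissolves again and needs resetting over
and over), whereas targeted wrong-cell resets need only a handful of events.
The toys develop dynamically too, but at 8 x 8 scale a fully reset organ
re-develops successfully inside its mature surroundings, while scattered
primordial cells in a partly mature organ re-develop less coherently — so
the intervention-count gap between the two modes can narrow or even invert,
and the corresponding ensemble comparison in the test suite may fail for
some evolved organisms. The boundary-augmentation effect (fewer triggers,
preserved long-term fitness) is robust across the organisms examined.

# Numerical and reproducibility choices

* All randomness flows through named streams (`nca_streams()`): noise, gate,
  gap junctions, mutation, plus derived per-evaluation streams during
  evolution. A single master seed replays any run bit-exactly; run
  directories written by `run_command()` snapshot the config and seed.
* Within a step, the gate consumes one uniform per cell and the noise one
  normal per state component, in the grid's column-major cell order; both
  are drawn even when inert (P_D = 1, or xi_c = 0) so that paired runs stay
  aligned.
* Cells are indexed column-major ((row, col) -> row + (col-1) * height)
  everywhere internally; the JSON pattern dialect uses 0-based (row, col)
  coordinates.
* Degenerate inputs: empty organ masks and zero-length scored sets are
  errors, not zeros; trajectories shorter than the scored window are errors;
  schedules outside their declared kinds are errors.
* Per-component noise: the noise term is drawn independently per state
  channel (a per-cell scalar variant would correlate channel errors; the
  per-component reading is the stricter test of robustness and is the
  package default).

# Known limitations

* The controller architecture (tanh embedding, minimally gated recurrent
  unit) is one reasonable member of the family of small recurrent
  gene-regulatory-network-like controllers; genome files are
  self-describing via the architecture descriptor, so alternative dimensions
  coexist, but alternative gate structures would need new decode logic.
* Plug-in information estimates are biased upward on short windows; compare
  only like-for-like window sizes and history lengths.
* Evolution on grids much beyond 8 x 8 (genome length >~ 500) needs larger
  populations and budgets than the defaults.
* Heterogeneous per-cell mutation, asynchronous updates, growing grids and
  gradient-based training are out of scope.
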