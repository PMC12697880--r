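# ncaging

An evolutionary Neural Cellular Automaton (NCA) platform for studying aging
as a **loss of morphogenetic goal-directedness**, with tools to accelerate
aging through cell-level damage mechanisms, to quantify the tissue's
information dynamics, and to test organ-level rejuvenation protocols.

## The science

Multicellular development can be modeled as a collective of identical,
locally communicating agents: each cell on an `N_x x N_y` grid carries a
continuous state `c_i(t)` of `N_C = N_G + N_H` channels (the first `N_G` are
cell-type indicators, the rest hidden communication channels) and updates it
with a shared recurrent controller,

```
c_i(t+1) = clip( c_i(t) + a_i(t) + xi ,  [-3, 3] ),    a_i = clip( f_theta(N_i(t)), [-1, 1] )
```

where `N_i(t)` is the cell's Moore neighborhood (out-of-grid and
gap-junction-blocked neighbors read as zero vectors), `f_theta` embeds each
neighbor state, mean-pools the embeddings, and passes them through a gated
recurrent unit, and `xi` is per-channel Gaussian noise of amplitude `xi_c`.
A cell's expressed type is `argmax` of its indicator channels.

The genome `x = {c_i(0)} ∪ theta` (structural + functional genes) is evolved
with CMA-ES to maximize the phenotype fitness

```
r = (2 n_G - N_j) + r_T * n_T - r_S * n_S
```

(`n_G` correct cells at the developmental horizon `t_D`, `n_T` steps with the
target fully realized, `n_S` stagnant step pairs). A pattern term of
`N_j = N_x * N_y` means the morphogenesis task is solved — 256 on the
canonical 16 x 16 three-type smiley-face target shipped with the package.

Organisms are selected only for development. Deployed far beyond `t_D` they
lack any morphostasis goal and their anatomy decays — organs blur and vanish
— even under unchanged conditions. The platform provides:

* four aging-acceleration mechanisms (rising misdifferentiation noise, a
  `sin^4` competency decline, permanent gap-junction closure, diffusive
  genetic damage `sigma_x = 0.01` per step);
* plug-in estimators of active information storage, transfer entropy and
  spatial entropy, including per-cell spatial maps that reveal that
  information about a lost organ persists at its former site;
* threshold-triggered rejuvenation interventions (`r_o < 0.6`, 25-step
  refractory): whole-organ or wrong-cells-only resets to primordial or
  target states, optionally boundary-augmented, with recurrent-memory
  erasure.

## Worked example

Evolve the 4 x 4 two-type stripe toy, deploy the organism past its
developmental horizon, and score it:

```r
library(ncaging)

cond <- toy_study_conditions("stripe")   # pattern + run configuration
res  <- evolve_nca(cond$pattern, cond$config, seed = 1)
res$solved
#> [1] TRUE
tail(res$history, 2)
#>    gen   best_r   mean_r best_pattern     sigma
#> 48  48 14.23333 3.931944           14 0.4084595
#> 49  49 15.76667 3.118056           16 0.4093832

traj <- simulate_nca(res$genome, cond$config, seed = 7, steps = 400)
nca_fitness(traj, cond$pattern, t_D = 20)
#> fitness r = 16.100 (pattern term 16; n_G = 16/16, n_T = 17, n_S = 16)
pattern_term(traj, cond$pattern, t = 400)   # end of life, 20 * t_D
#> [1] 16
spatial_entropy(type_grid(traj, 400))
#> [1] 1
```

`best_pattern` reaching 16 (= `N_j`) in generation 49 says the task was
solved within the 200-generation budget; the fitness breakdown at `t_D = 20`
shows a perfect pattern (`n_G = 16/16`) with the premature-completion bonus
(`n_T`) and stagnation penalty (`n_S`) itemized; the spatial entropy of 1
bit is exactly the value of an intact half-and-half stripe. This particular stripe
organism is stable to 400 steps; the organ-bearing toy face
(`toy_study_conditions("face")`) typically loses organ cells over the same
horizon — the emergent-aging phenomenon the platform exists to study.

Aging and rejuvenation experiments compose the same pieces:

```r
face <- toy_study_conditions("face")
org  <- evolve_nca(face$pattern, face$config, seed = 1)

aged <- simulate_nca(org$genome, face$config,
                     schedules = reference_mechanisms()$gap_junction,
                     seed = 1, steps = 1000)

policy <- intervention_policy(threshold = 0.6, mode = "wrong_cells_reset",
                              include_boundary = c(LeftEye = TRUE, RightEye = TRUE,
                                                   Mouth = FALSE),
                              payload = "initial_state", refractory = 25,
                              start = 20)
rej <- run_with_rejuvenation(org$genome, face$config, policy,
                             face$pattern$organs, face$pattern, seed = 1)
nrow(rej$events)          # intervention count over the lifespan
head(rej$scores)          # per-step organ scores
```

A shell-level entry point over the same commands (`evolve`, `simulate`,
`age`, `analyze`, `rejuvenate`) lives at `inst/scripts/nca-cli.R`:

```sh
Rscript inst/scripts/nca-cli.R age --config run.yaml --out rundir \
  --seed 7 --noise linear:0:1
```

Every run directory contains a config snapshot and seed ledger and is
replayable byte-for-byte.

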