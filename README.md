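# ammsim

An agent-based evolutionary simulator of motivation and wellbeing. Agents
live in an abstract environment of situations that can change their fitness;
they learn which situations to allow, predict, and seek out, and the
heritable parts of their motivation evolve over generations under natural
selection. The simulator exists to study how selection shapes affect-like
signals — in particular, why well-adapted agents end up *moderately* happy,
why negative cues come to feel stronger than positive ones (negativity
bias), and how wellbeing responds and adapts to lasting environmental
change (hedonic adaptation).

It is aimed at researchers in evolutionary psychology, affective science,
and behavioural modelling who want a small, fully reproducible sandbox in
which those phenomena *emerge* from selection on learning machinery rather
than being assumed.

## Model

The environment is a grid of `n = 80` situations with fitness-change
values `z` evenly spaced on `[-2, 2]`. Situation `i` is encountered with
base frequency equal to the standard normal density,

    p_i = exp(-z_i^2 / 2) / sqrt(2*pi),

so frequent situations matter little and rare ones matter much. An agent's
*effort* (niche construction) rescales its own encounter frequencies,
`q_i = A^phi_i * p_i` with `A = 5`, subject to a total absolute-effort
budget `kappa = 8`.

Each of `m = 200` periods per lifetime, for every situation:

- the outcome is allowed with probability `b = logistic(G + R)`, where `G`
  is a heritable instinct and `R` a learned reinforcement value;
- the prediction error is `eps = V - lambda`, where `V` is the heritable
  cue value and `lambda` the current prediction;
- the learning signal is the frequency-weighted error
  `omega = b * q * eps`;
- updates: `lambda' = 0.99*lambda + 2*omega`,
  `R' = 0.98*R + 3*omega`, and `phi' = phi + 0.01*omega` while
  `sum(|phi|) < kappa` (otherwise effort is pairwise-reallocated in 20
  randomized decisions per period).

Lifetime fitness is `F = sum_k sum_i b*q*z`. Each generation of `S = 300`
agents is bred by truncation selection — every offspring takes one parent
from the top 10% by fitness and one from the top 60%, inheriting each `G`
and `V` value from a random parent, clamped to `|.| <= 1.5`, plus
`N(0, 0.4)` mutation noise — for 80 generations.

Reflective wellbeing in a period is the positively valued share of
weighted prediction errors,

    W = sum(omega[omega > 0]) / sum(|omega|)  in [0, 1],

and the hedonic-adaptation experiment multiplies one situation's base
frequency by 20 for 40 periods (with reinforcement and effort frozen, so
only prediction learning can respond) and tracks `W` through onset,
adaptation, and reversal.

## Worked example

A reduced-size run (40 situations, 100 periods, 50 agents, 10
generations) that finishes in a few seconds:

```r
library(ammsim)

params <- amm_params(n_situations = 40, n_periods = 100,
                     pop_size = 50, n_generations = 10)
evo <- run_generations(params, seed = 1)
evo
#> <amm_evolution>
#>   10 generations x 50 individuals x 100 periods x 40 situations
#>   mean fitness: -0.14 (gen 1) -> 150.82 (gen 10)
#>   mean final-period wellbeing (last generation): 0.556
```

Mean fitness rises from about zero (naive, random founders) to ~151 as
selection installs adaptive instincts and cue values. Final wellbeing
settles slightly above neutral: positive weighted prediction errors
outweigh negative ones, but residual avoidance errors keep it well below
1. `tidy(evo)` returns the per-generation table, `glance(evo)` a one-row
summary, and `autoplot(evo)` / `plot_situations(evo, "V")` the standard
figures.

The evolved negativity bias and a hedonic shock:

```r
negativity_ratio(prediction_error_profile(evo))
#> [1] 5.96   # avoidance cues carry ~6x stronger prediction errors

set.seed(1)
shock <- run_shock_experiment(representative_individual(evo), evo$env,
                              shock_protocol(-1.481, pre_periods = 200),
                              params)
glance(shock)
#>   baseline onset_extremum shock_plateau rebound_extremum late_post direction
#> 1    0.576          0.342         0.572            0.597     0.578        -1
```

Reading the shock summary: wellbeing sits at a 0.576 baseline, plunges to
0.342 when the avoidance situation becomes 20x more frequent, adapts back
to 0.572 (just short of baseline — the residual offset), overshoots to
0.597 when the environment reverts, and decays back toward baseline.

`run_full_reproduction()` executes the whole pipeline (evolution, metrics,
both shock valences) over replicate seeds and writes `generations.csv`,
`situations_final.csv`, `shock_trace.csv`, and `summary.json`. A thin CLI
over the same functions lives at `inst/cli/amm.R`
(`Rscript amm.R run|shock|reproduce ...`).

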