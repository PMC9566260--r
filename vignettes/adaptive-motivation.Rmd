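---
title: "The adaptive-motivation simulator: model, parameters, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The adaptive-motivation simulator: model, parameters, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

ammsim simulates populations of agents whose motivational machinery —
instincts, reinforcement learning, prediction, and effortful niche
construction — evolves under natural selection, and asks what that
machinery implies for wellbeing. This vignette is the package's own
account of the model: what is computed, which knobs matter, which design
decisions were genuinely open and how they were settled, and where the
model's numerical behaviour needs care.

## The model

### Environment

The environment is a set of $n$ generic situations that differ only in
the fitness change $z_i$ they can cause and in how often they occur. The
$z_i$ form an evenly spaced inclusive grid on $[-2, 2]$ (a design choice;
any symmetric placement would do, and an even grid keeps the set
symmetric and reproducible). The base encounter frequency is the standard
normal density $p_i = e^{-z_i^2/2}/\sqrt{2\pi}$: common situations carry
small stakes, rare ones large stakes. The density is used literally, not
renormalised, so $q$ below is an encounter *rate* per period (it may
exceed 1), never a probability.

Agents modify their own environment: effort $\phi_i$ rescales encounter
frequencies exponentially,
$$q_i = A^{\phi_i} p_i, \qquad A = 5,$$
so $\phi_i = 1$ makes a situation five times more frequent and
$\phi_i = -1$ five times rarer.

### Within-lifetime dynamics

Each lifetime lasts $m$ periods, starting *naive*: predictions
$\lambda$, reinforcement $R$, and effort $\phi$ all zero. Within a period
the order of computation is fixed and matters:

1. encounter frequencies $q_i = A^{\phi_i} p_i$ from **current** effort;
2. outcome probabilities $b_i = \mathrm{logistic}(G_i + R_i)$ from the
   heritable instinct and current reinforcement (the alternative,
   nullifying behaviour has probability $1-b_i$ and no consequences);
3. prediction errors $\varepsilon_i = V_i - \lambda_i$ against the
   heritable cue value;
4. weighted errors $\omega_i = b_i q_i \varepsilon_i$ — the single
   learning and affect signal;
5. the period's reflective wellbeing and fitness increment
   $\sum_i b_i q_i z_i$ from these pre-update quantities;
6. the updates, all driven by this period's $\omega$:
   $\lambda' = \gamma_e \lambda + \alpha_e \omega$,
   $R' = \gamma_g R + \alpha_r \omega$, and the effort step.

Computing observables before any update, and driving every update with
the same period's $\omega$, is the only ordering under which the three
update rules share one signal; it is asserted against an independent
scalar oracle at tolerance $10^{-12}$ in the test suite.

Effort is budgeted: while $\sum_i |\phi_i| < \kappa$ the unconstrained
step $\phi_i' = \phi_i + \alpha_c \omega_i$ applies to every situation
(the budget is checked *before* the update). Once the budget binds, the
agent can only reallocate: 20 pairwise decisions per period, each drawing
distinct situations $i, j$ uniformly, evaluating the marginal change in
weighted prediction error of shifting one $\alpha_c$-step from $j$ to
$i$,
$$\Delta = \left(A^{\phi_i + \alpha_c s_i} - A^{\phi_i}\right)\omega_i +
  \left(A^{\phi_j - \alpha_c s_i} - A^{\phi_j}\right)\omega_j,$$
with $s_i$ the sign of $\phi_i$, and applying the shift (or its reverse
if $\Delta < 0$; nothing on a zero margin). Decisions are sequential, and
the signed sum $\sum_i \phi_i$ is conserved exactly. Two micro-choices
here were open and are fixed as follows: $s(0) = +1$, so a zero-effort
situation is not an absorbing state; and exactly one regime applies per
period — the unconstrained step below budget, reallocation at or above
it.

A consequence worth knowing: at the default parameters the budget never
actually binds. The unconstrained accumulation on a situation telescopes
to $\alpha_c \sum_k \omega_k \approx \alpha_c\,(\lambda^*/\alpha_e +
m\,(1-\gamma_e)V/\alpha_e)$, a few hundredths per situation, so a
lifetime's total absolute effort stays near 1, far below $\kappa = 8$.
Reallocation is therefore exercised in the tests through smaller budgets
rather than through default lifetimes. We considered the alternative
reading in which the 20 reallocation decisions run every period alongside
the unconstrained step; it drives total absolute effort far beyond
$\kappa$ (the decisions are not magnitude-conserving), violating the
budget's meaning, and we rejected it.

### Evolution

Only $G_i$ (instinct) and $V_i$ (cue value) are transmitted; every
lifetime starts naive. Founders draw every value from $N(0, 0.4)$.
Breeding is truncation selection: each of the $S$ offspring takes one
parent uniformly from the top 10% by lifetime fitness and one from the
top 60% (the elite pool is a subset of the mate pool, so elite-elite and
self-pairings can occur), chooses a parent independently per situation
and per trait (free recombination), clamps the chosen value to
$[-1.5, 1.5]$, and adds $N(0, 0.4)$ mutation noise. The clamp applies to
the inherited component only, so realised values can exceed the cap.
Fitness ties break by stable index order, making runs fully reproducible
from a seed.

### Wellbeing and derived statistics

Reflective wellbeing in a period is the positively valued share of
weighted prediction errors,
$$W = \frac{\sum_i \omega_i \,[\omega_i > 0]}{\sum_i |\omega_i|} \in [0, 1],$$
with $W = 0.5$ (neutral) defined for the degenerate all-zero case. The
absolute value in the denominator is required for the stated $[0,1]$
range; without it the statistic is unbounded. $W$ is scale-invariant and
monotone in each component, and the package reports the **final-period**
population mean as the headline wellbeing of a generation.

The negativity bias is summarised by the ratio of mean absolute
population-mean *unweighted* errors $\varepsilon$ over avoidance versus
approach situations. The unweighted error is used because its magnitude
is the model's proxy for emotional intensity, while $\omega$ is a
frequency-weighted learning signal. "Relatively common" situations are
operationalised as $|z| \le 1$, the denser half of the frequency curve.

### Hedonic-adaptation shock

One adapted individual lives 200 normal periods; then the base frequency
of the grid situation nearest a target $z$ (default $\pm 1.481$,
mapped to the nearest grid value) is multiplied by 20 for 40 periods and
restored for 80 more. From onset onwards reinforcement and effort are
frozen — behavioural change may not mask the affective response — while
prediction learning stays active, because it *is* the mechanism of
hedonic adaptation. The representative individual is the one with median
final-period wellbeing (a deterministic choice); the same individual
receives both shock valences. 80 post-periods are enough to watch the
post-reversal rebound decay.

## Parameters

| parameter | default | meaning |
|---|---|---|
| `n_situations` | 80 | grid size over $[-2,2]$ (unitless fitness deltas) |
| `n_periods` $m$ | 200 | periods per lifetime |
| `pop_size` $S$ | 300 | individuals per generation |
| `n_generations` | 80 | bred generations (generation 1 is the naive founders) |
| `A` | 5 | effort-to-frequency base; $>1$ so effort raises frequency |
| `alpha_e`, `gamma_e` | 2, 0.99 | prediction learning rate and retention |
| `alpha_r`, `gamma_g` | 3, 0.98 | reinforcement learning rate and retention |
| `alpha_c` | 0.01 | effort step per period |
| `kappa` | 8 | total absolute-effort budget |
| `inherit_cap` | 1.5 | clamp on the inherited component of $G$, $V$ |
| `mutation_sd` | 0.4 | mutation noise and founder SD |
| `elite_frac`, `mate_frac` | 0.10, 0.60 | truncation-selection fractions |
| `n_decisions` | 20 | reallocation decisions per constrained period |

The defaults are deliberately coarse round numbers; the model's
qualitative behaviour is robust to modest changes, and no empirical
calibration is intended. The retentions must stay close to (but below) 1:
they set the fixed points $\lambda^* = \alpha_e\bar\omega/(1-\gamma_e)$
and $R^* = \alpha_r\bar\omega/(1-\gamma_g)$ (200 and 150 times a constant
signal, verified by iteration in the tests) and the size of the residual
prediction error that survives adaptation.

## Numerical behaviour

**Fixed points and residuals.** With behaviour frozen ($b$, $q$
constant), $\lambda$ iterates a linear map with fixed point
$$\lambda^* = \frac{\alpha_e b q V}{1 - \gamma_e + \alpha_e b q},$$
approached geometrically with $|\varepsilon|$ decreasing monotonically to
the residual $|V - \lambda^*| = |V|(1-\gamma_e)/((1-\gamma_e)+\alpha_e b
q) > 0$. This residual is the model's "incomplete" hedonic adaptation:
decay guarantees wellbeing never fully returns to baseline.

**Saturation of the affect signal.** At the fixed point the weighted
error is $\omega^* = b q V (1-\gamma_e)/((1-\gamma_e)+\alpha_e b q)$,
which saturates at $(1-\gamma_e)|V|/\alpha_e$ once $b q \gg
(1-\gamma_e)/\alpha_e = 0.005$. In adapted populations both approach
situations ($bq$ of order 0.1–1) and avoidance situations ($bq$ of order
0.05) are in or near this saturated regime, so converged positive and
negative $\omega$ magnitudes are similar and the final-period population
mean of $W$ settles slightly above neutral — about 0.54 at the default
configuration (recomputed by `scripts/acceptance.R`). Substantially
higher equilibrium wellbeing would require avoidance outcomes to become
experienced at rates below ~0.005 per period, which the bounded instincts
(cap 1.5), the decaying reinforcement, and the $\kappa$-limited effort
cannot produce. The evolved negativity ratio at the same configuration is
about 6–7.

**Stability boundary.** The prediction recursion has coefficient
$\gamma_e - \alpha_e b q$; it is stable only while $\alpha_e b q <
1 + \gamma_e$. A 20-fold frequency shock to a high-probability approach
situation pushes $\alpha_e b q$ past this boundary: $\lambda$ then
oscillates divergently and the wellbeing trace saturates at its bounds
until reversal restores stability. Avoidance shocks stay stable because
$b$ is small. The five-stage hedonic pattern (baseline, deflection,
partial recovery, residual offset, post-reversal rebound) is therefore
asserted on the avoidance side, and the approach side is characterised by
its opposite deflection and faster recovery — which the half-life
statistic shows regardless of the oscillation. Users exploring approach
shocks should treat factors above $\approx (1+\gamma_e)/(2 b q_0)$ as
outside the model's smooth regime.

**Engines and RNG.** The lifetime loop exists twice: a compiled Rcpp
engine (the default, used for population evaluation) and a pure-R
reference engine. Both consume R's RNG with an identical draw protocol
(one uniform per index draw, rejection of duplicate partners), so seeded
runs agree to machine precision across engines; the tests assert
equality at $10^{-12}$ in both the unconstrained and the constrained
regime, alongside an independent scalar oracle for the period step.
Powers $A^\phi$ use `pow` in both engines for bit-level agreement.

## What the simulator does and does not emulate

All data are self-generated; the package consumes no external
measurements. The founders-plus-mutation generator reflects the study
conditions (zero-mean normal heritable values, SD 0.4) and the
environment is deliberately featureless: situations are generic,
independent, and one-dimensional. Real affective systems involve
correlated cues, multi-attribute situations, state-dependent valuation,
memory beyond exponential decay, and social transmission — none of which
are modelled. Passing tests therefore demonstrate the internal logic of
selection-shaped motivation (sign structure of evolved values, outcome
frequency asymmetry, negativity bias, hedonic dynamics), not quantitative
claims about organisms.

Test and acceptance problem sizes are the package's own choices: property
tests run a reduced configuration (40 situations, 100 periods, 50
individuals, 10 generations), which preserves every qualitative property
in seconds, while the acceptance script and the headline checks use the
full reference configuration (80/200/300/80) over five seeds.

## Known limitations

- Equilibrium wellbeing is insensitive to the effort mechanism (see the
  saturation analysis above); interventions on `kappa`, `A`, or
  `alpha_c` move fitness far more than wellbeing.
- The literal reallocation margin multiplies a frequency difference by
  $\omega$, which already contains a factor $A^\phi p$; a
  dimensionally cleaner alternative would be $\omega(A^{\pm\alpha_c}-1)$.
  The literal form is kept deliberately and flagged here.
- Strong approach shocks leave the smooth regime (stability boundary
  above).
- No diploidy, dominance, overlapping generations, mutation-rate
  evolution, or frequency-dependent selection; encounters and outcomes
  are expectation-weighted, not sampled events, so the only stochasticity
  within a lifetime is the reallocation pair draw.
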