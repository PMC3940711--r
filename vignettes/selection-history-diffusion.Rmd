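---
title: "Modeling selection history in pop-out search with the Ratcliff diffusion model"
author: "seldiff"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling selection history in pop-out search}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seldiff)
```

## The model

In a three-item colour-oddball saccade task the decisive computation is
which of the two display colours is the target colour. `seldiff` models
that decision as a drift-diffusion process: evidence starts at $z$,
accumulates with mean drift $v$ and within-trial standard deviation $s$,
and is absorbed either at the target-colour boundary $a$ (a correct
saccade) or at the distractor-colour boundary $0$ (an error). The observed
saccade latency is the absorption time plus a non-decision time $T_{er}$.
Three trial-to-trial variability components complete the full model:
drift varies across trials as $\mathcal N(v, \eta^2)$, the starting point
as $\mathcal U(z \pm S_z/2)$ and the non-decision time as
$\mathcal U(T_{er} \pm S_t/2)$.

The scientifically meaningful parameterisation of the starting point is
the relative bias $B = z/a$: $B = 0.5$ is unbiased, $B > 0.5$ favours the
target colour. `rdm_params()` therefore carries $B$, and $z = Ba$ is
formed only at the boundary to the Wiener-level numerics.

Selection history enters through a constraint scheme. Conditions are
classified by the preceding trial: search repeated (SRe) and search
switched (SSw) form the priming-of-pop-out family; target-colour
previewed (TP) and distractor-colour previewed (DP) form the
distractor-preview family. Within a family the preceding trial is
identical, so boundary separation and non-decision time are shared
($a_{POP}, T_{POP}$ and $a_{DPE}, T_{DPE}$), while bias and drift are
antisymmetric offsets: $B = 0.5 \pm \Delta B$ and $v = v_0 \pm \Delta v$
with the positive sign for the facilitated member (SRe, DP). With shared
$S_z, S_t, \eta$ this gives the 12-parameter full model
(`full_model_params()`, `expand_condition()`). Eight sub-models constrain
one or two of these parameters (`submodel_specs()`); each removed or
shared parameter reduces the optimiser dimension and the AIC/BIC count
$M$ by one.

## First-passage numerics

The Wiener first-passage density at the lower boundary is evaluated in
normalised coordinates ($w = z/a$, $\tau = t s^2/a^2$) with the classical
pair of series: the method-of-images (small-time) series below
$\tau = 0.1$ and the trigonometric (large-time) series above it, both
adaptively truncated with term bounds below $10^{-13}$, which keeps the
absolute density error well under $10^{-7}$. The upper boundary follows
by reflection ($v \to -v$, $z \to a - z$).

The distribution function never requires quadrature: the large-time
series integrates term by term in closed form,
$$F_0(t) = P_0 - \pi e^{-\tilde v w} \sum_{k\ge1}
  \frac{2k \sin(k\pi w)}{\tilde v^2 + k^2\pi^2}
  e^{-(\tilde v^2 + k^2\pi^2)\tau/2},$$
with $\tilde v = va/s^2$ and $P_0$ the closed-form absorption
probability, computed via `expm1` and switched to its series expansion
below $|2va/s^2| < 10^{-8}$ to avoid $0/0$ at vanishing drift. The series
converges for every $\tau > 0$; below $\tau = 10^{-7}$ the absorbed mass
is treated as zero. Inside the fitting loop the $\exp(-k^2 c)$ and
$\sin(k\pi w)$ sequences are advanced by multiplicative and Chebyshev
recurrences rather than per-term transcendental calls.

The variability integrals use Gauss–Hermite quadrature for $\eta$
(24 nodes by default) and Gauss–Legendre for $S_z$ and $S_t$ (12 nodes
each); the fit objective uses 20/10. Refining to 48/40 changes predicted
bin masses by about $10^{-4}$ at reference parameters, an order of
magnitude below the sampling noise of any quantity the package tests.
$S_t$ enters exactly as an average of shifted distribution functions.

## The scaling constant

All parameter containers carry an explicit diffusion coefficient `s`
defaulting to 1; only the ratios $va/s^2$, $z/a$ and $ts^2/a^2$ matter,
so `s` fixes the unit of the evidence scale and every routine is exact
for any value. The bundled reference table
(`reference_parameters()`) was estimated under the fitting-toolbox
convention $s = 0.1$, and only under that convention do its boundary
separations ($a \approx 0.06{-}0.12$) and drifts ($v \approx 0.5{-}0.8$)
reproduce the observed 94–100% accuracies and ~300 ms latencies of the
task; read at $s = 1$ the same numbers would imply near-chance accuracy.
`reference_full_params()` therefore returns the values with `s = 0.1`,
and fits or simulations at those values must use the same scaling.

## The synthetic-data stage

The generator emulates the study design. Each 32-trial set contains
eight designed pairs — the four conditions crossed with the two
distractor colours — in random order, so twelve of the sixteen designed
trials are target-present and four target-absent. Sixteen filler trials
are then inserted: the design description leaves their composition
partly open, and we read it as eight target-absent trials (four per
colour) and eight target-present trials (four per distractor colour),
placed uniformly at random in the nine gaps between pairs so that no
pair is ever split. Blocks hold two sets (64 trials), sessions five
blocks, and the default five sessions give exactly 1600 trials per
subject.

Condition labels are re-derived from the emitted displays by
`classify_trials()`, which looks only at each trial's immediate
predecessor within its block; the first trial of a block has no usable
predecessor (a drift-correction intervenes between blocks) and stays
unlabelled. Because fillers also create labelable transitions, a session
yields roughly 57/58/43/40 SRe/SSw/TP/DP trials — more than the ~32/36/26/24
analysed per session in the original study, whose exclusion rules are not
fully specified. The surplus makes synthetic recovery slightly easier
than the real data would be, which should be kept in mind when reading
recovery results.

Trial outcomes are drawn by an Euler–Maruyama integrator (default step
0.1 ms) with the Broadie–Glasserman/Gobet continuity correction: the
absorbing boundaries are pulled inward by $0.5826\,s\sqrt{dt}$, which
cancels the leading $O(\sqrt{dt})$ discrete-monitoring bias. At reference
parameters, halving the step changes mean latency by well under 1 ms, and
$10^6$ simulated trials sit within one binomial standard error of the
analytic response probability with a Kolmogorov distance below $10^{-3}$.
Target-absent trials receive Bernoulli false alarms (default rate 0.02,
per-subject configurable to the observed 0.6–10.6% range) and carry no
diffusion latency; the model addresses only the four search conditions.
Unlabelled target-present trials are simulated from an unbiased parameter
set ($B = 0.5$, $v = v_0$, POP-family $a$ and $T_{er}$) and excluded from
fitting — a block's first trial has no preceding trial, so no
condition-specific parameter set can apply to it.

What the generator does *not* emulate: display geometry and timing
(ellipse positions, foreperiods, the 600 ms absent-display duration),
blinks and fixation failures, post-error effects, and any contaminant
latency process. Passing recovery tests therefore show that the pipeline
is self-consistent at realistic parameters, not that real data are free
of these complications.

## Fitting

Latencies more than five standard deviations from the per-subject mean
(mean and SD from the full set of labelled target-present trials, one
pass) are discarded. Per condition, the correct-latency
10/30/50/70/90% quantiles are estimated by linear interpolation between
order statistics (type-7, the common default; the convention is a choice
— the original toolbox does not document its estimator). The observed
cell masses are $(0.1, 0.2, 0.2, 0.2, 0.2, 0.1) \times$ accuracy for the
six correct bins plus the error rate; expected masses come from
`bin_probabilities()`, floored at $10^{-5}$ so no cell divides by zero;
the error cell is dropped for a condition with perfect accuracy. The
objective sums $N(p_{obs}-p_{exp})^2/p_{exp}$ over the (up to) 28 cells.

The optimiser works on an unconstrained vector of dimension $M$:
logistic transform for the bias deltas (keeping $|\Delta B| < 0.5$), log
transforms for $a$, $S_z$, $S_t$, $\eta$ and for the gap
$T_{er} - S_t/2$ (keeping the minimum non-decision time nonnegative),
identity for drifts. Parameter vectors that still violate an invariant
(for instance $S_z$ exceeding $2\min(B, 1-B)a$ in some condition)
receive a large finite penalty, keeping derivative-free search
in-domain. Starting values come from a method-of-moments heuristic
($T_{er}$ from the fastest latency, normalised drift from overall
accuracy through the logistic form of the absorption probability, $a$
from the mean decision time); `n_restarts` simplex runs start from the
heuristic and jittered copies, and the best endpoint is polished by a
quasi-Newton (`nlminb`) run. The polish matters: in 12 dimensions the
simplex reliably finds the right basin but stalls about one chi-square
unit short of the minimum, and the quasi-Newton finisher recovers it.
Fits are deterministic given `seed`.

Degrees of freedom are $J(K-1) - M - n_{dropped}$ ($J = 4$ conditions,
$K = 7$ cells), and a fit is adequate below the $1-\alpha$ chi-square
quantile (`critical_chisq()`, 21.026 at 12 df and 19.675 at 11 df for
$\alpha = 0.05$). For AIC/BIC the likelihood is the multinomial
likelihood of the observed bin counts under the model's bin masses —
the same binning as the chi-square objective, the only construction
self-consistent with it — with $n$ = the subject's fitted trial count
in the BIC penalty.

## Recovery experiments and problem sizes

The package's end-to-end checks run at deliberately chosen sizes:

- *Simulator/analytic agreement*: $10^5$ trials at three reference
  parameter sets, compared by binomial error and a one-sample
  Kolmogorov–Smirnov test at $\alpha = 0.01$.
- *Parameter recovery*: ten seeded 1600-trial subjects generated at the
  P1 reference values and fitted with the full protocol. Across seeds
  the fitted $\Delta B_{POP}$ spreads with SD $\approx 0.034$ around the
  generating 0.1437; the weakly identified $\eta$ absorbs part of the
  sampling noise and couples with the bias deltas, which is the dominant
  contribution to that spread.
- *Chi-square calibration*: the same ten fits, compared with the
  df-matched critical value. With twelve free parameters the minimised
  statistic is approximately $\chi^2_{12}$; even a perfectly calibrated
  fit exceeds the 5% critical value in one seed out of ten reasonably
  often, so results of this check should be read with its binomial
  resolution in mind.
- *Model recovery*: ten replications of a three-subject study (P1, P2,
  P5) generated with both drift deltas set to zero, each subject fitted
  with the full and the drift-constrained model under a reduced
  optimisation budget, and compared by summed AIC. Three subjects is a
  conservative reduction: the expected summed-AIC margin scales with the
  subject count, so the preference for the true (constrained) model is
  harder, not easier, to detect than with five.

## Known limitations

- The model is a two-boundary race between colour assignments; the
  location decision among three items is not represented.
- $\eta$, $S_z$ and $S_t$ are weakly identified at the high accuracies
  typical of this task; group-level conclusions about them should rely
  on sign patterns, not point estimates.
- The Gaussian drift variability is untruncated, so a small mass of
  trials has negative effective drift; this matches common practice but
  is an assumption, not a measurement.
- The quantile chi-square statistic is only asymptotically chi-square
  distributed; its finite-sample exceedance rate at the 5% critical
  value can be slightly above 5%.
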