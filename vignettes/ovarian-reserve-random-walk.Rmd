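---
title: "Modelling ovarian reserve decay and menopause timing with random walks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling ovarian reserve decay and menopause timing with random walks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ovawalk)
```

## The model

The human ovarian reserve is a pool of dormant primordial follicles (PFs)
laid down around birth.  A follicle leaves the reserve when it commits to
growth (growth activation) or dies beforehand; menopause follows once the
reserve falls below roughly a thousand follicles.  `ovawalk` models the
per-follicle decision as a one-dimensional random walk of Integrated Stress
Response (ISR) activity $X(t)$: high activity holds the pregranulosa cells
in cell-cycle arrest, and the follicle activates when $X$ first reaches the
growth threshold at $0$, or dies if $X$ first reaches a death threshold at
$L$.  In discrete form the activity takes steps of size $\Delta x$ every
$\Delta t$ years, upward with probability $p$; for small steps this is the
drift–diffusion process

$$dX = -V\,dt + \sqrt{2D}\,dW, \qquad
  D = \frac{(\Delta x)^2}{2\Delta t}, \quad
  V = \frac{2\Delta x}{\Delta t}\Bigl(\tfrac12 - p\Bigr),$$

with diffusivity $D$ (size of the stochastic fluctuations) and drift $V$
(deterministic decrease of activity; biologically, the efficiency of
cellular repair).  The activity scale is arbitrary, so $X(0) = 1$
throughout.

With $N$ follicles at birth and independent, identically distributed exit
times $\tau$, the expected reserve is $\mathbb{E}[F(t)] = N\,P(\tau > t)$.
In the limit $L \to \infty$ the exit-time survival function is the
inverse-Gaussian-type law

$$S(t) = \Phi\!\left(\frac{x_0 - Vt}{\sqrt{2Dt}}\right)
  - e^{V x_0 / D}\,\Phi\!\left(-\frac{x_0 + Vt}{\sqrt{2Dt}}\right),$$

implemented in `fp_survival()`.  A woman's age at natural menopause (ANM)
is the first (monthly) age at which her reserve drops strictly below the
menopause threshold, 1,000 follicles by default.

### Default parameter values

| parameter | default | units | meaning |
|---|---|---|---|
| `D` | 0.004 | yr⁻¹ | diffusivity fitted to human PF counts |
| `V` | 0.051 | yr⁻¹ | drift fitted to human PF counts |
| `x0` | 1 | – | initial ISR activity (scale convention) |
| `L` | ∞ | – | death threshold; any `L ≥ 2` is practically equivalent |
| `mu`, `sigma` | 12.686, 0.497 | – | log-normal starting supply across women |
| `c` | 0 (0.03 when heterogeneous) | – | coefficient of variation of subject drift |
| threshold | 1000 | follicles | menopause definition |
| `dt` | 1/12 | yr | simulation grid: months of postnatal life |

The median starting supply is $e^{\mu} \approx 3.23\times 10^5$ follicles,
and the default decay curve crosses the 1,000-follicle threshold at an age
that rounds to 51 years — the population median ANM.

## Numerical choices

**Stable evaluation of the survival function.**  At the default parameters
$V x_0 / D = 12.75$, so the factor $e^{V x_0/D}$ multiplies a normal tail
of order $10^{-9}$ and worse; user parameters can be far harsher.  The
product is therefore evaluated as
`exp(V * x0 / D + pnorm(..., log.p = TRUE))`, never as the two factors
separately, and the death-before-activation probability
$(e^{V x_0/D} - 1)/(e^{V L/D} - 1)$ is computed in log space
(`hit_upper_probability()`).

**Finite death threshold.**  `finite_L_survival()` sums the eigenfunction
series of the two-sided absorbing problem on $(0, L)$, truncating when two
*consecutive* terms fall below $10^{-12}$ in magnitude (single-term tests
fail when $\sin(n\pi x_0/L)$ vanishes exactly, as it does for every even
$n$ at $x_0 = 1, L = 2$), with a hard cap of $10^4$ terms.

**Threshold crossing.**  `anm_from_curve()` brackets the root of
$N S(t) = \text{threshold}$ on $[0, 200]$ years, doubling the ceiling if
unbracketed, and solves to $10^{-6}$ years.

**Lattice conventions.**  The discrete simulator snaps $x_0$ and $L$ to the
nearest multiple of $\Delta x$ (refusing a start that snaps onto a
boundary), and absorbs when a step lands at or beyond a threshold.  With
$L = \infty$, occupancy propagation uses an effective ceiling placed where
the scale-function probability of ever reaching it is below $10^{-10}$.
The monthly lattice admits drifts only up to $\sqrt{2D/\Delta t}$; the
constructors refuse anything larger and report the admissible bound.

**Binomial thinning.**  For independent exit times, the reserve count is a
Markov chain with exact conditional law
$F(t_{k+1}) \mid F(t_k) \sim \mathrm{Binomial}\bigl(F(t_k),
S(t_{k+1})/S(t_k)\bigr)$, so a woman with $3\times10^5$ follicles is
simulated in ~1,400 binomial draws instead of $3\times10^5$ exit times.
Draws are made by inverting the binomial CDF at a uniform variate, so that
simulations sharing a seed are coupled monotonically: more follicles can
never mean earlier menopause, and stronger drift can never mean later.
One practical caveat discovered while validating the chain: R's `qbinom()`
carries a small upward bias when `prob` is close to 1 — precisely the
regime of monthly conditional survival ratios — which accumulates over
hundreds of steps.  The package therefore evaluates the quantile through
the complement, `size - qbinom(u, size, 1 - p, lower.tail = FALSE)`, which
is the same coupling computed in the accurate tail; with this form the
thinned chain is statistically indistinguishable from per-follicle
simulation.

**Per-follicle simulation.**  With constant positive drift and
$L = \infty$ the exit time is inverse-Gaussian
$\mathrm{IG}(x_0/V,\; x_0^2/2D)$ and is drawn by the
Michael–Schucany–Haas transform; otherwise exits come from the lattice
walk itself (compiled code).  Acute losses remove a random subset of the
follicles still in the reserve, which leaves the survivors' exit-time law
unchanged.

**Time-variant drift.**  Once drift changes mid-course no closed form
exists (the survivors' positions matter), so survival under a
piecewise-constant schedule comes from deterministic occupancy propagation
of the lattice law — the exact expectation of the walk — vectorised across
subjects in compiled code when each woman carries her own drift
multiplier.

## Design decisions

* **ANM definition.**  First monthly grid age with the reserve *strictly*
  below the threshold, reported in years; "drops below" implies strict
  crossing, and month resolution matches the simulation grid.
* **Age-38 drift boundary.**  The accelerating schedule
  `drift_schedule(38, c(0.024, 0.033))` uses left-closed segments: before
  age 38 the gentler value applies, from 38 onward the faster one.
* **Two drift parameterisations.**  The fitted constant drift
  (0.051 yr⁻¹ with $D = 0.004$) and the accelerating schedule
  (0.024/0.033 yr⁻¹) are alternative configurations on different activity
  scales; combined naively with $D = 0.004$ the schedule's decay curve
  never reaches the menopause threshold for most women.  The schedule's
  diffusivity is therefore anchored by `calibrate_diffusivity()`, which
  solves for the $D$ putting the median-woman crossing at a target age
  (51 years by default).  With that single anchor, the model *predicts*
  the remaining features of the accelerating-drift condition: a narrower
  ANM distribution than under subject-variable constant drift, and no
  simulated menopause after age 62.
* **Negative sampled drift.**  Subject drift multipliers $1 + cY$ are kept
  un-truncated (the normal model is taken at face value; at $c = 0.03$ a
  negative drift has probability $\approx \Phi(-33)$), but any occurrence
  triggers a warning.
* **Acute losses** are parameterised by a surviving *fraction* applied at
  the first grid age at or after the event, since published illustrations
  of chemotherapy-style losses do not fix an absolute magnitude.
* **Quantile decay curves** written by `run_population_command()` are
  expected trajectories $N_q\,S(t)$ for supply quantiles
  $N_q = e^{\mu + \sigma z_q}$, not stochastic realisations.
* **Supply counts** are rounded to integers (follicles are discrete), and
  the log-normal fit uses the maximum-likelihood ($n$-denominator)
  standard deviation of the logs.
* **Estimation.**  $(D, V)$ are fitted by bounded L-BFGS-B on
  $(\log D, \log V)$ from a 5×5 log-spaced multi-start grid, with the
  starting supply held fixed (estimated first from counts near birth);
  the objective is the sum of squared errors on natural-log counts, using
  postnatal ages only.  The fit is deterministic given the data.

## What the synthetic data emulate — and what they do not

`generate_synthetic_counts()` draws counts from the package's own decay
curve under multiplicative log-normal noise.  That is exactly the right
instrument for parameter-*recovery* testing (the generating truth is
known), and it mimics the order-of-magnitude scatter of histological
follicle counts.  It does not emulate the features that make real
histological datasets hard: non-random specimen ascertainment at older
ages, counting error that varies with age, prenatal dynamics before the
decay model starts, or model misspecification itself.  Passing recovery
tests therefore demonstrates that the estimator works when the model is
true — not that the model is true of any particular dataset.  Likewise the
simulated ANM distributions inherit every modelling assumption (iid exits,
a sharp 1,000-follicle threshold, log-normal supply), so their agreement
with published population statistics is a consistency check, not external
validation.

## Problem sizes

The test suite exercises the headline results at the study's full sizes —
$10^4$ simulated women for population distributions, $10^5$ lattice walks
at $\Delta t = 10^{-3}$ yr for the Monte-Carlo/closed-form comparison, 50
replicate fits for noisy parameter recovery — and uses smaller
configurations (a few hundred subjects, $10^4$–$2\times10^4$ walks) for
unit-level properties, chosen so that three Monte-Carlo standard errors
still separate signal from noise.

## Known limitations

* The model treats growth activation as a single-unit decision; granulosa
  cell multiplicity, post-activation atresia and menstrual cyclicity are
  out of scope.
* The survival series for a finite death threshold converges slowly for
  ages far below a month; `finite_L_survival()` is intended for the
  year-scale ages at which the threshold question arises.
* Fitting assumes the starting supply is known (or estimated separately);
  the optional joint three-parameter fit is provided but the two-stage
  procedure is the documented default.
* Published empirical ANM tables are third-party data; `compare_ecdf()`
  accepts any user-supplied table rather than bundling digitised values.
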