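---
title: "Methods: stratification, estimation and dynamics of the MDD vulnerability model"
author: "mddvuln"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stratification, estimation and dynamics of the MDD vulnerability model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mddvuln)
```

## The model and its assumptions

`mddvuln` models movement of an adolescent population between three
mental-health compartments: high MDD vulnerability (fraction $x$), low
vulnerability ($y$) and complete mental health ($z$):

$$\frac{dx}{dt} = a\mu - \mu x + \epsilon x y - \alpha x$$
$$\frac{dy}{dt} = b\mu - \mu y - \epsilon x y + \alpha x - \delta y z + \beta z$$
$$\frac{dz}{dt} = c\mu - \mu z + \delta y z - \beta z$$

The assumptions baked into this form:

* **Constant turnover.** Individuals enter at 15 and leave at 23 at the
  same per-capita rate $\mu$, splitting on entry into the three groups
  with probabilities $a$, $b$, $c$. There is no demographic growth.
* **Mass-action peer pressure.** Negative peer pressure moves the
  low-vulnerability group toward high vulnerability at rate
  $\epsilon x y$ (contacts with V1), positive peer pressure moves it
  toward complete mental health at rate $\delta y z$ (contacts with M).
* **Linear lifestyle flows.** Physical exercise drains V1 into V2 at
  per-capita rate $\alpha$; technology use drains M into V2 at rate
  $\beta$. Both are one-directional by construction.
* **No internal field.** Endogenous factors (genetics, trauma) are
  outside the model: only the four "nonclinical intervention" channels
  act on the symptom network.

Summing the equations gives the conservation law
$d(x+y+z)/dt = \mu\big((a+b+c) - (x+y+z)\big)$: the total fraction
relaxes toward $a+b+c$ at rate $\mu$. With the reference estimates
$a+b+c \approx 0.801$, so the model as printed does **not** preserve the
simplex $x+y+z=1$; see "Normalization" below.

## Stratification

Four questionnaire totals feed the stratification: SWB (SWLS, 5–35) and
the TMMS subscales EQ-A, EQ-C, EQ-R (8–40 each). Each is cut into
low / adequate / high with sex-specific thresholds for EQ-A and EQ-C.
One threshold in the published table cannot be taken literally: the
female EQ-A "low" bound is printed as $\le 36$, overlapping "high"
($\ge 36$); the only value that preserves a partition against the
adequate range 25–35 is $\le 24$, and that is what `default_scheme()`
encodes. Scores must be integers; non-integers are rejected rather than
rounded, because a half-point Likert total indicates an upstream scoring
error, not measurement noise.

The $3^4 = 81$ level combinations ("superposed states") are totalled
with **representative level scores** and banded: total $> 120$ complete
mental health, $100$–$120$ (inclusive) low vulnerability, $< 100$ high
vulnerability. The inclusive reading of the middle band is the only one
that makes the three rules exhaustive and exclusive on integers.

The representative scores themselves are not published — only the
constraints that the all-low state totals 80, the all-high state 140,
and that 1/50/30 states fall in the three bands. The default here takes
the midpoint of each male level range (open ranges capped at instrument
bounds) and rescales each variable affinely so low maps to 20 and high
to 35. Male ranges anchor the midpoints because the published
level-score map is sex-invariant while two variables' thresholds are
not, so one sex's ranges had to be chosen; the choice only shifts the
adequate-level representatives by fractions of a point. This default
need not reproduce the published 1/50/30 split: it yields 16 complete /
50 low / 15 high (the low-vulnerability count coincides, the tails do
not) — the basis for the printed split is unspecified, so the package asserts
the partition and monotonicity properties of the banding instead, and
`level_scores` is user-configurable through the scheme file for anyone
wishing to explore maps that do.

## Parameter estimation

All estimation arithmetic follows the reference procedure exactly, in
full precision, rounding only for display:

| Parameter | Default / procedure | Units |
|---|---|---|
| $\mu$ | canonical constant 0.00342 | /day |
| $a,b,c$ | (band fraction / $\mu$) / 365 | — |
| $\delta$ | 5 contacts/day × 1/10 needed = 0.5 | /day |
| $\epsilon$ | 5 contacts/day × 1/25 needed = 0.2 | /day |
| $\alpha$ | mean(0.5108, 0.5765 h) × 30 d / 24 h | /day |
| $\beta$ | mean(0.8667, 1.3551 h) × 15 d / 24 h | /day |

Hour weights are 1 / 0.5 / 0.15 h for the high/medium/low exercise
categories and 2 / 1 / 0.3 h for technology use; persistence windows
(how long the behaviour must be sustained to switch compartments) are
30 days for exercise and 15 for technology. All are overridable via
`est_config()`.

Three arithmetic quirks of the source chain are preserved deliberately
rather than silently corrected:

* $\mu$: the stated derivation $1/(8 \times 365)$ equals 0.000342, but
  0.00342 is what all downstream numbers use. `estimate_mu()` returns
  the true arithmetic; `mu_canonical` supplies the reference constant,
  and the estimation defaults use the latter because reproducing the
  published table requires it.
* $a$ and $c$: recomputation gives 0.3105/0.31055 and 0.0106 against
  printed 0.3104 and 0.0105 — last-digit slips, asserted in tests at
  ±0.0002 and ±0.0001.
* $x = 88/227 = 0.38766\ldots$ is printed as 0.3876 (truncated);
  the package rounds half-up, giving 0.3877 for display.

## Numerical choices

* **Integrator**: `deSolve::ode` with lsoda (adaptive, stiff-capable),
  `rtol = 1e-8`, `atol = 1e-10`, dense output on a fixed grid. The
  system is deterministic; no seeds are involved.
* **Steady state**: the state at `t_end` with terminal
  $\|f\|_\infty < 10^{-8}$. When no horizon is given, the horizon
  doubles from 100 days until the check passes (cap $2 \times 10^5$
  days). The slowest mode is the compartment-sum relaxation at rate
  $\mu$, so unnormalized runs need a few thousand days to converge;
  within-simplex modes settle in tens of days.
* **Time unit** is days throughout, because every estimated rate is
  per day (trajectory figures elsewhere labelled in seconds
  notwithstanding).
* **Equilibrium cubic**: coefficients evaluated exactly as printed;
  roots via companion-matrix eigenvalues, with complex parts below
  $10^{-9}$ (relative) treated as real. A degenerate cubic
  ($A = \epsilon\delta = 0$) falls back to the quadratic/linear
  solution with a warning. Admissibility defaults to $[0, 1]$;
  `admissible_max = a+b+c` is available for unnormalized work.
* **Normalization**: the equilibrium cubic is derived under
  $x+y+z = 1$, which conflicts with $a+b+c \approx 0.801$. The model
  integrates as printed by default; `normalize_entry = TRUE` rescales
  $(a,b,c)$ to sum to 1 for analyses that rely on the simplex (the
  cubic/integrator cross-validation does, and then the smallest
  admissible root matches the terminal $y$ to $10^{-5}$).
* **Eigenvalues**: closed forms $-(\mu+\alpha)$, $-\mu$,
  $-(\mu+\beta+\delta)$. The third is sometimes written
  "$-\mu+\beta+\delta$"; the trace and determinant of the Jacobian's
  2×2 block force the negative sign (the block's discriminant collapses
  to $(\delta+\beta)^2$, giving $-\mu$ and $-(\mu+\beta+\delta)$
  exactly). The literal expression survives as `r0_literal` because it
  is also the printed definition of $R_0$; the alternative bound
  $\delta(\mu+\alpha)/\epsilon$ is `r0_bound`. With the reference
  parameters `r0_literal` $\approx 1.19 > 1$ while every eigenvalue is
  negative — the report flags this tension in its notes and takes no
  position on which expression is "the" reproduction number.

## The synthetic-cohort generator

No raw questionnaire data are deposited for the reference study, so the
package generates cohorts itself.

`reference_cohort()` is a deterministic, sampling-free fixture that
reproduces every published marginal: 227 records, 99 female / 128 male,
band split 88/136/3, exercise counts 32/13/43 (high band) and 60/20/56
(low band), technology counts 63/52/21 (low band) and 1/0/2 (complete
band). Whatever was never published is a documented synthetic fill:
high-band technology and band-wise sex counts by deterministic
largest-remainder proportional allocation, one record per exercise
category in the complete band, scores fixed at level representatives
valid under both sexes' thresholds, ages the truncated-normal quantile
sequence for mean 18.58 / SD 0.29.

`generate_cohort()` draws random cohorts under configurable marginals:
states uniform within the target band, integer scores uniform within
the sex-appropriate level ranges, ages truncated-normal on [15, 23] by
inverse-CDF sampling, categories either to exact per-band tables or
uniformly when unspecified. Generation and classification are mutually
consistent by construction — every record classifies back into its
intended band.

What the generator does **not** emulate: psychometric correlations
between SWB and the EQ subscales beyond shared band membership,
item-level response behaviour, sex differences in lifestyle categories,
and any exercise×technology association within bands. Tests passing on
these cohorts therefore validate the pipeline's arithmetic and
invariants, not the field realism of the questionnaire distributions.

## Problem sizes used by the test suite

Desk scale throughout, as the package's own verification budget:
property loops use 25–50 random draws (300 for eigenvalue agreement in
the unit suite, 1000 in the end-to-end suite, at $10^{-10}$); trajectory
checks integrate 100–500 days on unit grids, with adaptive runs
converging by ~6400 days; sweeps use 5–8 grid points. The full suite
runs in well under a minute.

## Known limitations

* The three-group banding rests on representative level scores that the
  source never disclosed; per-participant banding by the default map is
  faithful to the thresholds but the 81-state band split is a modelling
  choice, not a reproduction.
* $a+b+c \ne 1$ under the reference estimates, so long-horizon totals
  drift to 0.801 unless entries are normalized; equilibrium statements
  mix the two conventions and must be read with the `normalize_entry`
  flag in mind.
* The two $R_0$ expressions are mutually inconsistent and neither
  predicts the observed stability; both are surfaced as provenance, not
  endorsed.
* No uncertainty quantification: the estimation chain is deterministic
  arithmetic on counts, and the source provides no variance model to
  propagate.
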