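# mddvuln

Compartmental modelling of adolescent vulnerability to major depressive
disorder (MDD).

## The problem

School- and college-based mental-health programmes need a way to triage
adolescents by MDD risk using nothing more than short questionnaires, and
to reason quantitatively about which *nonclinical* interventions — peer
interaction, physical exercise, limiting technology use — keep a
population out of the high-risk group. `mddvuln` implements such a
workflow for researchers in psychiatric epidemiology and mathematical
population modelling:

1. **Stratification.** Subjective well-being (Satisfaction With Life
   Scale) and the three Trait Meta-Mood Scale subscales (Attention,
   Clarity, Repair) are each cut into low / adequate / high levels with
   sex-specific thresholds, giving 3⁴ = 81 superposed states. Each
   state's representative total (80–140 points) assigns it to one of
   three bands: **high vulnerability (V1)** below 100, **low
   vulnerability (V2)** at 100–120, **complete mental health (M)** above
   120.

2. **The compartment model.** With x = V1/N, y = V2/N, z = M/N, the
   population moves between bands according to

   ```
   dx/dt = aμ − μx + εxy − αx
   dy/dt = bμ − μy − εxy + αx − δyz + βz
   dz/dt = cμ − μz + δyz − βz
   ```

   where μ is the per-capita rate of entering/leaving the adolescent
   system; a, b, c the entry probabilities into V1, V2, M; ε and δ the
   negative and positive peer-pressure contact rates (V1 pulling V2 up,
   M pulling V2 down); α the physical-exercise rate moving V1 → V2; and
   β the technology-use rate moving M → V2. All rates are per day.

3. **Estimation.** Every parameter is estimated from cohort summaries:
   entry probabilities from the band fractions ((fraction/μ)/365),
   peer-pressure rates from contact assumptions (contacts/day ×
   conversion probability), and α, β from weighted-mean daily hours of
   exercise/technology per band scaled by persistence windows
   (`mean(h₁, h₂) · days / 24`).

4. **Analysis.** Trajectory integration (stiff-capable lsoda), parameter
   sweeps, the equilibrium cubic in y (A y³ + B y² + C y + D = 0) with
   Vieta sums and positivity conditions, the Jacobian at the
   disease-free equilibrium (0, 0, 1) with closed-form eigenvalues
   −(μ+α), −μ, −(μ+β+δ), and both of the reproduction-number
   expressions that circulate for this model (reported side by side;
   they disagree, and the package does not adjudicate).

A synthetic-cohort generator reproduces the marginal structure of the
227-adolescent reference study (88/136/3 band split, 99 F / 128 M,
printed exercise and technology category counts), so the whole pipeline
runs end-to-end with no external data.

## Worked example

```r
library(mddvuln)
fit <- mdd_model(reference_cohort())
fit
#> Three-compartment MDD vulnerability model
#>
#> Call:
#>   mdd_model(cohort = reference_cohort())
#>
#> Cohort: n = 227 (V1 = 88, V2 = 136, M = 3)
#> Fractions (x, y, z): 0.3877, 0.5991, 0.0132
#>
#> Three-compartment MDD vulnerability model parameters (/day):
#>      mu       a       b       c   delta epsilon   alpha    beta
#>  0.0034  0.3106  0.4799  0.0106  0.5000  0.2000  0.6795  0.6943
```

88 of 227 adolescents (x = 0.3877) classify as highly vulnerable and
136 (y = 0.5991) as low-vulnerability; roughly 31% and 48% of entrants
arrive directly in those groups (a, b). Exercise moves people out of
the high-risk group somewhat faster than technology use erodes complete
mental health (α = 0.6795 vs β = 0.6943 per day, nearly balanced).

```r
summary(fit)$stability
#> Stability of the disease-free equilibrium (0, 0, 1)
#>   eigenvalues (closed form): -0.682961, -0.00342, -1.19774
#>   stable: TRUE
#>   R0 (literal -mu+beta+delta): 1.1909
#>   R0 bound (delta(mu+alpha)/epsilon): 1.7074
#>   ...
predict(fit)
#> Compartment trajectory: 6401 points over 6400 days
#>   terminal (x, y, z) = (0.002030, 0.798938, 0.000121)
#>   terminal |f|_inf = 2.12e-13 (steady)
```

All three eigenvalues are negative, so the disease-free state is locally
stable; the integrated cohort stabilizes with the low-vulnerability
fraction rising to ≈0.80 while the high-vulnerability and complete
fractions decay — the qualitative picture the model predicts under the
reference parameters. Sweeps reproduce the intervention story:

```r
sweep_terminal(reference_parameters(), "alpha", seq(0.3, 1.2, 0.15), t_end = 400)
# terminal x falls and y rises monotonically as exercise increases
```

A config-driven run writing CSV/JSON reports plus a digest manifest:

```r
run_pipeline(list(cohort = list(reference_fixture = TRUE), out_dir = "out"))
```

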