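---
title: "The independent multimutation model of disease age of onset"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The independent multimutation model of disease age of onset}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mmonset)
```

## The model and its assumptions

`mmonset` implements an accumulation ("multimutation") model of disease age
of onset. A fraction $f_s$ of a birth cohort is born susceptible; a
susceptible individual must undergo $m$ independent internal changes, each
arriving after an exponential waiting time, and onset coincides with the last
arrival. With $m_1 = m - 1$ changes at rate $k_1$ and one at rate $k_2$, the
susceptible prevalence — the onset CDF conditional on susceptibility — is

$$P_s(t, r) = \left[1 - e^{-r k_1 t}\right]^{m_1}\left[1 - e^{-r k_2 t}\right],$$

where $r$ is a dimensionless *biological clock rate* multiplying every rate,
so that $P_s(t, r) = P_s(rt, 1)$ exactly. Population prevalence is
$f_s P_s(t,r)$; the incidence rate is the analytic derivative of the closed
form (`incidence_rate()` never uses finite differences — a central-difference
oracle appears only in the tests).

Key assumptions, all load-bearing:

* **Independence.** The $m$ waiting times are mutually independent, and —
  for twins — the co-twin's onset process is independent of the index
  twin's *given* susceptibility. Discordance at a finite age therefore
  carries no environmental signal in this model.
* **Homogeneity.** All susceptible individuals share the same rates; cohorts
  differ only through the scalar clock rate $r$.
* **Two rate classes.** The general model allows $m$ distinct rates; only
  the two-rate family above is implemented, because it is the family the
  reference analyses actually fit. The degenerate single-rate ("3-parameter")
  model is the $k_2 = k_1$ boundary.

### Parameters

| parameter | meaning | units | default |
|---|---|---|---|
| `m1` | changes at rate `k1`; total $m = m_1 + 1$ | count | — |
| `k1`, `k2` | mutation rates | per year | — |
| `f_s` | lifetime-susceptible fraction | probability | 1 |
| `r` | clock rate | dimensionless | 1 |

The packaged reference sets (`usa_model_params()`) are the fits to USA
first-hospital-admission cumulative incidence: pooled and sex-stratified
4-parameter fits share $m = 16$; the 3-parameter male fit has $m = 10$ with
one rate. A note on bookkeeping: the single-rate model is stored as
$m_1 = m - 1$ with $k_2 = k_1$, so its closed form is
$[1-e^{-kt}]^{m}$ with the same code path as the two-rate model.

Derived summaries: the incidence peak (`peak_onset_age()`; the male and
female reference curves peak in the mid-to-late twenties and around thirty,
respectively, reproducing the known later onset in females), the windowed
mean onset age (`mean_onset_age()`), and the per-class mean waiting times
$T_i = 1/(r k_i)$ (`mutation_mean_times()`). For the female reference set
this yields $T_2 = 1/k_2 \approx 28.0$ y; a published rendering of this
quantity as 30.0 y is not the reciprocal of the published rate, and the
package reports the reciprocal.

## Twin-cohort algebra

Twin studies observe only pairs with at least one affected member. Splitting
each pair randomly across two subcohorts, the probability that randomly
chosen members of the two subcohorts are both affected, conditional on at
least one being affected, is the **subcohort concordance**

$$C_M = \frac{P_s^2}{P_s^2 + 2P_s(1-P_s)} = \frac{P_s}{2 - P_s}$$

for monozygotes. This is deliberately *not* the pairwise or probandwise
concordance of the broader twin literature; the package documents and names
the distinction. A historically printed variant $P_s(2-P_s)$ is algebraically
the *first-onset* distribution $P_{sx}^{+} = 1-(1-P_s)^2$ — the probability
that at least one member has onset — a genuinely different quantity kept
separate in `mz_state_probabilities()`. The ratio form is the one consistent
with its own inversion $P_s = 2C_M/(1+C_M)$ and with every derived value in
the shipped study table, which is why it is the implemented concordance.

For dizygotes the cotwin inherits susceptibility with probability
$S_{\mathrm{inher}}$, giving

$$C_D = \frac{S\,P_s}{1 + S - S\,P_s},$$

which plateaus at $S$ as $P_s \to 1$ (MZ concordance saturates at 1).
Inversions: `s_inher_from_prevalence()` and, eliminating $P_s$,
`s_inher_from_concordances()`. `fraction_unable()` is $1 - S$; the pooled
headline over a study table is its minimum.

### Per-study analysis paths

`analyze_study()` reproduces the three ways age information enters:

1. **Mean onset age reported** (e.g. Kallmann): solve
   `clock_rate_from_mean_age()` on the cohort window, then find the age at
   which the rescaled curve reaches the observed concordance.
2. **Narrow age range** (width $\le 10$ y, effectively an age cohort; e.g.
   Hoffer–Pollin, 38–48 y): take the midpoint as the representative age and
   solve `clock_rate_from_concordance()` there. The 10-year threshold is the
   package's rule for "narrow"; it is the smallest width that separates the
   38–48 y cohort from the 19–64 y one, and results are insensitive to any
   cut between 11 and 44 y on the shipped table.
3. **Wide or absent range** (e.g. Gottesman–Shields, 19–64 y): keep $r = 1$
   and report the `equivalent_age()` on the reference curve.

Studies with no age information get the algebraic columns only. Solver
failures warn per study and never abort the batch.

## Numerical choices

* **Quadrature**: `stats::integrate` with `rel.tol = 1e-10`,
  `abs.tol = 1e-12`. The integrands ($t\,\mathrm{IR}_s(t)$ and
  $C_M(P_s(t))$) are smooth, cheap and one-dimensional.
* **Root finding**: bracketed `stats::uniroot` only — every solved function
  is strictly monotone on its bracket (prevalence in $t$ and in $r$; the
  windowed mean onset age decreasing in $r$), so roots are unique and
  derivative-free bisection/secant is the robust choice. Age tolerances
  `1e-9` y, clock-rate tolerance `1e-9`, brackets $t \in [0, 200]$ y and
  $r \in [10^{-3}, 10^{2}]$.
* **Degenerate windows**: for extreme clock rates the cohort window holds no
  onset mass in floating point. The mean-age solver substitutes the exact
  limits — $\frac{m}{m+1}\frac{t_H^{m+1}-t_L^{m+1}}{t_H^m-t_L^m}$ as
  $r \to 0$ (density $\propto t^{m-1}$) and $t_L$ as $r \to \infty$ — so the
  bracket check remains truthful instead of erroring spuriously.
* **Peak location**: `stats::optimize` (golden section/parabolic) on
  $[0, 500/r]$; an endpoint "maximum" is reported as a bracketing failure.
  For $m = 1$ the rate is monotone decreasing and the function errors.
* **Fitting**: the objective is the sum of squared residuals between model
  and data expressed as dimensionless cumulative fractions, making it
  invariant to the data's population denominator. The lifetime risk enters
  linearly, so it is profiled out exactly
  ($\hat f_s = \sum g_i d_i / \sum g_i^2$, clipped to $[0,1]$) and the
  continuous search runs over $(\log k_1, \log k_2)$ via `stats::nlminb`
  from a $5\times5$ log-spaced lattice over $[0.01, 1]$ /y, inside an
  integer sweep over `m1` (default 1–40, generously bracketing plausible
  step counts at negligible cost). Multistart jitter is available but off by
  default; with it on, a seed (default 0) makes runs reproducible. The
  reported fit always has an objective no worse than a $50\times50$
  brute-force grid (checked in the tests).

## What the synthetic generator emulates — and what it does not

`simulate_incidence_dataset()` emulates the *structure* of historical
first-admission registries: sex-stratifiable cumulative incidence per
100,000 at ages 10–70 (2.5-y bins by default), monotone by construction.
Noise is multiplicative Gaussian — admission counts scale with cohort size —
followed by isotonic clipping (running maximum) to preserve cumulativity.
It does not emulate mortality, migration, diagnostic drift, or
hospitalization ascertainment beyond the census cutoff, so passing recovery
tests show the estimator works on data generated by the model, not that the
model describes any particular registry.

`simulate_onset_age()` is an exact sampler: onset is the maximum of $m_1$
Exponential($r k_1$) draws and one Exponential($r k_2$) draw, which has the
product-of-CDFs distribution by construction — mirroring the mechanistic
story rather than inverting the CDF numerically. `simulate_twin_cohort()`
builds MZ (both susceptible) and DZ (cotwin susceptible with probability
$S_{\mathrm{inher}}$) cohorts with independent onsets given susceptibility;
members whose onset exceeds the census age are not-yet-ill at that census,
matching cross-sectional study snapshots. Within-pair onset-age correlation
beyond shared susceptibility is deliberately absent: independence is the
model's literal content, not a verified biological claim.

Test problem sizes are chosen to keep Monte-Carlo error well below the
tolerances being checked while running in seconds: 20,000–50,000 pairs for
concordance-curve agreement (binomial standard errors $\lesssim 0.3$
percentage points), $10^5$ draws for distributional (Kolmogorov) checks at
the 0.01 level, and 100 replicates for the parameter-recovery study.

## Known limitations

* **Partial identifiability of $(k_2, f_s)$.** On 10–70 y cumulative curves
  the slow rate and the lifetime risk trade off along a ridge: the data pin
  their combination (the plateau approach) far more tightly than each
  separately. In the package's own recovery study (2% noise, 25 bins,
  $m_1$ fixed), $k_1$ is recovered within 10% essentially always, while
  $k_2$ and $f_s$ individually exceed 10% error in a large fraction of
  replicates; only at roughly 1% noise do all three land within 10% in
  $\ge 90\%$ of replicates. Interval estimates are out of scope (the method
  is pure least squares), so fitted $k_2$ and $f_s$ should be read with this
  ridge in mind.
* **Clock-rate precision is input-limited.** Solving the mean-onset-age
  equation with a target printed to 3 significant figures (23.8 y) pins the
  Kallmann-type clock rate only to about $\pm 0.02$; the package reports the
  exact solution of the equation as given.
* **No ascertainment correction.** Severity-enriched cohorts (long-stay
  hospital sampling) and screened cohorts (military induction) are modelled
  only through the clock rate, not through explicit selection models.
* **Equivalent ages beyond the bracket** (concordance targets approaching 1)
  correspond to ages beyond the human lifespan; the solvers error rather
  than extrapolate.
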