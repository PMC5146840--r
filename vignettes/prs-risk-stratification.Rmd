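---
title: "Risk stratification with a normal polygenic score model"
author: "prstrat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Risk stratification with a normal polygenic score model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prstrat)
```

## The model and its assumptions

`prstrat` works on the raw log-odds scale: the polygenic risk score of an
individual is $\mathrm{PRS} = \sum_i \beta_i x_i$, where $\beta_i$ is the
per-allele log odds ratio of SNP $i$ and $x_i \in [0,2]$ its effect-allele
dosage. Three assumptions drive everything downstream:

1. **Independent, unlinked loci.** Dosages are independent
   $\mathrm{Binomial}(2, p_i)$ draws (Hardy-Weinberg equilibrium), so the
   score has mean $\mu = 2\sum_i p_i\beta_i$ and variance
   $\sigma^2 = 2\sum_i p_i q_i \beta_i^2$ exactly, and is approximately
   normal by the central limit theorem once a few dozen loci contribute.
2. **Log-additive small effects.** Disease odds multiply by $e^{\beta_i}$
   per allele; the score is the individual's total genetic log odds offset.
3. **Rare disease.** Among cases the score density is the exponentially
   tilted population density, $g(r) \propto e^{r} f(r)$. Tilting a normal
   shifts its mean by its variance and leaves the variance unchanged:
   $G = N(\mu + \sigma^2, \sigma^2)$. This mean shift of $\sigma^2$ is the
   single quantity that links the score's dispersion to its discriminative
   ability.

Under these assumptions every stratification metric depends on the panel
only through $\sigma$, which is why the package lets you run the entire
analytic stage from a single number (`run_pipeline(sigma = 0.38)`), with
0.38 the dispersion of the 44-SNP East Asian breast-cancer panel that
motivates the defaults and 0.55 the value corresponding to the estimated
heritable component in the hypothetical full-knowledge scenario.

The score is deliberately **not standardized**: $\sigma$ is meaningful on
the log-odds scale (an SD difference in score is a $e^{\sigma}$-fold
difference in odds), and all published quantities the package reproduces
live on that scale.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `alpha` | 0.05 | one-sided replication threshold for SNP selection |
| `breaks` | deciles, 40-60 merged | percentile partition for PAR and tables |
| reference band | 40th-60th percentile | denominator of every interval OR |
| `prevalence` | 0.01 | population disease risk of the simulated disease |
| `sd_target` | unset | rescales simulated effects to an exact score SD |
| `alpha`/`tau` presets | 20/60 and 50/10 | lifetime and 10-year risk windows |

One-sided p-values are taken in the direction of the previously reported
risk allele: the signed statistic is $z = s\,\hat\beta/\mathrm{se}$ with
$s = \mathrm{sign}(\beta^{\text{reported}})$ and $p = P(Z \ge z)$, so
replication means "the effect goes the way it was first reported".

## Two conventions worth stating explicitly

**PCF is a top-tail quantity.** We define the proportion of cases followed
as the case share of the *top* $q$ of the population,
$\mathrm{PCF}(q) = \Phi(\Phi^{-1}(q) + \sigma)$. Written with the lower
tail, $\Phi(\Phi^{-1}(q) - \sigma)$, the same expression gives the case
share of the *bottom* $q$ — a quantity that is never what a screening
programme asks for (it gives 0.34% rather than 2.6% at $q = 1\%$,
$\sigma = 0.38$). The package uses the top-tail convention throughout;
the lower-tail form appears only as the inverse function
$\mathrm{PNF}(p) = \Phi(\Phi^{-1}(p) - \sigma)$, where it is correct.

**PAR is partition-invariant.** With interval odds ratios defined against
the 40-60 band, the attributable-risk sum telescopes:
$A_j/\mathrm{OR}_j = (v_j - u_j)\cdot A_{\mathrm{ref}}/0.2$, so
$$\mathrm{PAR} = 1 - \sum_j \frac{A_j}{\mathrm{OR}_j}
             = 1 - \frac{A_{\mathrm{ref}}}{0.2}
             = 1 - \frac{\Phi(\Phi^{-1}(0.6)+\sigma) -
                         \Phi(\Phi^{-1}(0.4)+\sigma)}{0.2},$$
identically for every partition of $(0,1)$. The `breaks` argument of
`polygenic_par()` is therefore a reporting choice, not a modelling one;
the test suite asserts the invariance to $10^{-12}$ across 10-, 20- and
100-bin partitions. At $\sigma = 0.38$ the value is 6.8%.

```{r par}
polygenic_par(0.38)
1 - case_share(0.4, 0.6, 0.38) / 0.2
```

## What the simulator emulates — and what it does not

`generate_cohort()` produces case-control data the way the downstream
analysis assumes they arise: Hardy-Weinberg genotypes at independent loci,
a logistic disease model whose linear predictor is the individual's PRS
plus an intercept, and **rejection sampling** of population draws until
each study's case and control quotas are met — the correct sampling model
for a case-control design, and the reason case genotype frequencies are
automatically tilted the way real case series are.

The logistic intercept is calibrated by bisection (tolerance $10^{-8}$) so
that the population disease probability equals `prevalence`. The
population expectation over genotypes is evaluated by quadrature against
the normal score approximation $N(\mu, \sigma^2)$ — the same approximation
the analytic model rests on; for panels of a few dozen SNPs its error in
realized prevalence is far below Monte-Carlo noise at any tested sample
size.

Deliberately absent, because the analytic model ignores them too: linkage
disequilibrium between panel SNPs, population stratification and
principal-component structure, age effects on risk (ages are drawn
uniformly and carried only as an adjustment covariate), and
estrogen-receptor subtype heterogeneity (subtype-specific analyses are a
matter of swapping in a subtype weight panel, not a separate code path).
Passing tests on simulated data therefore validate the *machinery* —
estimation, pooling, selection, scoring, projection — not the adequacy of
those assumptions for any particular real cohort.

Rate tables from `generate_rate_table()` are **synthetic**: 5-year band
shapes loosely patterned on female breast-cancer incidence and all-cause
mortality in East Asian registries, rescaled by a single factor so a
requested cumulative risk is met to $10^{-6}$. The calibration context is
explicit: by default the requested value is the population lifetime risk
(OR = 1, PAR = 0); passing `par = polygenic_par(sigma)` pins the
40-60-band reference risk instead, which is the natural way to anchor a
stratified table at a published reference-group figure (for instance a
3.64% lifetime risk). Published absolute-risk tables computed from
registry rate tables are not reproduced — those tables are external data —
so the projection module is validated by oracle and consistency tests
instead (below).

## Numerical choices

- **AUC** is computed by adaptive quadrature of the ROC integral
  $\int (1-G)\,dF$ (relative tolerance $10^{-10}$). For the equal-variance
  binormal pair this equals $\Phi(\sigma/\sqrt 2)$; the closed form is
  kept as an independent oracle in the tests rather than as the
  implementation, so the quadrature route stays honest.
- **Logistic fits** use iteratively reweighted least squares
  (`stats::glm`, binomial family) with convergence tolerance $10^{-8}$ and
  at most 100 iterations. Monomorphic dosages, non-convergence and
  (quasi-)separation are flagged per SNP and excluded from pooling with a
  warning, never silently dropped.
- **Selection ties** (equal one-sided p within a locus) go to the
  lexicographically smallest SNP identifier, keeping selection
  deterministic.
- **Absolute risk** integrates the cause-specific cumulative incidence on
  a piecewise-constant hazard grid with the survivor term accumulated from
  the starting age $\alpha$ to the current time — the standard form of the
  competing-risk projection. Each step is integrated *exactly* under its
  constant hazards ($\frac{h_1 \mathrm{OR}}{h_1\mathrm{OR}+h_2}
  S_t(1-e^{-(h_1\mathrm{OR}+h_2)\Delta})$), so refining the step below one
  year changes results only at floating-point level; the tests assert
  step-invariance rather than mere convergence. Band rates are expanded to
  the grid by constant interpolation; the interval OR is treated as
  age-constant, no score-by-age interaction being part of the model.
- **Missing dosages** at scoring time are mean-imputed as $2p_i$; the
  association stage instead drops incomplete observations SNP-wise.
- **Seeding**: one integer seed; each generator stage (panel, cohort,
  rates) consumes a distinct stream derived from it, so regenerating one
  artifact never perturbs another.

## Known limitations

- The PAR-deflated baseline reproduces the population hazard *exactly* on
  the hazard scale, but cumulative risks are concave in the hazard, so the
  percentile-weighted average of band risks undershoots the population
  cumulative risk by a Jensen gap that grows with $\sigma$ and with the
  magnitude of the cumulative risk. At the package's default conditions
  ($\sigma = 0.38$, lifetime risk a few percent) the gap is below 0.5%
  relative, the level the test suite asserts for both the lifetime and
  10-year windows; users pushing $\sigma$ well past 0.5 together with
  double-digit cumulative risks should expect visibly larger gaps.
- The normal model is an approximation for finite panels; with 44 SNPs
  the Kolmogorov-Smirnov distance to the simulated score distribution is
  below detection at the sample sizes tested, but very small panels (a
  handful of SNPs) or a single dominant effect will show departures.
- Case-control sampling tilts control scores slightly below the population
  mean at non-negligible prevalence (order $\sigma^2 K$ for prevalence
  $K$); the empirical-moment tests therefore run at $K \le 0.2\%$.
- `empirical_auc()` is the plain Mann-Whitney concordance; covariate-
  adjusted AUC improvements over a non-genetic risk model require
  individual-level covariate data and are out of scope.

## Validation design and problem sizes

The package's own validation (test suite) runs at sizes chosen to make
Monte-Carlo tolerances meaningful while keeping a full run under a minute
of simulation time: the main agreement check uses 44 SNPs rescaled to
$\sigma = 0.38$, prevalence 1%, and 25,000 cases against 75,000 controls,
comparing empirical band odds ratios (cut at model quantiles, referenced
to the 40-60 band) with their closed forms within 3 Monte-Carlo standard
errors, and the empirical AUC with the analytic 0.606 within $\pm 0.01$.
Replication behaviour is checked on a three-study design with 40 candidate
SNPs at 36 loci, half the loci carrying a true effect powered near 90%,
plus a separate 2000-SNP null panel for the size of the one-sided test.
Moment and Hardy-Weinberg convergence use 50,000 controls at prevalence
0.2%.
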