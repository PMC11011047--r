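---
title: "Quantitative genetics of ordinal limb-conformation defects"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative genetics of ordinal limb-conformation defects}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Limb-conformation defects in riding horses — open or closed hocks, toe-in
and toe-out stances, camped-under and camped-out postures, base-narrow and
base-wide placements, pastern and hoof-axis deviations — are scored in the
field by trained appraisers on a three-class ordinal scale: 0 (correct),
1 (slight defect), 2 (evident defect).  Animals are evaluated repeatedly,
by different appraisers and at different ages, and belong to a pedigreed
studbook population.  Breeders want to know three things:

1. how common each defect is, overall and within levels of the non-genetic
   factors (gender, birth period, stud selection criterion, evaluation-age
   group, appraiser);
2. whether a defect degrades the functional gait scores (walk, trot) the
   same animals receive; and
3. how heritable each defect is and how defects are genetically
   correlated, so that selection against one does not silently worsen
   another.

`limbgen` implements this full analysis chain for the Menorca Purebred
(PRMe) study design: ~500 evaluated animals, ~1120 repeated records (2.2
per animal), a pedigree of ~1000 animals over a handful of generations.

## The model

The core is the multi-trait repeatability animal model

$$\mathbf{y} = \mathbf{Xb} + \mathbf{Zu} + \mathbf{Wpe} + \mathbf{e}$$

with flat (bounded-uniform) priors on the systematic effects
$\mathbf{b}$ (gender 2, birth period 3, stud criterion 4, age group 2,
appraiser 3, reference-cell coded) and on the covariance components, and
Gaussian priors on the random effects:

$$\operatorname{var}\begin{pmatrix}\mathbf u\\ \mathbf{pe}\\ \mathbf e\end{pmatrix}
 = \begin{pmatrix}\mathbf A\otimes\Sigma_u & 0 & 0\\
                  0 & \mathbf I\otimes\Sigma_{pe} & 0\\
                  0 & 0 & \mathbf I\otimes\Sigma_e\end{pmatrix}$$

where $\mathbf A$ is the numerator relationship matrix.  Heritability and
genetic correlation are the usual transforms
$h^2 = \sigma^2_u/(\sigma^2_u+\sigma^2_{pe}+\sigma^2_e)$ and
$r_g = \sigma_u(i,j)/\sqrt{\sigma_u(i,i)\,\sigma_u(j,j)}$, applied **draw
by draw**, never to posterior means first.  (The only exception is the
cross-check against published tables, where printed posterior means are
the only available input; `h2_from_means()` documents that difference.)

Two deliberate modelling positions, both with a configuration switch or a
documented alternative:

* **Scale of analysis.**  The source analysis fits a *linear* Gaussian
  animal model directly to the 0/1/2 scores rather than a
  threshold-liability model.  We do the same.  The synthetic-data
  generator therefore exposes both the latent Gaussian scores and their
  0/1/2 discretisation: parameter-recovery checks run on the latent scale
  (where the model is exactly true), and the discretised scores exercise
  the descriptive statistics.  A threshold model is a stated non-goal.
* **Permanent environment.**  Printed matrix notation in the source shows
  the permanent environmental covariance premultiplied by $\mathbf A$,
  which would make `pe` a second additive-genetic effect.  Permanent
  environment is conventionally iid per animal, and the repeated-records
  design only identifies an animal-level non-genetic component under that
  convention, so the default is $\mathbf I\sigma^2_{pe}$; the printed form
  is available as `pe_covariance = "pedigree"`.

## The Gibbs sampler

Each sweep performs three blocked draws:

1. **Missing-score imputation** (`impute_missing_traits`): per-trait
   missingness is heavy in this design (per-trait N between ~318 and ~507
   of 1120 records), so multivariate runs impute missing trait entries
   from their Gaussian conditional given the record's observed traits.
2. **All location effects jointly** (`sample_location_effects`): the full
   conditional of $(\mathbf b,\mathbf u,\mathbf{pe})$ is Gaussian with
   precision
   $\Sigma_e^{-1}\!\otimes T'T + \Sigma_u^{-1}\!\otimes \mathbf A^{-1}
   + \Sigma_{pe}^{-1}\!\otimes \mathbf P$, $T=[X\,Z\,W]$.  The sparsity
   pattern of this matrix never changes, so the workspace precomputes the
   mapping from each template's nonzeros into the joint matrix and reuses
   one symbolic Cholesky analysis (CHOLMOD, via Matrix); per iteration
   only the numeric factorisation is redone.  Draws use the standard
   $P'L^{-\top}z$ construction.  Joint blocking mixes far better than
   single-site updates and makes a 20,000-round univariate chain on the
   study size a ~1 minute computation.
3. **Covariance components** (`sample_variance_components`):
   inverse-Wishart full conditionals with scale matrices
   $\mathbf u'\mathbf A^{-1}\mathbf u$, $\mathbf{pe}'\mathbf{pe}$,
   $\mathbf e'\mathbf e$ and degrees of freedom $q-t-1$, $p_a-t-1$,
   $n-t-1$ — the improper limit of an inverse-Wishart with prior df
   $-(t+1)$ and zero scale, which is the Bayesian realisation of the
   "bounded uniform" variance prior with bounds $(0,\infty)$.  In one
   trait this is $S/\chi^2_{n-2}$.

$\mathbf A^{-1}$ is never formed by inversion: Henderson's rules with the
inbreeding correction build it directly from the pedigree, with
inbreeding coefficients from the Meuwissen–Luo recursion.  The dense
tabular construction of $\mathbf A$ is retained (capped at order 3000 by
default) mainly as an oracle for tests.

### Numerical choices

* **Positivity floor** `variance_floor = 1e-8`: added to every scale
  matrix and imposed on the eigenvalues of every covariance draw.  This
  keeps a chain that wanders to zero variance (e.g. the null simulation,
  or degenerate constant data) from being absorbed; with all residuals
  zero, draws collapse towards the floor rather than erroring.
* **Initialisation**: missing scores start at trait means; all three
  covariance matrices start at one third of the phenotypic variance.
  Burn-in disposes of this.
* **Identifiability**: reference-cell coding keeps `X` full rank;
  declared-but-unobserved factor levels are dropped (their effects are
  inestimable), and genuinely aliased columns abort with a message.  Any
  full-rank coding yields identical variance posteriors.
* **Determinism**: one R RNG stream, seeded once per run from the model
  specification; the whole chain is reproducible bit for bit.
* **Chain protocol**: defaults are the long-run protocol (250,000
  iterations, 50,000 burn-in, every sample saved).  Tests and the
  acceptance report scale this down (20,000/5,000 and 8,000/2,000
  respectively) — parameter-recovery tolerances account for that.

## The synthetic world

`sim_config()` defaults encode the study design as stated: 217 founders
plus 4 generations of 200 (1017 animals, born 1961–2020 with birth years
uniform within per-cohort windows so that all three birth periods occur
among evaluated animals); 500 evaluated animals; records per animal
$1+\mathrm{Poisson}(1.2)$ (mean 2.2); five factors with 2/3/4/2/3 levels,
gender/birth period/stud criterion fixed per animal, appraiser and age
group varying per record (most animals are seen by more than one
appraiser); latent phenotypic variance 1 split as additive 0.25,
permanent environment 0.20, residual 0.55 — i.e. $h^2 = 0.25$ and
repeatability 0.45, mid-range for the published defect estimates.
Fixed-factor effects default to 0.1–0.3 latent-SD shifts, the order of
magnitude the factor screening detects in the real data.  Breeding values
follow the gametic recursion $u_i = \tfrac12(u_s+u_d)+m_i$ with Mendelian
sampling variance $d_i\Sigma_u$, $d_i = 0.5-0.25(F_s+F_d)$, so
$\operatorname{var}(\mathbf u) = \mathbf A\otimes\Sigma_u$ exactly.

What the generator does **not** emulate: selection and assortative
mating, overlapping generations, appraiser-by-animal interaction,
ordinal measurement error beyond thresholding, and the unknown empirical
joint distribution of the five factors.  A green recovery test therefore
establishes that the sampler recovers the parameters of data generated
under the model's own assumptions at the study's size and design — not
that the published estimates are correct for the real population.

## Descriptive statistics

* `prevalence_table()` counts **records**, not animals (the published
  per-trait N exceed the animal count), excludes missing scores from N,
  and rounds half away from zero to 2 dp.  The combined class-1+2
  percentage is reported as the **sum of the rounded** per-class
  percentages, which is how the published table is arithmetically
  consistent (4 of its 14 rows differ at 2 dp from `100*(n1+n2)/N`; the
  count-based value is kept as `pct12_raw`).
* `fit_multinomial_logit()` is a baseline-category (class 0) logit fit by
  Newton's method with step halving; per-factor significance is a
  likelihood-ratio drop-one test with `(levels-1)*(classes-1)` df.  LR
  was chosen over Wald (the source software's default is unstated)
  because it is invariant to parameterisation and better behaved at these
  cell sizes.  Separation (a factor level observed in a single outcome
  class) is flagged and the fit continues with a small ridge.
* `fit_gait_glm()` is the one-way fixed-effects comparison of a gait
  score across defect classes with Tukey–Kramer pairwise tests in their
  unbalanced form and a compact letter display.  The published table
  header says "Tukey LSD" while the methods text says "Tukey post hoc
  test"; Tukey–Kramer HSD is implemented, matching the conservative
  letter patterns shown.  Classes with fewer than two records are
  reported with their mean only.  With two groups the Tukey p-value
  reduces exactly to the pooled t-test p-value (tested).  Repeated
  records per animal are *not* modelled here, faithfully to the source's
  own GLM.

## Diagnostics

Geweke's Z compares the first 10% and last 50% of a chain, standardised
by spectral-density-at-zero estimates from an AR fit (order chosen by
AIC); |Z| > 2 flags disagreement.  The Monte Carlo standard error uses
batch means with $\lfloor\sqrt n\rfloor$ batches — the estimator behind
the published "MCse ≤ 0.001" statement is unspecified, so absolute MCse
values on real data are not acceptance-grade; scaling behaviour
($1/\sqrt n$ on iid chains, $\sqrt{(1+\phi)/(1-\phi)}$ inflation on
AR(1)) is what the tests pin down.  HPD intervals are sliding-window
shortest intervals on sorted draws.  `summarize_run()` flags any
monitored scalar with |Z| > 2 or MCse above a threshold (default 0.001).

Correlation "significance" follows the convention that the 95% HPD
interval excludes zero (the source reports a significance percentage
without stating its criterion).

## Known limitations

* Single chain (as in the source protocol); no Gelman–Rubin diagnostic.
* No threshold-liability model, no genomic relationship matrices, no
  unknown-parent groups (the source does not state how its software
  handled them; none are implemented).
* The exchangeability of animals holds distributionally but not draw by
  draw under relabelling, because the joint location block uses a
  fill-reducing ordering inside the sparse Cholesky.
* With ~2.2 records per animal and a shallow pedigree, the additive /
  permanent-environment split is weakly identified per trait; posterior
  standard deviations of $h^2$ around 0.05 at the study size are
  intrinsic to the design, not to the sampler.
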