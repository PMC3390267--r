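---
title: "Two-step REML analysis of genetic heterogeneity of residual variance"
author: "hetvar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-step REML analysis of genetic heterogeneity of residual variance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hetvar)
```

## The problem

In a conventional animal model the residual variance is a nuisance constant.
When genotypes differ in their *sensitivity to micro-environment*, the
residual variance itself carries additive genetic variation: some families
produce consistently uniform offspring, others variable ones. Selection on
that variation can improve uniformity of economically important traits.
Detecting it, however, is statistically delicate: each record carries only
about two effective degrees of freedom of information about its own
variance, so dispersion parameters are estimated with far less precision
than means, and the estimators in common use are biased in ways that matter
for interpretation.

`hetvar` implements the pragmatic two-step route — an ordinary animal-model
REML fit, followed by an animal-model REML fit to the log squared estimated
residuals — and, because the bias structure of this route is its most
important property, a complete Monte Carlo apparatus for studying it under
a known generative model.

## Generative model

Phenotypes are simulated from the multiplicative exponential model

$$ y_{ij} = b_{m i} + a_{m ij} + \exp\!\big((b_{vi} + a_{vij})/2\big)\,
   \epsilon_{ij}, \qquad \epsilon_{ij} \sim N(0, 1), $$

so each record's residual standard deviation is log-linear in a fixed
contemporary-group (CG) effect $b_v$ and an animal dispersion breeding
value $a_v$. Defaults (all tunable through `genetic_params()`):

| parameter | meaning | default | units |
|---|---|---|---|
| `sigma2_a` | additive variance, trait mean | 200 | kg² |
| `sigma2_Av_exp` | additive variance, log residual variance | 0.09 | log scale |
| `r_mv` | genetic correlation mean–dispersion | 0 | – |
| `b_m_range` | CG effects on the mean | U(300, 400) | kg |
| `b_v_range` | CG effects on log variance | U(5.40, 5.80) | log kg² |

Breeding values $(a_m, a_v)$ are bivariate normal for founders and
midparent-plus-Mendelian for descendants, the Mendelian term carrying
covariance $d_i\,G_{mv}$ with $d_i = 0.5\,(1 - (F_s + F_d)/2)$ — the same
$d_i$ that drives Henderson's rules, so inbreeding is handled exactly even
though random mating keeps it near zero here. The implied residual variance
of a CG is $E[\sigma^2_e] = \exp(b_v)\exp(\sigma^2_{Av,exp}/2)$
(`expected_residual_variance()`); integrated over the $b_v$ distribution at
`sigma2_Av_exp = 0.09` this gives a trait with mean 350 kg, phenotypic
variance near 480 kg² and heritability near 0.41.

The default population design (`sim_design()`) is balanced: 100 base sires
and 5 000 base dams, five discrete generations of 5 000 recorded offspring
(50 per sire, 1 per dam), 20% of the active parents of each sex replaced per
generation by randomly chosen previous-generation animals, random mating, no
selection. Contemporary groups are formed within generation from five sires
with ten offspring each, i.e. 100 CG per generation; each sire's 50
offspring are split into five blocks of ten assigned to distinct CGs by a
cyclic allocation over randomly ordered sires. Two readings of the CG count
were possible (100 per generation versus 100 in total); only the former is
consistent with 5 000 records per generation at 50 records per CG, so it is
the one implemented.

What the generator deliberately does **not** emulate: selection and
assortative mating, overlapping age structure, maternal effects, and any
environmental noise on the dispersion scale beyond the CG effect. The last
point matters when reading accuracy results: with only a fixed effect
disturbing the dispersion signal, EBV accuracies are upper bounds on what
comparably sized field data would give.

Reproducibility is bit-exact: one master seed spawns named sub-streams
(pedigree structure, CG effects, breeding values, residual draws), so any
component can be regenerated independently, and the standard-normal draws
$\epsilon$ are stored with the dataset.

## Step 1: the trait model

`fit_animal_model()` fits
$y = Xb + Z_1 a + Z_2 m + W c + e$ by REML with direct additive effects
always present, optional maternal additive and maternal permanent
environmental terms (the direct–maternal covariance is fixed at zero), and
two residual structures: a single variance (HOM) or one variance per sire
family (HET), records with an unknown or edited-out sire pooling into one
extra class. Data pass through `apply_edit_rules()` first: records beyond
±3.5 SD of the trait mean are trimmed, then CGs under 25 records and sire
families under 50 progeny are dropped, the last two rules iterated to a
fixed point.

## Step 2: the dispersion model

`dispersion_response()` turns step-1 residuals into $\ln(\hat e^2)$;
squared residuals below the $10^{-6}$ quantile of the positive values are
raised to that floor (quantile-based, hence scale-free) and the floored
count is reported, never silently absorbed. A cube-root transform
$(\hat e^2)^{1/3}$, closer to normal, is available as an alternative.
`fit_dispersion_model()` then fits the same CG fixed factor (step-1
covariates are not carried over, matching the dispersion model's design)
plus direct — optionally maternal — additive effects with a homoscedastic
residual, returning dispersion EBVs for every pedigree animal and the
log-scale heritability of the response with a delta-method standard error.

`compare_models()` performs the likelihood-ratio test of the dispersion
genetic term. Because a variance is tested at the boundary of its space,
the naive $\chi^2_1$ reference is conservative by a factor of two; the
headline p-value uses the equal mixture of a point mass at zero and
$\chi^2_1$, and the naive value is reported alongside. For several
components the plain $\chi^2_{\Delta k}$ is used (conservative).

`response_moments()` provides the standard diagnostic: if step-1 residuals
are normal, $\ln(\hat e^2)$ is a shifted log-$\chi^2_1$ with skewness
$\psi''(1/2)/\psi'(1/2)^{3/2} \approx -1.53$ — sharply non-normal, which is
precisely why the second-step REML estimates are biased.

## Scale conversion and derived parameters

The second step estimates variance on the log scale. Under the exponential
model the residual variance of an animal is lognormal, so the additive
variance on the residual-variance scale is taken as
$\sigma^2_{AV} = (\sigma^2_{\hat e})^2(\exp(\sigma^2_{Av,exp}) - 1)$,
anchored at the reference residual variance $\sigma^2_{\hat e}$ — the HOM
REML estimate, or the unweighted mean over sire families under HET
(`reference_residual_variance()`). This identity is the package's
calibration point: it maps $\sigma^2_{Av,exp} \in \{0.01, 0.09, 0.25\}$ to
evolvabilities $Ev = \sigma_{AV}/\sigma^2_{\hat e} =
\sqrt{\exp(\sigma^2_{Av,exp})-1}$ of 10.0%, 30.7% and 53.4% — the "about
10, 30 and 50 percent" regimes the simulation scenarios are named after.
$Ev$ is scale-free in $\sigma^2_{\hat e}$ by construction, and the
conversion round-trips to machine precision (both are tested).

The heritability of residual variance uses the regression-derived form
$h^2_v = \sigma^2_{AV}/(2\sigma^4_P + 3\sigma^2_{AV})$ with
$\sigma^2_P = \sigma^2_a + \sigma^2_m + \sigma^2_c + \sigma^2_{\hat e}$.
The formula comes from the cited derivation rather than from first
principles here; it is isolated in `h2v()` so it can be swapped, and its
standard error is propagated first-order from the log-scale heritability.
`ebv_correlation()` gives the usual rough indicator of the mean–dispersion
genetic correlation: the Pearson correlation of sire EBVs from the two
steps, restricted to sires with more than 50 progeny because the quantity
is meaningless at low EBV accuracy.

## REML engine: numerical choices

All fits share one sparse engine built on the mixed-model equations:

* **A-inverse** by Henderson's rules with exact inbreeding; the
  Meuwissen–Luo recursion (compiled) and the tabular method agree on every
  tested pedigree, and $A^{-1}$ is verified against the dense inverse.
* **Likelihood** via the sparse Cholesky factorisation of the coefficient
  matrix: $-2\log L_R = \log|R| + \sum_k (q_k\log\sigma^2_k + \log|K_k|) +
  \log|C| + y'Py$, checked to machine precision against a dense matrix-form
  oracle in the tests.
* **Updates**: average-information steps with the exact gradient (trace
  terms come from triangular solves against the Cholesky factor, chunked to
  bound memory). A step that leaves the parameter space is projected onto
  the boundary; components pinned at the boundary with outward-pointing
  gradients are dropped from the Newton system (active set); if no halved
  AI step improves the restricted likelihood, an EM step is taken. Accepted
  iterations therefore never decrease the likelihood (tested).
* **Floor and flags**: all components are kept above $10^{-8}$ times the
  response variance; a converged component at the floor is flagged
  `boundary` rather than reported as a hard zero.
* **Convergence**: change in restricted log-likelihood below `1e-7` *and*
  maximum relative component change below `1e-6` (floored components
  excluded), default cap of 200 iterations; non-convergence is an error
  carrying the last iterate, never a silent result.
* **Standard errors** from the inverse average-information matrix at
  convergence.
* **Identifiability**: the CG factor is coded as cell means (later factors
  drop their first level), and a rank check refuses a singular fixed design
  naming the confounded columns instead of silently dropping them.

Information criteria count only free variance components ($p$), with
AIC $= -2\log L_R + 2p$ and BIC $= -2\log L_R + p\ln(n - \mathrm{rank}(X))$:
REML solutions are predictions, not parameters, and the residual degrees of
freedom are the natural REML sample size. On simulated data this choice
reproduces the qualitative HOM/HET ordering seen in practice (AIC rewards
HET's fit, BIC's stiffer penalty prefers HOM).

Ten-fold cross-validation (`cross_validate()`) refits the model on each
training set and predicts held-out records as fitted fixed effects plus
pedigree-propagated BLUPs — the pedigree ties unobserved animals to the
training records, which is the natural mixed-model notion of prediction
here; predicting by fixed effects alone would charge the genetic term
twice. A CG confined to one fold after bounded re-randomisation is
predicted by the mean CG effect, with a warning.

## The Monte Carlo study and its scale

`run_scenario()` chains simulate → edit → step 1 → step 2 → parameters →
accuracies per replicate, redrawing failed replicates with the next derived
seed (at most 20% failures) and `summarize_mc()` aggregates bias (with SD
and SE over replicates — both, since either dispersion convention is in
use), the sire-EBV correlation, and Pearson accuracies of dispersion EBVs
for all animals, sires and dams.

Replicated runs in the tests and the acceptance script use a reduced preset
(`design_small()`: 2 generations × 20 sires × 1 000 dams, so 2 000 records
and 3 020 pedigree animals, 5 replicates), which keeps a full scenario under
a minute while preserving the 50-progeny sire families of the full design.
Two quantitative consequences of the reduction are worth knowing when
comparing against full-scale results: per-sire information is smaller
(sires serve at most 2 generations), which *increases* the upward bias of
the HET route at small dispersion variance beyond its full-scale level; and
a third of the pedigree are unrecorded base parents (against a sixth at
full scale), which *lowers* the all-animal average EBV accuracy. The
directional findings — HOM biased down, HET biased up and decreasingly so
in the true variance, sire accuracies far above dam accuracies, HET beating
HOM on sire accuracy — are stable across both scales.

## Known limitations

* The two-step route is the object of study, biases included; nothing here
  corrects them. One-step structural or double-hierarchical models are out
  of scope.
* The mean–dispersion genetic correlation is not estimable in this
  framework; `ebv_correlation()` indicates its sign, no more.
* Unknown-parent groups and genomic relationship matrices are not
  supported; unknown parents are treated as unrelated founders.
* Prediction for `cross_validate()` supports the package's model shape
  (one CG factor plus numeric covariates, optional extra factors); exotic
  fixed-effect structures would need their own predict method.
* The engine targets pedigrees up to a few tens of thousands of animals;
  trace computations are exact, not stochastic, and scale with the
  factor's fill-in.
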