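---
title: "Metabolomic-genomic prediction with mgblup: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Metabolomic-genomic prediction with mgblup}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mgblup)
```

This vignette is the package's own account of the statistical machinery it
implements: the joint phenotype–metabolome model and its two-step solution,
the quantities derived from it, the synthetic data generator used as the
test bed, and the numerical and design decisions that were genuinely open.

## 1. The joint model and its two-step solution

Phenotypes are plot records from multi-environment trials: lines tested in
randomised complete blocks (trials) nested within location × year
environments, with samples processed in batches. The phenotype equation is

$$
\mathbf{y} = \mathbf{X}\mathbf{b}_1 + \mathbf{Z}_m \mathbf{M}\boldsymbol\alpha
 + \mathbf{Z}_g\mathbf{g}_1 + \mathbf{Z}_g\mathbf{l}_1
 + \mathbf{Z}_{i_g}\mathbf{i}_{g_1} + \mathbf{Z}_{i_l}\mathbf{i}_{l_1}
 + \mathbf{Z}_t\mathbf{t}_1 + \mathbf{e}_1,
$$

where $\mathbf{M}$ is the plot × feature matrix of standardized metabolomic
intensities and $\boldsymbol\alpha \sim N(0, \mathbf{I}\sigma^2_\alpha)$ are
random regressions of the phenotype on every feature. Each feature column
follows the same mixed model as a phenotype (genomic, line, genotype ×
environment, line × environment, batch and residual terms), with one
*common* variance set across features. Genomic terms are correlated through
the VanRaden method-1 relationship matrix
$\mathbf{G} = \mathbf{Z}\mathbf{Z}'/(2\sum_i p_i(1-p_i))$; genotype ×
environment terms through $\mathrm{diag}(\mathbf{G},\dots,\mathbf{G})$ over
environments.

The breeding value of a line combines a metabolome-mediated and a direct
part, $\mathbf{a} = \sum_j \mathbf{g}_{j,2}\,\alpha_j + \mathbf{g}_1$.
Under the common-variance assumption the joint model can be solved by two
successive linear mixed models:

1. **Step 1** replaces $\mathbf{M}\boldsymbol\alpha$ by a per-plot effect
   $\mathbf{u} \sim N(0, \mathbf{Q}\sigma^2_u)$ with
   $\mathbf{Q} = \mathbf{M}\mathbf{M}'/q$ and $\sigma^2_u = q\sigma^2_\alpha$,
   and predicts $\hat{\mathbf{u}}$ (for every plot with features, phenotyped
   or not) and the direct genomic effects $\hat{\mathbf{g}}_1$.
2. **Step 2** treats $\hat{\mathbf{u}}$ as an observed response of the same
   six-term model and predicts the metabolome-mediated genomic effects
   $\hat{\mathbf{g}}_2$.

Predicted breeding values are $\hat{\mathbf{a}} = \hat{\mathbf{g}}_1 +
\hat{\mathbf{g}}_2$; the identity is asserted in code. The test suite
verifies the equivalence of this two-step procedure with a directly solved
joint system (explicit $\boldsymbol\alpha$ plus per-feature genomic BLUP
through Henderson's mixed model equations) to $10^{-4}$ on small instances
— the equivalence is algebraic, so it holds for any data and any fixed
variance components. Step 2 deliberately ignores the prediction error of
$\hat{\mathbf{u}}$ (homogeneous residual variance); that approximation is
inherent to the two-step procedure.

Derived genetic parameters, all at **plot level**: total phenotypic
variance $\sigma^2_P$ as the kernel-weighted sum of variance components
($\bar G$ for genomic terms, $\bar Q$ for the metabolomic term, 1
otherwise), direct heritability $h^2_d$, metabolomic variance ratio
$c^2_m$, common feature heritability $h^2_m$ from step 2, and
$h^2 = c^2_m h^2_m + h^2_d$. Plot-level (rather than line-mean) reporting
keeps the parameters comparable across experimental designs; the features
are measured per plot in any case. $h^2_m$ estimated from step 2 is
trait-dependent because it is effectively the heritability of the
phenotype-weighted sum of features; this is an acknowledged approximation
of the common-heritability framework.

## 2. REML and BLUP engine

All models run on a dense phenotypic covariance
$\mathbf{V} = \sum_k \sigma^2_k \mathbf{V}_k + \sigma^2_e\mathbf{I}$, where
$\mathbf{V}_k$ is the unit-variance contribution of term $k$. This makes
the per-iteration cost $O(n^3)$ in the number of plots and independent of
the number of random-effect levels; the intended scale is up to a few
thousand plots (the engine is not sparse and that is a stated non-goal).

* **Algorithm**: the first two iterations use a positivity-preserving
  EM-type fixed-point update
  $\sigma^{2,\mathrm{new}}_k = \sigma^2_k\,
  (\mathbf{y}'\mathbf{P}\mathbf{V}_k\mathbf{P}\mathbf{y})/
  \mathrm{tr}(\mathbf{P}\mathbf{V}_k)$; thereafter average-information
  (AI) updates with step halving, falling back to the fixed point whenever
  an AI step is inadmissible. AI steps are *active-set aware*: components
  pushed below the variance floor are pinned there and the AI system is
  re-solved for the remaining ones, which avoids the slow geometric decay
  of boundary components under pure EM.
* **Floor**: variances are floored at $10^{-10}\,\mathrm{var}(y)$ and
  re-enter estimation at every iteration (no permanent boundary lock-in).
* **Convergence**: maximum relative parameter change below $10^{-8}$ or
  restricted log-likelihood change below $10^{-9}$, at most 500 iterations;
  non-convergence is flagged, not thrown. These tolerances are package
  decisions — the underlying theory prescribes none.
* **Fixed effects**: one indicator column per observed location × year ×
  trial cell (cell-means coding). Any full-rank coding gives the same
  restricted likelihood, BLUPs and corrected phenotypes (tested); one had
  to be chosen.
* **BLUP**: solutions come from the V-inverse form of the mixed model
  equations, $\hat{\mathbf{u}}_k = \sigma^2_k \mathbf{K}_k \mathbf{Z}_k'
  \mathbf{P}\mathbf{y}$, so levels without records (unphenotyped lines,
  feature-only plots) are predicted through their covariance with observed
  levels. The reconstruction identity
  $\mathbf{y} = \mathbf{X}\hat{\mathbf{b}} + \sum_k \mathbf{Z}_k
  \hat{\mathbf{u}}_k + \hat{\mathbf{e}}$ is checked to $10^{-8}$ relative
  accuracy on every solve. A $10^{-6}$-scaled ridge is added only when a
  covariance factorization fails, and always with a warning.

## 3. Relationship matrices and standardization

Marker QC retains markers with minor allele frequency above 5% and
missingness below 20% (computed on observed calls), then sets surviving
missing genotypes to the heterozygote code. Allele frequencies for
centering are always recomputed from the supplied lines.

Feature standardization centers and scales each column to mean 0 and
standard deviation 1 with the **population (n) denominator**, which makes
the average diagonal of $\mathbf{Q} = \mathbf{M}\mathbf{M}'/q$ exactly 1 —
a convenient normalization for interpreting $\bar Q \sigma^2_u$. The
convention is configurable (`denominator = "n-1"`); the choice only
rescales $\sigma^2_u$ by $n/(n-1)$ and leaves predictions invariant.
Zero-variance features are dropped and counted. Any upstream "adjustment"
preprocessing can be injected as a function; the default is centering and
scaling only, since adjustment protocols are assay-specific.

## 4. Cross-validation, the LR method and scenarios

Validation responses are phenotypes corrected for the trial fixed effects
and batch effects of a full-data GBLUP fit. Two schemes: LOYO (mask all
plots of one year) and LOLO (mask all plots of one line). Scenarios define
what the validation set contributes: `g` — neither phenotypes nor features
(features are removed from $\mathbf{M}$ before standardization, so
standardization is always computed on the plots whose features are
available within the scenario); `gm` — features but not phenotypes (the
masked plots' $\hat u$ are predicted through $\mathbf{Q}$ in step 1 and
carried into step 2); `gp`/`gmp` — everything.

Predictive correlations and dispersion slopes are computed on validation
observations **pooled across folds** (one number per scheme × model ×
trait): per-fold metrics are undefined for LOLO folds of one line.
Differences between dependent correlations are tested with the Williams
form of the Hotelling–Williams $t$ ($n-3$ degrees of freedom, $n$ = pooled
validation observations).

The scenario with phenotypes masked but features retained is evaluated only
through the LR method, never through the predictive correlation with
corrected phenotypes: with validation features in the model, $\hat a$ and
the corrected phenotypes share environmental signal through
$\hat{\mathbf{u}}$, and the correlation stops measuring breeding-value
accuracy. The LR method instead compares predictions from nested data
scenarios on the validation lines: the correlation of
$\hat{\mathbf{a}}_p$ with $\hat{\mathbf{a}}_w$ estimates the ratio of
population accuracies, and the slope of $\hat{\mathbf{a}}_w$ on
$\hat{\mathbf{a}}_p$ estimates dispersion bias (expectation 1). Projected
accuracy gains multiply $(1 - \text{ratio})$ by the genomic-only accuracy
$\mathrm{cor}/\sqrt{h^2_{\text{corrected}}}$, where the heritability of
corrected phenotypes excludes the batch variance from the denominator, for
consistency with the correction applied.

Variance components in cross-validation are **re-estimated on each fold's
training data by default**; `vc = "full"` reuses full-data estimates in all
folds, which is the pragmatic choice for LOLO (hundreds of folds, each a
single linear solve instead of a REML run). Every result records which
policy was used. Both are defensible: fold-wise REML is the cleaner
inferential protocol, reused estimates are what large evaluations do in
practice.

## 5. The synthetic data generator

The generator draws all stages from the joint model with known parameters,
so every downstream estimator can be checked against truth. It emulates:
trials of 20–45 lines in randomised complete blocks with three replicates,
nested in location × year environments; two control lines in every trial;
contiguous processing batches within trials; roughly 45% of lines tested in
a second environment (matching the appearance rate implied by study-scale
data of ~2430 plots on 562 lines); binomially sampled 0/1/2 genotypes;
features and phenotypes from the model equations with fixed effects zero by
default (a `trial_effect_sd` hook injects them — the targets concern
variance structure, not fixed-effect recovery). Two optional population
structures make validation designs realistic where needed: year cohorts
(`line_assignment = "cohort"`, Beta-distributed per-cohort allele
frequencies with a chosen $F_{ST}$) and full-sib families
(`family_size`, two simulated parents per family with Mendelian
transmission). Batch-to-trial mapping in real programs is not public
knowledge; contiguous blocks are a stand-in.

Default generative variances give a trait with total phenotypic variance
about 1, metabolomic variance ratio $c^2_m = 0.5$, direct heritability
0.05 and common feature heritability 0.2 — the regime of a strongly
metabolome-mediated quality trait. Feature effects $\alpha$ act on the
*standardized* feature matrix (the same convention as $\mathbf{Q}$), and
the stored true $\mathbf{g}_{j,2}$ are rescaled by each feature's
population standard deviation so that the breeding-value identity holds
exactly for the $\alpha$ actually applied.

What the generator does **not** emulate: NMR spectra themselves (peak
shapes, chemical-shift correlation along the ppm axis), correlated features
(each feature is drawn independently — real features representing one
metabolite are strongly correlated), per-feature heritabilities (a
multiplier hook exists for robustness probes), non-Gaussian phenotypes, and
missing-data patterns. Passing tests therefore demonstrate correctness of
the estimators under the model's own assumptions, not robustness to their
violation on real spectra.

## 6. Problem sizes and statistical checks

The test suite works at deliberately scaled-down sizes chosen so the whole
suite runs in about a minute while keeping every check statistically
meaningful: REML calibration uses 50 replicates of a 100-line, two-
environment, three-replicate design with full-sib families (each component
and the implied heritability within three Monte-Carlo standard errors of
truth); the LR dispersion property uses 120 replicate leave-year-out folds
at the true variance components (mean slope within three standard errors of
1); the phenotypic-variance identity $E[S^2_y] = \sigma^2_P$ (which holds
in the absence of fixed effects) uses 120 replicates of a 30-line design;
and the LOLO-versus-LOYO ordering uses 90 lines in families nested within
year cohorts, where relatives of a left-out line are phenotyped under LOLO
but not under LOYO. The acceptance script repeats the LR dispersion
computation with 150 replicates under a caller-supplied seed.

Two empirical notes from building these checks. First, evaluating the LR
slope with fold-wise REML on a training set reduced to a *single*
environment is degenerate (the genomic variance is frequently floored and
the slope explodes); the dispersion property is therefore checked at the
known generative variance components, which is also the setting in which
its expectation is exactly 1. Second, exact row duplication of a dataset is
*not* a REML invariance: duplicated plots agree perfectly within identical
design cells, which deflates the residual variance — the suite checks
response-scaling equivariance (multiplying $y$ by $c$ multiplies every
variance by $c^2$) instead.

## 7. Known limitations

* Dense linear algebra throughout; no sparse or out-of-core path.
* Single-trait models with homogeneous residual variance; no pedigree
  relationships; no Bayesian or per-feature-heritability variants.
* Standard errors of variance components and heritabilities are not
  computed.
* The common-heritability assumption for features is required by the
  two-step procedure; traits whose metabolomic mediation is concentrated in
  a few highly heritable features will violate it.
* `run_pipeline()` and the exported functions are the interface; there is
  no shell executable.
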