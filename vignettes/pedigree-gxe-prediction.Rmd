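---
title: "Pedigree-based prediction with genotype-by-environment kernels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pedigree-based prediction with genotype-by-environment kernels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`pedgxe` implements the full analysis chain used to evaluate pedigree-based
prediction in a multi-year, managed-stress breeding program:

1. **Pedigree processing** — reading three-column pedigree records,
   topological ordering with cycle detection, generation-depth truncation,
   and the additive (numerator) relationship matrix **A** by the tabular
   method.
2. **Stage one** — per-trial linear mixed models fitted by REML, outlier
   screening, Cullis generalised heritabilities, and per-genotype
   per-environment BLUEs.
3. **Stage two** — a family of seven kernel-based mixed models (M1–M7) over
   the BLUEs, combining environment, additive, general/specific combining
   ability, and Hadamard-product interaction kernels, fitted by Bayesian
   multi-kernel Gibbs sampling with masked-record prediction.
4. **Cross-validation** — the CV2 (incomplete trials), CV1 (untested lines)
   and CV0 (untested years) schemes, with stress / non-stress / combined /
   crossed training compositions and weighted within-environment predictive
   ability.
5. **A synthetic breeding-program generator** with known simulation truth,
   so that every stage is testable without access to proprietary trial
   data.

# The models

Stage one fits, per trial,

$$y_{ijkl} = \mu + g_i + r_j + b_k + s_l + \beta\,x_{ijkl} + \varepsilon_{ijkl}$$

with genotype $g_i$ fixed (for BLUEs) or random (for heritability),
random replications $r_j$, random incomplete blocks $b_k$ (alpha-lattice
designs only), a random season term $s_l$ only when a trial genuinely spans
seasons, and a centred days-to-flowering covariate $x$. The combined-
condition model adds a fixed treatment (stress vs non-stress) effect and
allows a separate residual variance per treatment. Generalised
heritability is computed as
$H^2 = 1 - \bar v_{\mathrm{BLUP}}/(2\hat\sigma^2_g)$, where
$\bar v_{\mathrm{BLUP}}$ is the mean prediction-error variance of a
difference of two genotype BLUPs, obtained from the mixed-model equations
at the REML estimates.

Stage two models the BLUE $y_{ij}$ of line $i$ in environment $j$
(environment = year $\times$ stress condition) as a sum of zero-mean
Gaussian effect vectors, each with a known covariance kernel times an
unknown variance component:

| model | linear predictor |
|-------|------------------|
| M1 | $E_j + a_i$ |
| M2 | $E_j + a_i + aE_{ij}$ |
| M3 | $E_j + a_{P1} + a_{P2}$ |
| M4 | M3 $+\ a_{P1 \times P2}$ |
| M5 | M4 $+\ aE_{P1} + aE_{P2} + aE_{P1\times P2}$ |
| M6 | M4 $+\ aE_{P1} + aE_{P2} + aE_{ij}$ |
| M7 | M3 $+\ a_i + aE_{P1} + aE_{P2} + aE_{ij}$ |

with $\mathrm{cov}(a) = \mathbf{Z}_g\mathbf{A}\mathbf{Z}_g'\sigma^2_a$,
GCA kernels built from the parent sub-matrices $\mathbf{A}_{P1}$,
$\mathbf{A}_{P2}$, the SCA kernel as the Hadamard product of the two
parent kernels, and every environment interaction as the Hadamard product
of the corresponding main-effect kernel with the environment block kernel
$\mathbf{Z}_E\mathbf{Z}_E'$. The Schur product theorem keeps every
interaction kernel positive semidefinite. The only fixed effect is the
intercept; the environment main effect is a random effect with its own
variance, matching the models' distributional statements.

The interaction kernel used for the A-by-environment term in M6 and M7 is
the line-level kernel of M2; the formulas for those models restate their
components as "as before defined", and we read that literally rather than
re-deriving a cross-level kernel.

# Inference: multi-kernel Gibbs sampling

Stage two is Bayesian: each effect vector is sampled in the eigenbasis of
its kernel (where all conditional updates are diagonal), variance
components carry scaled-inverse-$\chi^2$ priors, and masked responses are
imputed by data augmentation each sweep, which is what yields predictions
for untested records. Responses are centred and scaled internally;
summaries return on the original kg/ha scale.

Numerical and prior choices, with reasons:

* **Priors**: $\mathrm{scaled\text{-}inv\text{-}}\chi^2(\nu = 5, S_0)$ per
  component, with $S_0$ set so the prior mode equals an equal share of
  50% of the phenotypic variance of the training responses (the remaining
  50% is the residual's share). This is the convention of the widely used
  multi-kernel samplers in this field. A consequence worth knowing: for a
  component with few levels (e.g. the environment main effect with a dozen
  environments) the prior share can exceed the true share and the
  posterior mean then sits 20–30% above the generating value; components
  with many levels are essentially unbiased. The parameter-recovery tests
  quantify this.
* **Chains**: 12,000 sweeps, 2,000 burn-in, thinning 5 by default;
  cross-validation runs use shorter chains (around 1,200/300/3) because
  only posterior-mean predictions are consumed there, and those stabilise
  quickly. Every fit requires an explicit seed and is bit-reproducible.
* **Eigenvalue clipping** at 1e-10 discards numerically null kernel
  directions.
* **Divergence guard**: any non-finite draw aborts with the iteration
  index.

The test suite holds the sampler against three independent oracles: the
closed-form ridge/shrinkage solution (variance updates disabled), the
direct mixed-model-equation BLUP at the posterior-mean variances, and a
naive full-covariance Gibbs sampler.

# Cross-validation design

* Fold assignment depends only on scheme, seed, replicate and the sorted
  record (CV2) or genotype (CV1) identifiers, so testing partitions are
  identical across training compositions; CV0 is deterministic
  (leave-one-year-out, one replicate).
* Kernels are always built over training plus testing records jointly;
  prediction of masked records falls out of the joint covariance.
* Predictive ability is the Pearson correlation between predicted and
  observed BLUEs *within* each environment-condition combination
  (environments with fewer than 3 scorable records are skipped), averaged
  with weights proportional to environment size — "weighted average"
  is not further defined in the source analyses, and record counts are the
  natural weight. Per replicate the fold-wise predictions are first
  integrated into one vector, then scored.
* Crossed calibrations (train on non-stress, predict stress, and the
  converse) exclude the target year in both conditions — a conservative
  reading of "novel environment".
* Checks are treated like any other genotype in fold assignment and
  scoring.

# The synthetic breeding program

The generator emulates, at desk scale, the topology that the analysis
relies on: founders crossed over several cycles with heavy parent reuse;
a small set of long-term check varieties present in every trial *and*
recurring as parents (as elite varieties do); sister lines (full sibs)
from each cross entering the program together; merit-based advancement in
which the top fraction of each year's entries (by observed mean yield) is
re-evaluated the following year; paired stress / non-stress trials each
year; RCBD and alpha-lattice layouts; a drought penalty applied to the
trial mean; wider per-trial residual-SD ranges under stress (which is
what depresses stress heritability); and a days-to-flowering covariate
with a fixed yield slope.

Default scale: 17 years × 2 conditions, 24 founders, 60 crosses × 2
sister lines per cycle over 3 cycles (~360 genotypes), 4 checks, 3
replications. These are desk-scale stand-ins for a program an order of
magnitude larger; the check count sits at the low end of the realistic
range so that the *share* of check records in a trial stays near what a
real multi-year series has (seven checks among two dozen entries would be
a quarter of every trial). With the default variance components
(additive 360,000; additive-by-environment 180,000;
genotype-by-condition 240,000; environment 250,000 (kg/ha)²; stress
residual SD drawn per trial from [700, 1500], non-stress from
[500, 1000]) the per-trial Cullis heritabilities fall inside the ranges
reported for real drought programs, with stress trials stochastically
below non-stress — the calibration the heritability-profile helper is
for.

Two generator terms are deliberately *absent* from the fitted models:

* a **genotype-by-condition** additive deviation (`sigma2_aC`),
  independent between stress and non-stress, making drought tolerance only
  partly the same trait as yield potential (cross-condition genetic
  correlation $\sigma^2_a/(\sigma^2_a+\sigma^2_{aC})$, 0.6 at the
  defaults). It is what makes crossed calibration genuinely harder, as
  observed in real programs.
* per-trial residual-SD heterogeneity beyond the two condition ranges.

What passing tests on these data do **not** show about real data: the
generator's additive values are exactly multivariate normal on the true
**A**, so pedigree information is as informative as it can possibly be;
there are no pedigree errors, no selection bias in who gets phenotyped
beyond the merit rule, no spatial field trends, and no epistasis or
dominance. Accuracies on real programs will be lower and model
differences smaller.

## Study conditions for the qualitative reproductions

The scheme comparison (CV2 ≥ CV1 > CV0) is asserted under an
interaction-dominant world: $\sigma^2_{aE}/\sigma^2_a = 5$, no stable
genotype-by-condition term, and 10% advancement. The choice is
deliberate: the hallmark of multi-year managed-drought series is that a
new year is close to unpredictable (novel-year predictive abilities
around 0.15 against 0.3+ for within-year schemes), which requires the
year-interaction share of genetic variance to dominate the stable share.
At interaction-to-main ratios near 1 the leave-one-year-out scheme is
*not* systematically worse in this generator — lines with own records in
other years (checks, advanced lines) are predicted well enough to offset
the new lines — and the ordering only emerges once interaction dominates.
We regard that as a finding about the data regime the original program
operates in, and document it rather than hiding it.

The crossed-calibration penalty is asserted at the default
genotype-by-condition variance (genetic correlation 0.6); the
combined-versus-single-condition comparison is asserted at a high genetic
correlation (0.857), because pooling conditions can only help when the
conditions mostly share their genetic signal — with weakly correlated
conditions the combined calibration genuinely loses to the
same-condition one in this generator, which mirrors why crossed
prediction is hard.

# Other design decisions

* Unknown parents are unrelated, non-inbred founders (standard tabular
  rule); parent-1/parent-2 are taken as recorded, with no attempt to
  infer maternal/paternal roles.
* Depth truncation counts generations upward from the phenotyped
  (terminal) lines; ancestors beyond the limit are dropped and the
  boundary ancestors re-declared founders. Default depth 7.
* Checks, which have no recorded parents, enter the GCA/SCA parent maps
  as selfs of themselves so that models M3–M7 can score them; lines with
  genuinely unresolvable parents are excluded and reported.
* Per-trial fits are done twice (genotype fixed for BLUEs, genotype
  random for heritability); REML estimation is delegated to `lme4` (and
  `glmmTMB` for the heteroscedastic combined model), after which BLUEs,
  BLUPs and prediction-error variances are recomputed from one explicit
  GLS / mixed-model-equation path so that all downstream quantities are
  mutually consistent.
* Outlier screening: externally studentized residuals of the whitened
  fit, two-sided t reference, Bonferroni–Holm correction at
  $\alpha = 0.05$ per trial, one refit (not iterated, to keep the
  procedure deterministic). Records flagged are set missing.
* Missing flowering-time covariates are imputed at the trial mean; the
  covariate is centred within trial.
* Duplicate genotype-by-environment BLUEs (two trials in one
  year-condition) merge by inverse-variance weighting.
* Stage-2 BLUEs enter unweighted; their standard errors are carried for
  reporting only.

# Problem sizes

Unit tests run on instances of 20–600 records; parameter recovery uses
600-record instances with 40 environments and 60 related lines (10
seeds); the scheme comparisons use an 8–10-year program with around 500
BLUEs, 10 cross-validation replicates and reduced chains. The
end-to-end acceptance script simulates a 10-year program (~600 BLUEs) and
runs three models through all three schemes with 3 replicates.

# Known limitations

* Dense linear algebra throughout; intended scale is up to a few thousand
  records.
* Single-trait stage 2 with homoscedastic residuals; no marker data, no
  factor-analytic or unstructured G×E covariances.
* Posterior means of small-level variance components inherit the prior
  pull described above; predictions are insensitive to this.
* The Cullis heritability uses the genotype-random refit of the same
  trial; trials with essentially no genotype signal can return 0 (with a
  warning), which is the honest answer for such trials.
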