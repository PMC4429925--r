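---
title: "Recursive structural equation models for milk coagulation traits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recursive structural equation models for milk coagulation traits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(milksem)
```

## The model

milksem fits Bayesian mixed models for four jointly recorded test-day milk
phenotypes — somatic cell score (SCS, log units), casein percentage (CAS,
%), rennet coagulation time (RCT, min) and curd firmness 30 min after
rennet addition (a30, mm) — with optional *recursive causal paths* among
the phenotypes. For record $i$ the structural form is

$$(\mathbf I - \boldsymbol\Lambda)\,\mathbf y_i =
  \mathbf B'\mathbf x_i + \mathbf h_{herd(i)} + \mathbf p_{cow(i)} +
  \mathbf s_{sire(i)} + \mathbf e_i,$$

where $\boldsymbol\Lambda$ holds the structural coefficients
$\lambda_{yx}$ (effect of phenotype $x$ on phenotype $y$, in units of $y$
per unit of $x$), $\mathbf x_i$ codes an intercept and four days-in-milk
classes (5–34, 35–64, 65–94, 95–125 d), and the random terms are herd,
cow permanent-environment and sire additive genetic effects. Priors and
covariance structures:

* $\mathbf s \sim N(\mathbf 0, \mathbf G \otimes \mathbf A)$ with
  $\mathbf A$ the numerator relationship matrix from a
  sire–maternal-grandsire pedigree (0.5/0.25 recursion);
* $\mathbf p \sim N(\mathbf 0, \mathbf P \otimes \mathbf I)$,
  $\mathbf h \sim N(\mathbf 0, \mathbf H \otimes \mathbf I)$,
  $\mathbf e \sim N(\mathbf 0, \mathbf R \otimes \mathbf I)$;
* $\lambda_{yx} \sim N(\lambda_0, \tau^2)$ with $\lambda_0 = 0$,
  $\tau^2 = 10\,000$; fixed effects $N(0, 10\,000)$;
* $\mathbf G$, $\mathbf P$, $\mathbf H$ inverse-Wishart with $\nu = 6$;
  $\mathbf R$ inverse-Wishart in the baseline multiple-trait model (MTM)
  and per-trait scaled inverse chi-square ($\nu = 6$) in any structural
  model, where $\mathbf R$ is forced diagonal — the standard parametric
  identification constraint for recursive systems.

Because the causal graph is acyclic, some trait ordering makes
$\boldsymbol\Lambda$ strictly lower triangular, so
$\det(\mathbf I - \boldsymbol\Lambda) = 1$ and the reduced form
$\mathbf y_i = (\mathbf I - \boldsymbol\Lambda)^{-1}(\cdot)$ needs no
Jacobian correction. Structures are *declared*, never searched: presets
`M0` (no paths), `M1` (SCS and CAS each affect RCT and a30), `M2`
(RCT affects a30), `M3` (SCS, CAS and RCT affect a30), and the two
auxiliary reductions `M1-SCS`, `M1-CAS`.

## Sampling scheme

`fit_sem()` runs Metropolis-Hastings-within-Gibbs, implemented in
compiled (RcppArmadillo) code driven by R's RNG, so chains are
bit-reproducible for a fixed seed:

* fixed effects, herd, cow and sire blocks from their multivariate-normal
  full conditionals; the sire block is updated individual-by-individual,
  shrunk through $\mathbf G^{-1}$ and the rows of $\mathbf A^{-1}$, so
  ancestors without records are sampled too;
* $\mathbf G$, $\mathbf P$, $\mathbf H$ (and $\mathbf R$ in the MTM) from
  inverse-Wishart full conditionals; SEM residual variances per trait
  from scaled inverse chi-squares;
* each $\lambda_{yx}$ by a scalar Gaussian random-walk on the reduced
  residuals of trait $y$. A closed-form normal conditional exists for
  recursive systems; MH is used deliberately (matching the reference
  analysis protocol) and the closed form serves as an independent test
  oracle.

Default protocol: 120 000 iterations, 20 000 burn-in, thinning 10 —
exactly 10 000 retained samples. Proposal SDs adapt only during burn-in
(Robbins-Monro toward 0.30 acceptance, batches of 50) and are frozen
afterwards so the post-burn-in kernel satisfies detailed balance.

Tunable parameters that matter in practice: `step_init` (proposal SD;
adaptation makes the default robust), the prior scale matrices (below),
and the chain protocol. The fixed-effect design uses a corner constraint
(fourth days-in-milk class as reference) because intercept plus four
classes is rank-deficient; the reference analysis does not state its
constraint, so this is a package choice.

### Prior scales

The analysis protocol fixes $\nu = 6$ but not the scale matrices. The
defaults are weakly informative and data-derived: each of the four
variance components is centred at *half an equal share* of the observed
phenotypic variance of its trait,
$S = \tfrac12\,(\nu - n_t - 1)\,\mathrm{diag}(\widehat{var}/4)$ for the
Wishart scales and $S_t = \tfrac12 (\nu - 2)\,\widehat{var}_t/4$ for the
residual chi-squares. Both are fully overridable via `prior_spec()`. For
traits with very little genetic signal and few sires these priors pull
variance ratios toward the prior centre; structural coefficients, which
are likelihood-dominated, are essentially unaffected. Whether $\nu = 6$
applies to the univariate residual priors as well is ambiguous in the
protocol; the package adopts $\nu = 6$ per trait.

## Derived quantities

SEM-scale dispersion matrices are mapped to the MTM scale per retained
draw, $\mathbf G^* = (\mathbf I-\boldsymbol\Lambda)^{-1}\mathbf G
(\mathbf I-\boldsymbol\Lambda)'^{-1}$ (likewise $\mathbf P^*, \mathbf
H^*, \mathbf R^*$), and every derived scalar is computed per draw and
then summarised (posterior mean, 95% highest-posterior-density interval):

* heritability $h^2 = 4\sigma^2_s / (\sigma^2_s + \sigma^2_p +
  \sigma^2_h + \sigma^2_e)$ (sire model, herd included in the
  phenotypic variance — the reporting convention adopted here; the
  alternative of excluding the herd term is noted but not used);
* genetic correlations from $\mathbf G^*$ alone, phenotypic correlations
  from $\mathbf G^* + \mathbf P^* + \mathbf H^* + \mathbf R^*$;
* SD-unit causal effects $\lambda'_{yx} = \lambda_{yx}\,sd(x)/sd(y)$
  using the *observed* phenotypic SDs of the fitted records, not
  model-implied SDs;
* variance losses $100\,(\sigma^2_{M0} - \sigma^2_{Mk}) /
  \sigma^2_{M0}$, reported both as point arithmetic on posterior means
  (the reporting convention for published loss percentages) and
  summarised per paired draw (`variance_loss_summary()`).

Per-draw propagation (rather than plugging summarised components into
the formulas) is the statistically coherent choice where the reporting
convention is ambiguous; the point-arithmetic variant is kept for the
variance losses because that is how such losses are conventionally
printed.

HPD intervals use the sorted-sample shortest-window method with ties
broken toward the lower start; effective sample sizes use Geyer's
initial-positive-sequence truncation of the autocorrelation sum.
Constant chains yield `NA` ESS with a warning.

## The synthetic-data generator

No individual-record dataset is deposited for the emulated study, so the
generator reproduces its *design*: 3266 first-lactation cows in 309
herds sired by 128 AI bulls within a 1254-bull sire-MGS pedigree and
about 2.7 records per cow (8783 records in total), shrinkable by a
single `scale` factor. Records per cow are zero-truncated Poisson with
mean 8783/3266; days-in-milk classes advance sequentially per cow from a
random start, mimicking monthly recording; cows are spread over herds
evenly and sires are drawn with heterogeneous popularity weights shared
across herds, so herd and sire effects are separable by design (a
`sires_per_herd` cap exists to create deliberately confounded fixtures).
The pedigree generator gives each non-founder bull a sire (known with
probability 0.9) and a maternal grandsire (known with probability 0.7)
among earlier bulls with popularity weights, creating the large paternal
half-sib families typical of AI breeding; founders are 35% of the
pedigree. Unknown parents enter as unrelated founders; unknown-parent
groups are out of scope.

`default_truth()` supplies the generator's true parameters. Full
$\mathbf G/\mathbf P/\mathbf H/\mathbf R$ matrices are not reported for
any fitted model, so the truth is a *consistent completion* assembled on
the MTM scale from: observed trait SDs (1.66, 0.23, 3.80, 8.53) for the
total variances of SCS, CAS and RCT; the model-based total 81.998 and
sire variance 3.829 for a30; baseline heritabilities (0.030, 0.157,
0.167) for the remaining sire variances; and the baseline genetic and
phenotypic correlation matrices for all covariances. These are
congruence-transformed to the SEM scale with the requested preset's
reference coefficient means (e.g. $\lambda_{a30,RCT} = -1.901$ under
M2). The SEM-scale residual is kept exactly diagonal by construction:
the residual takes 50% of the SEM-scale environmental variance per
trait and the remainder splits 30% herd / 70% permanent environment,
with *all* environmental off-diagonals carried by the herd and PE
components. This keeps the implied MTM-scale totals exact (the implied
a30 heritability is 0.1868, printed 0.187) at the cost of component
shares that are a modelling choice, not data. Should a requested
completion leave a matrix indefinite, it is projected to the nearest
positive semi-definite matrix with a warning. The structural (M1–M3)
truths need no projection; the causality-free `M0` truth does trigger it
for the herd+PE remainder, because with `Lambda = 0` the strong
environmental RCT–a30 association cannot be split between a diagonal
residual and positive semi-definite herd/PE parts without clipping — the
projection perturbs that truth's implied totals slightly. Days-in-milk fixed-effect contrasts are small plausible
early-lactation trends, another generator choice.

What the generator does *not* emulate: raw-scale somatic cell counts,
lactation-curve dynamics, censored coagulation times (the 5–10% of
samples that never coagulate within 30 min), missing traits, and
selection or non-random mating. Passing recovery tests therefore shows
the estimator is correct *under the assumed model*, not that field data
meet those assumptions.

## Validation strategy and problem sizes

The posterior estimates of the emulated study cannot be reproduced
without its records, so the test suite validates machinery instead:

* desk-scale arithmetic (SD-unit transforms, heritabilities, variance
  losses) reproduced exactly from printed summary inputs;
* parameter recovery at quarter scale (about 800 cows, 2200 records, 314
  pedigree bulls): 20 replicates simulated under the M2 truth and fitted
  with 15 000 iterations each; the posterior mean of
  $\lambda_{a30,RCT}$ must sit within 3 posterior SDs of the truth and
  the 95% HPD must cover it at roughly the nominal rate;
* a stripped single-trait model whose Gibbs draws are compared with the
  closed-form normal–inverse-chi-square posterior by Kolmogorov–Smirnov
  tests on 10 000 thinned draws;
* bit-identity of the SEM code path with an empty edge set and the MTM;
* algebraic properties (unit determinant, Neumann-series inverse,
  round-trip and PSD preservation of the scale transform, HPD/ESS
  closed forms on normal and AR(1) draws) on randomly generated cases;
* mutual-oracle pedigree checks: the tabular relationship matrix against
  a directly assembled Henderson-rule inverse on random pedigrees.

Chain lengths in the test suite (hundreds to a few thousand iterations
on reduced designs; 15 000 for the recovery replicates) are the sizes at
which these checks are statistically decisive; full-protocol chains are
intended for real analyses via `run_pipeline()`.

## Known limitations

* Sire-model only: dam pedigree and maternal effects are out of scope;
  dam-mediated covariance is absorbed by the residuals, which sits
  uneasily with a diagonal SEM residual — a known, accepted tension of
  recursive sire models.
* No model-choice criteria, no censoring model for RCT, no structure
  search, and no missing-phenotype imputation.
* The relationship matrix is built dense; at the 1254-bull scale this is
  cheap, but very large pedigrees would want a sparse-inverse assembly.
* Posterior draws are stored for dispersion parameters, fixed effects
  and structural coefficients; location random effects are summarised by
  posterior means only.
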