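---
title: "Polygenic risk scores by SVD projection: model, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Polygenic risk scores by SVD projection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

A polygenic risk score (PRS) summarizes a person's aggregate genetic
liability for a complex trait as a weighted sum over many variants. The
conventional construction estimates each variant's marginal effect in a
discovery cohort — with the leading genotype principal components added as
covariates to guard against population stratification — and then scores an
independent target cohort with those weights after LD clumping and p-value
thresholding. When the leading principal components are strongly correlated
with the phenotype (as happens whenever trait prevalence differs across
ancestries), this adjustment removes not only confounding but also genuine
predictive signal: the weights are *over-adjusted* and target-cohort
prediction collapses, especially in ancestrally mixed targets.

This package implements an alternative that regresses the phenotype on a
small, phenotype-selected set of genotype principal components and carries
the component coordinate system — not per-variant weights — to the target
cohort.

## The model

Genotypes are hard-call dosages $g_{ij} \in \{0,1,2\}$ counting the effect
allele. Each variant is normalized as
$z_{ij} = (g_{ij} - 2p_j)/\sqrt{2p_j(1-p_j)}$ with $p_j$ the allele
frequency; missing dosages contribute exactly 0 on the normalized scale
(the column mean). The working model is the linear random-effects model

$$y = \mu + Zb + e, \qquad b \sim N(0, \sigma_a^2 I),\quad
e \sim N(0, \sigma_e^2 I),$$

whose covariance structure is governed by the genetic relatedness matrix
$K = ZZ^T/m$. Writing the SVD $Z = U \Lambda V^T$ turns the model into a
regression on the principal components $u_k$, and the package fits the
reduced form

$$y = \mu + \sum_{k \in S} u_k \gamma_k + e$$

by ordinary least squares on a selected component set $S$.

Fitting the full random-effects model is deliberately out of scope: with
$m \gg n$ it has more parameters than observations, and its out-of-sample
application is itself an open problem. The component regression sidesteps
both issues.

### Scaling convention

Throughout the package, singular values $\lambda_k$ refer to the scaled
matrix $Z/\sqrt{m}$ — equivalently $\lambda_k = \sqrt{\sigma_k}$ with
$\sigma_k$ the eigenvalues of $K = ZZ^T/m$. Under this scaling the spectrum
bulk of an unstructured cohort sits near 1 (Marchenko–Pastur), the largest
singular value at $n = 1000$, $m = 100{,}000$ is about 1.1 and stays below
5, and the default component-selection cutoff below is meaningful. Under
unscaled $Z$ the same cutoff would be useless — every squared EigenCorr
would dwarf it.

### Component selection by EigenCorr

Components are ranked by

$$\mathrm{EigenCorr}_k = \mathrm{cor}(u_k, y)\,\lambda_k,$$

and $S = \{k : \mathrm{EigenCorr}_k^2 > 0.1\}$. The cutoff is the product
of two ceilings: under the null, $\mathrm{cor}(u_k, y)$ behaves as
$t/\sqrt{n-2+t^2}$ with $t$ a $t_{n-2}$ variable, giving a 95% bound of
0.062 at $n = 1000$ (`nullCorrBound()`), and the singular-value ceiling is
5, so $0.062^2 \times 5^2 = 0.0961 \le 0.1$. The key property — and the
reason this beats selecting components by eigenvalue — is that a component's
phenotype relevance is decoupled from its eigenvalue rank: a mid-spectrum
component can carry the strongest signal while the lead eigenvalue carries
none. Both selection rules (strict `>` at the cutoff, strict `<` at the
p-value threshold) follow the definitions above literally.

### Variant selection

Before the decomposition, variants are selected in the discovery cohort by
greedy LD clumping (take the smallest-p unprocessed variant as an index,
remove neighbors within a closed ±500 kb window whose dosage $r^2$ exceeds
$\rho$; every variant is index-eligible) followed by p-value thresholding
($p < \theta$) of a simple, unadjusted marginal regression scan. The
recommended operating point is $\rho = 0.1$, $\theta = 0.1$: tight enough
that retained variants are nearly independent, loose enough to keep the
information content feeding the decomposition. Ties on p are broken by
(chromosome, position, id), making the clump deterministic across
platforms. Whether the selection scan should itself be
covariate-adjusted is genuinely open; we default to the unadjusted scan
(the selection exists to enrich the decomposition, not to estimate
unbiased effects) and expose covariates as an option.

### Target projection and scoring

The right singular vectors are recovered from the Gram-matrix route
($v_k = Z^T u_k/\lambda_k$, computed on $Z/\sqrt{m}$), and a target matrix
$B$ — normalized with the *discovery* frequencies, on the model's variant
list and order — is projected as $u_k^{(B)} = B v_k / \lambda_k$. The score
is

$$\mathrm{PRS}_i = \sum_{k \in S} \hat\gamma_k\, u_{ik}^{(B)},$$

with no intercept (an option adds the stored $\hat\mu$ for calibrated
scores; the default $R^2$ evaluation is location-invariant either way).
Using discovery frequencies for the target normalization is a deliberate
choice the sources leave unstated: the projection only makes sense if both
cohorts live in the same coordinate system, and that system is defined by
the discovery normalization. `normalizeGenotypes(g, p = ...)` exposes the
switch.

A fitted model is shared as a plain-text bundle holding only the singular
values, right singular vectors, component effects and the variant list with
discovery frequencies — no individual-level genotypes or phenotypes, so
discovery confidentiality is preserved. Numeric fields are written with 17
significant digits and round-trip bit-identically.

## Tunable parameters

| parameter | where | default | meaning |
|---|---|---|---|
| `rho` | `selectionConfig()` | 0.1 | dosage $r^2$ above which a neighbor is clumped away |
| `theta` | `selectionConfig()` | 0.1 | marginal p-value threshold (strict) |
| `windowKb` | `selectionConfig()` | 500 | closed clump half-window, kb |
| `clumpP1` | `selectionConfig()` | 1 | index-eligibility p ceiling |
| `cutoff` | `trainSvdPrs()` | 0.1 | squared-EigenCorr selection cutoff |
| `kMax` | `spectralSvd()` | min(n, 100) | components computed and ranked |
| `nPcs` | `conventionalEffects()` | 10 | PC covariates of the baseline |
| `nPcs` | `fitAncestryModel()` | 20 | PC predictors of the classifier |
| `threshold` | `assignAncestry()` | 0.9 | posterior needed for a label |
| `mafMin`, `hwePMin`, `maxMissingRate` | `qcThresholds()` | 0.01, 1e-6, 0.05 | variant QC |

## The baseline and the ancestry module

The conventional baseline (`trainConventional()`/`ctScore()`) applies
$S_i = \sum_j \hat\beta_j g_{ij}$ on raw target dosages, with
$\hat\beta_j$ from marginal regressions carrying 10 PC covariates
(computed on the post-QC, pre-clump matrix; a genuinely open ordering, and
the switch is exposed), and missing target dosages imputed at the
discovery mean dosage $2p_j$.

The ancestry module mirrors reference-panel practice: PCA on the merged
reference-plus-query matrix, a Fisher linear discriminant (shared pooled
covariance) on the labeled samples' top 20 PC coordinates, and posterior
thresholding at 0.9 — samples below it stay "unassigned". Class priors are
equal by default: reference-panel class sizes are design artifacts, not
population proportions; a switch restores proportional priors. Queries that
were part of the merged PCA are looked up directly; new cohorts can be
projected out-of-sample through the stored right singular vectors.

## The simulator: what it emulates and what it does not

`simulateCohort()` generates discovery/target pairs under the
Balding–Nichols model: ancestral frequencies uniform on (0.05, 0.95),
population frequencies Beta-distributed around them with differentiation
$F_{ST}$ per population (0.15 by default, continental-scale divergence),
dosages binomial, phenotypes exactly $y = \mu + Zb + e + s(\mathrm{pop})$.
The per-population shift $s$ is the mechanism that emulates
structure-confounded phenotype differences — the regime where
over-adjustment bites — and defaults to 0; the directional comparisons use
1.3, matching the scale of real between-ancestry symptom-count contrasts
relative to their spread.

The default genetic architecture is infinitesimal: every variant causal
with per-variant effect variance $\sigma_a^2 = 10^{-4}$ on the normalized
scale, so the aggregate genetic variance is $m\sigma_a^2 = 0.5$ against
residual variance 1 while each single effect is far below detectability at
$n = 1000$. This is the package's own emulation choice, made because the
method targets highly polygenic traits whose per-variant effects are
individually negligible; with a sparse architecture of individually
estimable effects the conventional baseline is a well-matched tool and the
comparison below is not expected to favor projection.

Deliberately **not** emulated: within-window LD (variants are independent;
clumping tests construct correlated variants explicitly), pedigree or
cryptic relatedness, case-control liability traits, imputation error, and
genotyping batch effects. Passing simulation tests therefore demonstrates
the algebra and the structural mechanism, not performance on real LD
patterns. Phenotypes are continuous; real symptom counts are integer-valued
and skewed, which affects $R^2$ magnitudes but not the over-adjustment
mechanism.

All draws flow from one seed in a fixed stream order (frequencies,
discovery genotypes, target genotypes, causal effects, discovery errors,
target errors, missing masks), so a configuration pins the entire study
bit-for-bit; genotype generation is chunked column-major, which leaves the
stream independent of chunk size.

## Numerical choices

- **Gram-matrix SVD**: with $m \gg n$ the left system comes from
  eigendecomposing the $n \times n$ matrix $ZZ^T/m$; round-off-negative
  eigenvalues are clipped to 0, and $\sigma_k < 10^{-12}\sigma_1$ is
  treated as exact rank deficiency (such components never enter $S$ and
  refuse right-vector extraction).
- **Sign convention**: each $u_k$ is oriented so its largest-magnitude
  entry is positive, and $v_k$ inherits the orientation. Scores are
  provably sign-invariant; the convention only stabilizes serialized
  artifacts across linear-algebra backends.
- **Component effects**: although $\hat\gamma_k = u_k^T y$ when the $u_k$
  are mean-zero (exact for complete data), the joint OLS solve is used so
  the fit stays exact when missing-data imputation leaves columns slightly
  off-center.
- **HWE**: a closed-form 1-df chi-square goodness-of-fit test (not the
  exact test); at the $10^{-6}$ removal threshold and common-variant counts
  the difference is negligible, and monomorphic variants get p = 1 by
  convention. HWE is computed on all samples pooled, accepting
  structure-induced departures, mirroring QC run before any ancestry split.
- **Missing data**: mean-imputed per variant in association scans and LD
  ($r^2$ on raw dosages, PLINK-style), exactly 0 on the normalized scale,
  and $2p_j$ in conventional scoring.
- **Missing-rate QC direction**: variants are removed when missingness
  *exceeds* 0.05 — the standard reading; the removal-list phrasing "missing
  rate < 0.05" taken literally would discard well-called variants.
- **Harmonization**: variants match on (chromosome, position, unordered
  allele pair); ids are not trusted; swapped alleles flip dosages
  ($g \to 2-g$); no strand flipping is attempted — ambiguous A/T and C/G
  variants are removed in QC and non-matching allele sets are dropped.

## Problem sizes used by the test suite

The suite verifies the algebra on small random matrices
($n, m \le 100$, against direct SVD and closed forms), the spectral claims
on one $n = 1000$, $m = 100{,}000$ unstructured cohort, and the
directional method comparison on 20 simulated studies of
$1000/1000$ samples and $m = 5000$ variants (2 populations,
$F_{ST} = 0.15$, shift 1.3, infinitesimal genetics). These sizes were
chosen as the smallest at which the spectral bulk, the null-correlation
bound and the over-adjustment mechanism all operate at their intended
scales.

## Known limitations

- Variant selection and the decomposition use discovery data only; targets
  must contain every model variant (no on-the-fly imputation).
- The simulator's independence of variants means clumping behavior on
  realistic LD blocks is exercised only by constructed fixtures.
- $R^2$ is squared correlation, so scores are compared location- and
  scale-free; calibrated absolute scores need `addIntercept = TRUE` and a
  phenotype on the discovery scale.
- The EigenCorr cutoff presumes the $Z/\sqrt{m}$ scaling and roughly
  GWAS-scale $n$; very small $n$ inflates the null bound and the cutoff
  should be revisited via `nullCorrBound(n)`.

## A minimal session

```{r example}
library(svdprs)

study <- simulateCohort(simulationConfig(ancestryShift = c(0, 1.3),
                                         seed = 1))
model <- trainSvdPrs(study$discovery$genotypes, study$discovery$phenotype)
model
prs <- applySvdPrs(model, study$target$genotypes)
rSquared(prs, study$target$phenotype)

baseline <- trainConventional(study$discovery$genotypes,
                              study$discovery$phenotype)
rSquared(ctScore(study$target$genotypes, baseline),
         study$target$phenotype)
```
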