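---
title: "Models and design choices in bftrans"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design choices in bftrans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bftrans)
```

`bftrans` analyses the cholinergic basal forebrain (BF) in a case–control
imaging study and links its structural covariance to gene expression. This
vignette is the package's account of the science: the models it fits, the
parameters that matter, what the synthetic generator does and does not
emulate, and the choices made where the design was genuinely open.

## 1. Clinical-stage statistics

All group analyses are multiple linear regressions; a "difference" is the
t-test of the diagnosis coefficient with covariates in the model, and an
"adjusted correlation" is the t-test of the ROI coefficient in a
regression of the outcome on ROI plus covariates. This coefficient-test
reading of covariate adjustment is used consistently because it is the
only one that produces the residual degrees of freedom the per-analysis
reports carry.

Conventions adopted where a choice had to be made:

* **Two-sided tests throughout.** Every reported p equals
  `t_tail_p(statistic, df)` by construction, so tables are internally
  consistent.
* **Missing data** are handled by listwise deletion per model, and the
  used n is reported. Degrees of freedom therefore vary across analyses
  with the availability of each score, which is the behaviour a clinical
  sample with scattered missingness produces.
* **Levene's test** uses the median-centred (Brown–Forsythe) variant by
  default — robust to the mild skew of diffusivity measures — with the
  mean-centred variant as an option.
* **The decoupling (interaction) model** `choline ~ qT1 × diagnosis +
  age + sex` excludes smoking and cannabis by design: controls contain no
  smokers and cannabis use separates the groups strongly, so either
  covariate is nearly collinear with the interaction's group margin.
* **Group comparisons from summary statistics** (`t_from_summary()`)
  offer pooled and Welch variants behind a flag, since published
  demographic tables rarely state which was used.

Multiple-testing families are fixed and explicit: 3 region tests
(threshold 0.05/3 ≈ 0.0167), 8 clinical-correlate tests (0.00625), 12
cognitive tests (≈ 0.00417); FDR (Benjamini–Hochberg, via
`stats::p.adjust`) is used wherever a family is data-sized (vertices,
genes, gene sets).

## 2. Structural covariance mapping

`map_covariance()` correlates a BF seed's per-subject qT1 with every
vertex, FDR-corrected *within structure* (cortex per hemisphere, and each
subcortical structure separately) at q < 0.10, with a subthreshold
p < 0.05 flag as a fallback display. Subjects are pooled across groups by
default — covariance is a property of the sample, and pooling maximises
n — with a stratified mode available. Vertices missing in more than 20%
of subjects (configurable) or constant across subjects are excluded and
counted. No spatial smoothing is applied to r maps, and covariates are
not regressed out by default; a residualised mode can be built from
`ols_fit()` residuals if wanted.

## 3. Expression preprocessing and matching

Probe collapsing keeps QC-passing probes and selects, per gene, the probe
with the highest correlation to reference RNA-seq (ties break on the
lowest probe id). Sample QC is declarative — label allow-lists, a
bounding-box rule for BF-labelled coordinates, explicit exclusions — so
every removal is logged with its rule.

Sample-to-vertex matching assigns each cortical sample to its nearest
vertex by Euclidean distance in the shared mm frame. Numerical policy:

* samples farther than 10 mm (default) are removed **before**
  deduplication; the reverse order is available behind a flag since the
  order is not canonical;
* where several samples share a nearest vertex, the closest is retained;
  distance ties break on lowest vertex id, then lowest sample id, making
  the assignment order-invariant and deterministic;
* matching defaults to the left cortex only, reflecting atlases in which
  only a minority of donors sampled the right hemisphere; a
  both-hemispheres flag exists.

The retained set is a partial bijection (each sample one vertex, each
vertex at most one sample); this invariant is enforced downstream and its
violation is an integrity error, not a silent fix. Raising the cutoff can
only add matches, never remove one, because newly admitted samples are
necessarily farther than any previously retained competitor.

## 4. Region-specific expression: moderated t

Per gene, OLS of log2 expression on donor indicator blocks plus a
target-region indicator, restricted to donors that sampled both BF
regions. Donors enter as fixed effects: with a handful of donors
contributing blocks of samples, fixed indicators are the standard design
for this analysis and keep the per-gene model closed-form. The default
contrast is target-versus-all-other-sampled-regions, with a pairwise
(Ch1-3 vs NBM) mode; when the two BF contrasts are both run, moderation
hyperparameters are refit per contrast.

Empirical-Bayes moderation estimates (d₀, s₀²) by matching moments of
log s²_g: with `e_g = log s²_g − ψ(d_g/2) + log(d_g/2)`, d₀ solves
`ψ′(d₀/2) = var(e) − mean ψ′(d_g/2)` (trigamma inverse by Newton
iteration, tolerance 1e−10) and s₀² follows from the mean of e. When the
observed spread of log s² does not exceed its sampling variance, d₀ = ∞
and s₀² is the mean variance. Genes with zero residual variance or zero
residual df are flagged degenerate, excluded from hyperparameter
estimation, and reported with NA statistics. Posterior variances
interpolate raw and prior variance; t statistics use `d_g + d₀` degrees
of freedom, with the continuous t distribution at fractional df. The test
suite verifies exact agreement with an independent reference
implementation of the same estimator (limma) and the analytic limits
d₀ → 0 (ordinary t) and d₀ → ∞ (fully pooled variance).

Gene ranking uses the signed significance score `−log10(p)·sign(t)`,
which orders identically to (sign, p).

## 5. Imaging transcriptomics: per-gene mixed models

For each gene, the vertex-level covariance r at matched samples is
regressed on that gene's expression with a donor random intercept. The
REML fit is profiled to one dimension: for variance ratio
λ = σ²_donor/σ²_resid, all GLS quantities reduce to per-donor sums, and
the criterion `(n−p)·log RSS(λ) + log|V| + log|X'V⁻¹X|` is minimised by
golden-section search over log λ ∈ [−30, 12] (tolerance 1e−9). Fits whose
criterion at λ = 0 matches or beats the interior optimum are flagged
singular and fall back to OLS — dropping near-singular genes would bias
the decile ranking, so they stay in. The slope is tested by Wald t with
df = n − 2; a profile-ML likelihood-ratio test is available behind a
flag. Expression is not donor-z-scored by default (a flag exists);
slopes are exactly equivariant to expression scaling either way.

Deciles are flagged on the t ranking with size `floor(0.10·n)` per tail
and ties broken by gene identifier. The suite checks the fit against a
grid-search oracle over λ (step 1e−3) and against lme4.

## 6. Enrichment

Disease-set overlap uses the hypergeometric upper tail against a
collection harmonised to a background universe, with BH-FDR over sets and
a deterministic tie-break by set name. The default universe is all genes
surviving probe selection — external enrichment services use hidden,
irrecoverable backgrounds, so the package makes the background explicit
and configurable. GMT is the exchange format (read via fgsea).

Cell-type enrichment follows the specificity-index idea: the statistic
for gene g and cell type c is g's expression in c minus its mean
elsewhere, calibrated against a pooled row-permutation null (default 100
permutations, seeded, add-one-corrected), giving a probability-like pSI
in (0, 1]; constant genes get pSI = 1. Marker sets at thresholds
0.05 … 1e−4 are nested by construction (the classic nested-hexagon
display), and the enrichment grid is FDR-corrected jointly across
(cell type × threshold) cells, with a per-threshold option. Empty marker
sets yield NA cells rather than errors.

## 7. The synthetic generator

The generator produces data with the statistical structure the analysis
assumes, so that every stage can be validated by parameter recovery. It
emulates: two groups of 56/29; age, sex, smoking and cannabis
distributions with the cannabis–diagnosis overlap a psychosis sample
shows (no control smokers); a shared per-region demyelination latent that
co-perturbs qT1, AxD and RD; Ch1-3 group effects; choline coupled to left
NBM qT1 in controls (r = −0.5) and decoupled in patients; symptom scores
coupled to left-NBM microstructure within patients; a smooth projection
field over two cortical hemispheres plus labelled subcortical structures
(strong hippocampal weight) that scales each subject's BF latent; and a
six-donor expression bundle in the same coordinate frame with donor
intercepts, probe-level QC flags, BF-enriched genes, field-coupled
genes, one misplaced BF sample and two over-distance right-hemisphere
samples as planted QC cases.

Default magnitudes, chosen once and with units:

* **Ch1-3 effects 0.9 SD (qT1, AxD) and 0.7 SD (RD).** The case-control
  model includes cannabis use, which is strongly group-separating, so the
  adjusted diagnosis test pays a variance-inflation cost; 0.9 SD puts the
  adjusted t in the high-2s to 3 range, the regime such studies report.
  The weaker RD effect mirrors RD's role as the less sensitive myelin
  surrogate.
* **HC coupling r = −0.5** (more myelin, more choline). At n = 29 the
  correlation test's exact power is ≈ 0.82, so recovery checks allow
  two Monte-Carlo standard errors around the 80% recovery target.
* **Expression effects in total-SD units** (donor + residual variance,
  donor SD 0.3, residual SD 0.2–0.45 log2): a "1 SD" BF enrichment is 1 SD
  of observed expression, which the donor-adjusted model resolves with
  headroom given only 17 BF samples.
* **Field amplitude 30 ms per latent SD**, Gaussian bumps of bandwidth
  25 mm (positive frontal, negative occipital, flat subcortical weights),
  smooth noise through a 60-bump random basis (SD 35 ms) plus 15 ms white
  noise — enough spatial structure to make covariance mapping non-trivial
  without a mesh model.

What the generator does **not** emulate: MRI physics and preprocessing,
mesh topology of real brains, microarray noise beyond
log-normal + donor intercepts, within-donor normalisation pipelines, and
spatial autocorrelation of expression beyond the planted field. Passing
recovery tests therefore demonstrates that the analysis code recovers the
structure it assumes — not that real data satisfy those assumptions.

Determinism: every generator takes an explicit seed and identical
seed + config reproduce outputs exactly; the pipeline writes canonical
TSVs (6 significant digits, tab-separated, LF) so whole-run manifests are
byte-stable, and partial re-runs by stage name read the same files a full
run writes.

## 8. Problem sizes used in validation

The shipped tests run the full-size cohort (85 subjects) everywhere, a
250-vertex-per-hemisphere surface with a 400-gene bundle for the
structural chain, 1000–5000-gene draws for hyperparameter recovery, and
30–500 replicates for calibration and power properties; the acceptance
script uses 500 vertices per hemisphere and 1000 genes. These sizes were
chosen so each property is measured with useful Monte-Carlo precision
while the whole suite stays interactive; all scale knobs are config
arguments, and nothing in the code depends on these particular values.

## 9. Known limitations

* The per-gene mixed model uses a Wald t with df = n − 2; Satterthwaite
  or Kenward–Roger df are out of scope, which makes small-donor-count
  p-values mildly optimistic when donor variance is large.
* Covariance maps carry no spatial cluster inference and no
  autocorrelation-preserving (spin-test) nulls; per-vertex FDR within
  structure is the only correction.
* pSI calibration pools the permutation null across genes, which is exact
  under exchangeable gene scales and approximate otherwise.
* The clinical stage models linear effects only; no robust or
  nonparametric alternatives are provided.
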