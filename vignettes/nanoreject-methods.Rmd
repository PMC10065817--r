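---
title: "Methods: nCounter processing and rejection classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: nCounter processing and rejection classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`nanoreject` implements a complete analysis chain for NanoString
nCounter gene-expression profiling of kidney-transplant biopsies, from
per-lane RCC files to a penalized classifier separating antibody-mediated
rejection (AMR) from other diagnoses (no rejection, and borderline or
T-cell-mediated rejection pooled as one group). This vignette explains
the statistical procedures, the tunable parameters and their defaults,
the design decisions taken where the methodology is genuinely open, and
what the synthetic-cohort generator does and does not emulate.

## Lane quality control

Each lane carries imaging metrics (fields of view attempted/counted,
binding density in spots/µm²), six positive spike-in probes on a
descending titration (128, 32, 8, 2, 0.5, 0.125 fM), negative probes
measuring non-specific background, and the panel content. `lane_qc()`
computes, per sample:

* **imaging ratio** — counted/attempted FOV, pass at ≥ 0.75. The
  platform convention; configurable because vendors have shipped other
  defaults.
* **binding density** — pass inside 0.1–2.25 spots/µm².
* **titration linearity** — R² of the least-squares fit of log2(count)
  on log2(concentration), pass above 0.95. A flat titration has zero
  response variance; it is reported as R² = 0 with a degenerate-fit flag
  rather than `NA`, so downstream windowing stays total.
* **limit of detection** — the 0.5 fM positive probe must sit at least
  two standard deviations above the negative-control mean. The SD is the
  sample SD (n − 1): negative-probe sets are small and the unbiased
  estimator is the common vendor practice.
* **normalization factors** — the technical (positive-control) factor
  must lie in 0.1–2.0 and the content (reference-gene) factor in
  0.1–8.0. Factors are anchored to the cohort: factor_i = (arithmetic
  mean over samples of per-sample geometric means) / (geometric mean of
  sample i), so multiplying each sample by its factor equalizes the
  geometric means at the cohort mean.
* **reference geometric mean** — the housekeeping candidates' raw
  geometric mean must reach 30 counts.

Exclusion combines these as: out-of-window factor, low reference
geometric mean, imaging or limit-of-detection failure, or out-of-window
binding density — except that a binding-density violation alone is
forgiven when titration linearity and both factors pass (the
binding-density exception). Violations that do not exclude (linearity
alone, an excepted binding density) are still flagged, so the report
distinguishes "watch this lane" from "drop this lane". Whether a
limit-of-detection failure excludes (default) or merely flags is
configurable (`exclude_on_lod`), since published workflows differ.

## Background threshold and probe filtering

Each sample's background is the mean of its negative probes plus two
sample SDs; the study-level detection threshold is twice the highest
per-sample background. An endogenous probe is dropped when its count
falls below the threshold in at least half the samples — inclusive, with
`ceiling(n/2)` on odd cohorts, and strictly `count < T` so a count equal
to the threshold survives. Filtering runs on raw counts after sample QC
and before normalization. Housekeeping probes failing the same rule are
flagged but never silently removed: deleting a reference candidate would
invisibly change normalization, whereas a flag keeps the decision
auditable.

## Reference-gene selection (geNorm) and normalization

For candidate genes *j*, *k*, the pairwise variation is
V_jk = SD over samples of log2(x_j / x_k), and the stability of gene *j*
is M_j, the mean of V_jk over the other candidates. The least stable
gene is removed and M recomputed until two genes remain, which share the
final two-gene M. The three genes eliminated last become the references
(k = 3 follows standard nCounter practice; configurable). Ties in M
resolve to the lexicographically first symbol so elimination is
deterministic. The V(m/m+1) series comparing normalization factors built
from the m and m+1 most stable genes is reported for diagnostics but not
used for selection. Zero counts among candidates receive a 0.5
pseudocount (only when a zero actually occurs).

Normalization is two-step: the positive-control (technical) factor is
applied first, then the content factor from the selected references —
the usual order of operations on this platform; the positive-control
step can be disabled (`use_positives = FALSE`). After content
normalization the reference geometric mean is identical across samples
by construction.

One subtlety worth stating precisely: with cohort-anchored factors
(anchor = mean of per-sample geometric means), doubling one sample's
entire column multiplies that sample's factor by ½ *and* shifts the
anchor, so the renormalized matrix equals the original matrix times one
global scalar shared by every sample. The doubled sample acquires no
sample-specific change — relative expression is exactly invariant — but
absolute values are only invariant up to that common anchor ratio. This
is a property of any normalization anchored to a cohort statistic, and
the test suite asserts exactly this form.

## Differential expression

Fold changes are medians-based: log2(median_A) − log2(median_B) per
gene, with a 0.5 pseudocount added to both medians only when one is
zero. Significance uses the two-sided Wilcoxon rank-sum test — exact
enumeration when the smaller group has ≤ 12 samples and the gene has no
ties, otherwise the tie-corrected normal approximation with continuity
correction. A gene constant across both groups carries no rank
information and is reported as p = 1. Multiplicity is controlled with
Benjamini–Yekutieli, whose harmonic correction c(m) = Σ 1/i keeps the
false-discovery-rate guarantee under arbitrary dependence between genes
— appropriate for co-regulated panels. Tables sort by adjusted p, with
ties broken by |log2 fold change| (descending) then symbol; top-k lists
inherit that order. Cross-panel retest reliability correlates the log2
fold changes over the union of both panels' top-20 lists restricted to
shared symbols (the union is a documented choice; a single panel's list
or the intersection would also be defensible).

## Clustering diagnostics

Samples are clustered on log2(normalized + 1) endogenous expression
(the transform is a package choice; clustering raw scales lets a few
high-expressors dominate the Canberra sums). The distance is the
Canberra metric, Σ|x−y|/(|x|+|y|) with 0/0 coordinates contributing
nothing, and the linkage is Ward's minimum-variance in its
squared-dissimilarity dialect (ward.D2). Canberra distances are not
Euclidean, so Ward here is the pragmatic approximation commonly used in
practice rather than a variance decomposition in any embedding space.

Three validation statistics accompany the tree:

* **Hopkins statistic** — m = ⌈0.1 n⌉ (floor 10) sampled real points and
  m uniform points in the bounding box; H = Σu/(Σu+Σw) with u/w the
  respective nearest-real-neighbor distances. Uniform data give H near
  0.5, clustered data push H toward 1 (the convention in which higher
  means more clusterable). All-coincident data would make every w zero;
  H is then defined as 1 with a degeneracy flag.
* **Cophenetic correlation** — Pearson correlation between original and
  cophenetic distances. Note that only linkages that preserve
  ultrametric inputs (e.g. average) reproduce an ultrametric exactly;
  Ward heights are merge costs, so a Ward tree of an ultrametric input
  has r slightly below 1.
* **c-index** — for each k, C_k = (S_w − S_min)/(S_max − S_min) where
  S_w sums within-cluster distances over the tree cut at k and
  S_min/S_max are the attainable extremes with the same pair count; the
  optimal k minimizes C_k, ties resolving to the smallest k.

## AMR classifier

Model building operates on log2(normalized + 1) endogenous expression,
AMR versus everything else. Two filters precede the fit: near-zero
variance (most-common/second-most-common frequency ratio > 19 and
distinct values < 10% of n — the caret rule, via caret) and a greedy
correlation filter at |r| > 0.9 that removes the member of each
offending pair with the larger mean absolute correlation (caret's
`findCorrelation`, genes pre-sorted so ties are deterministic). The
classifier is L1-penalized logistic regression (glmnet), minimizing mean
deviance + λΣ|β| on per-gene standardized predictors, with the
standardization means and SDs frozen into the model.

λ is chosen by stratified 10-fold cross-validation at the minimum mean
held-out deviance (not the 1-SE rule — a documented choice; a fixed λ
can be supplied to replay a previously determined penalty, e.g. 0.034 or
0.120). Performance is reported from pooled out-of-fold probabilities,
with standardization and the fit redone inside each training fold at the
chosen λ; no nested re-selection of λ is performed inside folds.
Sensitivity and specificity are reported at probability threshold 0.5
with the Youden-optimal operating point alongside, since the choice of
threshold is an open clinical decision. AUC is the trapezoidal area of
the threshold-sweep ROC, which equals the Mann–Whitney U normalization
of the pooled probabilities (asserted against that oracle and pROC in
the tests).

Cross-panel transfer maps coefficient genes into the target panel by
gene symbol (probe IDs legitimately differ between panels) and applies
the *training* panel's frozen standardization — re-standardizing on the
test panel would leak test-set statistics into the decision rule. A
coefficient gene absent from the target panel is a hard mapping error
naming the gene, not a silent drop.

## The synthetic cohort generator

No suitable public cohort exists for this workflow, so validation rests
on simulated cohorts with known ground truth. The generator emulates a
three-group design (default 32/32/32 before QC attrition) on a large
panel (758 endogenous + 12 reference genes) with a small subpanel preset
(90 + 6) drawable from the same latent truth:

* endogenous counts: negative binomial with mean
  size_factor × 2^(baseline + group effect); baselines uniform on
  log2 ∈ [4, 10], dispersion 0.05 (variance μ + 0.05 μ²), per-sample
  size factors 2^N(0, 0.25) emulating RNA-input variation. Overdispersed
  counts are the standard model for hybridization-count platforms.
* planted group effects: by default 20 AMR-specific genes with graded
  effects spanning +0.8 to +2.5 log2 and 15 genes shared by both
  rejection phenotypes at +0.6 to +1.6 log2 — real panels show a range
  of fold changes, and a spread of true effects is also what makes
  cross-panel fold-change correlation a meaningful statistic (with all
  true effects equal, the correlation would measure only noise). Effect
  genes receive a baseline floor of 2^6 counts: genes curated into a
  disease panel are chosen to be reliably detectable, and without the
  floor a low-baseline effect gene can fall under the detection
  threshold on one panel but not another, which is a panel-design
  failure rather than the transfer behavior under study.
* housekeeping genes: lognormal with tiered coefficients of variation
  (defaults 0.05/0.05/0.05 then 0.2–0.6) and no group effect, so the
  true stability ranking is known.
* positive probes: linear in concentration at 150 counts/fM with 5%
  lognormal noise; negatives Poisson with mean 5, placing the 0.5 fM
  probe comfortably above background as on a functioning instrument.
* lane attributes drawn inside passing windows unless a named QC failure
  is injected (`inject_qc_failure()`: low FOV, high/low binding density,
  flat positives, depressed references), each violating exactly one
  criterion.

One seed fully determines the dataset, down to the bytes of the written
RCC files. Paired panels share baselines, effects and sample identities
but draw independent technical noise and size factors, mimicking two
assays run on aliquots of the same biopsies.

What the generator does **not** emulate: FFPE RNA degradation chemistry,
center/batch effects beyond size factors, probe cross-hybridization, and
correlated gene-gene structure beyond the planted group shifts. Passing
tests therefore demonstrate that the algorithms are implemented
correctly and recover known truth under a realistic noise model — not
that any particular clinical cohort will reproduce the same operating
characteristics.

## Numerical choices and degenerate inputs

* Pseudocounts: 0.5, applied only when a zero occurs (geNorm candidates,
  fold-change medians).
* geNorm ties: lexicographic; Wilcoxon ties: tie-corrected normal
  approximation; top-k ties: |log2FC| then symbol; c-index ties:
  smallest k.
* Empty-cohort (all samples excluded) and single-class responses are
  hard errors, not warnings.
* Seeds: a single global seed derives per-stage seeds by hashing the
  stage name (`stage_seed()`), so stages rerun in isolation reproduce
  their stream and full pipeline reruns are bit-identical (no
  timestamps are written into any output).

## Problem sizes used by the test suite

The suite validates geNorm against a brute-force oracle on one hundred
random 6–10 gene × 8–15 sample matrices; reference-tier and
cluster-number recovery on one hundred seeded replicates each; FDR
control on one hundred null cohorts of 200 genes × 30 samples; and
classifier recovery on ten seeded 90-sample, 500-gene cohorts with a
20-gene planted signature, including a paired-panel transfer check.
These sizes make the whole suite run in well under a minute per
criterion while keeping the Monte-Carlo assertions stable across seeds.

## Known limitations

* The RCC reader targets the common sectioned-CSV dialect; RLF binaries
  and PlexSet layouts are out of scope.
* Ward-on-Canberra is an accepted approximation, not a variance
  decomposition (see above).
* The classifier is binary (AMR vs not); the three-way diagnostic
  problem is not modeled.
* Cohort-anchored normalization makes absolute normalized values depend
  (weakly, through the anchor) on cohort composition; comparisons across
  separately normalized cohorts should rely on relative quantities.
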