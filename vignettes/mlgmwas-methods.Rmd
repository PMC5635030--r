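---
title: "Methods and design of the mlgmwas pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of the mlgmwas pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(mlgmwas)
```

## Scope

`mlgmwas` implements a metagenome-wide association study (MWAS) workflow for
case-control gut microbiome cohorts, of the kind used to relate gut bacterial
strains to atherosclerotic cardiovascular disease: gene-level abundance
profiles are binned into metagenomic linkage groups (MLGs), tested for
differential enrichment, organized into co-occurrence networks, summarized
into KEGG-module reporter scores, distilled into cross-validated
random-forest marker panels, screened against clinical indices, and checked
against medication confounding. The package starts from gene-by-sample count
matrices; read QC and mapping against a reference catalog are upstream of its
scope.

Because the real cohorts behind such studies are not redistributable, the
package ships a synthetic cohort generator with planted ground truth. Every
analysis stage therefore has a parameter-recovery test surface: the tests
know which genome bins, fold changes, module directions, clinical links and
drug effects were planted, and verify the pipeline recovers them.

## The synthetic community model

The generator is a deliberate stand-in: no generative description of a real
cohort exists, so its distributional choices are conventional rather than
estimated.

* **Catalog.** Each of `n_genomes` genomes contributes a contiguous block of
  genes (gene count uniform on a configurable interval). Partial annotation
  maps (KO, TMA-lyase enzyme family, virus) cover configurable fractions of
  genes; KO modules are drawn from the assigned KOs.
* **Composition.** Per-sample genome log abundances are normal: a per-genome
  baseline (itself N(0, `baseline_sd`^2), default sd 1.5, giving the heavy
  right tail of real communities) plus N(0, `dispersion`^2) sample noise
  (default 0.7, roughly the spread of log relative abundances seen across
  gut cohorts). Case samples add `log(2) * case_log2_fold_change` per genome;
  drug effects add the same way for treated cases only.
* **Counts.** Each sample's sequencing depth is distributed over genes by a
  single multinomial draw with weights `exp(genome log abundance) * w_g`,
  where `w_g` is a per-gene log-normal weight (sdlog `gene_weight_sd`,
  default 0.7) fixed across samples. Genes of one genome are therefore
  proportional across samples up to count noise — exactly the co-abundance
  signal MLG binning exploits. Zero inflation (default 5% in the pipeline
  cohort) blanks cells after the draw, emulating detection dropouts and
  exercising the prevalence filter.
* **Clinical indices** are linear responses to the latent log abundance of a
  target genome plus Gaussian noise; null indices use slope 0.
* **Depth.** Depth trades off against catalog size: the binning stage needs
  within-genome Spearman correlations near 0.8, the regime reported for real
  deep-shotgun cohorts (tens of millions of reads per sample). For the
  binning-scale cohort (50 genomes x 100-300 genes) we use 5e6 reads per
  sample; at 1e5 reads the mean count per gene is ~10 and rank correlations
  collapse into count noise, which no binning method survives. The default
  pipeline cohort (40 genomes x 100-200 genes) uses 1e6.

What the generator does **not** emulate: strain-level SNP structure, shared
genes between genomes (each gene belongs to exactly one genome, so planted
bins are cleanly separable), phage dynamics, compositional interactions
beyond closure, and covariate structure (age, BMI) in the metadata. Passing
tests therefore demonstrate algorithmic correctness under a favorable but
explicit model, not performance on real data.

All randomness flows through explicit integer seeds; the same seed gives
bit-identical cohorts and pipeline outputs.

## MLG binning

Genes originating from the same genome are physically linked and co-vary in
abundance across samples. The published MWAS literature defers the concrete
clustering to earlier work without restating it, so this package fixes its
own reproducible procedure:

1. Rank-transform each gene across samples (midranks for ties; samples with
   zero total are excluded).
2. Connect two genes when their Spearman correlation is at least
   `cc_threshold` (default 0.6); take connected components of this graph
   (computed blockwise, so the full gene-by-gene matrix is never held in
   memory).
3. Refine each component by average-linkage agglomeration on `1 - cc`, cut
   at height `1 - cc_threshold`. This splits chained components whose ends
   are uncorrelated.
4. Keep clusters containing **more than** `min_genes` genes (default 100,
   matching the convention that reported MLGs contain over 100 genes).

Genes are canonically ordered by id before clustering and all tie-breaks are
lexicographic, so the result is deterministic and invariant to input row
order. MLG abundance is the per-sample sum of member-gene relative
abundances. Taxonomy is assigned by reference-genome vote: a genome must
cover strictly more than half of an MLG's genes; the top three genomes are
always reported with coverage fraction and mean alignment identity. An
optional mean-identity floor for species-level calls is available
(`species_identity_min`) but off by default, since the vote rule alone is
the established convention.

## Differential abundance and multiple testing

Feature-wise two-sided Wilcoxon rank-sum tests with Benjamini-Hochberg
control at q < 0.05, per feature space (genes, genera, MLGs, KOs)
separately. Direction comes from the group mean ranks; features constant
across all samples get p = 1 and no direction. Medians per group are
reported for effect-size context.

A compositional caveat documented here because the tests rely on it:
relative abundances are closed, so enriching an *abundant* genome truly
depresses every other feature. Parameter-recovery tests that require
unplanted features to be null plant their effects on low-abundance genomes,
where the spillover is below detection at the tested sample sizes.

## Co-occurrence networks

All feature pairs with |Spearman cc| >= 0.3 become edges, computed
separately within case and control samples. Edge weight classes follow the
conventional drawing bands — thin [0.3, 0.5), medium [0.5, 0.7), thick
>= 0.7 (band edges are not specified in the figure conventions the bands
imitate; we close them on the left). Edge lists export as TSV and GraphML.

## Ordinations and PERMANOVA

* Bray-Curtis dissimilarity (via `vegan::vegdist`) on abundances as given;
  no re-normalization inside the metric.
* Jensen-Shannon divergence on per-sample renormalized profiles with
  pseudocount 1e-9, natural log (so the maximum is log 2); a square-root
  metric form is available but off by default.
* PCA is a centered eigen-decomposition over samples; on every component
  the largest-magnitude loading is made positive, fixing an otherwise
  arbitrary orientation.
* dbRDA embeds the distance matrix by principal coordinates (negative
  eigenvalues dropped; the discarded inertia is reported rather than
  Lingoes-corrected), projects the coordinates onto the centered group
  indicator, and takes principal axes of the fitted values (CAP). Feature
  weights are post-hoc Spearman correlations with the constrained scores.
* PERMANOVA uses the among/within decomposition of squared distances and
  the plus-one permutation rule `p = (1 + #{F_perm >= F_obs})/(1 + n_perm)`
  with 999 permutations by default, so p is never 0 and never below
  1/(n_perm + 1). The pseudo-F agrees with `vegan::adonis2` to numerical
  precision; the in-package implementation exists so the permutation rule,
  seeding, and exhaustive-enumeration tests are under direct control.

## Reporter scores

Per KO occurring in more than `min_samples` (default 5) samples, both
one-sided Wilcoxon p-values are computed; the smaller determines the
direction and the Z-score `Z = qnorm(1 - p)`, signed positive for case
enrichment. The published description is ambiguous about one-tail direction
— this both-sides-take-smaller construction is symmetric and documented. Z
is clamped to |Z| <= 8 as a numerical guard against p underflow. By default
Z comes from the raw one-tail p (the standard reporter construction); a
flag (`adjust_p`) derives it from BH-adjusted p instead, since the original
methods text permits that reading.

A module with k scored KOs aggregates `Z_raw = sum(Z)/sqrt(k)` and is
corrected against the mean and standard deviation of the same aggregate over
`n_background` (default 1000; unstated in the source convention) random
KO sets of size k. |corrected score| >= 1.6 (one-tail 95%) is the detection
threshold; 1.96 is the two-sided band conventionally drawn on plots.

## Marker selection (RFCV)

Repeated stratified five-fold cross-validation of random forests (ranger,
500 trees by default, sqrt(p) feature subsampling — conventional defaults,
all configurable). Within each training fold features are ranked by impurity
importance — ranking inside the fold avoids selection leakage; whether the
original analyses did this is unstated, so results may differ in that
detail — and nested top-k panels are scored on the held-out fold by
misclassification rate. Error curves from all folds x repeats are averaged;
the cutoff is the curve minimum plus the standard deviation at that point;
all panel sizes up to 25 with error under the cutoff are candidates and the
smallest is chosen. When the optimum is flat at zero standard deviation the
sizes attaining the minimum are the candidates; when no size <= 25 passes,
the argmin among sizes <= 25 is used with a warning. The reported marker
panel is the top of the full-data importance ranking. The out-of-fold
disease probabilities, however, are computed at the chosen panel *size* on
fold splits distinct from those that shaped the error curve, with each
training fold's own feature ranking: neither feature selection nor model
fitting ever sees a held-out sample, and the splits that tuned the panel
size are not reused for evaluation. Without this nesting, a classifier fit
to pure noise reports out-of-fold AUCs visibly above 0.5 — the classic
select-then-cross-validate optimism.

ROC/AUC uses the rank statistic with half credit for ties, a DeLong 95%
confidence interval, and the Youden index (max sensitivity + specificity
- 1; ties resolve to the lowest cutoff, favoring sensitivity). The
TMA-lyase classifier runs the same machinery on the 4-row enzyme-family
matrix (CutC/CutD/YeaW/YeaX); the model behind the corresponding published
ROC is unstated, so using the identical RFCV machinery is this package's
choice. An all-zero enzyme matrix returns degenerate probabilities of 0.5.
Multi-class designs support per-class downsampling to the smallest class
(`balance = TRUE`).

## Group LASSO

Logistic or linear regression with penalty `lambda * sum_g sqrt(p_g) *
||beta_g||_2`, solved by proximal gradient descent (ISTA with step 1/L from
the design's Gram spectral norm) with warm starts along a 30-point
log-spaced path from the smallest all-zero penalty down two decades. The
objective trace is recorded and is non-increasing by construction — a
property the test suite asserts. The reference penalty is chosen by BIC;
ten bootstrap refits give per-group selection frequencies. No grouped-lasso
solver ships with the package's dependency set, which is why the solver is
in-package; its single-group orthonormal solution is tested against the
closed-form group soft-threshold.

## Clinical indices and medication

Per index: a regression-forest RFCV pre-selects a small MLG panel, then
each selected MLG must pass a label-permutation Spearman test (p < 0.05,
|cc| >= 0.2; |cc| > 0.25 classed strong). The published figure convention
conflates "permutational Wilcoxon" with the Spearman statistic; this
package implements a label-permutation null for Spearman's cc and notes the
discrepancy here.

Per drug, three two-way cross-validated forest classifiers — treated cases
vs controls, untreated cases vs controls, treated vs untreated cases — each
report out-of-fold AUC and Youden's index; the disease signal dominating
the drug signal manifests as both case-vs-control AUCs exceeding the
treated-vs-untreated AUC. These comparisons use cross-validated
probabilities on the full feature matrix rather than a minimal marker panel
per stratum: the comparison logic needs the AUCs, not the panels. A
Jensen-Shannon PERMANOVA (999 permutations) among cases tests each drug's
community-level effect.

## Pipeline and configuration

`run_pipeline()` chains simulate → profiles → mlg → stats → markers from a
single YAML-serializable configuration; every run writes the resolved
configuration, all declared stage outputs, and a machine-readable run
report (package version, seed, per-stage counts) next to the results.
Stages can be toggled; a disabled stage that later stages depend on is an
actionable error. Reruns with the same configuration are bit-identical —
forest prediction seeds are derived explicitly because `ranger`'s
vote-tie-breaking would otherwise consume global RNG state.

## Problem sizes used by the test suite

Chosen once for a single-CPU workstation run and recorded here as the
package's own test conditions:

* binning recovery: 50 genomes x 100-300 genes, 120 samples, 20 seeds,
  depth 5e6;
* differential power/FDR: 50 genomes x 10-20 genes, 100 cases + 100
  controls, 20 seeds, planted 2x fold changes on low-baseline genomes;
* reporter calibration: 40 genomes x 30 genes with genome-coherent KOs,
  200 null modules x 2 label permutations, background 1000;
* classifier checks: 200 samples x 205 features with 5 planted markers;
  repeats = 2 and 200 trees for the null curve, repeats = 1 and 100 trees
  for the 10-seed recovery sweep (repeats only smooth the error curve);
* default pipeline cohort: 40 genomes x 100-200 genes, 60 cases + 60
  controls, depth 1e6.

## Known limitations

* The binning refinement guards against pathological chained components by
  keeping components larger than `refine_max` (default 5000 genes) whole
  with a warning rather than refining them.
* Reporter background correction is sampled, so corrected scores carry
  Monte-Carlo noise of order `1/sqrt(n_background)`.
* The group-LASSO path uses a fixed step size; very ill-conditioned designs
  converge slowly (the objective still never increases).
* All recovery guarantees are conditional on the generator's favorable
  structure (disjoint gene blocks, log-normal composition); none of the
  tests measure performance on real sequencing data.
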