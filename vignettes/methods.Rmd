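---
title: "Methods: models, parameters and design choices in mutscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in mutscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

mutscape reimplements a whole-exome somatic-mutation analysis workflow
for tumor cohorts — variant filtering, mutational signatures, genomic
scar scoring, signature-based subtyping with outcome models, and
actionability summaries — together with a synthetic-cohort generator
that provides ground truth at every level. This vignette documents the
statistical models, the tunable parameters and their defaults, the
numerical choices, and what the synthetic cohorts do and do not
emulate.

## Variant integration and evidence filtering

Call sets from four somatic callers are merged by their variant key
(sample, chromosome, position, ref, alt). The default is a union
(`min_support = 1`): the downstream evidence filters, not a voting
rule, carry the specificity. A vote threshold is available because
practice varies between pipelines; nothing in the filters depends on
it.

The SNV filters mirror the four standard false-call patterns:

* **normal_evidence** — the alt allele is present in the matched normal
  and the 2x2 tumor/normal alt/ref contingency is *not* significant
  (two-sided Fisher exact, `alpha_normal = 0.05`). A real somatic
  variant with slight normal contamination still shows a significant
  tumor excess; a germline leak does not.
* **strand_bias** — all alt reads fall on one strand *and* the alt-vs-ref
  strand contingency is significant (`alpha_strand = 0.05`). Requiring
  both conditions keeps low-depth variants (whose few reads can land on
  one strand by chance) from being discarded.
* **base_quality_drop** — mean base quality at the site at least
  `bq_drop = 10` Phred below the flanking mean.
* **poor_mapping** — mean mapping quality of alt reads below
  `mq_min = 20`.

The 0.05 levels are conventional choices: the source workflow states
only "statistically significant". `bq_drop` and `mq_min` are likewise
unspecified upstream; 10 Phred and MQ 20 are the values a GATK-era
pipeline would use, and all four are exposed in `filter_params()`.
Reasons accumulate rather than short-circuit, so rejection tallies per
criterion are meaningful. Records lacking the evidence needed for a
criterion are flagged `unevaluable` and reported separately — the
machine-readable replacement for a manual review step.

1-bp indels are additionally rejected in homopolymer runs of length
`hp_max = 6` or more, the classic FFPE/sequencing slippage artifact
context.

Fisher exact p-values are computed by a vectorized hypergeometric
routine using the same two-sided tie rule as `stats::fisher.test`
(tables whose point probability is at most the observed one times
1 + 1e-7 are summed). The test suite checks it against both
`stats::fisher.test` and an independent binomial-coefficient
enumeration, exhaustively over all tables with row margins up to 50, at
1e-12.

## Burden and hypermutation

Burden is somatic SNVs per Mb of sequenced target; the default target
size of 73.499 Mb is the capture footprint of the exome design this
pipeline is built around. Hypermutation uses a strict `> 10` SNVs/Mb
boundary; the inclusive `>= 10` variant is available because both
conventions appear in the literature. The boundary matters only for
samples at exactly 10.0 SNVs/Mb.

## Confirmation statistics

Targeted amplicon confirmation uses a one-sided Fisher exact test
(tumor VAF greater than control) at `alpha = 1e-9`. The one-sided form
follows from the directional criterion ("substantially higher in the
tumor"); the threshold is deliberately stringent so that, at typical
amplicon depths, essentially no control-level noise can confirm a
call. A stricter reading of the published threshold, 1e-10, can be
passed as `alpha`; at amplicon depths in the thousands the two
thresholds almost never disagree.

RNA-level detection counts a WES mutation as detected when at least one
alt read appears in the transcriptome data (`min_alt = 1`), stratified
by minimum RNA coverage (all / >=10x / >=30x by default). One read is
the weakest defensible criterion; detection rates are therefore upper
bounds within each stratum, which is why the stratification by
coverage — which removes expression-driven dropout — is the meaningful
axis.

## Mutational signatures

### Context matrices

SBS96 channels use the canonical pyrimidine-strand representation:
substitutions with a purine reference are reverse-complemented, giving
six substitution classes by 16 flanking contexts in COSMIC order. ID83
channels classify indels by length (1, 2, 3, 4, 5+), type, the number
of tandem repeat copies of the event sequence in the flanking
reference, and — for deletions without a flanking repeat copy —
microhomology length between the deleted sequence and the junction.
Classification needs flanking sequence (25 bp recommended); events with
insufficient flank are counted as unclassifiable rather than guessed.

### De novo extraction

Extraction is non-negative matrix factorization under the generalized
Kullback-Leibler divergence — the Poisson log-likelihood, which is the
right noise model for count catalogs — by multiplicative updates. For
each candidate rank k, `n_replicates` fits are run on bootstrap
resamples (per-sample multinomial resampling of the catalog) from
random initializations. Replicate signatures are clustered with a
one-per-replicate greedy cosine matching to iteratively re-estimated
centroids, and per-signature stability is the mean silhouette width
under cosine distance. The selected rank is the largest k with mean
silhouette at least 0.8 and no two consensus signatures with cosine
similarity above 0.95 (a degenerate split). This is a simplification
of the full solution-selection heuristics used by the reference
extractor tool; the silhouette criterion captures its core idea —
accept the richest factorization that bootstrapping reproduces — in an
auditable form.

Consensus exposures are refit by KL multiplicative updates with the
signatures held fixed. For column-stochastic signatures this fixed
point conserves per-sample totals exactly, so reconstructed catalogs
match observed mutation counts (the test suite asserts agreement
within 1%).

Convergence: updates stop when the relative objective change falls
below 1e-8 or after `max_iter` (default 2000) iterations;
non-converged fits are flagged, and the best iterate is used.

### Reference refitting

`decompose_to_reference()` fits each sample against a reference catalog
by non-negative least squares (Lawson-Hanson, via pracma), then
applies backward elimination: the signature whose removal costs the
least reconstruction cosine is dropped, refitting each time, while the
cost stays below `drop_tol = 0.01`. The tolerance controls the
sparsity/attribution trade-off: a signature explaining less than one
cosine-percent of a sample's catalog is treated as not confidently
present. Two consequences are documented and tested:

* a genuinely active but weakly contributing signature (for example a
  broad, flat signature at 30% weight behind a dominant focal one) can
  be absorbed by its neighbors — this is the intended behavior of
  sparse attribution, not an estimation failure;
* for *activity measurement* feeding the subtype classifier, the
  unsparsified fit (`drop_tol = 0`) is used, because tertile ranks
  must not be distorted by presence/absence decisions. This choice
  measurably improves subtype concordance on synthetic cohorts.

### Reference catalogs

The packaged SBS96 and ID83 catalogs are synthetic stand-ins (flagged
in their filenames) constructed to capture the qualitative character
of the named signatures: CpG-deamination focus (SBS1), TpC APOBEC
focus (SBS2/SBS13), a broad profile with C>G/T>A weight (SBS3), a
broad T>C-tilted clock profile (SBS5), and the analogous indel classes
(ID2/ID4/ID6/ID7/ID8). They are deliberately well separated (pairwise
cosine at most 0.36) so recovery tests measure the algorithms, not
catalog degeneracy. Real COSMIC catalogs can be supplied as TSV via
`read_catalog()`; results on real data should always use them.

## HRD genomic scars

From allele-specific copy-number segments:

* **LOH**: segments with minor copy number 0, longer than 15 Mb, not
  spanning the whole chromosome;
* **TAI**: allelic-imbalance segments (major != minor) touching a
  telomere and not crossing the centromere;
* **LST**: after dropping segments under 3 Mb and merging equal-CN
  neighbors, breakpoints between adjacent segments both at least 10 Mb
  with an inter-segment gap under 3 Mb, counted per chromosome arm
  (segments crossing the centromere midpoint are split).

The 15/10/3 Mb constants and the telomere/centromere rules are the
standard scar-score definitions from the HRD literature; the source
workflow names only the scoring package and "default parameters", so
these constants are exposed as arguments. Ploidy correction for LST is
not applied (the upstream default is ambiguous); segments are used as
given. HRD-high is score >= 42 (inclusive) or any pathogenic BRCA1/2
alteration, which overrides the score.

## SBS subtypes, survival and odds models

Aging activity (SBS1 + SBS5) and HRD activity (SBS3) are cut into
cohort tertiles at the empirical 33.33/66.67 percentiles (R quantile
type 7). Values equal to a cut point go to the lower tertile — a
documented, configurable tie-break that only matters with duplicated
activities. High means the top tertile; the 2x2 of (aging, HRD) levels
maps to subtypes 1 (low/high), 2 (low/low), 3 (high/low), 4
(high/high). Activities default to absolute counts; a proportions mode
exists because either convention is defensible and upstream usage is
not stated.

Group comparisons use the Wilcoxon rank-sum test, exact for combined
n <= 20 without ties, normal approximation with tie correction
otherwise. The subtype 1-vs-3 odds model is a logistic regression on
age and BMI with odds ratios rescaled to +10 years and +5 kg/m2;
complete separation is detected and handled by a weakly L2-penalized
IRLS refit, flagged in the output. Survival uses Kaplan-Meier curves
with log-rank tests and Cox proportional-hazards models with Efron tie
handling; "study" enters as a covariate rather than a stratum (the
upstream choice is unstated; with three sites and proportional
baselines the two differ little).

## Cross-cohort comparison and actionability

Per-gene frequency contrasts between cohorts are two-sided Fisher
tests with Benjamini-Hochberg q-values, flagged at q < 0.10. Germline
allele-frequency tests against reference populations use chi-square
when all expected cells reach 5 and Fisher otherwise. Copy-number
thresholding maps integer total copy number to the five GISTIC-style
classes (0, 1, 2, 3-4, >=5 by default) — a fixed cut table, since
amplitude thresholds relative to ploidy are not recoverable without
the segmentation pipeline. Neoantigen counting uses the strict
IC50 < 500 nM binding boundary with expression read count >= 1.
Actionability lookups run against a packaged, versioned snapshot table
in the OncoKB level schema (best level wins; the packaged table is
synthetic and illustrative — real analyses must substitute a genuine
snapshot).

## The synthetic cohort generator

The generator produces what the analysis assumes, with truth recorded:

* **Burden** is log-normal in SNVs/Mb (default meanlog log(1.29),
  sdlog 0.9, matching a median of 1.29 and a range of roughly
  0.07-22 SNVs/Mb over a few hundred tumors, with about 1% of samples
  above the 10 SNVs/Mb hypermutation boundary).
* **Signature mixtures**: by default the HRD (SBS3) share is coupled to
  the burden z-score through a Gaussian copula (rho = 0.95) with a
  Beta(0.8, 0.8) marginal, the remainder split between SBS1/SBS5, and
  APOBEC activity present in 35% of tumors. This calibration
  reproduces the reported TNBC activity structure: SBS3-SBS5
  correlation near -0.3, SBS1-SBS5 near +0.45, strongly coupled
  SBS2/SBS13, and subtypes 1 and 3 each covering roughly a quarter of
  the cohort.
* **Context counts** are multinomial draws from the tumor's mixture
  times the catalog — contexts are generated directly as channel
  labels, so no reference genome is needed (a genome-backed path for
  real data exists in the context-matrix builders).
* **Caller call sets**: four pseudo-callers with independent 5%
  dropout (no per-caller error profiles are published for the source
  workflow, so sensitivities are symmetric by design). Artifacts are
  injected at configurable rates; each carries evidence engineered to
  violate exactly one filter criterion at a severity that the filter
  should reject (e.g. 15 alt reads all on one strand against balanced
  reference reads), and is labeled with its intended rejection reason.
* **Scar events** are planted geometrically: interior 20 Mb LOH
  blocks, 30 Mb telomeric AI blocks, and adjacent 12 Mb
  state-transition pairs, each insulated by 5 Mb balanced spacer
  segments of alternating copy number so that no event contributes to
  another component; the planted counts are therefore recovered
  exactly by the scoring functions. The planted HRD score is normal
  (mean 47, sd 15, truncated at 0 and at genome capacity) and
  correlated with SBS3 exposure at rho = 0.62 on the latent scale;
  the realized Pearson correlation on raw exposures is attenuated to
  roughly 0.5-0.6 by the skewed exposure distribution, and further
  (to roughly 0.45) when SBS3 is *estimated* from a median-burden
  cohort rather than read from truth.
* **Survival** is exponential with per-subtype multiplicative hazards
  (defaults 1 / 1.5 / 2.6 / 1.5 for subtypes 1-4; baseline 0.008 per
  month with uniform administrative censoring over 120 months, giving
  roughly 40% events). An exponential baseline is the simplest
  generator consistent with proportional hazards, which is all the Cox
  recovery tests require.
* **Clinical covariates**: age is centered at 53 (sd 11) and coupled to
  aging-signature rank (r = 0.5), BMI at 30 (sd 6, r = 0.3), so
  subtype 1 tumors come from younger, leaner patients, matching the
  direction of the reported demographic contrasts. Pathogenic BRCA1/2
  flags are Bernoulli(0.10). For quantitative logistic-recovery tests,
  `simulate_subtype_labels()` plants exact log-odds (default
  -0.115/year and log(0.69)/5 per kg/m2, i.e. 68% and 31% decreases
  per 10 years and 5 kg/m2).

What the generator does **not** emulate: read-level data (alignment,
duplicates, FFPE chemistry), caller-specific error profiles, linkage
between mutations and real genomic coordinates, copy-number noise and
segmentation error, transcriptome quantification, and any population
structure. Passing tests on synthetic cohorts therefore demonstrates
the correctness of the statistical machinery under the stated
generative assumptions — not performance on real sequencing data.

## Problem sizes used in verification

The recovery studies use: 200 tumors with about 800 mutations each and
balanced five-signature mixtures for extraction recovery (rank range
3-6, 8 bootstrap replicates); 250-tumor cohorts for subtype
concordance at a median of 20 SNVs/Mb — the mutation load at which
per-tumor exposures are resolved enough that concordance measures the
classifier rather than multinomial noise (at the default 1.29 SNVs/Mb
median, concordance drops into the high-80s/low-90s because individual
tumor catalogs are small; both facts are expected behavior); 100
replicate cohorts for Cox CI coverage of the planted subtype-3 hazard
ratio of 2.6; and 100 replicates of n = 400 for logistic CI coverage.
Exhaustive Fisher verification covers all 2x2 tables with row margins
up to 50.

## Known limitations

* Rank selection is a silhouette simplification of the reference
  extractor's composite heuristics; on real, noisier catalogs the two
  can disagree near the stability boundary.
* The packaged signature catalogs are synthetic; quantitative
  statements about real tumors require the genuine COSMIC catalogs.
* Scar scoring takes segments as given; purity/ploidy estimation and
  segmentation error are upstream concerns.
* The OncoKB-style snapshot is a schema demonstration, not a curated
  knowledge base.
* Consequence annotation (nonsilent status, gene assignment) is an
  input column, not computed from transcripts.
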