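---
title: "Methods: PU-bagged SVM voting for pathway gene discovery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: PU-bagged SVM voting for pathway gene discovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical model behind `puvote`, the
assumptions it rests on, the tunable parameters and their defaults, what the
synthetic-data generator does and does not emulate, and the numerical and
design choices made where the method description left room.

## The model

The object of inference is a per-gene confidence that the gene participates
in the transcriptional program of a seed pathway gene set.  The data are one
gene × patient matrix of normalized, non-negative expression values per
cancer cohort.  The design transposes the usual orientation: **genes are
samples, patients are features**.  The rationale is that co-regulated genes
share a profile *across patients* (who vary in pathway activity), so a
discriminant in patient space separates the pathway's program from the rest
of the transcriptome.

Labels are positive–unlabeled.  The seed set supplies positives.  Genes
belonging to other curated hallmark collections are *excluded* from training
(they follow other coherent programs and would contaminate the negative
pool) but are still scored.  Everything else is the unlabeled pool treated
as negatives during sampling — the PU approximation.

For each cohort an ensemble of `members` (default `M = 1000`; the desk-scale
analyses in this repository use 200) linear SVMs is trained.  Member *m*:

1. receives all `P` positives and `round(np_ratio × P)` unlabeled genes
   drawn uniformly without replacement (`np_ratio` default 20);
2. holds out `holdout_frac` (default 0.3) of its sample, stratified by
   class, for a test-precision estimate;
3. is preprocessed by `log2(x + 1)` and per-patient standardization with
   moments fit **on its own training split only** (no hold-out leakage);
4. fits a linear SVM (hinge loss, L2 penalty, `cost = 1`, no class
   weighting — the NP subsampling already sets the class balance);
5. classifies every gene in the transcriptome by `sign(w·x + b)` — hard
   labels, no probability calibration, because the ensemble's statistic is a
   vote count.

`votes(g)` is the number of members classifying `g` positive.  Cohort
ensembles aggregate into a pan-cancer table: `prevalence(g)` counts cohorts
with `votes(g) ≥ 1`, and `avg_vote(g)` averages votes **only over voting
cohorts**, so a gene voted strongly in few cohorts is not diluted by the
cohorts that ignore it.  The pan-cancer ranking score orders genes by
`(avg_vote, prevalence)` lexicographically with exact tie preservation.

### Assumptions

* Expression is already normalized (TPM-like); no library-size or batch
  correction is attempted.
* Gene identifiers match by exact, case-sensitive string equality.
* Co-membership in the pathway program expresses itself as linear structure
  in patient space after `log2(x+1)`; kernel machines and other nonlinear
  members are deliberately out of scope for interpretability.
* Patients are exchangeable features within a cohort; cohorts are combined
  only at the vote level, never by pooling patients, so large cohorts cannot
  dominate the pan-cancer view.

## NP-ratio calibration

`calibrate_np_ratio()` probes a ratio grid (default 1, 10, 15, 20, 25, 30)
with a fixed number of members per ratio and summarizes two precisions per
member: on its 30% hold-out and on the *initial data* (all positives plus
all unlabeled genes).  Hold-out precision falls as the ratio grows; initial
precision rises, since members that see more of the unlabeled pool predict
positives more conservatively.  The chosen ratio is the **smallest whose
pooled median initial precision exceeds 0.5** — the weak-classifier
requirement — generalized deterministically; if no ratio qualifies the
argmax is taken with a warning.  On data where even balanced sampling gives
initial precision above 0.5 the rule legitimately selects a small ratio;
the default of 20 reflects the reference setting for real transcriptomes.
A member predicting nothing positive has *undefined* precision, reported as
missing and excluded from medians rather than scored zero, so conservative
members are not penalized twice.

## In-bag optimism and out-of-bag voting

Every member's bag contains **all** positives, so votes for positive genes
are partially in-sample: a linear member at `cost = 1` can memorize a
substantial fraction of its training positives even when the data carry no
signal at all, while sampled negatives are anti-memorized.  Evaluations that
rank the positives by in-bag votes therefore carry optimism, and a null
dataset does *not* give a null AUC.  `pu_ensemble()` consequently also
records, for every gene, the votes among members whose **training split did
not contain it** (`oob_votes`, `oob_n`, and their ratio `oob_rate`) — the
standard out-of-bag device of bagging estimators.  Under a no-signal null
the OOB rate is exchangeable across genes and rank evaluations center at
AUC 0.5, which is how the package's null-behaviour checks are run.  In-bag
votes remain the method's primary confidence score and are what all ranked
analyses consume.

## Enrichment machinery

`gsea_es()` implements the classic Kolmogorov–Smirnov running sum: along the
list ranked by decreasing score, hits increment by `|score|^p` normalized
over hits and misses decrement by `1/(N − N_hits)`; the enrichment score is
the signed maximum deviation and the leading edge collects hits at or before
the extremum.  The weight exponent defaults to `p = 0` (classic), which
makes the statistic invariant under monotone transforms of the scores and
exactly checkable against small enumerable oracles; `p = 1` is available.
Rank ties are broken by a seed-fixed shuffle: deterministic, but with no
systematic input-order bias.

`permutation_enrichment()` permutes the gene-to-score assignment
(`scheme = "scores"`, default) or the set membership (`"labels"`); with the
hit-set size fixed the two nulls coincide.  The z-score uses the null
mean/sd (missing when the null sd is zero) and the p-value is the add-one
estimator `(1 + #{|ES_null| ≥ |ES_obs|})/(1 + n_perm)`, never exactly zero.
Because the null ES is discrete on small universes, the comparison uses a
`1e-9` absolute tolerance so permutations tying the observed value count as
at least as extreme despite floating-point noise.  Default permutation
counts echo the reference analysis: 10,000 for gene- and patient-level
enrichment, 1,000 for module activity.

Fisher's exact test, Wilcoxon rank-sum and the logistic (Wald) association
between a per-gene covariate and voted status delegate to the standard R
implementations behind thin interfaces; Cohen's *d* uses the pooled standard
deviation (the unpooled convention would change magnitudes, not signs).
Complete separation in the logistic fit is flagged and yields missing
statistics rather than a misleading z.

## Functional modules

The module analysis reconstructs a network-based functional enrichment: for
each annotation term, the *highly voted candidates* (voted non-seed genes
with votes at or above the median nonzero vote — a parameter-free default
tied to the vote distribution; top-k and explicit thresholds are available)
annotated to the term induce a subgraph of the PPI network, and the largest
connected component of at least `min_size = 3` genes becomes a module.  This
is the simplest reading of "modules formed by the highly-voted candidates":
term-restricted, connectivity-required.  Modules are scored by vote-ranked
permutation GSEA and reported by decreasing z; **relative significance** is
each module's share of the summed positive z (modules with non-positive z
are excluded from shares), so shares sum to 1.

Module *activity* in a patient contrast ranks genes by
`log2((mean_A + 1)/(mean_B + 1))` — a deliberately simple fold-change
backend with a pluggable interface for moderated fits — and calls the module
activated or inactivated by the sign of its enrichment score.  Module
*classifiers* are plain logistic regressions on the module genes'
`log2(x+1)` expression over repeated stratified hold-outs (default 100 at
60/40), reporting AUC and AUCPR (average precision) as mean ± sd, and a
per-gene `effect_z` — mean/sd of the gene's standardized coefficient across
hold-outs — which feeds hub ranking (degree within the module subgraph,
then `|z|`, highlight at `|z| > 2`).

## Survival and subtype analyses

`risk_score()` combines `log2(x+1)` expression with pre-trained per-gene
log-hazard coefficients (the same scale the ensemble trains on) and splits
patients at the median score; patients exactly at the median go to the
low-risk group, a deterministic tie rule.  Kaplan–Meier curves and the
two-group log-rank test are consumed from the `survival` package behind a
thin interface, with administrative censoring at the chosen horizon
(default 5 years); fitting of Cox or additive-hazard models is likewise
delegated to standard estimators and out of scope here.  `stage_trend()`
summarizes scores per pathologic stage with one-sided adjacent rank-sum
tests and a strict-monotonicity flag.

`weight_enrichment()` asks whether a patient subtype concentrates among the
patients that drive the ensemble: patients are ranked by their mean member
weight and the flagged patients form the hit set of a permutation GSEA.  The
ranking is **signed** by default: a subtype tied to one pole of the latent
pathway activity concentrates at one end of the signed weights, whereas
ranking by `|weight|` folds both extremes together and can wash out a real
one-sided association (`use_abs = TRUE` restores the magnitude ranking).

## The synthetic-data generator

`generate_bundle()` emulates exactly the structure the method assumes, and
nothing more.  Per cohort, each patient draws a latent pathway activity
`a ~ N(0,1)`; seed and hidden-member genes follow
`softplus(baseline + factor_strength·a + noise)`, excluded-hallmark
stand-ins load identically on an independent second factor, and decoys have
no factor.  The softplus link keeps expression non-negative without
truncating the rank structure a linear SVM exploits.  Defaults — 3 cohorts,
2,000 genes (60 seed / 40 hidden / 200 excluded), 150 patients per cohort,
factor strength 1.5, noise sd 1, master seed 17 — are the canonical
desk-scale study conditions every property check in the package references;
they were chosen once as a realistic signal-to-noise regime for co-regulated
transcripts and are not tuned per test.

The subtype flag marks the top 20% of patients by latent activity
(thresholding rather than sampling, so the subtype–weight association is a
deterministic consequence of the factor at high strength); receptor-status
columns are noisy derivatives.  Survival times are exponential with
log-hazard proportional to the standardized risk score of a bundled
50-gene coefficient model, with uniform censoring over one to ten years;
stages follow risk quartiles with noise.  Annotations give each of six core
stand-in genes a focused block of experimentally supported terms, let hidden
members share terms from two affiliated cores, and give annotated decoys
diffuse background terms; one term annotates exactly the planted PPI module,
a connected subgraph planted inside the hidden members of a
preferential-attachment graph.  Per-cohort RNG streams derive from the
master seed by fixed offsets, so adding cohorts never perturbs existing
ones, and repeated generation is bit-identical (the PPI igraph object is
structurally identical; only its internal environment defeats naive
serialization comparison).

Deliberately **not** emulated: batch and library-size artifacts, realistic
gene–gene covariance beyond the planted factors, annotation-graph structure
(terms are flat sets), and dropout or count noise.  Tests passing on this
generator therefore demonstrate the machinery's correctness and the
method's behaviour under its own assumptions — not performance on real
transcriptomes.

## Numerical choices and degenerate inputs

* Duplicate gene rows in expression input collapse by mean (deterministic,
  order-independent), with a warning.
* Zero-variance genes get missing correlation-baseline scores; missing
  scores rank below everything (−∞) in AUC computations.
* Zero-sd features pass through standardization unscaled.
* `precision` of an empty prediction, z at zero permutation sd, Cohen's *d*
  at zero pooled sd, and the odds ratio of a zero-margin table are all
  *missing*, never 0, and excluded from medians.
* Member, cohort, hold-out and permutation seeds derive from the master
  seed by a fixed counter scheme, so results are independent of execution
  order and reproducible from a single integer.

## Problem sizes

The repository's tests and the acceptance script run at the desk scale the
defaults above describe: 200-member ensembles for the three-cohort recovery
and null analyses, 250-member pairs for vote stability, 100 members per
ratio for the calibration sweep over ratios 1/5/20, 100-member single-cohort
ensembles for five replicate module-recovery runs, and 500–2,000
permutations for enrichment checks against exhaustive oracles.  These sizes
were chosen so the full suite completes in minutes on one CPU while leaving
every statistical conclusion comfortably powered.

## Known limitations

* The PU approximation treats unlabeled genes as negatives during sampling;
  hidden true members sampled as negatives depress member precision
  estimates even when the classifier is right — an inherent property, not a
  bug, and the reason precision near 1 is not expected at high NP ratios.
* In-bag votes for positives carry in-sample optimism (see above); use the
  OOB view for unbiased evaluation of the positives' ranking.
* The module-identification algorithm is a reconstruction: term-induced
  largest connected component at a median-vote threshold.  Other readings
  (seeded growth, merging, significance cutoffs) would yield different
  module sets.
* The fold-change backend for module activity ignores variance moderation;
  plug in a moderated fit where counts are available.
* Linear members only; programs expressed nonlinearly in patient space will
  be missed.
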