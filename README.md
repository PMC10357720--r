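# puvote

Positive–unlabeled (PU) bagged SVM ensembles for discovering genes
co-patterned with a seed pathway gene set across cancer transcriptomes.

## The problem

Curated pathway gene sets — for instance the ~200-gene "TNFα signaling via
NFκB" hallmark — are incomplete: many genes that respond to the same
regulatory program are not in the set, and the unlabeled remainder of the
transcriptome cannot be treated as clean negatives.  `puvote` addresses this
as a PU learning problem with an unusual orientation: **genes are the
samples and patients are the features**.  A gene's expression profile across
the patients of a cancer cohort is the feature vector; the seed set supplies
the positives; "negatives" are repeatedly subsampled from the unlabeled
pool.

For each cohort the package trains an ensemble of `M` linear support vector
machine member classifiers.  Member *m* sees all `P` positives plus
`round(ratio × P)` negatives drawn uniformly without replacement (the
**NP ratio**, calibrated so each member remains a weak-but-better-than-random
classifier), holds out 30% of its sample for a precision estimate, and is
then applied to the whole transcriptome.  A gene's **vote**

> `votes(g) = #{ m : w_m · x_g + b_m > 0 }  ∈ [0, M]`

is the ensemble's confidence that it belongs to the seed pathway's program.
Per-cohort votes are combined into a pan-cancer view: a gene's **cancer
prevalence** is the number of cohorts voting for it and its **average vote**
is the mean vote over only those voting cohorts.  Because every member's bag
contains every positive, the package also reports **out-of-bag votes**
(members whose training split excluded the gene), the unbiased analogue used
for null-behaviour checks.

Downstream the package provides the rest of the analysis chain: a Pearson
correlation baseline and rank AUC evaluation; permutation GSEA
(Kolmogorov–Smirnov running sum, z-score and add-one permutation p); Fisher
exact enrichment and proportion-vs-vote-threshold curves; Jaccard functional
similarity over annotation terms; PPI functional-module discovery with
vote-ranked enrichment, module activity in patient contrasts and
module-based subtype classifiers; and risk scoring with Kaplan–Meier /
log-rank survival stratification.  A self-contained synthetic-data generator
plants all of this structure (a latent pathway-activity factor, hidden true
members, a PPI module, subtype and survival signal) so the whole pipeline is
testable without external data.

## Worked example

```r
library(puvote)

bundle <- generate_bundle(default_config())   # 3 cohorts, 2000 genes, 150 patients
labels <- build_label_vector(
  rownames(bundle$expression[[1]]),
  bundle$gene_sets$SEED_PATHWAY,
  bundle$gene_sets[grep("^EXCL_HM_", names(bundle$gene_sets))])
print(labels)
#> <label_vector> 2000 genes: 60 positive, 1740 negative, 200 excluded

fit <- pu_ensemble(bundle$expression[[1]], labels, members = 50, seed = 1)
summary(fit)
#> PU voting ensemble — cohort SIM01 (M = 50, NP ratio 20)
#>   voted genes: 256 / 2000
#>   median precision: test 0.714, initial 0.794
#>   vote quantiles (voted genes):
#>   0%  25%  50%  75% 100%
#>    1    2    4   26   50
```

The median member precision on the held-out split (0.714) and on the full
labeled data (0.794) say each member is a reasonable weak classifier; 256 of
2000 genes collect at least one vote.  The votes recover the planted truth:

```r
v <- fit$votes
median(v[bundle$truth$hidden])   # hidden true members
#> [1] 18.5
median(v[bundle$truth$decoys])   # decoys
#> [1] 0
roc_auc(v, bundle$truth$seed, setdiff(names(v), bundle$truth$seed))
#> [1] 1
```

Hidden pathway members (never labeled positive) receive a median of 18.5/50
votes while decoys receive none, and the seed genes are ranked perfectly
(AUC = 1).  Multiple cohorts aggregate with
`aggregate_pan_cancer(list_of_fits)`, and `find_modules()`,
`module_classifier()`, `risk_score()` + `km_logrank()` and
`weight_enrichment()` continue the analysis; `run_pipeline()` wires all
stages into one reproducible, manifest-hashed run (also available from the
shell via `inst/cli/puvote`).

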