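# Permutation/GSEA machinery, Fisher enrichment, proportion-vs-threshold
# curves, Jaccard functional similarity and the small statistical helpers the
# downstream analyses share.

# Core Kolmogorov-Smirnov running sum over a ranked hit indicator.
# hits increment by |score|^p / sum over hits; misses decrement by 1/(N - Nh).
running_sum <- function(hit, weights = NULL) {
  n <- length(hit)
  nh <- sum(hit)
  if (nh == 0L) stop_pu("hit set does not intersect the ranked list")
  if (nh == n) {
    inc <- rep(1 / nh, n) # degenerate: all hits, curve climbs to 1
    return(cumsum(inc))
  }
  step <- numeric(n)
  if (is.null(weights)) {
    step[hit] <- 1 / nh
  } else {
    w <- abs(weights[hit])
    if (sum(w) == 0) step[hit] <- 1 / nh else step[hit] <- w / sum(w)
  }
  step[!hit] <- -1 / (n - nh)
  cumsum(step)
}

signed_max <- function(curve) {
  i <- which.max(abs(curve))
  curve[i]
}

# rank genes by decreasing score; ties broken by a seed-fixed shuffle so the
# ordering is deterministic but carries no systematic input-order bias
rank_genes <- function(scores, tie_seed = 1L) {
  stopifnot(!is.null(names(scores)))
  shuffle <- with_seed(tie_seed, sample.int(length(scores)))
  ord <- order(-scores, shuffle)
  scores[ord]
}

#' GSEA enrichment score and running-sum curve
#'
#' Classic Kolmogorov-Smirnov form: along the list ranked by decreasing score,
#' hits increment the running sum by `|score|^exponent` (normalized over
#' hits), misses decrement by `1/(N - N_hits)`; the enrichment score is the
#' signed maximum deviation, and the leading edge is the hits at or before the
#' extremum.  `weight_exponent = 0` (default) is the classic unweighted
#' statistic, invariant under monotone transforms of the scores; `1` gives the
#' weighted variant.
#'
#' @param scores Named numeric gene scores (need not be sorted).
#' @param hit_set Gene set to test (must intersect `names(scores)`).
#' @param weight_exponent 0 (classic) or 1 (weighted).
#' @param tie_seed Seed for the tie-breaking shuffle.
#' @return Object of class `"enrichment_result"` with `es`, `running_sum`,
#'   `leading_edge`, `hits`, `misses`, and `ranked` (the ordering used).
#' @export
gsea_es <- function(scores, hit_set, weight_exponent = 0, tie_seed = 1L) {
  ranked <- rank_genes(scores, tie_seed)
  hit <- names(ranked) %in% hit_set
  weights <- if (weight_exponent == 0) NULL else abs(ranked)^weight_exponent
  curve <- running_sum(hit, weights)
  i_max <- which.max(abs(curve))
  le <- if (curve[i_max] >= 0) {
    names(ranked)[seq_len(i_max)][hit[seq_len(i_max)]]
  } else {
    names(ranked)[seq(i_max, length(ranked))][hit[seq(i_max, length(ranked))]]
  }
  structure(list(es = curve[i_max], running_sum = curve, leading_edge = le,
                 hits = sum(hit), misses = sum(!hit),
                 ranked = names(ranked), perm_mean = NA_real_,
                 perm_sd = NA_real_, z = NA_real_, p = NA_real_,
                 n_perm = 0L),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("<enrichment_result> ES = %.4f (%d hits / %d misses)\n",
              x$es, x$hits, x$misses))
  if (x$n_perm > 0L) {
    cat(sprintf("  z = %s, p = %.4g (%d permutations)\n",
                ifelse(is.na(x$z), "NA", sprintf("%.3f", x$z)), x$p, x$n_perm))
  }
  invisible(x)
}

#' @export
plot.enrichment_result <- function(x, ...) {
  graphics::plot(seq_along(x$running_sum), x$running_sum, type = "l",
                 xlab = "rank", ylab = "running enrichment score", ...)
  graphics::abline(h = 0, lty = 3)
  i <- which.max(abs(x$running_sum))
  graphics::points(i, x$running_sum[i], col = "red3", pch = 19)
  invisible(x)
}

#' Permutation test around a GSEA enrichment score
#'
#' The observed ES is compared with a null distribution obtained by permuting
#' the gene-to-score assignment (`scheme = "scores"`, the default) or the
#' gene-set membership (`scheme = "labels"`); with a fixed hit-set size the
#' two schemes define the same exchangeable null.  The z-score uses the null
#' mean/sd (`NA` when the null sd is 0) and the p-value is the add-one
#' estimator `(1 + #{|ES_null| >= |ES_obs|}) / (1 + n_perm)`, never exactly 0.
#'
#' @inheritParams gsea_es
#' @param n_perm Number of permutations (>= 100).
#' @param seed RNG seed.
#' @param scheme `"scores"` or `"labels"`.
#' @return An `"enrichment_result"` with `perm_mean`, `perm_sd`, `z`, `p`,
#'   `n_perm` filled in.
#' @export
permutation_enrichment <- function(scores, hit_set, n_perm = 10000L, seed = 1L,
                                   scheme = c("scores", "labels"),
                                   weight_exponent = 0) {
  scheme <- match.arg(scheme)
  if (n_perm < 100L) stop_pu("n_perm must be >= 100")
  res <- gsea_es(scores, hit_set, weight_exponent, tie_seed = seed)
  n <- length(res$ranked)
  nh <- res$hits
  null_es <- with_seed(derive_seed(seed, 1L, stream = 7L), {
    if (weight_exponent == 0) {
      # ES depends only on hit positions: sample positions directly
      # (identical null for both schemes at exponent 0)
      vapply(seq_len(n_perm), function(i) {
        hit <- logical(n)
        hit[sample.int(n, nh)] <- TRUE
        signed_max(running_sum(hit))
      }, numeric(1L))
    } else if (scheme == "scores") {
      vapply(seq_len(n_perm), function(i) {
        perm <- stats::setNames(unname(scores)[sample.int(length(scores))],
                                names(scores))
        gsea_es(perm, hit_set, weight_exponent, tie_seed = seed)$es
      }, numeric(1L))
    } else {
      vapply(seq_len(n_perm), function(i) {
        hs <- sample(names(scores), nh)
        gsea_es(scores, hs, weight_exponent, tie_seed = seed)$es
      }, numeric(1L))
    }
  })
  res$perm_mean <- mean(null_es)
  res$perm_sd <- stats::sd(null_es)
  res$z <- if (is.na(res$perm_sd) || res$perm_sd == 0) NA_real_ else
    (res$es - res$perm_mean) / res$perm_sd
  # tolerance-aware comparison: on small universes the null ES is discrete
  # and permutations tying the observed value must count as at least as
  # extreme despite floating-point noise in the running sum
  res$p <- (1 + sum(abs(null_es) >= abs(res$es) - 1e-9)) / (1 + n_perm)
  res$n_perm <- as.integer(n_perm)
  res
}

#' Fisher's exact enrichment test on a 2x2 table
#'
#' Conditional odds ratio and two-sided exact p-value from the hypergeometric
#' distribution (tables with probability at most that of the observed one are
#' summed).  A zero margin yields `p = 1` and an undefined (`NA`) odds ratio.
#'
#' @param in_both,in_a_only,in_b_only,in_neither Non-negative integer cell
#'   counts.
#' @return List with `odds_ratio` and `p`.
#' @export
fisher_enrichment <- function(in_both, in_a_only, in_b_only, in_neither) {
  cells <- c(in_both, in_a_only, in_b_only, in_neither)
  if (any(cells < 0) || any(cells != round(cells))) {
    stop_pu("cell counts must be non-negative integers")
  }
  tab <- matrix(cells, 2L, 2L, byrow = TRUE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    return(list(odds_ratio = NA_real_, p = 1))
  }
  ft <- stats::fisher.test(tab)
  list(odds_ratio = unname(ft$estimate), p = ft$p.value)
}

#' Proportion of reference genes above sweeping score thresholds
#'
#' At each threshold `t`, the proportion of genes with `score >= t` that
#' belong to the reference set, with a Fisher exact test of that subset
#' against its complement.  Thresholds whose subset is empty are dropped with
#' a warning.
#'
#' @param scores Named numeric gene scores.
#' @param reference_set Reference gene set (e.g. an oncogenic collection).
#' @param thresholds Numeric thresholds (sorted internally).
#' @param alpha Significance level for the per-threshold flag.
#' @return `data.frame` of class `"proportion_curve"` with `threshold`,
#'   `n_selected`, `proportion`, `odds_ratio`, `p`, `significant`.
#' @export
proportion_curve <- function(scores, reference_set, thresholds, alpha = 0.05) {
  if (!length(thresholds)) stop_pu("thresholds must be non-empty")
  thresholds <- sort(thresholds)
  in_ref <- names(scores) %in% reference_set
  rows <- lapply(thresholds, function(t) {
    sel <- !is.na(scores) & scores >= t
    if (!any(sel)) {
      warn_pu("no gene reaches threshold ", t, "; point dropped")
      return(NULL)
    }
    fe <- fisher_enrichment(sum(sel & in_ref), sum(sel & !in_ref),
                            sum(!sel & in_ref), sum(!sel & !in_ref))
    data.frame(threshold = t, n_selected = sum(sel),
               proportion = mean(in_ref[sel]), odds_ratio = fe$odds_ratio,
               p = fe$p, significant = fe$p < alpha)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("proportion_curve", class(out))
  out
}

#' @export
plot.proportion_curve <- function(x, ...) {
  graphics::plot(x$threshold, x$proportion, type = "b",
                 col = ifelse(x$significant, "red3", "grey50"), pch = 19,
                 xlab = "score threshold", ylab = "proportion in reference set",
                 ...)
  invisible(x)
}

#' Jaccard index of two sets
#'
#' `|A ∩ B| / |A ∪ B|`; 0 by convention when both sets are empty.
#'
#' @param a,b Character vectors.
#' @return Value in `[0, 1]`.
#' @export
jaccard <- function(a, b) {
  u <- union(a, b)
  if (!length(u)) return(0)
  length(intersect(a, b)) / length(u)
}

#' Jaccard functional-similarity profile against core genes
#'
#' For each gene, the Jaccard index between its evidence-filtered annotation
#' term set and each core gene's term set.  Genes without surviving
#' annotations have similarity 0 everywhere; by the zero-similarity rule they
#' are excluded from a core gene's ranking downstream (see
#' [similarity_ranking()]).
#'
#' @param annotations An [annotation_table()].
#' @param genes Genes to profile.
#' @param core_genes The reference genes (each must carry annotations after
#'   filtering, otherwise an error names the offender).
#' @param evidence_filter Evidence codes treated as experimentally validated.
#' @return Numeric matrix (genes x core genes) of class
#'   `"similarity_profile"`.
#' @export
similarity_profile <- function(annotations, genes, core_genes,
                               evidence_filter = experimental_evidence()) {
  keep <- annotations[annotations$evidence %in% evidence_filter, , drop = FALSE]
  term_sets <- split(keep$term_id, keep$gene)
  missing_core <- core_genes[!core_genes %in% names(term_sets)]
  if (length(missing_core)) {
    stop_pu("core gene(s) without surviving annotations: ",
            paste(missing_core, collapse = ", "))
  }
  out <- matrix(0, length(genes), length(core_genes),
                dimnames = list(genes, core_genes))
  for (cg in core_genes) {
    ct <- term_sets[[cg]]
    for (g in genes) {
      gt <- term_sets[[g]]
      if (!is.null(gt)) out[g, cg] <- jaccard(gt, ct)
    }
  }
  structure(out, class = c("similarity_profile", "matrix", "array"))
}

#' Similarity ranking for one core gene
#'
#' Returns the similarity scores of all profiled genes with nonzero similarity
#' to `core_gene` (the core gene itself removed) — the ranked universe used
#' for candidate enrichment.
#'
#' @param profile A [similarity_profile()].
#' @param core_gene One of the profile's core genes.
#' @return Named numeric vector of nonzero similarities.
#' @export
similarity_ranking <- function(profile, core_gene) {
  stopifnot(core_gene %in% colnames(profile))
  s <- profile[, core_gene]
  s <- s[names(s) != core_gene & s > 0]
  s
}

#' Rank-sum comparison of two groups with Cohen's d
#'
#' One-sided Wilcoxon rank-sum test (alternative: `a` stochastically greater
#' than `b`) and Cohen's d with the pooled standard deviation (`NA` when the
#' pooled sd is 0).
#'
#' @param a,b Numeric vectors (each of length >= 2).
#' @return List with `p` and `d`.
#' @export
group_compare <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L) stop_pu("both groups need >= 2 values")
  p <- suppressWarnings(stats::wilcox.test(a, b, alternative = "greater")$p.value)
  sp <- sqrt(((length(a) - 1) * stats::var(a) + (length(b) - 1) * stats::var(b)) /
               (length(a) + length(b) - 2))
  d <- if (is.na(sp) || sp == 0) NA_real_ else (mean(a) - mean(b)) / sp
  list(p = p, d = d)
}

#' Logistic association between a gene covariate and voted status
#'
#' Univariate logistic regression of the 0/1 voted indicator on a per-gene
#' covariate (e.g. a hazard z-score), reporting the Wald z and p for the
#' slope.  Complete or quasi-complete separation is flagged and yields `NA`
#' statistics.
#'
#' @param covariate Named numeric per gene.
#' @param voted Named 0/1 (or logical) per gene; names must match.
#' @return List with `z`, `p`, `separation`.
#' @export
voted_status_association <- function(covariate, voted) {
  genes <- intersect(names(covariate), names(voted))
  if (!length(genes)) stop_pu("covariate and voted status share no genes")
  y <- as.integer(voted[genes] > 0)
  x <- covariate[genes]
  ok <- is.finite(x)
  y <- y[ok]; x <- x[ok]
  if (length(unique(y)) < 2L) stop_pu("both voted and unvoted genes required")
  sep <- FALSE
  fit <- withCallingHandlers(
    stats::glm(y ~ x, family = stats::binomial()),
    warning = function(w) {
      msg <- conditionMessage(w)
      if (grepl("fitted probabilities numerically 0 or 1", msg) ||
          grepl("did not converge", msg)) {
        sep <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  if (max(abs(stats::coef(fit)), na.rm = TRUE) > 15) sep <- TRUE
  if (sep) return(list(z = NA_real_, p = NA_real_, separation = TRUE))
  s <- summary(fit)$coefficients
  list(z = unname(s["x", "z value"]), p = unname(s["x", "Pr(>|z|)"]),
       separation = FALSE)
}
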