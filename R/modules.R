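# Network functional modules: term-induced connected PPI subgraphs of
# highly-voted candidates, scored by vote-ranked GSEA, plus module activity in
# patient subgroups, module-based subtype classifiers and hub ranking.

#' Default 'highly voted' threshold
#'
#' The parameter-free default: the median of the nonzero votes.  Configurable
#' alternatives are a top-k cut or an explicit vote threshold.
#' @param votes Named numeric/integer votes.
#' @return Threshold value.
#' @export
high_vote_threshold <- function(votes) {
  v <- votes[votes > 0]
  if (!length(v)) stop_pu("no voted gene")
  stats::median(v)
}

#' Identify highly-voted functional modules in a PPI graph
#'
#' For each annotation term, the candidates (voted non-seed genes) at or above
#' the high-vote threshold that are annotated to the term induce a PPI
#' subgraph; the largest connected component of size at least `min_size`
#' becomes a functional module.  Each module is scored by [score_module()]
#' (vote-ranked permutation GSEA over all candidates) and modules are returned
#' ranked by decreasing z.
#'
#' @param ppi Undirected `igraph` PPI graph over gene symbols.
#' @param votes Named numeric votes of the candidate genes (voted non-seed
#'   genes with their votes).
#' @param term_sets [gene_sets()] keyed by term.
#' @param min_size Minimum module size (default 3).
#' @param threshold High-vote threshold; default [high_vote_threshold()].
#' @param n_perm,seed Passed to [score_module()].
#' @return List of `"functional_module"` objects (possibly empty, with a
#'   warning), each with `term_id`, `term_name`, `genes`, `subgraph`,
#'   `enrichment`, `z`, and `relative_significance` (`NA` until
#'   [relative_significance()]).
#' @export
find_modules <- function(ppi, votes, term_sets, min_size = 3L,
                         threshold = NULL, n_perm = 1000L, seed = 1L) {
  cand <- names(votes)[votes > 0]
  if (!length(intersect(cand, igraph::V(ppi)$name))) {
    stop_pu("no candidate gene present in the PPI graph")
  }
  threshold <- threshold %||% high_vote_threshold(votes)
  high <- names(votes)[votes >= threshold]
  desc <- attr(term_sets, "descriptions")
  modules <- list()
  for (i in seq_along(term_sets)) {
    tg <- intersect(intersect(term_sets[[i]], high), igraph::V(ppi)$name)
    if (length(tg) < min_size) next
    sub <- igraph::induced_subgraph(ppi, tg)
    comp <- igraph::components(sub)
    big <- which.max(comp$csize)
    if (comp$csize[big] < min_size) next
    mg <- igraph::V(sub)$name[comp$membership == big]
    msub <- igraph::induced_subgraph(sub, mg)
    enr <- score_module(votes, mg, n_perm = n_perm, seed = seed)
    modules[[length(modules) + 1L]] <- structure(
      list(term_id = names(term_sets)[i],
           term_name = unname(desc[names(term_sets)[i]]) %||% "",
           genes = sort(mg), subgraph = msub, enrichment = enr,
           z = enr$z, relative_significance = NA_real_),
      class = "functional_module")
  }
  if (!length(modules)) {
    warn_pu("no term yields a connected module of size >= ", min_size)
    return(list())
  }
  z <- vapply(modules, function(m) ifelse(is.na(m$z), -Inf, m$z), numeric(1L))
  modules[order(z, decreasing = TRUE)]
}

#' @export
print.functional_module <- function(x, ...) {
  cat(sprintf("<functional_module> %s (%s): %d genes, z = %s, share = %s\n",
              x$term_id, x$term_name, length(x$genes),
              ifelse(is.na(x$z), "NA", sprintf("%.2f", x$z)),
              ifelse(is.na(x$relative_significance), "NA",
                     sprintf("%.1f%%", 100 * x$relative_significance))))
  invisible(x)
}

#' Vote-ranked enrichment of a gene module
#'
#' Permutation GSEA with the candidates ranked by their votes and the module
#' genes as the hit set.
#'
#' @param votes Named numeric votes over the candidate universe.
#' @param module_genes Module gene set (must be a subset of the universe).
#' @param n_perm,seed Passed to [permutation_enrichment()].
#' @return An `"enrichment_result"`.
#' @export
score_module <- function(votes, module_genes, n_perm = 10000L, seed = 1L) {
  if (!all(module_genes %in% names(votes))) {
    stop_pu("module genes missing from the ranked universe")
  }
  permutation_enrichment(votes, module_genes, n_perm = n_perm, seed = seed)
}

#' Relative significance shares of a module set
#'
#' Each reported module's share is its z divided by the sum of z over modules
#' with finite positive z; non-positive-z modules keep `NA`.  Shares over the
#' reported modules sum to 1.
#'
#' @param modules List of `"functional_module"` objects.
#' @return The modules with `relative_significance` filled in.
#' @export
relative_significance <- function(modules) {
  z <- vapply(modules, `[[`, numeric(1L), "z")
  pos <- which(is.finite(z) & z > 0)
  if (!length(pos)) stop_pu("no module with finite positive z")
  total <- sum(z[pos])
  for (i in pos) modules[[i]]$relative_significance <- z[i] / total
  modules
}

#' Log2 fold-change ranking between two patient groups
#'
#' The default differential backend: `log2((mean_A + 1) / (mean_B + 1))` per
#' gene on the normalized-abundance scale.  A different backend (e.g. a
#' voom-style moderated fit) can be plugged in as a function
#' `f(expr, group_a, group_b) -> named numeric`.
#'
#' @param expr An [expression_matrix()].
#' @param group_a,group_b Patient id vectors (>= 2 each).
#' @param backend Optional replacement backend function.
#' @return Named numeric log2 fold-changes (positive = up in `group_a`).
#' @export
differential_rank <- function(expr, group_a, group_b, backend = NULL) {
  ga <- intersect(group_a, colnames(expr))
  gb <- intersect(group_b, colnames(expr))
  if (length(ga) < 2L || length(gb) < 2L) stop_pu("both groups need >= 2 patients")
  if (!is.null(backend)) return(backend(expr, ga, gb))
  ma <- rowMeans(unclass(expr)[, ga, drop = FALSE])
  mb <- rowMeans(unclass(expr)[, gb, drop = FALSE])
  log2((ma + 1) / (mb + 1))
}

#' Module activity in a patient contrast
#'
#' Permutation GSEA on a fold-change ranking with the module genes as the hit
#' set; the module is called `activated` when the enrichment score is
#' positive, `inactivated` otherwise.
#'
#' @param fold_changes Named numeric per-gene ranking statistic (e.g. from
#'   [differential_rank()]).
#' @param module_genes Module gene set.
#' @param n_perm Number of permutations (default 1000).
#' @param seed RNG seed.
#' @return Object of class `"module_activity"` with `direction`, `z`, `p`,
#'   `es`, `n_perm`.
#' @export
module_activity <- function(fold_changes, module_genes, n_perm = 1000L,
                            seed = 1L) {
  enr <- permutation_enrichment(fold_changes, module_genes, n_perm = n_perm,
                                seed = seed)
  structure(list(direction = if (enr$es > 0) "activated" else "inactivated",
                 z = enr$z, p = enr$p, es = enr$es, n_perm = enr$n_perm,
                 enrichment = enr),
            class = "module_activity")
}

#' @export
print.module_activity <- function(x, ...) {
  cat(sprintf("<module_activity> %s (ES = %.3f, z = %s, p = %.4g)\n",
              x$direction, x$es,
              ifelse(is.na(x$z), "NA", sprintf("%.2f", x$z)), x$p))
  invisible(x)
}

# area under the precision-recall curve by average precision
# (mean precision at the rank of each positive)
aucpr <- function(scores, labels) {
  ord <- order(scores, decreasing = TRUE)
  y <- labels[ord]
  prec_at <- cumsum(y) / seq_along(y)
  sum(prec_at * y) / sum(y)
}

#' Hold-out classifier report for a functional module
#'
#' Repeated stratified hold-outs (default 100 at 60/40) of a logistic
#' regression on the module genes' log2(x+1) expression to predict a binary
#' subtype flag, reporting AUC and AUCPR on the held-out 40% as mean ± sd.
#' Per-gene effect sizes are summarized as `effect_z = mean / sd` of each
#' gene's standardized coefficient across hold-outs (the hub-ranking input).
#'
#' @param expr An [expression_matrix()] (will be restricted to
#'   `module_genes`).
#' @param module_genes Module gene set.
#' @param flags Named 0/1 (or logical) subtype flag per patient; both classes
#'   need >= 5 patients.
#' @param n_holdouts Number of hold-out repetitions.
#' @param train_frac Training fraction per hold-out.
#' @param seed Master RNG seed.
#' @return Object of class `"module_classifier"` with `auc_mean`, `auc_sd`,
#'   `aucpr_mean`, `aucpr_sd`, `n_holdouts`, `auc`, `aucpr` (per hold-out) and
#'   `effect_z` (named per-gene).
#' @export
module_classifier <- function(expr, module_genes, flags, n_holdouts = 100L,
                              train_frac = 0.6, seed = 1L) {
  genes <- intersect(module_genes, rownames(expr))
  if (!length(genes)) stop_pu("no module gene present in the expression matrix")
  pats <- intersect(colnames(expr), names(flags))
  y <- as.integer(flags[pats] > 0)
  if (sum(y == 1L) < 5L || sum(y == 0L) < 5L) {
    stop_pu("both classes need >= 5 patients")
  }
  x <- t(log2p1(unclass(expr)[genes, pats, drop = FALSE]))
  x <- scale(x)
  x[, !is.finite(colSums(x))] <- 0
  idx1 <- which(y == 1L)
  idx0 <- which(y == 0L)
  aucs <- numeric(n_holdouts)
  prs <- numeric(n_holdouts)
  coefs <- matrix(NA_real_, n_holdouts, length(genes),
                  dimnames = list(NULL, genes))
  for (h in seq_len(n_holdouts)) {
    tr <- with_seed(derive_seed(seed, h, stream = 30L), {
      c(sample_exact(idx1, max(1L, round(train_frac * length(idx1)))),
        sample_exact(idx0, max(1L, round(train_frac * length(idx0)))))
    })
    te <- setdiff(seq_along(y), tr)
    df_tr <- data.frame(y = y[tr], x[tr, , drop = FALSE])
    fit <- suppressWarnings(stats::glm(y ~ ., data = df_tr,
                                       family = stats::binomial()))
    pr <- suppressWarnings(
      stats::predict(fit, data.frame(x[te, , drop = FALSE]), type = "response"))
    sc <- stats::setNames(pr, paste0("p", te))
    aucs[h] <- roc_auc(sc, paste0("p", te[y[te] == 1L]),
                       paste0("p", te[y[te] == 0L]))
    prs[h] <- aucpr(pr, y[te])
    cf <- stats::coef(fit)[-1L]
    coefs[h, ] <- cf[make.names(genes)]
  }
  ez <- apply(coefs, 2L, function(v) {
    s <- stats::sd(v, na.rm = TRUE)
    if (is.na(s) || s == 0) NA_real_ else mean(v, na.rm = TRUE) / s
  })
  structure(list(genes = genes, n_holdouts = as.integer(n_holdouts),
                 auc_mean = mean(aucs), auc_sd = stats::sd(aucs),
                 aucpr_mean = mean(prs), aucpr_sd = stats::sd(prs),
                 auc = aucs, aucpr = prs,
                 effect_z = stats::setNames(ez, genes)),
            class = "module_classifier")
}

#' @export
print.module_classifier <- function(x, ...) {
  cat(sprintf(paste0("<module_classifier> %d genes, %d hold-outs: ",
                     "AUC %.2f +/- %.2f, AUCPR %.2f +/- %.2f\n"),
              length(x$genes), x$n_holdouts, x$auc_mean, x$auc_sd,
              x$aucpr_mean, x$aucpr_sd))
  invisible(x)
}

#' Rank module genes as network hubs
#'
#' Genes are ranked lexicographically by (degree within the module subgraph,
#' absolute effect z); genes with `|z| > 2` are flagged as highlighted.
#'
#' @param module A `"functional_module"` (or any list with `genes` and
#'   `subgraph`).
#' @param effect_z Named per-gene effect z-scores covering the module genes
#'   (e.g. `module_classifier()$effect_z`).
#' @return `data.frame` with `gene`, `degree`, `effect_z`, `highlighted`,
#'   ordered by rank.
#' @export
hub_ranking <- function(module, effect_z) {
  genes <- module$genes
  if (!all(genes %in% names(effect_z))) {
    stop_pu("effect_z must cover all module genes")
  }
  deg <- igraph::degree(module$subgraph)[genes]
  z <- effect_z[genes]
  out <- data.frame(gene = genes, degree = as.integer(deg),
                    effect_z = as.numeric(z),
                    highlighted = !is.na(z) & abs(z) > 2,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$degree, -abs(out$effect_z)), , drop = FALSE]
  rownames(out) <- NULL
  out
}
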