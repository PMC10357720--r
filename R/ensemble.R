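# The core method: positive-unlabeled bagging of linear SVM member
# classifiers with genes as samples and patients as features, NP-ratio
# calibration, majority voting over members, pan-cancer aggregation, and the
# conventional Pearson-correlation baseline.

#' Partition a gene universe into positive / negative / excluded labels
#'
#' Genes in `positives` are labeled positive; genes belonging to any exclusion
#' set (other hallmark collections) but not to `positives` are excluded from
#' training; everything else is treated as negative (the unlabeled pool of PU
#' learning).  Positive status takes precedence over exclusion.
#'
#' @param universe Character vector of all gene symbols under study.
#' @param positives Seed pathway gene set (must intersect `universe`).
#' @param exclusion_sets Optional [gene_sets()] whose members are excluded
#'   from the negative pool.
#' @return Named factor over `universe` of class `"label_vector"` with levels
#'   `positive`, `negative`, `excluded`.
#' @export
build_label_vector <- function(universe, positives, exclusion_sets = NULL) {
  universe <- as.character(universe)
  if (anyDuplicated(universe)) stop_pu("duplicate genes in universe")
  pos <- intersect(universe, positives)
  if (!length(pos)) stop_pu("no positive gene present in the universe")
  excl <- character(0)
  if (!is.null(exclusion_sets) && length(exclusion_sets)) {
    excl <- setdiff(intersect(universe, unique(unlist(exclusion_sets))), pos)
  }
  status <- rep("negative", length(universe))
  names(status) <- universe
  status[pos] <- "positive"
  status[excl] <- "excluded"
  structure(factor(status, levels = c("positive", "negative", "excluded")),
            names = universe, class = c("label_vector", "factor"))
}

#' @export
print.label_vector <- function(x, ...) {
  tab <- table(unclass(x))
  cat(sprintf("<label_vector> %d genes: %s positive, %s negative, %s excluded\n",
              length(x), tab[1L], tab[2L], tab[3L]))
  invisible(x)
}

label_genes <- function(labels, status) names(labels)[labels == status]

#' Draw one member classifier's training sample
#'
#' All positives are included; `round(np_ratio * n_positives)` negatives are
#' drawn uniformly without replacement from the negative pool.  Excluded genes
#' never enter the sample.
#'
#' @param labels A [build_label_vector()] result.
#' @param np_ratio Negative-to-positive sampling ratio (e.g. 20).
#' @param seed RNG seed for the draw.
#' @return List of class `"pu_manifest"` with `positives`, `negatives`,
#'   `np_ratio`, `seed`.
#' @export
sample_training_set <- function(labels, np_ratio, seed = 1L) {
  stopifnot(np_ratio > 0)
  pos <- label_genes(labels, "positive")
  neg_pool <- label_genes(labels, "negative")
  n_neg <- round(np_ratio * length(pos))
  if (n_neg > length(neg_pool)) {
    stop_pu("need ", n_neg, " negatives but only ", length(neg_pool),
            " available")
  }
  neg <- with_seed(seed, sample_exact(neg_pool, n_neg))
  structure(list(positives = pos, negatives = neg, np_ratio = np_ratio,
                 seed = seed), class = "pu_manifest")
}

#' Precision of a predicted-positive gene set
#'
#' `|predicted ∩ true| / |predicted|`.  An empty prediction yields `NA`
#' ("undefined as missing"): conservative members are excluded from median
#' summaries rather than scored 0.
#'
#' @param predicted_positive,true_positive Character vectors of gene symbols.
#' @return Precision in `[0, 1]`, or `NA` for an empty prediction.
#' @export
precision <- function(predicted_positive, true_positive) {
  if (!length(predicted_positive)) return(NA_real_)
  length(intersect(predicted_positive, true_positive)) / length(predicted_positive)
}

# log2(x+1) then per-patient (column) standardization with moments fitted on
# the member's training split only; zero-sd patients pass through unscaled
standardize_fit <- function(x_train) {
  center <- colMeans(x_train)
  scl <- apply(x_train, 2L, stats::sd)
  scl[!is.finite(scl) | scl == 0] <- 1
  list(center = center, scale = scl)
}

standardize_apply <- function(x, std) {
  sweep(sweep(x, 2L, std$center, "-"), 2L, std$scale, "/")
}

# decision values for raw (log2-transformed, unstandardized) gene rows: fold
# the member's standardization into the weight vector once
member_decision <- function(member, x_log) {
  w <- member$patient_weights / member$std$scale
  b <- member$bias - sum(member$std$center * w)
  as.numeric(x_log %*% w) + b
}

#' Train one SVM member classifier
#'
#' The sampled genes are split 70/30 stratified by class; features (patients)
#' are log2(x+1)-transformed and standardized with moments fit on the training
#' split only; a linear support vector machine (hinge loss, L2 penalty,
#' `cost`, no class weighting — the NP sampling already balances) is fit on
#' the 70% and its hold-out precision measured on the 30%.  The decision rule
#' is `sign(w . x + b)`.
#'
#' @param expr An [expression_matrix()] containing all manifest genes.
#' @param manifest A [sample_training_set()] result.
#' @param holdout_frac Fraction of the sample reserved for testing
#'   (default 0.3).
#' @param seed RNG seed for the split.
#' @param cost SVM cost parameter `C`.
#' @param standardize Standardize features on the training split
#'   (default `TRUE`).
#' @return List of class `"pu_member"` with `patient_weights` (on the
#'   standardized feature scale), `bias`, `std` (feature moments), `manifest`,
#'   `split`, `seed`, `test_precision`, and `initial_precision` (filled by
#'   [evaluate_initial()]).
#' @export
train_member <- function(expr, manifest, holdout_frac = 0.3, seed = 1L,
                         cost = 1, standardize = TRUE) {
  genes <- c(manifest$positives, manifest$negatives)
  missing <- setdiff(genes, rownames(expr))
  if (length(missing)) stop_pu("manifest genes absent from expression: ",
                               paste(utils::head(missing, 3L), collapse = ", "))
  y <- factor(rep(c("pos", "neg"),
                  c(length(manifest$positives), length(manifest$negatives))),
              levels = c("pos", "neg"))
  split <- with_seed(seed, {
    test_pos <- sample_exact(seq_along(manifest$positives),
                             max(1L, round(holdout_frac * length(manifest$positives))))
    test_neg <- length(manifest$positives) +
      sample_exact(seq_along(manifest$negatives),
                   max(1L, round(holdout_frac * length(manifest$negatives))))
    c(test_pos, test_neg)
  })
  if (length(split) >= length(genes)) stop_pu("hold-out split leaves no training data")
  x <- log2p1(unclass(expr)[genes, , drop = FALSE])
  x_train <- x[-split, , drop = FALSE]
  y_train <- y[-split]
  if (!all(c("pos", "neg") %in% y_train)) {
    stop_pu("training split lost a class; increase sample size")
  }
  std <- if (standardize) standardize_fit(x_train) else
    list(center = rep(0, ncol(x)), scale = rep(1, ncol(x)))
  xs_train <- standardize_apply(x_train, std)
  fit <- e1071::svm(xs_train, y_train, kernel = "linear", cost = cost,
                    scale = FALSE)
  w <- as.numeric(t(fit$coefs) %*% fit$SV)
  b <- -fit$rho
  # libsvm orients the decision value toward the class of the first training
  # row; flip so that positive decision values mean "pos"
  if (fit$levels[fit$labels[1L]] != "pos") {
    w <- -w
    b <- -b
  }
  names(w) <- colnames(expr)
  member <- structure(list(patient_weights = w, bias = b, std = std,
                           manifest = manifest, split = genes[split],
                           seed = seed, test_precision = NA_real_,
                           initial_precision = NA_real_),
                      class = "pu_member")
  dv_test <- member_decision(member, x[split, , drop = FALSE])
  pred <- genes[split][dv_test > 0]
  truth <- intersect(genes[split], manifest$positives)
  member$test_precision <- precision(pred, truth)
  member
}

#' Precision of a member on the initial (full labeled) data
#'
#' Scores every positive and negative gene of the cohort (excluded genes are
#' left out) with the member's decision rule and returns the precision of the
#' predicted-positive set; `NA` when the member predicts nothing positive.
#'
#' @param member A [train_member()] result.
#' @param expr The member's cohort [expression_matrix()].
#' @param labels The cohort [build_label_vector()].
#' @return Precision in `[0, 1]` or `NA`.
#' @export
evaluate_initial <- function(member, expr, labels) {
  genes <- c(label_genes(labels, "positive"), label_genes(labels, "negative"))
  genes <- intersect(genes, rownames(expr))
  dv <- member_decision(member, log2p1(unclass(expr)[genes, , drop = FALSE]))
  precision(genes[dv > 0], label_genes(labels, "positive"))
}

#' Fit a PU-bagged SVM voting ensemble for one cohort
#'
#' The fitting function at the package's core.  `members` linear SVM member
#' classifiers are trained on independent NP-ratio subsamples (seeds derived
#' from `seed` by a fixed counter scheme), and every gene in `x` — including
#' genes excluded from training — is scored by majority voting: `votes(g)` is
#' the number of members whose decision rule classifies `g` positive.
#'
#' @param x An [expression_matrix()] (genes as samples, patients as features).
#' @param labels A [build_label_vector()] over the genes of `x`.
#' @param members Number of member classifiers `M`.
#' @param np_ratio Negative-to-positive sampling ratio.
#' @param holdout_frac Hold-out fraction per member.
#' @param cost SVM cost parameter.
#' @param standardize Standardize features per member (default `TRUE`).
#' @param seed Master RNG seed.
#' @param initial_precision Also score each member on the initial data
#'   (default `TRUE`; adds one full-matrix pass per member).
#' @return An object of class `"pu_ensemble"`: list with `cohort`, `votes`
#'   (named integer over all genes), `oob_votes` / `oob_n` / `oob_rate`
#'   (out-of-bag voting, see Details), `members` (list of `"pu_member"`),
#'   `M`, `labels`, `np_ratio`, `seed`, `call`.  Supports `print()`,
#'   `summary()`, `coef()` (mean patient weights), `predict()` (votes for new
#'   gene profiles) and `plot()`.
#'
#' @details Because every member's bag contains all positive genes, in-bag
#' votes for the positives carry in-sample optimism: a member partially
#' memorizes its training genes, so positives collect votes even without any
#' signal.  As in other bagging methods, the out-of-bag (OOB) view removes
#' this: `oob_votes(g)` counts positive votes only among members whose
#' training split did not contain `g`, `oob_n(g)` counts those members, and
#' `oob_rate = oob_votes / oob_n` is the unbiased analogue of the vote used
#' for null-behaviour evaluation.  The in-bag `votes` remain the method's
#' primary confidence score.
#' @seealso [aggregate_pan_cancer()], [calibrate_np_ratio()],
#'   [patient_weights()]
#' @examples
#' \donttest{
#' bundle <- generate_bundle(sim_config(n_cohorts = 1, genes_total = 300,
#'                                      n_seed = 25, n_hidden = 10,
#'                                      n_excluded = 30,
#'                                      patients_per_cohort = 60,
#'                                      module_size = 5, ppi_nodes = 100))
#' labels <- build_label_vector(rownames(bundle$expression[[1]]),
#'                              bundle$gene_sets$SEED_PATHWAY,
#'                              bundle$gene_sets[grep("EXCL", names(bundle$gene_sets))])
#' fit <- pu_ensemble(bundle$expression[[1]], labels, members = 20, seed = 1)
#' summary(fit)
#' }
#' @export
pu_ensemble <- function(x, labels, members = 1000L, np_ratio = 20,
                        holdout_frac = 0.3, cost = 1, standardize = TRUE,
                        seed = 1L, initial_precision = TRUE) {
  stopifnot(inherits(x, "expr_matrix"), members >= 1L)
  if (!setequal(names(labels), rownames(x))) {
    stop_pu("labels must cover exactly the genes of the expression matrix")
  }
  labels <- labels[rownames(x)]
  genes <- rownames(x)
  x_log <- log2p1(unclass(x))
  votes <- stats::setNames(integer(length(genes)), genes)
  oob_votes <- stats::setNames(integer(length(genes)), genes)
  oob_n <- stats::setNames(integer(length(genes)), genes)
  member_list <- vector("list", members)
  init_genes <- c(label_genes(labels, "positive"), label_genes(labels, "negative"))
  pos_set <- label_genes(labels, "positive")
  for (m in seq_len(members)) {
    s_samp <- derive_seed(seed, m, stream = 10L)
    s_split <- derive_seed(seed, m, stream = 11L)
    manifest <- sample_training_set(labels, np_ratio, seed = s_samp)
    member <- train_member(x, manifest, holdout_frac = holdout_frac,
                           seed = s_split, cost = cost,
                           standardize = standardize)
    dv <- member_decision(member, x_log)
    votes <- votes + (dv > 0)
    in_train <- genes %in% setdiff(c(manifest$positives, manifest$negatives),
                                   member$split)
    oob_votes <- oob_votes + ((dv > 0) & !in_train)
    oob_n <- oob_n + !in_train
    if (initial_precision) {
      idx <- match(init_genes, genes)
      member$initial_precision <- precision(init_genes[dv[idx] > 0], pos_set)
    }
    member$manifest <- list(positives = manifest$positives,
                            negatives = manifest$negatives,
                            np_ratio = np_ratio, seed = s_samp)
    member_list[[m]] <- member
  }
  votes <- stats::setNames(as.integer(votes), genes)
  oob_votes <- stats::setNames(as.integer(oob_votes), genes)
  oob_n <- stats::setNames(as.integer(oob_n), genes)
  oob_rate <- ifelse(oob_n > 0, oob_votes / oob_n, NA_real_)
  structure(list(cohort = cohort(x), votes = votes, oob_votes = oob_votes,
                 oob_n = oob_n, oob_rate = oob_rate, members = member_list,
                 M = as.integer(members), labels = labels,
                 np_ratio = np_ratio, seed = seed, call = match.call()),
            class = "pu_ensemble")
}

#' @export
print.pu_ensemble <- function(x, ...) {
  cat(sprintf("PU voting ensemble — cohort %s: %d members, NP ratio %g\n",
              x$cohort, x$M, x$np_ratio))
  cat(sprintf("  %d/%d genes received >= 1 vote\n",
              sum(x$votes > 0), length(x$votes)))
  invisible(x)
}

#' @rdname pu_ensemble
#' @param object,... A fitted `"pu_ensemble"`; further arguments are ignored.
#' @export
summary.pu_ensemble <- function(object, ...) {
  tp <- vapply(object$members, `[[`, numeric(1L), "test_precision")
  ip <- vapply(object$members, `[[`, numeric(1L), "initial_precision")
  out <- list(cohort = object$cohort, M = object$M, np_ratio = object$np_ratio,
              n_voted = sum(object$votes > 0), n_genes = length(object$votes),
              median_test_precision = stats::median(tp, na.rm = TRUE),
              median_initial_precision = stats::median(ip, na.rm = TRUE),
              vote_quantiles = stats::quantile(object$votes[object$votes > 0]))
  class(out) <- "summary.pu_ensemble"
  out
}

#' @export
print.summary.pu_ensemble <- function(x, ...) {
  cat(sprintf("PU voting ensemble — cohort %s (M = %d, NP ratio %g)\n",
              x$cohort, x$M, x$np_ratio))
  cat(sprintf("  voted genes: %d / %d\n", x$n_voted, x$n_genes))
  cat(sprintf("  median precision: test %.3f, initial %.3f\n",
              x$median_test_precision, x$median_initial_precision))
  cat("  vote quantiles (voted genes):\n")
  print(x$vote_quantiles)
  invisible(x)
}

#' @rdname pu_ensemble
#' @export
coef.pu_ensemble <- function(object, ...) {
  w <- vapply(object$members, `[[`,
              numeric(length(object$members[[1L]]$patient_weights)),
              "patient_weights")
  rowMeans(w)
}

#' @rdname pu_ensemble
#' @param newdata Matrix of gene expression profiles (genes as rows, the
#'   ensemble's patients as columns) to score.
#' @export
predict.pu_ensemble <- function(object, newdata, ...) {
  if (inherits(newdata, "expr_matrix")) newdata <- unclass(newdata)
  stopifnot(is.matrix(newdata))
  pats <- names(object$members[[1L]]$patient_weights)
  if (!is.null(colnames(newdata))) {
    if (!all(pats %in% colnames(newdata))) {
      stop_pu("newdata must contain the ensemble's patient columns")
    }
    newdata <- newdata[, pats, drop = FALSE]
  } else if (ncol(newdata) != length(pats)) {
    stop_pu("newdata has ", ncol(newdata), " columns; ensemble expects ",
            length(pats))
  }
  x_log <- log2p1(newdata)
  votes <- integer(nrow(newdata))
  for (member in object$members) {
    votes <- votes + (member_decision(member, x_log) > 0)
  }
  stats::setNames(as.integer(votes), rownames(newdata))
}

#' @rdname pu_ensemble
#' @export
plot.pu_ensemble <- function(x, ...) {
  v <- x$votes[x$votes > 0]
  graphics::hist(v, breaks = 30, col = "grey70", border = "white",
                 main = sprintf("Vote distribution — %s (M = %d)", x$cohort, x$M),
                 xlab = "votes (voted genes only)", ...)
  invisible(x)
}

#' Mean patient weights of a fitted ensemble
#'
#' Per-patient mean of the member weight vectors, on the standardized feature
#' scale.  Patients with large absolute weight have the most influence on the
#' ensemble's decision rule (the handle used for subtype enrichment).
#'
#' @param model A [pu_ensemble()] fit.
#' @return `data.frame` with `patient_id`, `weight` (signed) and `abs_weight`.
#' @export
patient_weights <- function(model) {
  stopifnot(inherits(model, "pu_ensemble"))
  w <- coef(model)
  data.frame(patient_id = names(w), weight = as.numeric(w),
             abs_weight = abs(as.numeric(w)), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Calibrate the NP sampling ratio
#'
#' Trains `members_per_ratio` members per ratio per cohort and summarizes the
#' distributions of hold-out (test) and initial-data precision.  The chosen
#' ratio is the smallest whose pooled median initial precision exceeds 0.5 —
#' the weak-classifier requirement; if none qualifies, the argmax is chosen
#' with a warning.
#'
#' @param exprs Named list of [expression_matrix()] (one per cohort).
#' @param labels_list A single [build_label_vector()] shared by all cohorts,
#'   or a list parallel to `exprs`.
#' @param ratios Increasing NP ratios to probe (>= 2 values).
#' @param members_per_ratio Members per ratio per cohort.
#' @param seed Master RNG seed.
#' @param ... Passed to [train_member()] (`cost`, `standardize`,
#'   `holdout_frac`).
#' @return Object of class `"np_calibration"`: `summary` data.frame (ratio,
#'   median test/initial precision, member counts), `precisions` long
#'   data.frame, `chosen_ratio`.
#' @export
calibrate_np_ratio <- function(exprs, labels_list,
                               ratios = c(1, 10, 15, 20, 25, 30),
                               members_per_ratio = 100L, seed = 1L, ...) {
  if (inherits(exprs, "expr_matrix")) exprs <- list(exprs)
  if (inherits(labels_list, "label_vector")) {
    labels_list <- rep(list(labels_list), length(exprs))
  }
  if (length(ratios) < 2L) stop_pu("provide at least 2 ratios")
  if (is.unsorted(ratios, strictly = TRUE)) stop_pu("ratios must be strictly increasing")
  rows <- list()
  for (ci in seq_along(exprs)) {
    expr <- exprs[[ci]]
    labels <- labels_list[[ci]][rownames(expr)]
    for (ri in seq_along(ratios)) {
      for (m in seq_len(members_per_ratio)) {
        s_samp <- derive_seed(seed, m + 1000L * ci, stream = 20L + ri)
        s_split <- derive_seed(seed, m + 1000L * ci, stream = 50L + ri)
        manifest <- sample_training_set(labels, ratios[ri], seed = s_samp)
        member <- train_member(expr, manifest, seed = s_split, ...)
        ip <- evaluate_initial(member, expr, labels)
        rows[[length(rows) + 1L]] <- data.frame(
          cohort = cohort(expr), ratio = ratios[ri], member = m,
          test_precision = member$test_precision, initial_precision = ip)
      }
    }
  }
  prec <- do.call(rbind, rows)
  med <- do.call(rbind, lapply(split(prec, prec$ratio), function(d) {
    data.frame(ratio = d$ratio[1L],
               median_test = stats::median(d$test_precision, na.rm = TRUE),
               median_initial = stats::median(d$initial_precision, na.rm = TRUE),
               n_members = nrow(d))
  }))
  med <- med[order(med$ratio), , drop = FALSE]
  rownames(med) <- NULL
  qualifying <- med$ratio[med$median_initial > 0.5]
  if (length(qualifying)) {
    chosen <- min(qualifying)
  } else {
    chosen <- med$ratio[which.max(med$median_initial)]
    warn_pu("no ratio reaches median initial precision > 0.5; ",
            "falling back to argmax ratio ", chosen)
  }
  structure(list(summary = med, precisions = prec, chosen_ratio = chosen),
            class = "np_calibration")
}

#' @export
print.np_calibration <- function(x, ...) {
  cat("NP-ratio calibration (pooled over cohorts and members)\n")
  print(x$summary, row.names = FALSE)
  cat("chosen ratio:", x$chosen_ratio, "\n")
  invisible(x)
}

#' @export
plot.np_calibration <- function(x, ...) {
  s <- x$summary
  graphics::matplot(s$ratio, cbind(s$median_test, s$median_initial),
                    type = "b", pch = c(1, 19), lty = 1,
                    col = c("grey40", "red3"), xlab = "NP ratio",
                    ylab = "pooled median precision", ylim = c(0, 1), ...)
  graphics::abline(h = 0.5, lty = 3)
  graphics::legend("right", c("testing data", "initial data"),
                   col = c("grey40", "red3"), pch = c(1, 19), bty = "n")
  invisible(x)
}

#' Aggregate per-cohort ensembles into pan-cancer votes
#'
#' For every gene in the union of the cohorts' universes: `prevalence` is the
#' number of cohorts voting for it at least once, and `avg_vote` is the mean
#' vote computed only over those voting cohorts (0 when no cohort votes).
#' Genes absent from a cohort count as 0 votes there.
#'
#' @param models List of [pu_ensemble()] fits.
#' @return Object of class `"pan_votes"`: `table` data.frame (`gene`,
#'   `prevalence`, `avg_vote`), `votes` gene-by-cohort matrix, `n_cohorts`.
#' @export
aggregate_pan_cancer <- function(models) {
  if (inherits(models, "pu_ensemble")) models <- list(models)
  if (!length(models)) stop_pu("need at least one ensemble")
  genes <- sort(unique(unlist(lapply(models, function(m) names(m$votes)))))
  vm <- matrix(0L, length(genes), length(models),
               dimnames = list(genes,
                               vapply(models, `[[`, character(1L), "cohort")))
  for (j in seq_along(models)) {
    v <- models[[j]]$votes
    vm[names(v), j] <- as.integer(v)
  }
  voted <- vm >= 1L
  prevalence <- rowSums(voted)
  avg <- ifelse(prevalence > 0, rowSums(vm * voted) / pmax(prevalence, 1L), 0)
  tab <- data.frame(gene = genes, prevalence = as.integer(prevalence),
                    avg_vote = as.numeric(avg), row.names = NULL,
                    stringsAsFactors = FALSE)
  structure(list(table = tab, votes = vm, n_cohorts = length(models)),
            class = "pan_votes")
}

#' @export
print.pan_votes <- function(x, ...) {
  cat(sprintf("<pan_votes> %d genes across %d cohorts; %d voted in >= 1 cohort\n",
              nrow(x$table), x$n_cohorts, sum(x$table$prevalence > 0)))
  invisible(x)
}

#' Ranking score of pan-cancer votes
#'
#' Average vote over voting cohorts with cancer prevalence as tie-breaker;
#' unvoted genes score 0.  Ties in both components remain tied, so rank-based
#' metrics such as [roc_auc()] are unaffected by arbitrary ordering.
#'
#' @param pan A [aggregate_pan_cancer()] result.
#' @return Named numeric score vector over all genes.
#' @export
pan_scores <- function(pan) {
  stopifnot(inherits(pan, "pan_votes"))
  tab <- pan$table
  # integer rank of avg_vote scaled past the prevalence range: exact
  # lexicographic (avg_vote, prevalence) ordering with ties preserved
  a_rank <- match(tab$avg_vote, sort(unique(tab$avg_vote)))
  stats::setNames(a_rank * (pan$n_cohorts + 1) + tab$prevalence, tab$gene)
}

#' Pan-cohort out-of-bag vote rates
#'
#' Mean out-of-bag vote rate per gene across a list of fitted ensembles: the
#' exchangeability-respecting score used to evaluate null behaviour (see
#' [pu_ensemble()] Details).
#'
#' @param models List of [pu_ensemble()] fits.
#' @return Named numeric vector over the union of gene universes.
#' @export
oob_scores <- function(models) {
  if (inherits(models, "pu_ensemble")) models <- list(models)
  genes <- sort(unique(unlist(lapply(models, function(m) names(m$oob_rate)))))
  rm_ <- matrix(NA_real_, length(genes), length(models),
                dimnames = list(genes, NULL))
  for (j in seq_along(models)) {
    r <- models[[j]]$oob_rate
    rm_[names(r), j] <- r
  }
  rowMeans(rm_, na.rm = TRUE)
}

#' Pearson-correlation baseline score
#'
#' The conventional alternative: each gene is scored by the mean (or max)
#' Pearson correlation of its expression profile with the positive genes'
#' profiles (excluding the gene itself).  Zero-variance genes get `NA`.
#'
#' @param expr An [expression_matrix()].
#' @param positives Seed gene set.
#' @param aggregate `"mean"` (default) or `"max"`.
#' @return Named numeric score per gene (`NA` for constant genes).
#' @export
correlation_baseline <- function(expr, positives, aggregate = c("mean", "max")) {
  aggregate <- match.arg(aggregate)
  if (ncol(expr) < 2L) stop_pu("need at least 2 patients")
  pos <- intersect(positives, rownames(expr))
  if (!length(pos)) stop_pu("no positive gene in the expression matrix")
  x <- t(log2p1(unclass(expr)))
  sds <- apply(x, 2L, stats::sd)
  ok <- sds > 0
  cm <- suppressWarnings(stats::cor(x[, ok, drop = FALSE],
                                    x[, intersect(pos, colnames(x)[ok]),
                                      drop = FALSE]))
  scores <- stats::setNames(rep(NA_real_, nrow(expr)), rownames(expr))
  for (g in rownames(cm)) {
    r <- cm[g, setdiff(colnames(cm), g)]
    r <- r[is.finite(r)]
    if (length(r)) scores[g] <- if (aggregate == "mean") mean(r) else max(r)
  }
  scores
}

#' Rank-based ROC AUC with tie correction
#'
#' Equivalent to the scaled Mann-Whitney U statistic; missing scores are
#' treated as `-Inf` (ranked below everything).
#'
#' @param scores Named numeric score per gene.
#' @param positives,negatives Gene sets defining the two classes (both
#'   non-empty after intersection with `names(scores)`).
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, positives, negatives) {
  pos <- intersect(positives, names(scores))
  neg <- intersect(negatives, names(scores))
  if (!length(pos) || !length(neg)) stop_pu("both classes must be non-empty")
  s <- scores[c(pos, neg)]
  s[is.na(s)] <- -Inf
  r <- rank(s)
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}
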