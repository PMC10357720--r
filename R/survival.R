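# Risk scoring from pre-trained coefficients, Kaplan-Meier stratification
# with log-rank testing, stage trends, and patient-weight subtype enrichment.

#' Per-patient risk scores from a pre-trained risk model
#'
#' `score(patient) = sum_g coef(g) * log2(expr(g, patient) + 1)` over the
#' genes shared by `gene_subset`, the model and the expression matrix (the
#' log2(x+1) scale matches the ensemble preprocessing).  Patients are split at
#' the median into high/low risk groups; patients exactly at the median go to
#' the low-risk group (deterministic tie rule).
#'
#' @param expr An [expression_matrix()].
#' @param model A [risk_model()].
#' @param gene_subset Genes to use (default: all model genes).
#' @param log_transform Apply log2(x+1) before weighting (default `TRUE`).
#' @return `data.frame` of class `"risk_scores"` with `patient_id`, `score`,
#'   `group`.
#' @export
risk_score <- function(expr, model, gene_subset = names(model),
                       log_transform = TRUE) {
  genes <- intersect(intersect(gene_subset, names(model)), rownames(expr))
  if (!length(genes)) {
    stop_pu("no usable gene: missing from expression: ",
            paste(utils::head(setdiff(intersect(gene_subset, names(model)),
                                      rownames(expr)), 5L), collapse = ", "))
  }
  x <- unclass(expr)[genes, , drop = FALSE]
  if (log_transform) x <- log2p1(x)
  score <- as.numeric(crossprod(x, as.numeric(model[genes])))
  med <- stats::median(score)
  out <- data.frame(patient_id = colnames(expr), score = score,
                    group = ifelse(score > med, "high", "low"),
                    stringsAsFactors = FALSE)
  class(out) <- c("risk_scores", class(out))
  out
}

#' Kaplan-Meier curves and log-rank test between patient groups
#'
#' Observations are administratively censored at the horizon; the product-
#' limit estimator is computed per group and the groups compared with the
#' two-sample log-rank test.
#'
#' @param clinical A [clinical_table()].
#' @param groups Named group label per patient (e.g. `risk_score()` output's
#'   `group` column named by patient).
#' @param horizon_years Follow-up horizon in years (default 5).
#' @return Object of class `"km_result"` with `fit` (a
#'   [survival::survfit] object), `chisq`, `df`, `p`, `horizon_years`, `n`.
#' @export
km_logrank <- function(clinical, groups, horizon_years = 5) {
  pats <- intersect(clinical$patient_id, names(groups))
  if (!length(pats)) stop_pu("groups share no patients with the clinical table")
  cl <- clinical[match(pats, clinical$patient_id), , drop = FALSE]
  grp <- factor(groups[pats])
  if (nlevels(grp) < 2L || any(table(grp) == 0L)) {
    stop_pu("need two non-empty groups")
  }
  horizon <- horizon_years * 365.25
  time <- pmin(cl$survival_time, horizon)
  event <- ifelse(cl$survival_time <= horizon, cl$event, 0L)
  df <- data.frame(time = time, event = event, grp = grp)
  fit <- survival::survfit(survival::Surv(time, event) ~ grp, data = df)
  if (sum(event) == 0L) {
    # no event inside the horizon: curves are flat, no evidence of difference
    chisq <- 0
    p <- 1
  } else {
    sd <- survival::survdiff(survival::Surv(time, event) ~ grp, data = df)
    chisq <- unname(sd$chisq)
    p <- stats::pchisq(chisq, df = nlevels(grp) - 1L, lower.tail = FALSE)
  }
  structure(list(fit = fit, chisq = chisq, df = nlevels(grp) - 1L, p = p,
                 horizon_years = horizon_years, n = as.integer(table(grp))),
            class = "km_result")
}

#' @export
print.km_result <- function(x, ...) {
  cat(sprintf("<km_result> %d-year horizon, groups n = %s; log-rank chisq = %.3f (df %d), p = %.4g\n",
              x$horizon_years, paste(x$n, collapse = "/"), x$chisq, x$df, x$p))
  invisible(x)
}

#' @export
plot.km_result <- function(x, ...) {
  graphics::plot(x$fit, col = c("red3", "grey30"), lwd = 2,
                 xlab = "days", ylab = "survival probability", ...)
  graphics::legend("bottomleft",
                   legend = sub("^grp=", "", names(x$fit$strata)),
                   col = c("red3", "grey30"), lwd = 2, bty = "n")
  invisible(x)
}

#' Risk-score trend across pathologic stages
#'
#' Per-stage median and IQR, one-sided rank-sum tests for each adjacent stage
#' pair (higher stage > lower), and a monotonicity flag (medians strictly
#' increasing).  Stages with fewer than 2 patients are excluded with a
#' warning; `"unknown"` stages are ignored.
#'
#' @param scores A `risk_scores` data.frame (or named numeric per patient).
#' @param stages Named stage per patient (I..IV or unknown).
#' @return List of class `"stage_trend"`: `summary` data.frame, `pairwise`
#'   data.frame, `monotone` flag.
#' @export
stage_trend <- function(scores, stages) {
  if (inherits(scores, "risk_scores")) {
    scores <- stats::setNames(scores$score, scores$patient_id)
  }
  pats <- intersect(names(scores), names(stages))
  st <- stages[pats]
  keep <- st %in% c("I", "II", "III", "IV")
  st <- factor(st[keep], levels = c("I", "II", "III", "IV"))
  sc <- scores[pats][keep]
  counts <- table(st)
  small <- names(counts)[counts > 0 & counts < 2]
  if (length(small)) {
    warn_pu("stage(s) with < 2 patients excluded: ", paste(small, collapse = ", "))
  }
  lv <- names(counts)[counts >= 2]
  if (length(lv) < 2L) stop_pu("need at least 2 populated stages")
  per <- lapply(lv, function(s) {
    v <- sc[st == s]
    data.frame(stage = s, n = length(v), median = stats::median(v),
               q1 = unname(stats::quantile(v, 0.25)),
               q3 = unname(stats::quantile(v, 0.75)))
  })
  summ <- do.call(rbind, per)
  pw <- lapply(seq_len(length(lv) - 1L), function(i) {
    hi <- sc[st == lv[i + 1L]]
    lo <- sc[st == lv[i]]
    data.frame(pair = paste(lv[i + 1L], ">", lv[i]),
               p = group_compare(hi, lo)$p)
  })
  pairwise <- do.call(rbind, pw)
  structure(list(summary = summ, pairwise = pairwise,
                 monotone = !is.unsorted(summ$median, strictly = TRUE)),
            class = "stage_trend")
}

#' @export
print.stage_trend <- function(x, ...) {
  cat("Risk-score trend across stages (monotone:", x$monotone, ")\n")
  print(x$summary, row.names = FALSE)
  print(x$pairwise, row.names = FALSE)
  invisible(x)
}

#' Subtype enrichment among highly weighted patients
#'
#' Patients are ranked by their signed ensemble weights (by default) and the
#' flagged patients form the hit set of a permutation GSEA — the patient-level
#' analogue of gene-set enrichment.  Signed ranking is the default because a
#' subtype tied to one pole of the latent pathway activity concentrates at one
#' end of the signed weights, whereas the absolute ranking mixes both extremes;
#' set `use_abs = TRUE` to rank by influence magnitude instead.
#'
#' @param weights A [patient_weights()] data.frame, or a named numeric vector
#'   of patient weights.
#' @param subtype_flags Named 0/1 (or logical) flag per patient.
#' @param n_perm Number of permutations (default 10000).
#' @param seed RNG seed.
#' @param use_abs Rank by `|weight|` instead of signed weight (default
#'   `FALSE`).
#' @return An `"enrichment_result"` over patients.
#' @export
weight_enrichment <- function(weights, subtype_flags, n_perm = 10000L,
                              seed = 1L, use_abs = FALSE) {
  if (is.data.frame(weights)) {
    weights <- stats::setNames(weights$weight, weights$patient_id)
  }
  pats <- intersect(names(weights), names(subtype_flags))
  if (!length(pats)) stop_pu("weights and flags share no patients")
  flagged <- pats[subtype_flags[pats] > 0]
  if (!length(flagged) || length(flagged) == length(pats)) {
    stop_pu("need at least one flagged and one unflagged patient")
  }
  w <- weights[pats]
  if (use_abs) w <- abs(w)
  permutation_enrichment(w, flagged, n_perm = n_perm, seed = seed)
}
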