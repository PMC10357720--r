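# Single entry point wiring all stages into reproducible file-based runs.
# Stages communicate through plain-text artifacts in the output directory, so
# a rerun with the same configuration reproduces byte-identical outputs.

#' Pipeline run configuration
#'
#' Defaults echo the reference analysis settings: 1000 members at NP ratio 20
#' with a 70/30 hold-out, calibration ratios 1:1 to 30:1, 10,000 permutations
#' for gene/patient enrichment and 1,000 for module activity.  All seeds are
#' explicit; there are no wall-clock defaults.
#'
#' @param sim A [sim_config()] for the simulate stage.
#' @param members Member classifiers per cohort ensemble.
#' @param np_ratio NP sampling ratio for training.
#' @param holdout_frac Hold-out fraction per member.
#' @param cost SVM cost.
#' @param calibration_ratios NP ratios probed by the calibrate stage.
#' @param members_per_ratio Members per ratio in calibration.
#' @param n_perm Permutations for enrichment stages.
#' @param n_perm_modules Permutations for module scoring/activity.
#' @param min_module_size Minimum functional-module size.
#' @param horizon_years Kaplan-Meier horizon.
#' @param seed Master seed for all stages.
#' @param out_dir Output directory.
#' @return List of class `"run_config"`.
#' @export
pipeline_config <- function(sim = default_config(), members = 1000L,
                            np_ratio = 20, holdout_frac = 0.3, cost = 1,
                            calibration_ratios = c(1, 10, 15, 20, 25, 30),
                            members_per_ratio = 100L, n_perm = 10000L,
                            n_perm_modules = 1000L, min_module_size = 3L,
                            horizon_years = 5, seed = 1L, out_dir = "puvote_run") {
  structure(list(sim = sim, members = as.integer(members),
                 np_ratio = np_ratio, holdout_frac = holdout_frac, cost = cost,
                 calibration_ratios = calibration_ratios,
                 members_per_ratio = as.integer(members_per_ratio),
                 n_perm = as.integer(n_perm),
                 n_perm_modules = as.integer(n_perm_modules),
                 min_module_size = as.integer(min_module_size),
                 horizon_years = horizon_years, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "run_config")
}

#' Load a pipeline configuration from YAML
#'
#' Unspecified fields fall back to the [pipeline_config()] defaults; the `sim`
#' block is passed to [sim_config()].
#'
#' @param path YAML file.
#' @return A `"run_config"`.
#' @export
load_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  sim <- if (!is.null(raw$sim)) do.call(sim_config, raw$sim) else default_config()
  args <- raw[setdiff(names(raw), "sim")]
  do.call(pipeline_config, c(list(sim = sim), args))
}

pipeline_stages <- function() {
  c("simulate", "calibrate", "train", "aggregate", "enrich", "modules",
    "survival")
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

write_json_out <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  path
}

#' Run the full analysis pipeline on synthetic data
#'
#' Executes the requested stages in dependency order
#' (simulate -> calibrate -> train -> aggregate -> enrich -> modules ->
#' survival), writing every artifact as TSV/JSON under `config$out_dir` and a
#' machine-readable manifest (`manifest.json`) with seeds, package version and
#' md5 hashes of all outputs.  Stages read their upstream artifacts from disk,
#' so a subset of stages can be rerun against an existing directory; a missing
#' upstream artifact raises an error naming the stage to run first.
#'
#' @param config A [pipeline_config()].
#' @param stages Subset of stages to run (default: all).
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config, stages = pipeline_stages()) {
  stopifnot(inherits(config, "run_config"))
  stages <- match.arg(stages, pipeline_stages(), several.ok = TRUE)
  stages <- pipeline_stages()[pipeline_stages() %in% stages]
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  sim_dir <- file.path(out, "sim")
  outputs <- character(0)
  need <- function(path, stage) {
    if (!all(file.exists(path))) {
      stop_pu("missing upstream artifact ", paste(path, collapse = ", "),
              "; run the '", stage, "' stage first")
    }
    path
  }
  load_bundle_files <- function() {
    cfg <- config$sim
    cohorts <- sprintf("SIM%02d", seq_len(cfg$n_cohorts))
    expr_paths <- file.path(sim_dir, paste0("expr_", cohorts, ".tsv"))
    need(c(expr_paths, file.path(sim_dir, "gene_sets.gmt")), "simulate")
    exprs <- Map(read_expression, expr_paths, cohorts)
    names(exprs) <- cohorts
    list(exprs = exprs,
         sets = read_gmt(file.path(sim_dir, "gene_sets.gmt")))
  }
  make_labels <- function(exprs, sets) {
    build_label_vector(rownames(exprs[[1L]]), sets$SEED_PATHWAY,
                       sets[grep("^EXCL_HM_", names(sets))])
  }

  if ("simulate" %in% stages) {
    paths <- write_bundle(generate_bundle(config$sim), sim_dir)
    outputs <- c(outputs, unname(paths))
  }

  if ("calibrate" %in% stages) {
    b <- load_bundle_files()
    labels <- make_labels(b$exprs, b$sets)
    cal <- calibrate_np_ratio(b$exprs, labels, ratios = config$calibration_ratios,
                              members_per_ratio = config$members_per_ratio,
                              seed = derive_seed(config$seed, 1L, stream = 100L),
                              holdout_frac = config$holdout_frac,
                              cost = config$cost)
    outputs <- c(outputs,
                 write_tsv(cal$summary, file.path(out, "calibration.tsv")),
                 write_json_out(list(chosen_ratio = cal$chosen_ratio),
                                file.path(out, "calibration.json")))
  }

  if ("train" %in% stages) {
    b <- load_bundle_files()
    labels <- make_labels(b$exprs, b$sets)
    votes_rows <- list()
    weight_rows <- list()
    prec_rows <- list()
    for (i in seq_along(b$exprs)) {
      fit <- pu_ensemble(b$exprs[[i]], labels, members = config$members,
                         np_ratio = config$np_ratio,
                         holdout_frac = config$holdout_frac,
                         cost = config$cost,
                         seed = derive_seed(config$seed, i, stream = 200L))
      votes_rows[[i]] <- data.frame(gene = names(fit$votes),
                                    cohort = fit$cohort,
                                    vote = as.integer(fit$votes))
      w <- patient_weights(fit)
      w$cohort <- fit$cohort
      weight_rows[[i]] <- w
      s <- summary(fit)
      prec_rows[[i]] <- data.frame(cohort = fit$cohort, members = fit$M,
                                   median_test = s$median_test_precision,
                                   median_initial = s$median_initial_precision)
    }
    outputs <- c(outputs,
                 write_tsv(do.call(rbind, votes_rows),
                           file.path(out, "votes.tsv")),
                 write_tsv(do.call(rbind, weight_rows),
                           file.path(out, "patient_weights.tsv")),
                 write_tsv(do.call(rbind, prec_rows),
                           file.path(out, "member_precision.tsv")))
  }

  votes_long <- function() {
    p <- need(file.path(out, "votes.tsv"), "train")
    utils::read.delim(p, stringsAsFactors = FALSE)
  }
  pan_from_disk <- function() {
    v <- votes_long()
    wide <- stats::xtabs(vote ~ gene + cohort, data = v)
    models <- lapply(colnames(wide), function(co) {
      structure(list(cohort = co,
                     votes = stats::setNames(as.integer(wide[, co]),
                                             rownames(wide))),
                class = "pu_ensemble")
    })
    aggregate_pan_cancer(models)
  }

  if ("aggregate" %in% stages) {
    pan <- pan_from_disk()
    outputs <- c(outputs,
                 write_tsv(pan$table, file.path(out, "pan_votes.tsv")))
  }

  if ("enrich" %in% stages) {
    need(file.path(out, "pan_votes.tsv"), "aggregate")
    b <- load_bundle_files()
    pan <- utils::read.delim(file.path(out, "pan_votes.tsv"),
                             stringsAsFactors = FALSE)
    avg <- stats::setNames(pan$avg_vote, pan$gene)
    onc <- b$sets$ONCOGENIC
    enr <- permutation_enrichment(avg, onc, n_perm = config$n_perm,
                                  seed = derive_seed(config$seed, 1L,
                                                     stream = 300L))
    voted <- avg[avg > 0]
    curve <- proportion_curve(voted, onc,
                              stats::quantile(voted, seq(0, 0.9, by = 0.1)))
    outputs <- c(outputs,
                 write_json_out(list(es = enr$es, z = enr$z, p = enr$p,
                                     n_perm = enr$n_perm,
                                     hits = enr$hits, misses = enr$misses),
                                file.path(out, "oncogenic_enrichment.json")),
                 write_tsv(curve, file.path(out, "proportion_curve.tsv")))
  }

  if ("modules" %in% stages) {
    v <- votes_long()
    b <- load_bundle_files()
    need(file.path(sim_dir, c("ppi.tsv", "annotations.tsv")), "simulate")
    ppi <- read_ppi(file.path(sim_dir, "ppi.tsv"))
    terms <- read_annotations(file.path(sim_dir, "annotations.tsv"))
    co1 <- v[v$cohort == v$cohort[1L], ]
    seed_genes <- b$sets$SEED_PATHWAY
    cand <- stats::setNames(co1$vote, co1$gene)
    cand <- cand[!(names(cand) %in% seed_genes) & cand > 0]
    mods <- find_modules(ppi, cand, terms, min_size = config$min_module_size,
                         n_perm = config$n_perm_modules,
                         seed = derive_seed(config$seed, 1L, stream = 400L))
    if (length(mods)) mods <- relative_significance(mods)
    mod_json <- lapply(mods, function(m) {
      list(term_id = m$term_id, term_name = m$term_name, genes = m$genes,
           z = m$z, p = m$enrichment$p,
           relative_significance = m$relative_significance)
    })
    outputs <- c(outputs,
                 write_json_out(mod_json, file.path(out, "modules.json")))
  }

  if ("survival" %in% stages) {
    need(file.path(sim_dir, c("clinical.tsv", "risk_model.tsv")), "simulate")
    b <- load_bundle_files()
    clinical <- read_clinical(file.path(sim_dir, "clinical.tsv"))
    rm_ <- read_risk_model(file.path(sim_dir, "risk_model.tsv"))
    scores_all <- do.call(rbind, lapply(b$exprs, risk_score, model = rm_))
    rownames(scores_all) <- NULL
    groups <- stats::setNames(scores_all$group, scores_all$patient_id)
    km <- km_logrank(clinical, groups, horizon_years = config$horizon_years)
    st <- stage_trend(stats::setNames(scores_all$score, scores_all$patient_id),
                      stats::setNames(clinical$stage, clinical$patient_id))
    wp <- need(file.path(out, "patient_weights.tsv"), "train")
    wdf <- utils::read.delim(wp, stringsAsFactors = FALSE)
    co1 <- wdf[wdf$cohort == wdf$cohort[1L], ]
    flags <- stats::setNames(clinical$tnbc, clinical$patient_id)
    we <- weight_enrichment(stats::setNames(co1$weight, co1$patient_id),
                            flags, n_perm = config$n_perm,
                            seed = derive_seed(config$seed, 1L, stream = 500L))
    outputs <- c(outputs,
                 write_tsv(scores_all, file.path(out, "risk_scores.tsv")),
                 write_json_out(list(chisq = km$chisq, p = km$p,
                                     horizon_years = km$horizon_years,
                                     n = km$n),
                                file.path(out, "km_logrank.json")),
                 write_json_out(list(summary = st$summary,
                                     pairwise = st$pairwise,
                                     monotone = st$monotone),
                                file.path(out, "stage_trend.json")),
                 write_json_out(list(es = we$es, z = we$z, p = we$p,
                                     n_perm = we$n_perm),
                                file.path(out, "weight_enrichment.json")))
  }

  manifest <- list(
    package = "puvote",
    version = as.character(utils::packageVersion("puvote")),
    seed = config$seed,
    stages = stages,
    config = unclass(config[setdiff(names(config), "sim")]),
    sim_config = unclass(config$sim),
    outputs = lapply(stats::setNames(outputs, basename(outputs)), function(p) {
      list(path = p, md5 = unname(tools::md5sum(p)))
    }))
  write_json_out(manifest, file.path(out, "manifest.json"))
  invisible(manifest)
}
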