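# Synthetic-data generator.  Produces a fully self-contained bundle with the
# statistical structure the PU-voting method assumes: a latent per-patient
# pathway-activity factor loading on seed genes and on hidden true members,
# decoy genes without the factor, stand-ins for other hallmark sets, term
# annotations overlapping the truth, a PPI graph with a planted module,
# subtype labels tied to the factor, and survival times driven by a risk
# score.  It deliberately does NOT imitate batch effects, library-size
# artifacts, or gene-gene covariance beyond the planted factors.

#' Configuration for the synthetic-data generator
#'
#' @param n_cohorts Number of cancer-cohort expression matrices.
#' @param genes_total Total genes per cohort.
#' @param n_seed Planted positives (the seed pathway gene set).
#' @param n_hidden True pathway members outside the seed set: the genes the
#'   method is supposed to discover.
#' @param n_excluded Stand-ins for genes of other hallmark sets (excluded from
#'   training, still scored).
#' @param patients_per_cohort Patients per cohort.
#' @param factor_strength Loading of the latent pathway-activity factor on
#'   seed and hidden genes (0 = no signal).
#' @param noise_sd Standard deviation of per-cell Gaussian noise on the latent
#'   (pre-softplus) scale.
#' @param subtype_fraction Fraction of patients flagged with the pathway-driven
#'   subtype (the TNBC analogue): the top fraction by latent activity.
#' @param baseline_hazard Baseline exponential hazard per day for simulated
#'   survival.
#' @param risk_effect Multiplier on the standardized risk score in the
#'   log-hazard (0 = survival unrelated to expression).
#' @param ppi_nodes Number of genes carried into the PPI graph.
#' @param ppi_attach Preferential-attachment edges per new node.
#' @param module_size Size of the planted connected PPI module (drawn from the
#'   hidden members).
#' @param seed Master RNG seed; per-cohort streams are derived from it by
#'   fixed offsets so adding cohorts never perturbs existing ones.
#' @return A validated list of class `"sim_config"`.
#' @export
sim_config <- function(n_cohorts = 3L, genes_total = 2000L, n_seed = 60L,
                       n_hidden = 40L, n_excluded = 200L,
                       patients_per_cohort = 150L, factor_strength = 1.5,
                       noise_sd = 1.0, subtype_fraction = 0.2,
                       baseline_hazard = 5e-4, risk_effect = 1.0,
                       ppi_nodes = 400L, ppi_attach = 2L, module_size = 12L,
                       seed = 17L) {
  cfg <- list(n_cohorts = as.integer(n_cohorts),
              genes_total = as.integer(genes_total),
              n_seed = as.integer(n_seed), n_hidden = as.integer(n_hidden),
              n_excluded = as.integer(n_excluded),
              patients_per_cohort = as.integer(patients_per_cohort),
              factor_strength = as.numeric(factor_strength),
              noise_sd = as.numeric(noise_sd),
              subtype_fraction = as.numeric(subtype_fraction),
              baseline_hazard = as.numeric(baseline_hazard),
              risk_effect = as.numeric(risk_effect),
              ppi_nodes = as.integer(ppi_nodes),
              ppi_attach = as.integer(ppi_attach),
              module_size = as.integer(module_size),
              seed = as.integer(seed))
  counts <- c("n_cohorts", "genes_total", "n_seed", "n_hidden", "n_excluded",
              "patients_per_cohort", "ppi_nodes", "ppi_attach", "module_size")
  if (any(vapply(cfg[counts], function(v) v <= 0L, logical(1L)))) {
    stop_pu("all counts in sim_config must be positive")
  }
  if (cfg$n_seed + cfg$n_hidden + cfg$n_excluded >= cfg$genes_total) {
    stop_pu("n_seed + n_hidden + n_excluded must be < genes_total")
  }
  if (cfg$factor_strength < 0 || cfg$noise_sd < 0) {
    stop_pu("factor_strength and noise_sd must be >= 0")
  }
  if (cfg$subtype_fraction <= 0 || cfg$subtype_fraction >= 1) {
    stop_pu("subtype_fraction must be in (0, 1)")
  }
  if (cfg$module_size > cfg$n_hidden) {
    stop_pu("module_size cannot exceed n_hidden")
  }
  if (cfg$ppi_nodes > cfg$genes_total) stop_pu("ppi_nodes exceeds genes_total")
  structure(cfg, class = "sim_config")
}

#' The canonical desk-scale simulation configuration
#'
#' 3 cohorts, 2,000 genes (60 seed, 40 hidden, 200 excluded), 150 patients
#' per cohort, factor strength 1.5, noise sd 1, master seed 17.  All
#' property-style checks in the package reference this configuration.
#' @return A [sim_config()].
#' @export
default_config <- function() sim_config()

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0("<sim_config> %d cohorts x %d genes x %d patients; ",
                     "seed/hidden/excluded = %d/%d/%d; factor %.2g, noise %.2g, ",
                     "rng seed %d\n"),
              x$n_cohorts, x$genes_total, x$patients_per_cohort, x$n_seed,
              x$n_hidden, x$n_excluded, x$factor_strength, x$noise_sd, x$seed))
  invisible(x)
}

#' Generate a synthetic multi-cohort bundle
#'
#' Per cohort, each patient receives a latent pathway activity
#' `a ~ N(0, 1)`.  Expression of seed and hidden genes is
#' `softplus(baseline + factor_strength * a + noise)`; excluded-hallmark
#' stand-ins load on an independent second factor of the same strength;
#' decoys are `softplus(baseline + noise)`.  The softplus link keeps
#' expression non-negative without truncating the rank structure a linear SVM
#' exploits.  The subtype flag marks the top `subtype_fraction` of patients by
#' latent activity (thresholding, not sampling, so subtype enrichment among
#' high-weight patients is guaranteed at high factor strength).  Survival
#' times are exponential with log-hazard proportional to the bundled risk
#' model's score; stages follow risk-score quartiles with noise.  Annotation
#' terms overlap the truth set (one term is exactly the planted PPI module),
#' and the PPI graph carries one planted connected module inside the hidden
#' members.
#'
#' @param config A [sim_config()].
#' @return A list of class `"sim_bundle"` with elements `expression` (named
#'   list of [expression_matrix()]), `truth` (`seed`, `hidden`, `excluded`,
#'   `decoys`), `gene_sets`, `core_genes`, `annotations`, `ppi`,
#'   `module_genes`, `clinical`, `risk_model`, `config`.
#' @export
generate_bundle <- function(config = default_config()) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  genes <- c(sprintf("SEED%03d", seq_len(cfg$n_seed)),
             sprintf("HID%03d", seq_len(cfg$n_hidden)),
             sprintf("EXC%03d", seq_len(cfg$n_excluded)),
             sprintf("DEC%04d", seq_len(cfg$genes_total - cfg$n_seed -
                                          cfg$n_hidden - cfg$n_excluded)))
  seed_set <- genes[seq_len(cfg$n_seed)]
  hidden_set <- genes[cfg$n_seed + seq_len(cfg$n_hidden)]
  excl_set <- genes[cfg$n_seed + cfg$n_hidden + seq_len(cfg$n_excluded)]
  decoys <- setdiff(genes, c(seed_set, hidden_set, excl_set))
  signal <- c(seed_set, hidden_set)

  # master-stream draws: gene baselines, risk model, annotations, PPI
  master <- derive_seed(cfg$seed, 0L, stream = 1L)
  shared <- with_seed(master, {
    baseline <- stats::setNames(stats::runif(length(genes), 2, 6), genes)
    risk_genes <- sample_exact(signal, min(50L, length(signal)))
    coefs <- stats::setNames(abs(stats::rnorm(length(risk_genes), 0.15, 0.05)),
                             risk_genes)
    module_genes <- sample_exact(hidden_set, cfg$module_size)
    list(baseline = baseline, risk = risk_model(coefs),
         module_genes = sort(module_genes))
  })

  ppi <- with_seed(derive_seed(cfg$seed, 0L, stream = 2L),
                   simulate_ppi(genes, shared$module_genes, cfg))
  ann <- with_seed(derive_seed(cfg$seed, 0L, stream = 3L),
                   simulate_annotations(seed_set, hidden_set, decoys,
                                        shared$module_genes))

  exprs <- vector("list", cfg$n_cohorts)
  clin <- vector("list", cfg$n_cohorts)
  for (i in seq_len(cfg$n_cohorts)) {
    co <- sprintf("SIM%02d", i)
    res <- with_seed(derive_seed(cfg$seed, i, stream = 4L),
                     simulate_cohort(co, genes, signal, excl_set,
                                     shared$baseline, shared$risk, cfg))
    exprs[[i]] <- res$expr
    clin[[i]] <- res$clinical
  }
  names(exprs) <- vapply(exprs, cohort, character(1L))
  clinical <- do.call(rbind, clin)
  class(clinical) <- c("clinical_table", "data.frame")

  excl_split <- split(excl_set, rep(1:4, length.out = length(excl_set)))
  sets <- gene_sets(c(list(SEED_PATHWAY = seed_set, ONCOGENIC = signal),
                      stats::setNames(excl_split, paste0("EXCL_HM_", 1:4))),
                    c("seed pathway hallmark", "oncogenic truth analogue",
                      rep("other-hallmark stand-in", 4)))

  structure(list(expression = exprs,
                 truth = list(seed = seed_set, hidden = hidden_set,
                              excluded = excl_set, decoys = decoys),
                 gene_sets = sets,
                 core_genes = seed_set[seq_len(min(6L, length(seed_set)))],
                 annotations = ann, ppi = ppi,
                 module_genes = shared$module_genes,
                 clinical = clinical, risk_model = shared$risk,
                 config = cfg),
            class = "sim_bundle")
}

#' @export
print.sim_bundle <- function(x, ...) {
  cat(sprintf(paste0("<sim_bundle> %d cohorts (%s); %d genes, %d patients total; ",
                     "planted module of %d genes\n"),
              length(x$expression), paste(names(x$expression), collapse = ", "),
              nrow(x$expression[[1L]]), nrow(x$clinical),
              length(x$module_genes)))
  invisible(x)
}

# one cohort: expression + clinical (assumes caller seeded the RNG)
simulate_cohort <- function(co, genes, signal, excl_set, baseline, risk, cfg) {
  np <- cfg$patients_per_cohort
  pats <- sprintf("%s_P%03d", co, seq_len(np))
  a <- stats::rnorm(np)            # pathway activity
  b <- stats::rnorm(np)            # independent factor for excluded hallmarks
  lat <- matrix(baseline[genes], length(genes), np)
  lat[match(signal, genes), ] <- lat[match(signal, genes), ] +
    cfg$factor_strength * matrix(a, length(signal), np, byrow = TRUE)
  lat[match(excl_set, genes), ] <- lat[match(excl_set, genes), ] +
    cfg$factor_strength * matrix(b, length(excl_set), np, byrow = TRUE)
  lat <- lat + matrix(stats::rnorm(length(genes) * np, sd = cfg$noise_sd),
                      length(genes), np)
  vals <- softplus(lat)
  dimnames(vals) <- list(genes, pats)
  expr <- expression_matrix(vals, co)

  tnbc <- a >= stats::quantile(a, 1 - cfg$subtype_fraction)
  er <- ifelse(tnbc, "neg", ifelse(stats::runif(np) < 0.85, "pos", "neg"))
  pr <- ifelse(tnbc, "neg", ifelse(stats::runif(np) < 0.75, "pos", "neg"))
  her2 <- ifelse(tnbc, "neg", ifelse(stats::runif(np) < 0.25, "pos", "neg"))

  rg <- intersect(names(risk), genes)
  score <- as.numeric(crossprod(log2p1(vals[rg, , drop = FALSE]),
                                as.numeric(risk[rg])))
  z <- as.numeric(scale(score))
  hazard <- cfg$baseline_hazard * exp(cfg$risk_effect * z)
  t_event <- stats::rexp(np, rate = hazard)
  t_cens <- stats::runif(np, 365, 3650)
  time <- pmin(t_event, t_cens)
  event <- as.integer(t_event <= t_cens)
  stage_idx <- pmin(pmax(findInterval(z + stats::rnorm(np, sd = 0.5),
                                      stats::quantile(z, c(0.25, 0.5, 0.75))) + 1L,
                         1L), 4L)
  clinical <- clinical_table(pats, co, time, event,
                             stage = c("I", "II", "III", "IV")[stage_idx],
                             er = er, pr = pr, her2 = her2,
                             tnbc = as.integer(tnbc))
  list(expr = expr, clinical = clinical)
}

# preferential-attachment PPI over a gene subset plus one planted connected
# module (spanning path + random chords) inside the hidden members
simulate_ppi <- function(genes, module_genes, cfg) {
  pool <- unique(c(module_genes,
                   sample_exact(setdiff(genes, module_genes),
                                cfg$ppi_nodes - length(module_genes))))
  g <- igraph::sample_pa(length(pool), power = 1, m = cfg$ppi_attach,
                         directed = FALSE)
  igraph::V(g)$name <- sample(pool) # detach hub status from gene category
  k <- length(module_genes)
  path_edges <- cbind(module_genes[-k], module_genes[-1L])
  extra <- t(utils::combn(module_genes, 2L))
  extra <- extra[stats::runif(nrow(extra)) < 0.3, , drop = FALSE]
  g <- igraph::add_edges(g, t(rbind(path_edges, extra)))
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
}

# annotation table emulating focused core-gene biology: each core stand-in
# owns a small block of experimentally supported terms; hidden members share a
# couple of terms from the cores they affiliate with (so their Jaccard
# similarity to cores is high); annotated decoys mostly carry diffuse
# background terms, a few touching one core term with heavy dilution.  One
# term annotates exactly the planted PPI module.
simulate_annotations <- function(seed_set, hidden_set, decoys, module_genes) {
  core <- seed_set[seq_len(min(6L, length(seed_set)))]
  n_core_terms <- 4L
  core_terms <- lapply(seq_along(core),
                       function(i) sprintf("T:CORE%d_%d", i, seq_len(n_core_terms)))
  bg_terms <- sprintf("T:BG%02d", 1:20)
  add <- function(rec, genes, terms, evidence = "IDA") {
    rec[[length(rec) + 1L]] <- data.frame(
      gene = rep(genes, each = length(terms)),
      term_id = rep(terms, times = length(genes)),
      term_name = rep(terms, times = length(genes)),
      evidence = evidence, stringsAsFactors = FALSE)
    rec
  }
  rec <- list()
  rec <- add(rec, module_genes, "T:MODULE")
  for (i in seq_along(core)) rec <- add(rec, core[i], core_terms[[i]])
  # hidden members: two affiliated cores, two terms from each, one background
  for (h in hidden_set) {
    aff <- sample_exact(seq_along(core), 2L)
    for (i in aff) rec <- add(rec, h, sample_exact(core_terms[[i]], 2L))
    rec <- add(rec, h, sample_exact(bg_terms, 1L),
               evidence = sample(c("IDA", "IEA"), 1L))
  }
  # annotated decoys: diffuse background, a third also graze one core term
  ann_dec <- sample_exact(decoys, min(120L, length(decoys)))
  for (k in seq_along(ann_dec)) {
    rec <- add(rec, ann_dec[k], sample_exact(bg_terms, sample(2:3, 1L)),
               evidence = sample(c("IDA", "IEA"), 1L))
    if (k %% 3L == 0L) {
      i <- sample_exact(seq_along(core), 1L)
      rec <- add(rec, ann_dec[k], sample_exact(core_terms[[i]], 1L))
    }
  }
  # non-core seed genes: light background annotation
  for (s in setdiff(seed_set, core)) {
    rec <- add(rec, s, sample_exact(bg_terms, 1L))
  }
  df <- unique(do.call(rbind, rec))
  df$term_name <- ifelse(df$term_id == "T:MODULE",
                         "planted functional module",
                         paste("process", df$term_id))
  annotation_table(df$gene, df$term_id, df$term_name, df$evidence)
}

#' Write a simulation bundle to disk in the package's standard formats
#'
#' Expression matrices as TSV (one per cohort), gene sets as GMT, annotations
#' as GAF-like TSV, PPI as a 2-column edge list, clinical table and risk
#' coefficients as TSV, and the configuration as YAML — exactly the formats
#' the readers in this package consume.
#'
#' @param bundle A [generate_bundle()] result.
#' @param dir Output directory (created if missing).
#' @return Named character vector of written paths, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "sim_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c()
  for (co in names(bundle$expression)) {
    p <- file.path(dir, paste0("expr_", co, ".tsv"))
    write_expression(bundle$expression[[co]], p)
    paths[paste0("expr_", co)] <- p
  }
  paths["gene_sets"] <- write_gmt(bundle$gene_sets, file.path(dir, "gene_sets.gmt"))
  paths["annotations"] <- write_annotations(bundle$annotations,
                                            file.path(dir, "annotations.tsv"))
  paths["ppi"] <- write_ppi(bundle$ppi, file.path(dir, "ppi.tsv"))
  paths["clinical"] <- write_clinical(bundle$clinical,
                                      file.path(dir, "clinical.tsv"))
  paths["risk_model"] <- write_risk_model(bundle$risk_model,
                                          file.path(dir, "risk_model.tsv"))
  cfg_path <- file.path(dir, "sim_config.yaml")
  yaml::write_yaml(unclass(bundle$config), cfg_path)
  paths["config"] <- cfg_path
  invisible(paths)
}
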