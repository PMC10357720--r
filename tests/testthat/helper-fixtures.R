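# Shared fixtures.  Expensive artifacts are memoized for the duration of the
# test run so several test files can reuse one computation.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# small configuration for fast unit tests (overridable defaults)
tiny_config <- function(...) {
  args <- list(n_cohorts = 1L, genes_total = 300L, n_seed = 25L,
               n_hidden = 10L, n_excluded = 40L, patients_per_cohort = 60L,
               ppi_nodes = 120L, module_size = 5L, seed = 11L)
  over <- list(...)
  args[names(over)] <- over
  do.call(sim_config, args)
}

tiny_bundle <- function() fixture("tiny_bundle", generate_bundle(tiny_config()))

default_bundle <- function() {
  fixture("default_bundle", generate_bundle(default_config()))
}

bundle_labels <- function(bundle, cohort_idx = 1L) {
  build_label_vector(rownames(bundle$expression[[cohort_idx]]),
                     bundle$gene_sets$SEED_PATHWAY,
                     bundle$gene_sets[grep("^EXCL_HM_", names(bundle$gene_sets))])
}

# the acceptance-scale ensembles: 3 cohorts x 200 members on the default
# synthetic configuration (signal) and on its zero-signal counterpart
default_fits <- function() {
  fixture("default_fits", {
    b <- default_bundle()
    labels <- bundle_labels(b)
    lapply(seq_along(b$expression), function(i) {
      pu_ensemble(b$expression[[i]], labels, members = 200L,
                  seed = 100L + i)
    })
  })
}

null_fits <- function() {
  fixture("null_fits", {
    b <- fixture("null_bundle", generate_bundle(sim_config(factor_strength = 0)))
    labels <- bundle_labels(b)
    lapply(seq_along(b$expression), function(i) {
      pu_ensemble(b$expression[[i]], labels, members = 200L,
                  seed = 100L + i)
    })
  })
}

# brute-force GSEA running-sum oracle (classic, exponent 0), independent of
# the package implementation: explicit loop over ranks
oracle_es <- function(hit) {
  n <- length(hit)
  nh <- sum(hit)
  cur <- 0
  best <- 0
  for (i in seq_len(n)) {
    cur <- cur + if (hit[i]) 1 / nh else -1 / (n - nh)
    if (abs(cur) > abs(best)) best <- cur
  }
  best
}

# exhaustive null over all hit-position memberships of size nh in a list of n
oracle_exact_p <- function(n, nh, es_obs) {
  combos <- utils::combn(n, nh)
  es_all <- apply(combos, 2L, function(pos) {
    hit <- logical(n)
    hit[pos] <- TRUE
    oracle_es(hit)
  })
  mean(abs(es_all) >= abs(es_obs) - 1e-12)
}

# brute-force AUC by pair counting (ties count 1/2)
oracle_auc <- function(scores, pos, neg) {
  s_pos <- scores[pos]
  s_neg <- scores[neg]
  tot <- 0
  for (a in s_pos) for (b in s_neg) {
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  }
  tot / (length(s_pos) * length(s_neg))
}

# exact two-sided Fisher p by hypergeometric enumeration (tables with
# probability <= observed, with the conventional relative tolerance)
oracle_fisher_p <- function(a, b, c, d) {
  m <- a + c
  n_ <- b + d
  k <- a + b
  x_all <- max(0, k - n_):min(k, m)
  probs <- stats::dhyper(x_all, m, n_, k)
  p_obs <- stats::dhyper(a, m, n_, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}
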