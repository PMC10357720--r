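test_that("enrichment score matches the brute-force running sum", {
  sc <- setNames(c(5, 4, 3, 2, 1), paste0("g", 1:5))
  # hits at the top two ranks climb to +1
  r <- gsea_es(sc, c("g1", "g2"))
  expect_equal(r$es, 1.0)
  expect_equal(r$leading_edge, c("g1", "g2"))
  expect_equal(r$hits + r$misses, 5L)
  # a single hit at the bottom: running sum reaches -1 before the hit
  r2 <- gsea_es(sc, "g5")
  expect_equal(r2$es, -1.0)
  # all genes hits: degenerate normalization climbs to 1 at the last rank
  r3 <- gsea_es(sc, paste0("g", 1:5))
  expect_equal(r3$es, 1.0)
  expect_equal(which.max(abs(r3$running_sum)), 5L)
  expect_error(gsea_es(sc, "absent"), "intersect")

  # random cases against the independent oracle
  set.seed(4)
  for (i in 1:20) {
    n <- sample(6:40, 1)
    scores <- setNames(sample(seq_len(n)), paste0("x", seq_len(n))) # no ties
    hits <- sample(names(scores), sample(seq_len(n - 1), 1))
    expect_equal(gsea_es(scores, hits)$es,
                 oracle_es(names(sort(scores, decreasing = TRUE)) %in% hits))
  }
})

test_that("classic ES is invariant under monotone score transforms and matches fgsea", {
  set.seed(7)
  sc <- setNames(rnorm(50), paste0("g", 1:50))
  hits <- sample(names(sc), 8)
  base <- gsea_es(sc, hits)
  expect_equal(gsea_es(exp(sc), hits)$es, base$es)
  expect_equal(gsea_es(rank(sc) / 50, hits)$es, base$es)

  ord <- order(sc, decreasing = TRUE)
  fg <- fgsea::calcGseaStat(sc[ord], selectedStats = which(names(sc)[ord] %in% hits),
                            gseaParam = 0)
  expect_equal(base$es, fg, tolerance = 1e-12)
})

test_that("permutation p matches exhaustive enumeration on small universes", {
  sc <- setNames(c(6, 5, 4, 3, 2, 1), paste0("g", 1:6))
  for (hits in list(c("g1", "g2"), c("g1", "g6"), c("g3", "g5"))) {
    res <- permutation_enrichment(sc, hits, n_perm = 2000L, seed = 5L)
    exact <- oracle_exact_p(6L, 2L, res$es)
    expect_lt(abs(res$p - exact), 2 / sqrt(2000))
    expect_gt(res$p, 0) # add-one estimator never returns 0
  }

  # extreme configuration: hits occupy the top ranks
  n <- 60
  sc2 <- setNames(rev(seq_len(n)), paste0("h", seq_len(n)))
  res2 <- permutation_enrichment(sc2, paste0("h", 1:6), n_perm = 1000L,
                                 seed = 2L)
  expect_lte(res2$p, 0.05)
  expect_gt(res2$z, 0)

  # exchangeable scores: z undefined-as-missing is only for degenerate nulls,
  # but tied observed scores give a small |ES| and large p
  sc3 <- setNames(rep(1, 40), paste0("t", 1:40))
  res3 <- permutation_enrichment(sc3, paste0("t", 1:5), n_perm = 500L,
                                 seed = 3L)
  expect_gt(res3$p, 0.5)
})

test_that("the two permutation schemes agree on the exchangeable null", {
  set.seed(12)
  sc <- setNames(rnorm(40), paste0("g", 1:40))
  hits <- sample(names(sc), 6)
  a <- permutation_enrichment(sc, hits, n_perm = 1500L, seed = 9L,
                              scheme = "scores")
  b <- permutation_enrichment(sc, hits, n_perm = 1500L, seed = 9L,
                              scheme = "labels")
  expect_equal(a$es, b$es)
  expect_lt(abs(a$p - b$p), 2 / sqrt(1500))
})

test_that("Fisher enrichment reproduces exact hypergeometric enumeration", {
  expect_equal(fisher_enrichment(2, 0, 0, 2)$p, 1 / 3)
  sym <- fisher_enrichment(5, 5, 5, 5)
  expect_equal(sym$p, 1)
  expect_equal(sym$odds_ratio, 1, tolerance = 1e-6)
  cross <- fisher_enrichment(0, 10, 10, 0)
  expect_equal(cross$odds_ratio, 0)
  expect_equal(cross$p, oracle_fisher_p(0, 10, 10, 0))
  # zero margin convention
  degenerate <- fisher_enrichment(0, 0, 3, 4)
  expect_equal(degenerate$p, 1)
  expect_true(is.na(degenerate$odds_ratio))

  # every non-degenerate table with N <= 12
  for (n_tot in 2:12) {
    parts <- expand.grid(a = 0:n_tot, b = 0:n_tot, c = 0:n_tot)
    parts <- parts[rowSums(parts) <= n_tot, ]
    for (k in sample(nrow(parts), min(nrow(parts), 60))) {
      a <- parts$a[k]; b <- parts$b[k]; c <- parts$c[k]
      d <- n_tot - a - b - c
      if ((a + b) == 0 || (c + d) == 0 || (a + c) == 0 || (b + d) == 0) next
      expect_equal(fisher_enrichment(a, b, c, d)$p,
                   oracle_fisher_p(a, b, c, d), tolerance = 1e-9,
                   label = sprintf("table %d,%d,%d,%d", a, b, c, d))
    }
  }
})

test_that("proportion curves track the reference fraction", {
  sc <- setNames(seq_len(100), paste0("g", 1:100))
  ref <- paste0("g", 51:100) # the top-scored half
  pc <- proportion_curve(sc, ref, thresholds = c(1, 26, 51, 76))
  expect_true(all(diff(pc$proportion) >= 0))
  expect_equal(pc$proportion[pc$threshold == 51], 1.0)
  expect_equal(pc$proportion[pc$threshold == 1], 0.5) # global fraction
  expect_warning(proportion_curve(sc, ref, thresholds = c(1, 1000)), "dropped")
})

test_that("jaccard index satisfies its set-theoretic properties", {
  expect_equal(jaccard(c("a", "b", "c"), c("b", "c", "d")), 0.5)
  expect_equal(jaccard(letters[1:3], letters[1:3]), 1.0)
  expect_equal(jaccard(letters[1:3], letters[5:6]), 0)
  expect_equal(jaccard(character(0), character(0)), 0)
  set.seed(21)
  for (i in 1:50) {
    a <- sample(letters, sample(0:10, 1))
    b <- sample(letters, sample(1:10, 1))
    j <- jaccard(a, b)
    expect_equal(j, jaccard(b, a))
    expect_true(j >= 0 && j <= 1)
  }
})

test_that("similarity profiles follow the zero-similarity exclusion rule", {
  ann <- annotation_table(
    gene = c("CORE", "CORE", "G1", "G1", "G2", "G3"),
    term_id = c("T1", "T2", "T1", "T2", "T1", "T9"),
    term_name = "x", evidence = c("IDA", "IDA", "IDA", "IDA", "IDA", "IEA"))
  prof <- similarity_profile(ann, c("G1", "G2", "G3"), "CORE")
  expect_equal(unname(prof["G1", "CORE"]), 1.0)  # shares all terms
  expect_equal(unname(prof["G2", "CORE"]), 0.5)
  expect_equal(unname(prof["G3", "CORE"]), 0)    # only IEA evidence -> no terms
  rk <- similarity_ranking(prof, "CORE")
  expect_setequal(names(rk), c("G1", "G2"))      # zero-similarity genes excluded
  expect_error(similarity_profile(ann, "G1", "UNANNOTATED"), "UNANNOTATED")
})

test_that("candidates sharing annotation terms with a core gene enrich at high similarity", {
  b <- default_bundle()
  genes <- rownames(b$expression[[1L]])
  core <- b$core_genes[1L]
  prof <- similarity_profile(b$annotations, genes, core)
  rk <- similarity_ranking(prof, core)
  hits <- intersect(names(rk), b$truth$hidden)
  expect_gt(length(hits), 3L)
  res <- permutation_enrichment(rk, hits, n_perm = 1000L, seed = 4L)
  expect_gt(res$z, 0)
})

test_that("group comparison matches exact rank enumeration", {
  same <- group_compare(1:10, 1:10)
  expect_equal(same$d, 0)
  shifted <- group_compare(rnorm(200, 1), rnorm(200, 0))
  expect_lt(shifted$p, 0.01)

  # exact: enumerate all 20 rank assignments of A = {1,2,3} vs B = {4,5,6}
  a <- c(1, 2, 3)
  b <- c(4, 5, 6)
  combos <- combn(6, 3)
  u_obs <- sum(outer(a, b, ">"))
  u_null <- apply(combos, 2L, function(ix) {
    ra <- (1:6)[ix]
    rb <- (1:6)[-ix]
    sum(outer(ra, rb, ">"))
  })
  p_exact <- mean(u_null >= u_obs)
  expect_equal(group_compare(a, b)$p, p_exact)

  expect_true(is.na(group_compare(rep(1, 5), rep(1, 5))$d))
})

test_that("logistic voted-status association behaves under null, power and separation", {
  set.seed(15)
  n <- 2000
  voted <- setNames(rbinom(n, 1, 0.3), paste0("g", 1:n))
  x_null <- setNames(rnorm(n), names(voted))
  null_fit <- voted_status_association(x_null, voted)
  expect_lt(abs(null_fit$z), 3)
  expect_false(null_fit$separation)

  x_pow <- setNames(rnorm(n) + voted, names(voted))
  pow_fit <- voted_status_association(x_pow, voted)
  expect_gt(pow_fit$z, 5)

  x_sep <- setNames(voted + rnorm(n, sd = 1e-4), names(voted))
  sep_fit <- voted_status_association(x_sep, voted)
  expect_true(sep_fit$separation)
  expect_true(is.na(sep_fit$z))
})
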