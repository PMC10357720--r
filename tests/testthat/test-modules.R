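toy_ppi <- function() {
  igraph::graph_from_edgelist(rbind(
    c("A1", "A2"), c("A2", "A3"), c("A1", "A3"),
    c("B1", "B2"), c("B2", "B3"), c("B1", "B3")), directed = FALSE)
}

test_that("term-induced connected components become modules", {
  g <- toy_ppi()
  votes <- setNames(c(10, 9, 8, 7, 6, 5), c("A1", "A2", "A3", "B1", "B2", "B3"))
  terms <- gene_sets(list(T = c("A1", "A2", "A3")), "triangle A")
  mods <- find_modules(g, votes, terms, min_size = 3L, threshold = 1,
                       n_perm = 200L, seed = 1L)
  expect_length(mods, 1L)
  expect_setequal(mods[[1L]]$genes, c("A1", "A2", "A3"))
  expect_equal(mods[[1L]]$term_id, "T")

  expect_warning(none <- find_modules(g, votes, terms, min_size = 4L,
                                      threshold = 1, n_perm = 200L),
                 "no term")
  expect_length(none, 0L)
})

test_that("module scoring flags top-voted modules and degenerate inputs", {
  votes <- setNames(c(60:11), paste0("g", 1:50))
  res <- score_module(votes, paste0("g", 1:6), n_perm = 500L, seed = 2L)
  expect_gt(res$z, 0)
  expect_lte(res$p, 0.05)

  flat <- setNames(rep(1, 50), paste0("g", 1:50))
  res_flat <- score_module(flat, paste0("g", 1:6), n_perm = 200L, seed = 2L)
  expect_gt(res_flat$p, 0.2)
  expect_error(score_module(votes, "absent", n_perm = 200L), "missing")
})

test_that("relative significance shares positive z and sums to one", {
  mk <- function(z) structure(list(z = z, relative_significance = NA_real_),
                              class = "functional_module")
  mods <- relative_significance(list(mk(3), mk(1)))
  expect_equal(vapply(mods, `[[`, numeric(1L), "relative_significance"),
               c(0.75, 0.25))
  single <- relative_significance(list(mk(2)))
  expect_equal(single[[1L]]$relative_significance, 1.0)
  tied <- relative_significance(list(mk(2), mk(2)))
  expect_equal(sum(vapply(tied, `[[`, numeric(1L), "relative_significance")), 1)
  mixed <- relative_significance(list(mk(4), mk(-2)))
  expect_equal(mixed[[1L]]$relative_significance, 1.0)
  expect_true(is.na(mixed[[2L]]$relative_significance))
  expect_error(relative_significance(list(mk(-1))), "positive z")
})

test_that("fold-change ranking is antisymmetric and hits limit cases", {
  vals <- matrix(c(10, 10, 2, 2,
                   40, 40, 2, 2,
                   5, 5, 5, 5), 3, 4, byrow = TRUE,
                 dimnames = list(c("FLAT", "UP", "SAME"), paste0("p", 1:4)))
  e <- expression_matrix(vals, "TOY")
  fc <- differential_rank(e, c("p1", "p2"), c("p3", "p4"))
  expect_equal(unname(fc["SAME"]), 0)
  expect_gt(unname(fc["UP"]), 1.5) # log2(41/3) ~ 3.8
  rev_fc <- differential_rank(e, c("p3", "p4"), c("p1", "p2"))
  expect_equal(unname(fc), -unname(rev_fc))
  # identical groups
  fc0 <- differential_rank(e, c("p1", "p2"), c("p1", "p2"))
  expect_true(all(fc0 == 0))
  # large-mean doubling approaches logFC 1
  vals2 <- matrix(c(2000, 2000, 1000, 1000), 1, 4,
                  dimnames = list("G", paste0("p", 1:4)))
  e2 <- expression_matrix(vals2, "TOY")
  expect_equal(unname(differential_rank(e2, c("p1", "p2"), c("p3", "p4"))),
               1, tolerance = 1e-2)
})

test_that("module activity direction follows the enrichment sign", {
  fc <- setNames(c(5:1, -(1:45)) / 10, paste0("g", 1:50))
  up <- module_activity(fc, paste0("g", 1:5), n_perm = 300L, seed = 1L)
  expect_equal(up$direction, "activated")
  expect_gt(up$z, 0)
  down <- module_activity(fc, paste0("g", 46:50), n_perm = 300L, seed = 1L)
  expect_equal(down$direction, "inactivated")
})

test_that("module classifiers separate a determined label and stay null on permuted labels", {
  set.seed(33)
  n <- 80
  vals <- matrix(2^runif(5 * n, 0, 6), 5, n,
                 dimnames = list(paste0("g", 1:5), paste0("p", 1:n)))
  flags <- setNames(as.integer(vals["g1", ] > median(vals["g1", ])),
                    colnames(vals))
  e <- expression_matrix(vals, "TOY")
  # single determining gene: every hold-out ranks the test set perfectly
  rep1 <- module_classifier(e, "g1", flags, n_holdouts = 20L, seed = 2L)
  expect_equal(rep1$auc_mean, 1.0, tolerance = 1e-9)
  expect_equal(rep1$auc_sd, 0)
  expect_true(all(rep1$aucpr <= 1 & rep1$aucpr >= 0))
  # noise genes alongside keep performance near-perfect
  rep5 <- module_classifier(e, paste0("g", 1:5), flags, n_holdouts = 20L,
                            seed = 2L)
  expect_gt(rep5$auc_mean, 0.9)

  # label permutation: AUC centred at 0.5 across permutation seeds
  aucs <- vapply(1:10, function(s) {
    perm <- setNames(withr::with_seed(s, sample(unname(flags))), names(flags))
    module_classifier(e, paste0("g", 1:5), perm, n_holdouts = 30L,
                      seed = 3L)$auc_mean
  }, numeric(1L))
  expect_gt(mean(aucs), 0.4)
  expect_lt(mean(aucs), 0.6)
})

test_that("hub ranking orders by degree then effect size with the z > 2 highlight", {
  star <- igraph::graph_from_edgelist(rbind(c("HUB", "S1"), c("HUB", "S2"),
                                            c("HUB", "S3")), directed = FALSE)
  module <- list(genes = c("HUB", "S1", "S2", "S3"), subgraph = star)
  z <- c(HUB = 0.5, S1 = 3, S2 = -1, S3 = 2.1)
  rk <- hub_ranking(module, z)
  expect_equal(rk$gene[1L], "HUB")              # degree dominates
  expect_equal(rk$gene[2L], "S1")               # |z| breaks the tie
  expect_setequal(rk$gene[rk$highlighted], c("S1", "S3"))
  # threshold rule: |z| = {2.1, 1.9} highlights exactly one gene
  z2 <- c(HUB = 2.1, S1 = 1.9, S2 = 0, S3 = 0)
  expect_equal(sum(hub_ranking(module, z2)$highlighted), 1L)
  expect_error(hub_ranking(module, z[1:2]), "cover")
})
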