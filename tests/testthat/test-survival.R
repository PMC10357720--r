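test_that("risk scores are linear and median-split deterministically", {
  vals <- matrix(c(3, 1, 7, 0, 2, 5), 2, 3, byrow = TRUE,
                 dimnames = list(c("G1", "G2"), paste0("p", 1:3)))
  e <- expression_matrix(vals, "TOY")
  m0 <- risk_model(c(G1 = 0, G2 = 0))
  expect_true(all(risk_score(e, m0)$score == 0))

  m1 <- risk_model(c(G1 = 2))
  rs <- risk_score(e, m1, log_transform = FALSE)
  expect_equal(rs$score, c(6, 2, 14))
  expect_equal(rs$group, c("low", "low", "high")) # median goes to low

  rs2 <- risk_score(e, risk_model(c(G1 = 4)), log_transform = FALSE)
  expect_equal(rs2$score, 2 * rs$score)           # linear in coefficients
  expect_equal(rs2$group, rs$group)

  expect_error(risk_score(e, risk_model(c(ABSENT = 1))), "missing")
})

test_that("log-rank matches the hand-computed worked example", {
  # group A: events at t = 1, 2; group B: events at t = 3, 4
  cl <- clinical_table(paste0("p", 1:4), "TOY", c(1, 2, 3, 4), rep(1L, 4))
  groups <- setNames(c("A", "A", "B", "B"), paste0("p", 1:4))
  km <- km_logrank(cl, groups, horizon_years = 5)
  # O_A = 2, E_A = 1/2 + 1/3, V = 1/4 + 2/9 -> chi-square ~ 2.882
  expect_equal(km$chisq, (2 - 5 / 6)^2 / (1 / 4 + 2 / 9), tolerance = 1e-6)
  expect_equal(km$chisq, 2.882, tolerance = 1e-3)

  # identical groups: no evidence
  cl2 <- clinical_table(paste0("p", 1:4), "TOY", c(1, 2, 1, 2), rep(1L, 4))
  km2 <- km_logrank(cl2, setNames(c("A", "B", "A", "B")[c(1, 3, 2, 4)],
                                  paste0("p", 1:4)), 5)
  expect_equal(km2$chisq, 0, tolerance = 1e-9)
  expect_equal(km2$p, 1)

  # all censored: flat curves, chi-square 0
  cl3 <- clinical_table(paste0("p", 1:4), "TOY", c(10, 20, 30, 40), rep(0L, 4))
  km3 <- km_logrank(cl3, groups, 5)
  expect_equal(km3$chisq, 0)
  expect_true(all(km3$fit$surv == 1))
})

test_that("log-rank is invariant to group relabeling and KM matches the ECDF", {
  set.seed(44)
  n <- 40
  cl <- clinical_table(paste0("p", 1:n), "TOY", rexp(n, 1 / 500), rep(1L, n))
  grp <- setNames(rep(c("A", "B"), n / 2), paste0("p", 1:n))
  km_ab <- km_logrank(cl, grp, 50)
  swapped <- setNames(ifelse(grp == "A", "B", "A"), names(grp))
  expect_equal(km_logrank(cl, swapped, 50)$chisq, km_ab$chisq)

  # without censoring the product-limit estimate is the empirical survival
  one <- km_logrank(cl, grp, 50)$fit
  sf <- summary(one)
  grp_a_times <- sort(cl$survival_time[grp[cl$patient_id] == "A"])
  surv_a <- sf$surv[sf$strata == "grp=A"]
  emp <- vapply(sf$time[sf$strata == "grp=A"],
                function(t) mean(grp_a_times > t), numeric(1L))
  expect_equal(unname(surv_a), emp, tolerance = 1e-9)
})

test_that("stage trends flag monotone risk and reject degenerate input", {
  set.seed(5)
  n <- 200
  stage <- setNames(sample(c("I", "II", "III", "IV"), n, replace = TRUE),
                    paste0("p", 1:n))
  sc_mono <- setNames(match(stage, c("I", "II", "III", "IV")) +
                        rnorm(n, sd = 0.01), names(stage))
  st <- stage_trend(sc_mono, stage)
  expect_true(st$monotone)
  expect_true(all(st$pairwise$p < 0.01))

  sc_null <- setNames(rnorm(n), names(stage))
  st0 <- stage_trend(sc_null, stage)
  expect_false(isTRUE(st0$monotone) && all(st0$pairwise$p < 0.01))

  one_stage <- setNames(rep("II", 10), paste0("p", 1:10))
  expect_error(stage_trend(setNames(rnorm(10), paste0("p", 1:10)), one_stage),
               "2 populated stages")
})

test_that("weight enrichment matches the exhaustive oracle and detects forced signal", {
  # 6 patients, 2 flagged: compare against enumeration of all 15 memberships
  w <- setNames(c(0.9, 0.7, 0.5, 0.3, 0.2, 0.1), paste0("p", 1:6))
  flags <- setNames(c(1, 1, 0, 0, 0, 0), paste0("p", 1:6))
  res <- weight_enrichment(w, flags, n_perm = 2000L, seed = 6L)
  exact <- oracle_exact_p(6L, 2L, res$es)
  expect_lt(abs(res$p - exact), 2 / sqrt(2000))
  expect_gt(res$es, 0) # flagged patients occupy the top ranks

  # flags independent of weights: no signal
  set.seed(10)
  w2 <- setNames(rnorm(200), paste0("q", 1:200))
  f2 <- setNames(rbinom(200, 1, 0.25), names(w2))
  res2 <- weight_enrichment(w2, f2, n_perm = 1000L, seed = 6L)
  expect_lt(abs(res2$z), 3)
  expect_error(weight_enrichment(w2, setNames(rep(1, 200), names(w2))),
               "unflagged")
})
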