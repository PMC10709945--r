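test_that("OLS fits agree with lm: coefficients, log-likelihood, F-test, slope t-tests", {
  set.seed(41)
  n <- 30
  x1 <- rnorm(n); x2 <- rnorm(n)
  y <- 1 + 2 * x1 - 0.5 * x2 + rnorm(n)
  fit <- fit_linear_model(y, cbind(1, x1, x2))
  ref <- lm(y ~ x1 + x2)
  expect_equal(unname(fit$coefficients), unname(coef(ref)), tolerance = 1e-10)
  expect_equal(fit$loglik, as.numeric(logLik(ref)), tolerance = 1e-10)
  expect_equal(fit$loglik, -(n / 2) * (log(2 * pi * fit$sse / n) + 1))
  sm <- summary(ref)
  expect_equal(fit$overall_p,
               unname(pf(sm$fstatistic[1], sm$fstatistic[2],
                         sm$fstatistic[3], lower.tail = FALSE)),
               tolerance = 1e-10)
  expect_equal(unname(fit$slope_p), unname(sm$coefficients[-1, 4]),
               tolerance = 1e-10)
})

test_that("perfect and degenerate fits are handled", {
  x <- rnorm(10)
  fit <- fit_linear_model(2 * x, cbind(1, x))
  expect_equal(unname(fit$coefficients[2]), 2)
  expect_equal(fit$sse, 0)
  expect_equal(fit$overall_p, 0)

  fit0 <- fit_linear_model(x, matrix(1, 10, 1))
  expect_equal(unname(fit0$coefficients[1]), mean(x))

  dup <- fit_linear_model(x, cbind(1, x * 0))  # constant slope column
  expect_true(dup$degenerate)
  expect_true(is.na(dup$overall_p))
})

test_that("likelihood ratio test matches lmtest-style computation and nesting rules", {
  set.seed(42)
  n <- 50
  s <- rbinom(n, 2, 0.3); m <- runif(n)
  y <- 0.5 * s + rnorm(n)
  f1 <- fit_linear_model(y, cbind(1, s), "M1")
  f2 <- fit_linear_model(y, cbind(1, s, m), "M2")
  f3 <- fit_linear_model(y, cbind(1, s, m, s * m), "M3")

  lrt <- likelihood_ratio_test(f3, f2)
  expect_equal(lrt$df, 1)
  stat_ref <- 2 * (as.numeric(logLik(lm(y ~ s + m + s:m))) -
                     as.numeric(logLik(lm(y ~ s + m))))
  expect_equal(lrt$stat, stat_ref, tolerance = 1e-10)
  expect_equal(lrt$p, pchisq(stat_ref, 1, lower.tail = FALSE))
  expect_equal(likelihood_ratio_test(f3, f1)$df, 2)

  same <- likelihood_ratio_test(f2, f2)
  expect_equal(same$stat, 0)
  expect_equal(same$p, 1)
  expect_error(likelihood_ratio_test(f2, f3), "at least as many")
  expect_error(likelihood_ratio_test(
    f3, fit_linear_model(y[-1], cbind(1, s[-1]))), "different sample")

  # nesting monotonicity over random triples
  for (i in 1:20) {
    y2 <- rnorm(n)
    l1 <- fit_linear_model(y2, cbind(1, s))$loglik
    l2 <- fit_linear_model(y2, cbind(1, s, m))$loglik
    l3 <- fit_linear_model(y2, cbind(1, s, m, s * m))$loglik
    expect_true(l3 >= l2 - 1e-10 && l2 >= l1 - 1e-10)
    expect_gte(likelihood_ratio_test(
      fit_linear_model(y2, cbind(1, s, m, s * m)),
      fit_linear_model(y2, cbind(1, s, m)))$stat, 0)
  }
})

test_that("single_marker_assoc matches lm and is null-calibrated", {
  x <- rnorm(20)
  r <- single_marker_assoc(x, x)
  expect_equal(r$slope, 1)
  expect_equal(r$p, 0)
  expect_true(is.na(single_marker_assoc(rep(1, 20), x)$slope))

  set.seed(43)
  x <- rbinom(50, 2, 0.4); y <- rnorm(50) + 0.3 * x
  got <- single_marker_assoc(x, y)
  sm <- summary(lm(y ~ x))$coefficients
  expect_equal(got$slope, sm[2, 1], tolerance = 1e-10)
  expect_equal(got$p, sm[2, 4], tolerance = 1e-10)

  # p approximately uniform under independence
  ps <- replicate(1000, single_marker_assoc(rbinom(128, 2, 0.3),
                                            rnorm(128))$p)
  expect_gt(ks.test(ps, punif)$p.value, 0.01)
})

test_that("memo_test applies the three-gate grouping rule", {
  set.seed(44)
  n <- 128
  s <- rbinom(n, 2, 0.3)
  m <- runif(n, 0.25, 0.75)
  # strong interaction: all gates pass -> G1
  y <- 0.5 * s + 0.5 * m + 3 * s * (m - 0.5) + rnorm(n, 0, 0.3)
  r <- memo_test(y, s, m)
  expect_equal(r$group, "G1")
  expect_true(r$is_memo)
  expect_true(r$p_m3_overall < 0.05 && r$p_m3_vs_m2 < 0.05 &&
                r$p_m3_vs_m1 < 0.05)

  # overall gate fails -> not evaluated regardless of LRTs
  r0 <- memo_test(rnorm(n, 0, 10), s, m)
  if (r0$p_m3_overall >= 0.05) expect_equal(r0$group, "not_evaluated")

  # strong marginal methylation effect, no interaction -> typically G3
  y3 <- 2 * m + rnorm(n, 0, 0.2)
  r3 <- memo_test(y3, s, m)
  if (!is.na(r3$p_m3_overall) && r3$p_m3_overall < 0.05 &&
      r3$p_m3_vs_m2 >= 0.05 && r3$p_m3_vs_m1 < 0.05)
    expect_equal(r3$group, "G3")

  # degenerate inputs
  rm_ <- memo_test(y, rep(1, n), m)
  expect_equal(rm_$group, "not_evaluated")
  expect_false(rm_$is_memo)
  expect_equal(memo_test(y[1:10], s[1:10], m[1:10], min_n = 30)$group,
               "not_evaluated")
})

test_that("memo_test is invariant to sample permutation and fills eQTL/meQTL p-values", {
  set.seed(45)
  n <- 100
  s <- rbinom(n, 2, 0.3); m <- runif(n, 0.25, 0.75)
  y <- 0.4 * s + 2 * s * (m - 0.5) + rnorm(n, 0, 0.5)
  r1 <- memo_test(y, s, m)
  perm <- sample(n)
  r2 <- memo_test(y[perm], s[perm], m[perm])
  for (f in c("p_m3_overall", "p_m3_vs_m2", "p_m3_vs_m1", "b33",
              "eqtl_p", "meqtl_p"))
    expect_equal(r1[[f]], r2[[f]], tolerance = 1e-9)
  expect_equal(r1$eqtl_p, single_marker_assoc(s, y)$p, tolerance = 1e-12)
  expect_equal(r1$meqtl_p, single_marker_assoc(s, m)$p, tolerance = 1e-12)
})

test_that("map_triple and memo_scan wire matrices to the test", {
  co <- toy_cohort(n = 60, seed = 46)
  # make g1 respond to rs1 moderated by cg1
  s <- co$genotypes$dosages[, "rs1"]
  m <- co$methylation$values[, "cg1"]
  vals <- co$expression$values
  set.seed(47)
  vals[, "g1"] <- exp(0.5 * s + 4 * s * (m - 0.5) + rnorm(60, 0, 0.4))
  expr <- feature_matrix(co$expression$samples, co$expression$features,
                         vals, "expression")
  expr <- filter_and_transform_expression(expr, min_median_fpkm = 0)
  triples <- enumerate_triples(co$genotypes, co$methylation, expr,
                               window_bp = 1e6)
  res <- memo_scan(triples, co$genotypes, co$methylation, expr)
  expect_equal(nrow(res), nrow(triples))
  row <- res[res$snp_id == "rs1" & res$cpg_id == "cg1" &
               res$gene_id == "g1", ]
  expect_equal(row$group, "G1")
  direct <- memo_test(expr$values[, "g1"], s, m)
  expect_equal(row$p_m3_vs_m2, direct$p_m3_vs_m2)
})
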