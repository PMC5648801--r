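test_that("BH adjustment reproduces the step-up arithmetic and its properties", {
  expect_equal(bh_fdr(c(0.001, 0.02, 0.04)), c(0.003, 0.03, 0.04))
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_equal(bh_fdr(0.37), 0.37)
  # order invariance: adjusted values travel with their p-values
  set.seed(55)
  p <- runif(40)
  perm <- sample(40)
  expect_equal(bh_fdr(p)[perm], bh_fdr(p[perm]), tolerance = 1e-15)
  expect_error(bh_fdr(c(0.5, 0)), "\\(0, 1\\]")
  expect_error(bh_fdr(c(0.5, 1.2)), "\\(0, 1\\]")
})

test_that("feature scan recovers the exact Wilcoxon p for 3-vs-3 separation", {
  scores <- c(a = 0.9, b = 0.8, c = 0.7, d = 0.1, e = 0.2, f = 0.3)
  alt <- matrix(rep(c(1, 1, 1, 0, 0, 0), 2), nrow = 2, byrow = TRUE,
                dimnames = list(c("SEP", "NULLG"), names(scores)))
  alt["NULLG", ] <- c(1, 0, 1, 0, 1, 0)
  res <- scan_features(scores, alt, fdr_threshold = 0.2)
  sep <- res[res$feature_id == "SEP", ]
  # complete separation 3v3: 2 * 1/C(6,3) * ... = 0.1 by exact enumeration
  expect_equal(sep$p_value, 0.1, tolerance = 1e-12)
  expect_identical(sep$direction, "positive")
  expect_equal(sep$n_altered, 3L)
  expect_equal(sep$n_wildtype, 3L)
})

test_that("identical group distributions give p = 1 on a symmetric fixture", {
  scores <- c(s1 = 0.1, s2 = 0.9, s3 = 0.4, s4 = 0.6)
  alt <- matrix(c(1, 1, 0, 0), nrow = 1,
                dimnames = list("G", names(scores)))
  res <- scan_features(scores, alt)
  expect_equal(res$p_value, 1)
})

test_that("scan direction always matches the sign of the median difference", {
  set.seed(66)
  scores <- setNames(runif(40), sprintf("s%d", 1:40))
  alt <- matrix(rbinom(40 * 15, 1, 0.4), nrow = 15,
                dimnames = list(sprintf("g%d", 1:15), names(scores)))
  res <- scan_features(scores, alt)
  expect_identical(res$direction,
                   ifelse(res$median_is_altered >= res$median_is_wildtype,
                          "positive", "negative"))
  expect_true(all(res$n_altered + res$n_wildtype == 40L))
  expect_identical(res$significant, res$fdr < 0.01)
})

test_that("monomorphic features are skipped and empty universes refused", {
  scores <- c(s1 = 0.2, s2 = 0.8, s3 = 0.5)
  alt <- matrix(c(1, 1, 1, 1, 0, 1), nrow = 2, byrow = TRUE,
                dimnames = list(c("allmut", "ok"), names(scores)))
  expect_message(res <- scan_features(scores, alt), "skipped")
  expect_identical(res$feature_id, "ok")
  expect_error(scan_features(scores, alt, gene_universe = "absent"),
               "universe")
})

test_that("per-cancer logistic flags separation and matches the pooled fit", {
  set.seed(77)
  n <- 120
  is <- runif(n)
  status <- rbinom(n, 1, plogis(-1 + 2 * is))
  # two 'cancers' that are copies of the same subgroup -> per-cancer = global
  global <- per_cancer_logistic(c(is, is), c(status, status),
                                rep("ALL", 2 * n))
  per <- per_cancer_logistic(c(is, is), c(status, status),
                             rep(c("A", "B"), each = n))
  expect_equal(per$odds_ratio[1], per$odds_ratio[2], tolerance = 1e-8)
  # pooled identical subgroups: same ML slope as each subgroup fit
  each <- per_cancer_logistic(is, status, rep("A", n))
  expect_equal(per$odds_ratio[1], each$odds_ratio, tolerance = 1e-6)
  expect_false(any(global$separation))

  sep <- per_cancer_logistic(is, as.integer(is > median(is)), rep("A", n))
  expect_true(sep$separation)
  expect_true(is.infinite(sep$odds_ratio))

  expect_error(per_cancer_logistic(is, rep(1, n), rep("A", n)),
               "no cancer type had both outcome levels")
})

test_that("logistic CI covers the null when status is independent of IS", {
  set.seed(88)
  covered <- replicate(200, {
    is <- runif(80)
    status <- rbinom(80, 1, 0.5)
    fit <- per_cancer_logistic(is, status, rep("A", 80))
    !fit$separation && fit$ci_low <= 1 && fit$ci_high >= 1
  })
  expect_gt(mean(covered), 0.9)  # nominal 95%, Monte-Carlo slack
})

test_that("IS regressions report slope, R2 and the documented transform", {
  # perfectly collinear fixture
  x <- 1:10
  col <- suppressWarnings(regress_is(0.05 * x + 0.1, x, log_transform = FALSE))
  expect_equal(col$r_squared, 1, tolerance = 1e-12)

  # y = 2x + 1 recovered exactly without the log transform
  fit <- suppressWarnings(regress_is(2 * x + 1, x, log_transform = FALSE))
  expect_equal(fit$slope, 2, tolerance = 1e-12)
  expect_equal(fit$intercept, 1, tolerance = 1e-12)

  # log10(x + 1) transform: slope on the transformed axis
  set.seed(99)
  burden <- rpois(50, 100)
  y <- 0.1 * log10(burden + 1) + rnorm(50, sd = 0.01)
  lf <- regress_is(y, burden)
  expect_equal(lf$slope, 0.1, tolerance = 0.1)
  expect_identical(lf$predictor, "log10(covariate + offset)")

  expect_error(regress_is(runif(5), rep(3, 5), log_transform = FALSE),
               "zero variance")
  # null R2 has expectation 1/(n-1)
  set.seed(101)
  r2 <- replicate(400, regress_is(rnorm(20), rnorm(20),
                                  log_transform = FALSE)$r_squared)
  expect_equal(mean(r2), 1 / 19, tolerance = 0.3)
})

test_that("per-group regressions are emitted alongside the global fit", {
  set.seed(111)
  g <- rep(c("A", "B"), each = 30)
  x <- runif(60, 1, 100)
  y <- ifelse(g == "A", 0.2, -0.2) * log10(x + 1) + rnorm(60, sd = 0.05)
  fit <- regress_is(y, x, grouping = g)
  expect_identical(fit$group, c("global", "A", "B"))
  expect_gt(fit$slope[fit$group == "A"], 0)
  expect_lt(fit$slope[fit$group == "B"], 0)
})

test_that("group comparisons pick Wilcoxon for 2 groups and ANOVA for 3+", {
  # symmetric two-group fixture -> exact p = 1
  two <- group_compare(c(1, 4, 2, 3), c("a", "a", "b", "b"))
  expect_identical(two$method, "wilcoxon")
  expect_equal(two$p_value, 1)

  set.seed(121)
  y <- rnorm(60)
  g3 <- rep(c("a", "b", "c"), each = 20)
  three <- group_compare(y, g3)
  expect_identical(three$method, "anova")
  expect_equal(three$p_value,
               summary(aov(y ~ factor(g3)))[[1]][["Pr(>F)"]][1],
               tolerance = 1e-12)
  expect_identical(three$summary$group, c("a", "b", "c"))
  expect_equal(three$summary$n, rep(20L, 3))

  # 3-SD shift at n = 20/group is essentially always detected
  shifted <- group_compare(c(rnorm(20), rnorm(20, 3)),
                           rep(c("lo", "hi"), each = 20))
  expect_lt(shifted$p_value, 0.001)

  expect_warning(
    group_compare(c(1, 2, 3), factor(c("a", "a", "b"), levels = c("a", "b", "z"))),
    "empty")
  expect_error(group_compare(1:3, rep("a", 3)), "at least 2")
})

test_that("three equal-mean groups reject at about the nominal 5% level", {
  set.seed(131)
  rej <- replicate(400, {
    group_compare(rnorm(36), rep(c("a", "b", "c"), each = 12))$p_value < 0.05
  })
  expect_gt(mean(rej), 0.02)
  expect_lt(mean(rej), 0.08)
})
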