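# Independent oracle: posterior from directly evaluated normal densities.
direct_posterior <- function(cc, m_r, m_n, s, priors = c(0.5, 0.5)) {
  num <- priors[1] * dnorm(cc, m_r, s)
  den <- num + priors[2] * dnorm(cc, m_n, s)
  num / den
}

test_that("a single-gene predictor recovers the class covariate means", {
  values <- matrix(c(0.9, 1.1, -0.9, -1.1), nrow = 1,
                   dimnames = list("g1", sprintf("s%d", 1:4)))
  labels <- c(s1 = "responder", s2 = "responder",
              s3 = "non_responder", s4 = "non_responder")
  model <- fit_bccp(values, labels, selections = "g1", weights = c(g1 = 1))
  expect_equal(unname(model$class_means["responder"]), 1)
  expect_equal(unname(model$class_means["non_responder"]), -1)
  expect_gt(model$pooled_sd, 0)
  # midpoint covariate with equal priors -> posterior exactly 0.5
  mid <- matrix(0, nrow = 1, dimnames = list("g1", "mid"))
  expect_equal(score_bccp(model, mid)$is_score, 0.5, tolerance = 1e-12)
  # covariate at the responder mean, separation >> SD -> score near 1
  at_mean <- matrix(1, nrow = 1, dimnames = list("g1", "atm"))
  expect_gt(score_bccp(model, at_mean)$is_score, 0.99)
})

test_that("label swap negates weights and maps scores to their complement", {
  cohort <- make_two_class(n_genes = 60, n_per_class = 8, n_signal = 12,
                           delta = 2, seed = 12)
  centered <- center_genes(cohort)
  labels <- cohort$annotations$response
  swapped <- ifelse(labels == "responder", "non_responder", "responder")
  sel_a <- select_signature(centered, labels)
  sel_b <- select_signature(centered, swapped)
  model_a <- fit_bccp(centered, labels, selections = sel_a)
  model_b <- fit_bccp(centered, swapped, selections = sel_b)
  common <- intersect(model_a$genes, model_b$genes)
  expect_equal(model_b$weights[common], -model_a$weights[common],
               tolerance = 1e-12)
  sa <- score_bccp(model_a, centered)$is_score
  sb <- score_bccp(model_b, centered)$is_score
  expect_equal(sb, 1 - sa, tolerance = 1e-9)
})

test_that("scores are valid posteriors and match the density oracle", {
  for (rep in 1:25) {
    set.seed(100 + rep)
    cohort <- make_two_class(n_genes = 40, n_per_class = 6, n_signal = 8,
                             delta = 1.5, seed = 100 + rep)
    centered <- center_genes(cohort)
    sel <- select_signature(centered, p_threshold = 0.2, fold_threshold = 1.1)
    if (!any(sel$selected)) next
    model <- fit_bccp(centered, selections = sel)
    scored <- score_bccp(model, centered)
    expect_true(all(scored$is_score >= 0 & scored$is_score <= 1))
    cc <- compound_covariate(model, centered)
    oracle <- direct_posterior(cc, model$class_means[["responder"]],
                               model$class_means[["non_responder"]],
                               model$pooled_sd)
    expect_equal(scored$is_score, unname(oracle), tolerance = 1e-12)
    expect_identical(scored$call,
                     ifelse(scored$is_score > 0.5, "responder", "non_responder"))
  }
})

test_that("platform transfer drops missing genes and refits densities", {
  cohort <- make_two_class(n_genes = 50, n_per_class = 10, n_signal = 15,
                           delta = 2.5, seed = 13)
  centered <- center_genes(cohort)
  sel <- select_signature(centered)
  model <- fit_bccp(centered, selections = sel)
  expect_gt(length(model$genes), 4)

  keep <- model$genes[-(1:2)]
  sub <- centered$values[keep, , drop = FALSE]
  expect_message(scored <- score_bccp(model, sub), "excluded")
  expect_equal(unique(scored$n_genes_used), length(keep))
  # refitted densities on the surviving genes equal a model trained on them
  refit <- fit_bccp(centered, selections = keep, weights = model$weights)
  expect_equal(scored$is_score, score_bccp(refit, sub)$is_score,
               tolerance = 1e-12)

  # < 50% matched is refused without force
  tiny <- centered$values[model$genes[1], , drop = FALSE]
  expect_error(score_bccp(model, tiny), "50%")
  expect_silent(suppressMessages(score_bccp(model, tiny, force = TRUE)))

  # id mapping restores otherwise-unmatchable platform ids
  renamed <- centered$values
  rownames(renamed) <- paste0("probe_", rownames(renamed))
  mapping <- data.frame(from = paste0("probe_", rownames(centered$values)),
                        to = rownames(centered$values))
  expect_equal(score_bccp(model, renamed, mapping = mapping)$is_score,
               score_bccp(model, centered)$is_score, tolerance = 1e-12)
})

test_that("AUC follows the rank formulation, ties included", {
  # perfectly separated scores
  roc <- roc_analysis(c(0.9, 0.8, 0.2, 0.1), c("responder", "responder",
                                               "non_responder", "non_responder"))
  expect_equal(roc$auc, 1)
  expect_equal(roc$sensitivity, 1)
  expect_equal(roc$specificity, 1)

  # all-tied scores degrade to 0.5
  expect_equal(roc_analysis(rep(0.5, 10),
                            rep(c("responder", "non_responder"), 5))$auc, 0.5)

  # O(n^2) pair-counting oracle on random fixtures with ties
  for (rep in 1:20) {
    set.seed(200 + rep)
    n1 <- sample(3:10, 1); n0 <- sample(3:10, 1)
    scores <- round(c(rnorm(n1, 1), rnorm(n0)), 1)  # rounding forces ties
    labels <- rep(c("responder", "non_responder"), c(n1, n0))
    pos <- scores[labels == "responder"]
    neg <- scores[labels == "non_responder"]
    pairs <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
    expect_equal(roc_analysis(scores, labels)$auc, mean(pairs),
                 tolerance = 1e-12)
  }

  expect_error(roc_analysis(1:4, rep("responder", 4)), "two classes")
})

test_that("AUC agrees with pROC and is invariant to the posterior transform", {
  skip_if_not_installed("pROC")
  cohort <- make_two_class(n_genes = 80, n_per_class = 15, n_signal = 10,
                           delta = 1.2, seed = 14)
  centered <- center_genes(cohort)
  sel <- select_signature(centered, p_threshold = 0.05)
  model <- fit_bccp(centered, selections = sel)
  scored <- score_bccp(model, centered)
  labels <- cohort$annotations$response
  mine <- roc_analysis(scored$is_score, labels)$auc
  ref <- as.numeric(pROC::auc(pROC::roc(response = labels,
                                        predictor = scored$is_score,
                                        levels = c("non_responder", "responder"),
                                        direction = "<", quiet = TRUE)))
  expect_equal(mine, ref, tolerance = 1e-12)
  # posterior is monotone in the covariate when m_R > m_N
  cc <- compound_covariate(model, centered)
  expect_equal(roc_analysis(unname(cc), labels)$auc, mine, tolerance = 1e-12)
})

test_that("fitted class means converge to the planted covariate means", {
  # single gene, weight 1: covariate is the gene itself, planted means +/- 2
  err <- vapply(c(20, 100, 500), function(n) {
    set.seed(n)
    values <- matrix(c(rnorm(n, 2), rnorm(n, -2)), nrow = 1,
                     dimnames = list("g1", sprintf("s%d", 1:(2 * n))))
    labels <- rep(c("responder", "non_responder"), each = n)
    model <- fit_bccp(values, labels, selections = "g1", weights = c(g1 = 1))
    max(abs(model$class_means - c(responder = 2, non_responder = -2)))
  }, numeric(1))
  expect_lt(err[3], err[1])
  expect_lt(err[3], 0.15)
})

test_that("degenerate training is refused", {
  values <- matrix(rep(c(1, -1), each = 2), nrow = 1,
                   dimnames = list("g1", sprintf("s%d", 1:4)))
  labels <- rep(c("responder", "non_responder"), each = 2)
  expect_error(fit_bccp(values, labels, selections = "g1", weights = c(g1 = 1)),
               "zero pooled SD|constant within classes")
})
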