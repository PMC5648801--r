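#' Fit a Bayesian compound covariate predictor (BCCP)
#'
#' The selected genes are combined into a scalar compound covariate per
#' sample, `c_j = sum_g w_g x_gj`, with weights `w_g` the training
#' t-statistics of the gene selection. Equal-variance Gaussian
#' class-conditional densities of the covariate are then fitted: the two
#' class means and a pooled (across classes) SD, plus class priors. The
#' posterior responder probability of a new sample under this model is the
#' IS score.
#'
#' @param expr centered training expression ([ExpressionMatrix] or matrix);
#'   use [center_genes()] first.
#' @param labels per-sample class labels (or `NULL` to use the `response`
#'   annotation).
#' @param selections gene selection table from [select_signature()]; only
#'   rows with `selected == TRUE` enter the model. Alternatively a
#'   character vector of gene ids together with `weights`.
#' @param weights optional named numeric weights, required when
#'   `selections` is a plain gene id vector.
#' @param priors class prior probabilities `(responder, non_responder)`,
#'   summing to 1. Equal priors (the default) make the 0.5 cutoff the
#'   likelihood-ratio boundary.
#' @param cutoff posterior cutoff for responder calls, default 0.5.
#' @param pool_variance if `TRUE` (default) a single pooled SD is used for
#'   both class densities; `FALSE` fits per-class SDs.
#' @param positive label treated as the responder class.
#' @return a `SignatureModel`: genes, weights, class means, pooled SD,
#'   priors, cutoff, plus the training covariate data needed to refit
#'   densities when genes are lost on platform transfer.
#' @export
fit_bccp <- function(expr, labels = NULL, selections, weights = NULL,
                     priors = c(0.5, 0.5), cutoff = 0.5,
                     pool_variance = TRUE, positive = "responder") {
  values <- expr_values(expr)
  labels <- resolve_labels(expr, labels)
  if (is.data.frame(selections)) {
    sel <- selections[selections$selected, , drop = FALSE]
    genes <- sel$gene_id
    weights <- stats::setNames(sel$t_statistic, genes)
  } else {
    genes <- as.character(selections)
    if (is.null(weights)) stop("`weights` required when `selections` is a gene id vector")
    weights <- stats::setNames(as.numeric(weights[genes]), genes)
  }
  if (!length(genes)) stop("no selected genes: cannot fit a predictor")
  if (anyNA(weights) || any(!is.finite(weights))) {
    stop("all gene weights must be finite (infinite t-statistics cannot be used as weights)")
  }
  missing <- setdiff(genes, rownames(values))
  if (length(missing)) {
    stop(sprintf("selected gene(s) absent from training matrix: %s",
                 paste(utils::head(missing, 5L), collapse = ", ")))
  }
  stopifnot(length(priors) == 2L, all(priors > 0),
            abs(sum(priors) - 1) < 1e-8, cutoff > 0, cutoff < 1)

  training_values <- values[genes, , drop = FALSE]
  dens <- covariate_densities(training_values, labels, weights,
                              pool_variance, positive)
  model <- list(
    genes = genes,
    weights = weights,
    class_means = dens$class_means,
    pooled_sd = dens$pooled_sd,
    class_sds = dens$class_sds,
    priors = priors,
    cutoff = cutoff,
    pool_variance = pool_variance,
    training_values = training_values,
    training_labels = labels,
    provenance = list(
      n_training_samples = ncol(values),
      n_responders = sum(labels == positive),
      positive = positive,
      fitted = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
    )
  )
  structure(model, class = "SignatureModel")
}

# Gaussian class-conditional densities of the compound covariate.
covariate_densities <- function(values, labels, weights, pool_variance,
                                positive) {
  cc <- drop(crossprod(weights[rownames(values)], values))
  is_pos <- labels == positive
  if (sum(is_pos) < 2L || sum(!is_pos) < 2L) {
    stop("each class needs at least 2 samples to estimate covariate densities")
  }
  m <- c(responder = mean(cc[is_pos]), non_responder = mean(cc[!is_pos]))
  v1 <- stats::var(cc[is_pos])
  v0 <- stats::var(cc[!is_pos])
  n1 <- sum(is_pos)
  n0 <- sum(!is_pos)
  pooled_sd <- sqrt(((n1 - 1) * v1 + (n0 - 1) * v0) / (n1 + n0 - 2))
  if (pooled_sd == 0) {
    stop("compound covariate is constant within classes: zero pooled SD")
  }
  class_sds <- if (pool_variance) {
    c(responder = pooled_sd, non_responder = pooled_sd)
  } else {
    if (v1 == 0 || v0 == 0) stop("zero within-class covariate variance")
    c(responder = sqrt(v1), non_responder = sqrt(v0))
  }
  list(class_means = m, pooled_sd = pooled_sd, class_sds = class_sds,
       covariate = cc)
}

#' Compute compound covariates for a model
#'
#' @param model a `SignatureModel`.
#' @param expr centered expression matrix containing (a subset of) the
#'   model genes.
#' @return named numeric vector of per-sample compound covariates, using
#'   the model genes present in `expr`.
#' @export
compound_covariate <- function(model, expr) {
  values <- expr_values(expr)
  genes <- intersect(model$genes, rownames(values))
  if (!length(genes)) stop("no model genes present in the matrix")
  drop(crossprod(model$weights[genes], values[genes, , drop = FALSE]))
}

#' Score samples with a fitted BCCP: the IS score
#'
#' Computes each sample's compound covariate under the model weights and
#' returns the Gaussian posterior probability of the responder class
#' (`is_score` in `[0, 1]`), together with the dichotomized call at the
#' model cutoff. The input cohort must be centered on itself
#' ([center_genes()]), mirroring the re-normalization applied independently
#' to training and test sets.
#'
#' Genes absent from the new platform are dropped and the class densities
#' are refitted on the training data restricted to the surviving genes
#' (weights are not re-normalized), keeping training and scoring covariates
#' on the same scale. Fewer than half the model genes matching is an error
#' unless `force = TRUE`.
#'
#' @param model a `SignatureModel` from [fit_bccp()].
#' @param expr centered expression of the cohort to score.
#' @param mapping optional two-column `data.frame` (`from`, `to`) renaming
#'   platform ids in `expr` to model gene ids before matching.
#' @param force allow scoring with fewer than 50% of model genes matched.
#' @return `data.frame` with `sample_id`, `is_score`, `call`
#'   (`responder`/`non_responder` by `is_score > cutoff`), and
#'   `n_genes_used`.
#' @export
score_bccp <- function(model, expr, mapping = NULL, force = FALSE) {
  values <- expr_values(expr)
  if (!is.null(mapping)) {
    stopifnot(is.data.frame(mapping), all(c("from", "to") %in% names(mapping)))
    idx <- match(rownames(values), mapping$from)
    hit <- !is.na(idx)
    rn <- rownames(values)
    rn[hit] <- mapping$to[idx[hit]]
    check_unique_ids(rn, "mapped gene")
    rownames(values) <- rn
  }
  genes <- intersect(model$genes, rownames(values))
  n_used <- length(genes)
  if (!n_used) stop("no model genes present in the cohort")
  if (n_used < 0.5 * length(model$genes) && !force) {
    stop(sprintf("only %d of %d model genes matched (< 50%%); pass force = TRUE to score anyway",
                 n_used, length(model$genes)))
  }
  if (n_used < length(model$genes)) {
    message(sprintf("score_bccp: %d of %d model genes excluded on this platform; class densities refitted",
                    length(model$genes) - n_used, length(model$genes)))
    dens <- covariate_densities(
      model$training_values[genes, , drop = FALSE],
      model$training_labels, model$weights,
      isTRUE(model$pool_variance),
      model$provenance$positive %||% "responder"
    )
    class_means <- dens$class_means
    class_sds <- dens$class_sds
  } else {
    class_means <- model$class_means
    class_sds <- model$class_sds %||%
      c(responder = model$pooled_sd, non_responder = model$pooled_sd)
  }
  cc <- drop(crossprod(model$weights[genes], values[genes, , drop = FALSE]))
  is_score <- posterior_responder(cc, class_means, class_sds, model$priors)
  data.frame(
    sample_id = colnames(values),
    is_score = unname(is_score),
    call = ifelse(is_score > model$cutoff, "responder", "non_responder"),
    n_genes_used = n_used,
    stringsAsFactors = FALSE
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Posterior P(responder | c) under Gaussian class-conditional densities,
# computed in log space so extreme covariates do not underflow to 0/0.
posterior_responder <- function(cc, class_means, class_sds, priors) {
  lr <- log(priors[1L]) +
    stats::dnorm(cc, class_means[["responder"]], class_sds[["responder"]],
                 log = TRUE)
  ln <- log(priors[2L]) +
    stats::dnorm(cc, class_means[["non_responder"]],
                 class_sds[["non_responder"]], log = TRUE)
  m <- pmax(lr, ln)
  exp(lr - m) / (exp(lr - m) + exp(ln - m))
}

#' ROC analysis of scores against binary truth
#'
#' AUC by the rank (Mann-Whitney) formulation with midrank tie correction,
#' plus the cutoff maximizing the sum of sensitivity and specificity
#' (Youden), with ties broken toward the higher cutoff. Calls are
#' `score > cutoff`, matching the IS-score convention.
#'
#' @param scores numeric scores.
#' @param labels binary truth, aligned with `scores`.
#' @param positive label of the positive (responder) class; defaults to
#'   `"responder"` when present, otherwise the larger of two levels.
#' @return list with `auc`, `youden_cutoff`, `sensitivity`, `specificity`
#'   (the last two evaluated at the Youden cutoff), and `n_positive`,
#'   `n_negative`.
#' @export
roc_analysis <- function(scores, labels, positive = NULL) {
  stopifnot(length(scores) == length(labels))
  ok <- !is.na(scores) & !is.na(labels)
  scores <- scores[ok]
  labels <- as.character(labels[ok])
  lev <- unique(labels)
  if (length(lev) != 2L) stop("truth labels must contain exactly two classes")
  if (is.null(positive)) {
    positive <- if ("responder" %in% lev) "responder" else max(lev)
  }
  is_pos <- labels == positive
  n1 <- sum(is_pos)
  n0 <- sum(!is_pos)
  r <- rank(scores)  # midranks handle ties
  auc <- (sum(r[is_pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  cuts <- sort(unique(c(-Inf, scores)))
  j <- vapply(cuts, function(ct) {
    mean(scores[is_pos] > ct) + mean(scores[!is_pos] <= ct)
  }, numeric(1))
  best <- max(which(j == max(j)))  # ties -> higher cutoff
  youden <- cuts[best]
  list(
    auc = auc,
    youden_cutoff = youden,
    sensitivity = mean(scores[is_pos] > youden),
    specificity = mean(scores[!is_pos] <= youden),
    n_positive = n1,
    n_negative = n0
  )
}

#' Random stratified train/test split
#'
#' Minimal split utility for held-out evaluation of the predictor.
#'
#' @param labels per-sample class labels (named or aligned by position).
#' @param train_fraction fraction of each class assigned to training.
#' @return list of index vectors `train` and `test`.
#' @export
split_cohort <- function(labels, train_fraction = 0.5) {
  stopifnot(train_fraction > 0, train_fraction < 1)
  idx <- seq_along(labels)
  train <- unlist(lapply(split(idx, labels), function(i) {
    sample(i, max(1L, floor(train_fraction * length(i))))
  }), use.names = FALSE)
  list(train = sort(train), test = sort(setdiff(idx, train)))
}
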