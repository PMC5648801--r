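#' Select signature genes by two-sample t-test and fold change
#'
#' Per-gene pooled-variance (Student) two-sample t-test of responders
#' versus non-responders on log2 expression, combined with a fold-change
#' filter: a gene is selected when `p_value < p_threshold` and the absolute
#' class-mean difference is at least `log2(fold_threshold)`. The defaults
#' (P < 0.005, 1.5-fold) are the stringent cutoff used to define the immune
#' signature.
#'
#' Genes that are constant within and between both classes have an
#' undefined t statistic; they are reported with `p_value = 1` and left
#' unselected, with a warning. A gene with zero pooled variance but
#' distinct class means separates the classes perfectly and is reported
#' with an infinite t and `p_value = 0`.
#'
#' @param expr an [ExpressionMatrix] or numeric genes x samples matrix on
#'   the log2 scale.
#' @param labels per-sample class labels; either a vector aligned with the
#'   samples or `NULL` to use the `response` annotation of `expr`.
#' @param p_threshold p-value cutoff (default 0.005).
#' @param fold_threshold fold-change cutoff on the linear scale (default
#'   1.5, i.e. `log2(1.5)` on the log2 scale).
#' @param positive label treated as the responder class (fold changes are
#'   responder minus non-responder).
#' @return `data.frame` with one row per gene — `gene_id`, `t_statistic`,
#'   `log2_fold_change`, `p_value`, `selected` — ordered by ascending
#'   p-value.
#' @export
select_signature <- function(expr, labels = NULL, p_threshold = 0.005,
                             fold_threshold = 1.5, positive = "responder") {
  values <- expr_values(expr)
  labels <- resolve_labels(expr, labels)
  is_pos <- labels == positive
  n1 <- sum(is_pos)
  n0 <- sum(!is_pos)
  if (n1 < 2L || n0 < 2L) {
    stop("each class needs at least 2 samples for a pooled-variance t-test")
  }
  m1 <- rowMeans(values[, is_pos, drop = FALSE])
  m0 <- rowMeans(values[, !is_pos, drop = FALSE])
  v1 <- apply(values[, is_pos, drop = FALSE], 1L, stats::var)
  v0 <- apply(values[, !is_pos, drop = FALSE], 1L, stats::var)
  sp2 <- ((n1 - 1) * v1 + (n0 - 1) * v0) / (n1 + n0 - 2)
  diff <- m1 - m0
  se <- sqrt(sp2 * (1 / n1 + 1 / n0))
  t_stat <- diff / se
  df <- n1 + n0 - 2
  p <- 2 * stats::pt(-abs(t_stat), df = df)
  # zero pooled variance: perfect separation (diff != 0) or fully constant
  degenerate <- se == 0
  p[degenerate & diff != 0] <- 0
  t_stat[degenerate] <- sign(diff[degenerate]) * Inf
  constant <- degenerate & diff == 0
  if (any(constant)) {
    warning(sprintf("%d constant gene(s): t undefined, reported unselected with p = 1",
                    sum(constant)))
    p[constant] <- 1
    t_stat[constant] <- NA_real_
  }
  selected <- (p < p_threshold) & (abs(diff) >= log2(fold_threshold)) & !constant
  out <- data.frame(
    gene_id = rownames(values),
    t_statistic = t_stat,
    log2_fold_change = diff,
    p_value = p,
    selected = selected,
    stringsAsFactors = FALSE
  )
  out <- out[order(out$p_value), , drop = FALSE]
  rownames(out) <- NULL
  out
}

resolve_labels <- function(expr, labels) {
  if (is.null(labels)) {
    ann <- expr_annotations(expr)
    if (is.null(ann) || !"response" %in% names(ann)) {
      stop("`labels` not given and `expr` carries no response annotation")
    }
    labels <- ann$response
  }
  values <- expr_values(expr)
  if (!is.null(names(labels))) labels <- labels[colnames(values)]
  labels <- as.character(labels)
  if (length(labels) != ncol(values) || anyNA(labels)) {
    stop("`labels` must provide one non-missing label per sample")
  }
  if (length(unique(labels)) != 2L) stop("`labels` must have exactly two classes")
  labels
}

#' Center genes across samples
#'
#' Re-normalizes an expression matrix by centering each gene's expression
#' level across the tissues of the cohort, the step applied independently
#' to training and test sets before signature transfer. The median is the
#' default centering statistic (robust for cross-platform transfer); the
#' mean is available as an option.
#'
#' @param expr an [ExpressionMatrix] or numeric genes x samples matrix.
#' @param statistic `"median"` (default) or `"mean"`.
#' @return the same container type with each gene centered; idempotent.
#' @export
center_genes <- function(expr, statistic = c("median", "mean")) {
  statistic <- match.arg(statistic)
  values <- expr_values(expr)
  if (ncol(values) < 2L) {
    stop("centering needs at least 2 samples (one sample degenerates to all zeros)")
  }
  center <- switch(statistic,
    median = apply(values, 1L, stats::median),
    mean = rowMeans(values)
  )
  expr_like(expr, values - center)
}

#' Mean signature score over a gene list
#'
#' Per-sample mean of centered expression over the genes of `gene_list`
#' present in the matrix — the construction used for comparator signatures
#' such as the interferon-gamma or cytolytic-activity scores. The matrix is
#' median-centered internally (a no-op if already centered).
#'
#' @param expr an [ExpressionMatrix] or numeric genes x samples matrix
#'   (log2 scale).
#' @param gene_list character vector of gene ids.
#' @return named numeric vector of per-sample scores, with attribute
#'   `n_genes_used` giving the intersection size.
#' @export
mean_signature_score <- function(expr, gene_list) {
  values <- expr_values(center_genes(expr))
  used <- intersect(gene_list, rownames(values))
  if (!length(used)) stop("none of the listed genes are present in the matrix")
  message(sprintf("mean_signature_score: using %d of %d listed genes",
                  length(used), length(unique(gene_list))))
  scores <- colMeans(values[used, , drop = FALSE])
  attr(scores, "n_genes_used") <- length(used)
  scores
}
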