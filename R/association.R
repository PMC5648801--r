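#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up BH adjusted p-values (monotone in rank, capped at 1), returned
#' in the input order. Thin validated wrapper over
#' `stats::p.adjust(method = "BH")`.
#'
#' @param p numeric p-values in (0, 1].
#' @return adjusted values, same length and order as `p`.
#' @export
bh_fdr <- function(p) {
  if (!length(p)) return(numeric(0))
  if (anyNA(p) || any(p <= 0 | p > 1)) stop("p-values must lie in (0, 1]")
  stats::p.adjust(p, method = "BH")
}

# Wilcoxon rank-sum p-value: exact enumeration when the smaller arm has
# <= `exact_max` observations and there are no ties; otherwise the normal
# approximation with continuity and tie correction.
wilcoxon_p <- function(x, y, exact_max = 8L) {
  use_exact <- min(length(x), length(y)) <= exact_max &&
    !any(duplicated(c(x, y)))
  suppressWarnings(
    stats::wilcox.test(x, y, exact = use_exact, correct = TRUE)$p.value
  )
}

#' Scan alteration features for association with IS scores
#'
#' For every gene of the universe present in the binary alteration matrix,
#' tests whether IS scores differ between altered and wild-type samples
#' (two-sided Wilcoxon rank-sum; exact enumeration when the smaller arm
#' has at most 8 samples and no ties, normal approximation with tie and
#' continuity correction otherwise), then applies Benjamini-Hochberg FDR
#' control across the tested universe. Direction is the sign of the median
#' IS difference (altered minus wild-type). Features with an empty altered
#' or wild-type arm are skipped with a message.
#'
#' @param is_scores numeric IS scores named by sample id (or an IS score
#'   table from [score_bccp()]).
#' @param alteration_matrix binary (0/1) genes x samples matrix: mutation
#'   presence, amplification or deletion calls.
#' @param gene_universe character vector of genes to test (e.g. the 373
#'   mutation drivers or the 87 amplified / 123 deleted genes); defaults
#'   to all rows of the matrix.
#' @param fdr_threshold significance threshold on the adjusted values
#'   (default 0.01, the 1% FDR line of the genome-wide scans).
#' @return `data.frame` with one row per tested feature: `feature_id`,
#'   `n_altered`, `n_wildtype`, `median_is_altered`, `median_is_wildtype`,
#'   `direction`, `p_value`, `fdr`, `significant`; ordered by ascending
#'   p-value.
#' @export
scan_features <- function(is_scores, alteration_matrix, gene_universe = NULL,
                          fdr_threshold = 0.01) {
  scores <- as_is_scores(is_scores)
  stopifnot(is.matrix(alteration_matrix))
  samples <- intersect(names(scores), colnames(alteration_matrix))
  if (length(samples) < 2L) stop("need at least 2 samples shared between scores and matrix")
  if (is.null(gene_universe)) gene_universe <- rownames(alteration_matrix)
  genes <- intersect(gene_universe, rownames(alteration_matrix))
  if (!length(genes)) stop("gene universe does not intersect the alteration matrix")
  s <- scores[samples]
  rows <- lapply(genes, function(g) {
    altered <- alteration_matrix[g, samples] != 0
    n1 <- sum(altered)
    n0 <- sum(!altered)
    if (n1 == 0L || n0 == 0L) return(NULL)
    med1 <- stats::median(s[altered])
    med0 <- stats::median(s[!altered])
    data.frame(
      feature_id = g,
      n_altered = n1,
      n_wildtype = n0,
      median_is_altered = med1,
      median_is_wildtype = med0,
      direction = if (med1 >= med0) "positive" else "negative",
      p_value = wilcoxon_p(s[altered], s[!altered]),
      stringsAsFactors = FALSE
    )
  })
  skipped <- sum(vapply(rows, is.null, logical(1)))
  if (skipped) {
    message(sprintf("scan_features: %d feature(s) skipped (no altered or no wild-type samples)",
                    skipped))
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no testable features (every feature monomorphic)")
  out$fdr <- bh_fdr(pmin(out$p_value, 1))
  out$significant <- out$fdr < fdr_threshold
  out <- out[order(out$p_value), , drop = FALSE]
  rownames(out) <- NULL
  out
}

as_is_scores <- function(is_scores) {
  if (is.data.frame(is_scores)) {
    stopifnot(all(c("sample_id", "is_score") %in% names(is_scores)))
    return(stats::setNames(is_scores$is_score, is_scores$sample_id))
  }
  if (is.null(names(is_scores))) stop("IS scores must be named by sample id")
  is_scores
}

#' Per-cancer logistic odds ratios of dichotomized genomic status on IS
#'
#' Within each cancer type, fits a maximum-likelihood logistic regression
#' of a dichotomized genomic status (e.g. above/below the within-cancer
#' median mutation count or CIN score) on the IS score, and reports the
#' odds ratio per unit IS with a Wald 95% CI and p-value. Cancers missing
#' one of the outcome levels are skipped with a message; complete
#' separation is flagged and the OR reported as `Inf`/0 with `NA` CI.
#'
#' @param is_scores numeric IS scores (named) or a score table.
#' @param status binary outcome (0/1), aligned with the scores.
#' @param cancer_type cancer label per sample; a single label gives the
#'   global fit.
#' @return `data.frame` with `cancer_type`, `n`, `odds_ratio`, `ci_low`,
#'   `ci_high`, `p_value`, `separation`.
#' @export
per_cancer_logistic <- function(is_scores, status, cancer_type) {
  scores <- as_is_scores_aligned(is_scores, status)
  stopifnot(length(status) == length(scores),
            length(cancer_type) == length(scores))
  if (any(!is.na(status) & !(status %in% c(0, 1)))) stop("status must be 0/1")
  rows <- lapply(split(seq_along(scores), cancer_type), function(idx) {
    y <- status[idx]
    x <- scores[idx]
    ok <- !is.na(y) & !is.na(x)
    y <- y[ok]; x <- x[ok]
    lev <- unique(y)
    if (length(lev) < 2L) {
      message(sprintf("per_cancer_logistic: '%s' skipped (single outcome level)",
                      cancer_type[idx[1L]]))
      return(NULL)
    }
    fit <- suppressWarnings(stats::glm(y ~ x, family = stats::binomial()))
    co <- summary(fit)$coefficients
    slope <- co["x", "Estimate"]
    se <- co["x", "Std. Error"]
    # near-perfect separation: diverging slope / huge SE
    separated <- !fit$converged || abs(slope) > 15 || se > 100
    data.frame(
      cancer_type = cancer_type[idx[1L]],
      n = length(y),
      odds_ratio = if (separated) ifelse(slope > 0, Inf, 0) else exp(slope),
      ci_low = if (separated) NA_real_ else exp(slope - 1.96 * se),
      ci_high = if (separated) NA_real_ else exp(slope + 1.96 * se),
      p_value = co["x", "Pr(>|z|)"],
      separation = separated,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no cancer type had both outcome levels")
  rownames(out) <- NULL
  out
}

as_is_scores_aligned <- function(is_scores, ref) {
  if (is.data.frame(is_scores)) is_scores <- as_is_scores(is_scores)
  as.numeric(is_scores)
}

#' Regress IS scores on mutation burden or CIN
#'
#' Ordinary least squares of IS score on a genomic covariate, globally and
#' optionally per group (cancer type). Burden and CIN covariates are
#' log10(x + 1)-transformed by default, matching the log-scaled axes these
#' relationships are displayed on; the +1 offset handles zero counts.
#'
#' @param is_scores numeric IS scores (named) or a score table.
#' @param covariate numeric covariate (e.g. non-synonymous count or CIN
#'   score), aligned with the scores.
#' @param grouping optional group label per sample; adds per-group fits.
#' @param log_transform apply `log10(covariate + offset)` first.
#' @param offset offset added inside the log (default 1).
#' @return `data.frame` with `group` (`"global"` first), `predictor`,
#'   `slope`, `intercept`, `r_squared`, `p_value`, `n`.
#' @export
regress_is <- function(is_scores, covariate, grouping = NULL,
                       log_transform = TRUE, offset = 1) {
  y <- as_is_scores_aligned(is_scores, covariate)
  stopifnot(length(covariate) == length(y))
  x <- if (log_transform) log10(covariate + offset) else covariate
  predictor <- if (log_transform) "log10(covariate + offset)" else "covariate"
  fit_one <- function(xi, yi, label) {
    ok <- is.finite(xi) & is.finite(yi)
    xi <- xi[ok]; yi <- yi[ok]
    if (length(xi) < 3L) stop("regression needs n >= 3")
    if (stats::var(xi) == 0) stop("covariate has zero variance")
    fit <- stats::lm(yi ~ xi)
    sm <- summary(fit)
    data.frame(
      group = label,
      predictor = predictor,
      slope = unname(stats::coef(fit)[2L]),
      intercept = unname(stats::coef(fit)[1L]),
      r_squared = sm$r.squared,
      p_value = sm$coefficients[2L, 4L],
      n = length(xi),
      stringsAsFactors = FALSE
    )
  }
  out <- fit_one(x, y, "global")
  if (!is.null(grouping)) {
    per <- lapply(split(seq_along(y), grouping),
                  function(idx) fit_one(x[idx], y[idx], as.character(grouping[idx[1L]])))
    out <- rbind(out, do.call(rbind, per))
  }
  rownames(out) <- NULL
  out
}

#' Compare IS scores across groups
#'
#' Two groups: two-sided Wilcoxon rank-sum (exact for small untied
#' samples). Three or more groups: one-way ANOVA on the IS scores. Serves
#' the molecular-subtype, MSI-status and viral-status contrasts. Empty
#' groups are dropped with a warning.
#'
#' @param is_scores numeric IS scores (named) or a score table.
#' @param groups group label per sample.
#' @return list with `p_value`, `method` (`"wilcoxon"` or `"anova"`), and
#'   `summary` (per-group `n`, `median`, `q1`, `q3`).
#' @export
group_compare <- function(is_scores, groups) {
  y <- as_is_scores_aligned(is_scores, groups)
  stopifnot(length(groups) == length(y))
  declared <- if (is.factor(groups)) levels(groups)
              else unique(as.character(groups))
  ok <- !is.na(y) & !is.na(groups)
  y <- y[ok]
  groups <- as.character(groups[ok])
  empty <- setdiff(declared, unique(groups))
  if (length(empty)) {
    warning(sprintf("dropping empty group(s): %s", paste(empty, collapse = ", ")))
  }
  groups <- factor(groups, levels = setdiff(declared, empty))
  k <- nlevels(groups)
  if (k < 2L) stop("need at least 2 non-empty groups")
  split_y <- split(y, groups)
  smry <- data.frame(
    group = names(split_y),
    n = vapply(split_y, length, integer(1)),
    median = vapply(split_y, stats::median, numeric(1)),
    q1 = vapply(split_y, function(v) unname(stats::quantile(v, 0.25)), numeric(1)),
    q3 = vapply(split_y, function(v) unname(stats::quantile(v, 0.75)), numeric(1)),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
  if (k == 2L) {
    p <- wilcoxon_p(split_y[[1L]], split_y[[2L]])
    method <- "wilcoxon"
  } else {
    p <- summary(stats::aov(y ~ groups))[[1L]][["Pr(>F)"]][1L]
    method <- "anova"
  }
  list(p_value = p, method = method, summary = smry)
}
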