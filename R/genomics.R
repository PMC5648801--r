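#' Per-sample mutation burden accounting
#'
#' Counts mutations per sample by category. Frameshift/in-frame indels are
#' protein-altering, so they are included in `n_nonsynonymous` (the Fig.-4
#' style mutational-burden axis) and additionally tallied as `n_indel`, a
#' sub-count; `n_total = n_nonsynonymous + n_silent + n_other` therefore
#' counts every record exactly once.
#'
#' @param mutations mutation `data.frame` (`sample_id`, `gene_symbol`,
#'   `variant_classification`), e.g. from [read_maf()] or
#'   [simulate_mutations()].
#' @param category_map named character vector mapping
#'   `Variant_Classification` terms to `c("nonsynonymous", "silent",
#'   "other")`, with an `indel` attribute; defaults to [maf_vocabulary()].
#'   Unmapped terms are counted as "other" with a warning.
#' @param roster optional character vector of sample ids; samples in the
#'   roster but absent from the table get all-zero rows, and the output is
#'   ordered by the roster.
#' @return `data.frame` with `sample_id`, `n_nonsynonymous`, `n_indel`,
#'   `n_silent`, `n_other`, `n_total`.
#' @export
count_burden <- function(mutations, category_map = maf_vocabulary(),
                         roster = NULL) {
  stopifnot(all(c("sample_id", "variant_classification") %in% names(mutations)))
  cls <- mutations$variant_classification
  cat <- unname(category_map[cls])
  unmapped <- is.na(cat)
  if (any(unmapped)) {
    warning(sprintf("unmapped Variant_Classification term(s) counted as 'other': %s",
                    paste(unique(cls[unmapped]), collapse = ", ")))
    cat[unmapped] <- "other"
  }
  indel_terms <- attr(category_map, "indel") %||% character(0)
  samples <- if (is.null(roster)) unique(mutations$sample_id) else roster
  check_unique_ids(samples, "roster sample")
  tally <- function(keep) {
    t0 <- table(factor(mutations$sample_id[keep], levels = samples))
    as.integer(t0)
  }
  out <- data.frame(
    sample_id = samples,
    n_nonsynonymous = tally(cat == "nonsynonymous"),
    n_indel = tally(cls %in% indel_terms),
    n_silent = tally(cat == "silent"),
    n_other = tally(cat == "other"),
    stringsAsFactors = FALSE
  )
  out$n_total <- out$n_nonsynonymous + out$n_silent + out$n_other
  out
}

#' Chromosomal instability (CIN) score
#'
#' Per-sample sum of squared gene-level GISTIC2 continuous copy-number
#' values: `cin_j = sum_g g_gj^2`. When per-sample tumor purity (in
#' (0, 1]) is supplied, the purity-adjusted score
#' `adjusted_cin = purity * cin` is also reported.
#'
#' @param gistic numeric genes x samples matrix of gene-level GISTIC2
#'   values (finite).
#' @param purity optional numeric purity per sample, named by sample id or
#'   aligned with the columns; `NA` entries give a missing adjusted score.
#' @return `data.frame` with `sample_id`, `cin_score`, `adjusted_cin`,
#'   `purity_used`.
#' @export
cin_score <- function(gistic, purity = NULL) {
  if (!is.matrix(gistic) || !is.numeric(gistic)) {
    stop("`gistic` must be a numeric genes x samples matrix")
  }
  if (!all(is.finite(gistic))) stop("GISTIC2 values must be finite")
  scores <- colSums(gistic^2)
  samples <- colnames(gistic) %||% as.character(seq_len(ncol(gistic)))
  adjusted <- rep(NA_real_, length(scores))
  purity_used <- rep(NA_real_, length(scores))
  if (!is.null(purity)) {
    p <- if (!is.null(names(purity))) unname(purity[samples]) else purity
    if (length(p) != length(scores)) {
      stop("`purity` must provide one value per sample")
    }
    if (any(!is.na(p) & (p <= 0 | p > 1))) stop("purity must lie in (0, 1]")
    purity_used <- p
    adjusted <- p * scores
  }
  data.frame(
    sample_id = samples,
    cin_score = unname(scores),
    adjusted_cin = adjusted,
    purity_used = purity_used,
    stringsAsFactors = FALSE
  )
}

#' Genomic M / C / NOS typing
#'
#' Classifies each tumor on the mutational-burden and chromosomal-
#' instability axes: mutator (M) when the non-synonymous mutation count
#' strictly exceeds `mut_threshold` (default 200), chromosome-instable (C)
#' when the CIN score strictly exceeds `cin_threshold` (default 5000), not
#' otherwise specified (NOS) when neither, and the explicit overlap label
#' MC when both (no silent precedence; downstream contrasts exclude MC by
#' default).
#'
#' @param burden burden table from [count_burden()].
#' @param cin CIN table from [cin_score()].
#' @param mut_threshold mutation-count threshold (strict `>`).
#' @param cin_threshold CIN-score threshold (strict `>`).
#' @param burden_column column of `burden` used as the mutation axis.
#' @return `data.frame` with `sample_id`, `label` in
#'   `c("M", "C", "NOS", "MC")`, and the thresholds used; restricted to the
#'   samples present in both inputs.
#' @export
classify_type <- function(burden, cin, mut_threshold = 200,
                          cin_threshold = 5000,
                          burden_column = "n_nonsynonymous") {
  stopifnot(burden_column %in% names(burden))
  common <- intersect(burden$sample_id, cin$sample_id)
  if (!length(common)) stop("no samples shared between burden and CIN tables")
  b <- burden[[burden_column]][match(common, burden$sample_id)]
  k <- cin$cin_score[match(common, cin$sample_id)]
  m <- b > mut_threshold
  c_ <- k > cin_threshold
  label <- ifelse(m & c_, "MC", ifelse(m, "M", ifelse(c_, "C", "NOS")))
  n_mc <- sum(label == "MC")
  if (n_mc) {
    message(sprintf("classify_type: %d sample(s) exceed both thresholds (label MC)", n_mc))
  }
  data.frame(
    sample_id = common,
    label = label,
    mut_threshold = mut_threshold,
    cin_threshold = cin_threshold,
    stringsAsFactors = FALSE
  )
}
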