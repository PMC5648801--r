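#' Expression matrix container
#'
#' A light container for a log2-scale genes x samples expression matrix with
#' optional per-sample annotations (response label, cancer type, platform).
#' Gene and sample identifiers must be unique and every value finite.
#'
#' @param values numeric matrix, genes in rows, samples in columns, with
#'   complete `dimnames`.
#' @param annotations optional `data.frame` of per-sample annotations; must
#'   have one row per sample, identified either by `rownames` or a
#'   `sample_id` column, covering exactly the samples of `values`.
#' @return an object of class `ExpressionMatrix` with elements `values` and
#'   `annotations`.
#' @export
ExpressionMatrix <- function(values, annotations = NULL) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix (genes x samples)")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("`values` must carry gene ids as rownames and sample ids as colnames")
  }
  check_unique_ids(rownames(values), "gene")
  check_unique_ids(colnames(values), "sample")
  if (!all(is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-finite expression value at gene '%s', sample '%s'",
                 rownames(values)[bad[1L]], colnames(values)[bad[2L]]))
  }
  if (!is.null(annotations)) {
    annotations <- as.data.frame(annotations)
    ids <- if ("sample_id" %in% names(annotations)) {
      as.character(annotations$sample_id)
    } else {
      rownames(annotations)
    }
    if (!setequal(ids, colnames(values)) || anyDuplicated(ids)) {
      stop("`annotations` must describe exactly the samples of `values`")
    }
    annotations <- annotations[match(colnames(values), ids), , drop = FALSE]
    rownames(annotations) <- colnames(values)
  }
  structure(list(values = values, annotations = annotations),
            class = "ExpressionMatrix")
}

check_unique_ids <- function(ids, what) {
  if (anyNA(ids) || any(!nzchar(ids))) {
    stop(sprintf("missing/empty %s identifier", what))
  }
  dup <- ids[duplicated(ids)]
  if (length(dup)) {
    stop(sprintf("duplicate %s identifier(s): %s", what,
                 paste(unique(dup), collapse = ", ")))
  }
  invisible(ids)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d samples\n",
              nrow(x$values), ncol(x$values)))
  if (!is.null(x$annotations)) {
    cat("annotations:", paste(names(x$annotations), collapse = ", "), "\n")
  }
  invisible(x)
}

# Accept either an ExpressionMatrix or a bare genes x samples matrix.
expr_values <- function(x) {
  if (inherits(x, "ExpressionMatrix")) x$values
  else if (is.matrix(x) && is.numeric(x)) x
  else stop("expected an ExpressionMatrix or a numeric genes x samples matrix")
}

expr_annotations <- function(x) {
  if (inherits(x, "ExpressionMatrix")) x$annotations else NULL
}

# Rebuild with the same container type as the input.
expr_like <- function(x, values) {
  if (inherits(x, "ExpressionMatrix")) {
    ExpressionMatrix(values, annotations = x$annotations)
  } else {
    values
  }
}

#' @export
print.SignatureModel <- function(x, ...) {
  cat(sprintf(paste0(
    "SignatureModel (Bayesian compound covariate predictor)\n",
    "  genes: %d   class means (responder / non-responder): %.4g / %.4g\n",
    "  pooled SD: %.4g   priors: (%.2g, %.2g)   cutoff: %.2g\n"),
    length(x$genes), x$class_means[["responder"]],
    x$class_means[["non_responder"]], x$pooled_sd,
    x$priors[1L], x$priors[2L], x$cutoff))
  invisible(x)
}
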