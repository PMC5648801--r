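#' Read a log2 expression matrix from TSV
#'
#' Expects the UCSC/TCGA matrix dialect: tab-separated, UTF-8, mandatory
#' header row, first column holds the identifiers. Sample order in the file
#' is preserved; duplicated identifiers are an error, as are non-numeric or
#' (by default) missing cells.
#'
#' @param path path to a TSV file.
#' @param orientation `"genes_in_rows"` (default), `"samples_in_rows"`, or
#'   `"auto"`, which assumes genes in rows whenever the table has at least as
#'   many rows as columns (expression matrices are almost always tall).
#' @param impute_missing if `TRUE`, missing cells are filled with the
#'   per-gene median instead of being rejected.
#' @return an [ExpressionMatrix].
#' @export
read_expression <- function(path,
                            orientation = c("genes_in_rows",
                                            "samples_in_rows", "auto"),
                            impute_missing = FALSE) {
  orientation <- match.arg(orientation)
  values <- read_id_matrix(path)
  if (orientation == "auto") {
    orientation <- if (nrow(values) >= ncol(values)) "genes_in_rows"
                   else "samples_in_rows"
  }
  if (orientation == "samples_in_rows") values <- t(values)
  if (anyNA(values)) {
    if (!impute_missing) {
      bad <- which(is.na(values), arr.ind = TRUE)[1L, ]
      stop(sprintf(
        "missing expression value at gene '%s', sample '%s' (set impute_missing = TRUE for per-gene median imputation)",
        rownames(values)[bad[1L]], colnames(values)[bad[2L]]))
    }
    med <- apply(values, 1L, stats::median, na.rm = TRUE)
    idx <- which(is.na(values), arr.ind = TRUE)
    values[idx] <- med[idx[, 1L]]
  }
  out <- ExpressionMatrix(values)
  message(sprintf("read_expression: %d genes, %d samples from %s",
                  nrow(values), ncol(values), path))
  out
}

#' Write an expression or copy-number matrix to TSV
#'
#' Inverse of [read_expression()]/[read_gistic()]: identifiers round-trip
#' exactly, values to the precision of the decimal representation.
#'
#' @param x an [ExpressionMatrix] or numeric genes x samples matrix.
#' @param path output path.
#' @param id_column header name for the identifier column.
#' @export
write_expression <- function(x, path, id_column = "gene_id") {
  values <- expr_values(x)
  df <- data.frame(id = rownames(values), values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1L] <- id_column
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_expression
#' @export
write_gistic <- function(x, path, id_column = "gene_id") {
  write_expression(x, path, id_column = id_column)
}

# Shared TSV -> validated numeric matrix loader. Errors name the offending
# row/column so malformed exports are diagnosable.
read_id_matrix <- function(path) {
  raw <- utils::read.delim(path, sep = "\t", header = TRUE,
                           check.names = FALSE, colClasses = "character",
                           na.strings = c("NA", ""), quote = "",
                           fileEncoding = "UTF-8")
  if (ncol(raw) < 2L) stop("expected an id column plus at least one sample column")
  ids <- raw[[1L]]
  check_unique_ids(ids, "row")
  check_unique_ids(names(raw)[-1L], "column")
  body <- as.matrix(raw[, -1L, drop = FALSE])
  values <- suppressWarnings(array(as.numeric(body), dim = dim(body)))
  bad <- which(is.na(values) & !is.na(body), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("malformed numeric cell '%s' at row '%s', column '%s' in %s",
                 body[bad[1L, , drop = FALSE]], ids[bad[1L, 1L]],
                 colnames(body)[bad[1L, 2L]], path))
  }
  dimnames(values) <- list(ids, colnames(body))
  values
}

#' Read a gene-level GISTIC2 copy-number matrix from TSV
#'
#' Signed continuous gene-level copy-number estimates (amplification
#' positive, deletion negative), genes in rows. All values must be present
#' and finite.
#'
#' @inheritParams read_expression
#' @return numeric matrix, genes x samples.
#' @export
read_gistic <- function(path) {
  values <- read_id_matrix(path)
  if (anyNA(values) || !all(is.finite(values))) {
    bad <- which(!is.finite(values) | is.na(values), arr.ind = TRUE)[1L, ]
    stop(sprintf("missing/non-finite GISTIC2 value at gene '%s', sample '%s'",
                 rownames(values)[bad[1L]], colnames(values)[bad[2L]]))
  }
  values
}

#' Standard MAF Variant_Classification vocabulary
#'
#' The closed set of GDC MAF `Variant_Classification` terms the package
#' recognises, mapped to burden categories. Frameshift and in-frame indels
#' count as protein-altering (non-synonymous) and are additionally tallied
#' as indels by [count_burden()].
#'
#' @return named character vector: term -> category in
#'   `c("nonsynonymous", "silent", "other")`, with attribute `indel` listing
#'   the indel terms.
#' @export
maf_vocabulary <- function() {
  map <- c(
    Missense_Mutation        = "nonsynonymous",
    Nonsense_Mutation        = "nonsynonymous",
    Nonstop_Mutation         = "nonsynonymous",
    Splice_Site              = "nonsynonymous",
    Translation_Start_Site   = "nonsynonymous",
    Frame_Shift_Del          = "nonsynonymous",
    Frame_Shift_Ins          = "nonsynonymous",
    In_Frame_Del             = "nonsynonymous",
    In_Frame_Ins             = "nonsynonymous",
    Silent                   = "silent",
    `3'UTR`                  = "other",
    `5'UTR`                  = "other",
    `3'Flank`                = "other",
    `5'Flank`                = "other",
    Intron                   = "other",
    IGR                      = "other",
    RNA                      = "other",
    Splice_Region            = "other",
    Targeted_Region          = "other"
  )
  attr(map, "indel") <- c("Frame_Shift_Del", "Frame_Shift_Ins",
                          "In_Frame_Del", "In_Frame_Ins")
  map
}

#' Read a somatic mutation table in MAF format
#'
#' Requires at least the `Hugo_Symbol`, `Tumor_Sample_Barcode` and
#' `Variant_Classification` columns; `#`-prefixed header comments are
#' skipped. One record per called variant. Classification terms outside the
#' standard vocabulary are preserved but flagged with a warning (they are
#' later counted under "other").
#'
#' @param path path to a MAF file.
#' @return `data.frame` with columns `sample_id`, `gene_symbol`,
#'   `variant_classification`.
#' @export
read_maf <- function(path) {
  raw <- utils::read.delim(path, sep = "\t", header = TRUE,
                           check.names = FALSE, comment.char = "#",
                           colClasses = "character", quote = "",
                           fileEncoding = "UTF-8")
  required <- c("Hugo_Symbol", "Tumor_Sample_Barcode", "Variant_Classification")
  missing <- setdiff(required, names(raw))
  if (length(missing)) {
    stop(sprintf("MAF file %s lacks required column(s): %s", path,
                 paste(missing, collapse = ", ")))
  }
  out <- data.frame(
    sample_id = raw$Tumor_Sample_Barcode,
    gene_symbol = raw$Hugo_Symbol,
    variant_classification = raw$Variant_Classification,
    stringsAsFactors = FALSE
  )
  unknown <- setdiff(unique(out$variant_classification), names(maf_vocabulary()))
  if (length(unknown)) {
    warning(sprintf("unrecognised Variant_Classification term(s): %s (will count as 'other')",
                    paste(unknown, collapse = ", ")))
  }
  out
}

#' Write a mutation table as a minimal MAF
#'
#' @param mutations `data.frame` as returned by [read_maf()].
#' @param path output path.
#' @export
write_maf <- function(mutations, path) {
  df <- data.frame(
    Hugo_Symbol = mutations$gene_symbol,
    Tumor_Sample_Barcode = mutations$sample_id,
    Variant_Classification = mutations$variant_classification,
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a clinical table from TSV
#'
#' Columns: `sample_id` (mandatory, unique), and any of `survival_time`
#' (days, >= 0), `event` (0/1), `cancer_type`, `purity` (in (0, 1] when
#' present), `msi_status` (MSI-H/MSI-L/MSS), `viral_status`. Row order is
#' preserved and invariants are enforced on load.
#'
#' @param path path to a TSV file.
#' @return validated `data.frame`.
#' @export
read_clinical <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          na.strings = c("NA", ""), quote = "",
                          fileEncoding = "UTF-8")
  if (!"sample_id" %in% names(df)) stop("clinical table lacks a sample_id column")
  validate_clinical(df)
}

validate_clinical <- function(df) {
  check_unique_ids(as.character(df$sample_id), "sample")
  if ("survival_time" %in% names(df)) {
    t <- df$survival_time
    if (any(!is.na(t) & (!is.finite(t) | t < 0))) {
      stop("survival_time must be finite and >= 0")
    }
  }
  if ("event" %in% names(df)) {
    e <- df$event
    if (any(!is.na(e) & !(e %in% c(0, 1)))) stop("event must be 0 or 1")
  }
  if ("purity" %in% names(df)) {
    p <- df$purity
    if (any(!is.na(p) & (p <= 0 | p > 1))) {
      stop("purity must lie in (0, 1] when present")
    }
  }
  if ("msi_status" %in% names(df)) {
    m <- df$msi_status
    ok <- c("MSI-H", "MSI-L", "MSS")
    if (any(!is.na(m) & !(m %in% ok))) {
      stop(sprintf("msi_status must be one of %s", paste(ok, collapse = ", ")))
    }
  }
  df
}

#' @rdname read_clinical
#' @param clinical validated clinical `data.frame`.
#' @export
write_clinical <- function(clinical, path) {
  utils::write.table(validate_clinical(clinical), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Serialize / restore a trained signature model
#'
#' The model is stored as a single JSON document: gene ids, t-statistic
#' weights, compound-covariate class densities, priors, cutoff, the
#' training compound covariates needed to refit densities after platform
#' gene loss, and a provenance block.
#'
#' @param model a `SignatureModel` from [fit_bccp()].
#' @param path output path (`.json`).
#' @export
write_signature_model <- function(model, path) {
  payload <- unclass(model)
  # named vectors must go out as JSON objects, not bare arrays
  payload$weights <- as.list(payload$weights)
  payload$class_means <- as.list(payload$class_means)
  payload$class_sds <- as.list(payload$class_sds)
  payload$training_values <- as.data.frame(payload$training_values)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_signature_model
#' @export
read_signature_model <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  tv <- as.matrix(payload$training_values)
  rownames(tv) <- payload$genes
  model <- list(
    genes = payload$genes,
    weights = stats::setNames(as.numeric(unlist(payload$weights)[payload$genes]),
                              payload$genes),
    class_means = unlist(payload$class_means),
    pooled_sd = payload$pooled_sd,
    class_sds = unlist(payload$class_sds),
    priors = as.numeric(unlist(payload$priors)),
    cutoff = payload$cutoff,
    pool_variance = isTRUE(payload$pool_variance),
    training_values = tv,
    training_labels = unlist(payload$training_labels),
    provenance = payload$provenance
  )
  structure(model, class = "SignatureModel")
}
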