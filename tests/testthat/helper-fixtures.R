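# Shared fixture builders: everything generated in code, nothing on disk.

make_expr <- function(values, samples = NULL, genes = NULL, response = NULL) {
  if (is.null(genes)) genes <- sprintf("g%02d", seq_len(nrow(values)))
  if (is.null(samples)) samples <- sprintf("s%02d", seq_len(ncol(values)))
  dimnames(values) <- list(genes, samples)
  ann <- if (is.null(response)) NULL else
    data.frame(sample_id = samples, response = response,
               stringsAsFactors = FALSE)
  ExpressionMatrix(values, annotations = ann)
}

# Two-class matrix: `n_signal` genes shifted by `delta` in responders.
make_two_class <- function(n_genes = 50, n_per_class = 5, n_signal = 0,
                           delta = 0, sd = 1, seed = 42) {
  set.seed(seed)
  n <- 2 * n_per_class
  response <- rep(c("responder", "non_responder"), each = n_per_class)
  values <- matrix(rnorm(n_genes * n, sd = sd), nrow = n_genes)
  if (n_signal > 0) {
    values[seq_len(n_signal), response == "responder"] <-
      values[seq_len(n_signal), response == "responder"] + delta
  }
  make_expr(values, response = response)
}

write_tsv_fixture <- function(df, path = tempfile(fileext = ".tsv")) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

expr_tsv_fixture <- function(values, genes, samples,
                             path = tempfile(fileext = ".tsv")) {
  df <- data.frame(gene_id = genes, values, check.names = FALSE)
  names(df)[-1] <- samples
  write_tsv_fixture(df, path)
}
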