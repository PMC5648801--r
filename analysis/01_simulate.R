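#!/usr/bin/env Rscript
# Generate the synthetic study cohort: a two-class expression matrix with a
# planted immune-response signature (5% of genes shifted by 2 noise-SD in
# responders, 25 samples per arm), a per-sample somatic mutation table, a
# gene-level copy-number matrix, and clinical follow-up whose hazard is
# linked to the planted class. Everything downstream reads these files.

suppressPackageStartupMessages(library(immunosig))

out_dir <- "results/cohort"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

config <- simulation_config(seed = 1)
cohort <- simulate_cohort(config)

write_expression(cohort$expr, file.path(out_dir, "expression.tsv"))
write_maf(cohort$mutations, file.path(out_dir, "mutations.maf"))
write_gistic(cohort$cna, file.path(out_dir, "cna.tsv"))
write_clinical(cohort$clinical, file.path(out_dir, "clinical.tsv"))
jsonlite::write_json(
  list(de_genes = cohort$de_genes,
       response = setNames(as.list(cohort$expr$annotations$response),
                           cohort$expr$annotations$sample_id),
       config = unclass(config)),
  file.path(out_dir, "truth.json"), auto_unbox = TRUE, pretty = TRUE)

cat(sprintf(
  "Simulated cohort: %d genes x %d samples, %d planted DE genes,\n%d mutation records, CIN expectation %.0f, written to %s/\n",
  config$n_genes, 2 * config$n_samples_per_class, length(cohort$de_genes),
  nrow(cohort$mutations), config$n_genes * config$cna_magnitude^2, out_dir))
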