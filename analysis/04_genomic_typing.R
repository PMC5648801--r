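#!/usr/bin/env Rscript
# Genomic characterisation of the cohort: per-sample mutation burden, CIN
# score (sum of squared gene-level copy-number values) with purity
# adjustment, M / C / NOS typing at the >200 mutation and >5000 CIN
# thresholds, and the IS-vs-burden / IS-vs-CIN regressions.

suppressPackageStartupMessages(library(immunosig))

mutations <- read_maf("results/cohort/mutations.maf")
cna <- read_gistic("results/cohort/cna.tsv")
clinical <- read_clinical("results/cohort/clinical.tsv")
scores <- read.delim("results/is_scores_training.tsv")

burden <- count_burden(mutations, roster = clinical$sample_id)
cin <- cin_score(cna, purity = setNames(clinical$purity, clinical$sample_id))
types <- classify_type(burden, cin)

merged <- Reduce(function(a, b) merge(a, b, by = "sample_id"),
                 list(burden, cin, types))
write.table(merged, "results/genomic_typing.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

is <- setNames(scores$is_score, scores$sample_id)
keep <- types$label %in% c("M", "C", "NOS")  # MC excluded from contrasts
cmp <- if (length(unique(types$label[keep])) >= 2) {
  group_compare(is[types$sample_id[keep]], types$label[keep])
} else NULL

reg_burden <- regress_is(is[burden$sample_id], burden$n_nonsynonymous)
reg_cin <- regress_is(is[cin$sample_id], cin$cin_score)
write.table(rbind(cbind(axis = "burden", reg_burden),
                  cbind(axis = "cin", reg_cin)),
            "results/is_regressions.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

cat(sprintf("Typing: %s\n", paste(sprintf("%s=%d", names(table(types$label)),
                                          table(types$label)), collapse = " ")))
if (!is.null(cmp)) {
  cat(sprintf("IS score by genomic type (%s): p = %.3g\n", cmp$method, cmp$p_value))
}
cat(sprintf(
  "IS ~ log10(burden+1): slope %.3f (R2 %.3f, p %.3g); IS ~ log10(CIN+1): slope %.3f (R2 %.3f, p %.3g)\n",
  reg_burden$slope, reg_burden$r_squared, reg_burden$p_value,
  reg_cin$slope, reg_cin$r_squared, reg_cin$p_value))
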