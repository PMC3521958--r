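#!/usr/bin/env Rscript
# 01: simulate the study cohort.
#
# One control group and three disease stages at microarray-scale sample
# counts (23/45/31/81), 300 genes with 60 planted DE genes (3 sd shift) and
# two planted correlated modules (one of them disease-only).  Writes one
# expression TSV per condition, the sample metadata, and the ground truth.

library(micascade)

RES <- file.path("results", "analysis")
dir.create(file.path(RES, "data"), recursive = TRUE, showWarnings = FALSE)

spec <- glioma_like_spec(n_genes = 300, seed = 1L)
cohort <- generate_cohort(spec)

md <- do.call(rbind, lapply(cohort$conditions, function(cc)
  data.frame(sample_id = colnames(cohort$expr[[cc]]), condition = cc)))
utils::write.table(md, file.path(RES, "data", "metadata.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
for (cc in cohort$conditions)
  write_expression(cohort$expr[[cc]],
                   file.path(RES, "data", paste0(cc, ".tsv")), condition = cc)
utils::write.table(
  data.frame(gene_id = cohort$truth$de_genes),
  file.path(RES, "data", "truth_de_genes.tsv"),
  sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(cohort$truth$blocks,
                   file.path(RES, "data", "truth_blocks.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

cat(sprintf("cohort: %d genes, conditions %s with %s samples\n",
            spec$n_genes, paste(cohort$conditions, collapse = "/"),
            paste(spec$samples_per_condition, collapse = "/")))
cat(sprintf("planted: %d DE genes, %d module blocks -> %s\n",
            length(cohort$truth$de_genes), length(spec$module_blocks),
            file.path(RES, "data")))
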