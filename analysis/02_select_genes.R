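#!/usr/bin/env Rscript
# 02: select cancer-related genes.
#
# Wilcoxon rank-sum test of the control group against each disease stage at
# the raw significance level 2.5e-7, then intersection across stages:
# G1 = GI_II n GI_III n GI_IV.  Writes the per-stage gene sets, the working
# set, and a per-stage count table.

library(micascade)

RES <- file.path("results", "analysis")
dir.create(file.path(RES, "selection"), recursive = TRUE, showWarnings = FALSE)
md <- file.path(RES, "data", "metadata.tsv")
conds <- unique(utils::read.delim(md)$condition)
expr <- lapply(conds, function(cc)
  read_expression(file.path(RES, "data", paste0(cc, ".tsv")), metadata = md))
names(expr) <- conds
control <- conds[1L]

alpha <- 2.5e-7
sets <- list()
for (cc in setdiff(conds, control)) {
  sets[[cc]] <- rank_sum_select(expr[[control]], expr[[cc]], alpha = alpha,
                                label = paste0("GI_", cc))
  write_gene_set(sets[[cc]],
                 file.path(RES, "selection", paste0("GI_", cc, ".tsv")))
}
working <- intersect_stages(sets, label = "G1")
write_gene_set(working, file.path(RES, "selection", "G1.tsv"))

counts <- data.frame(gene_set = c(paste0("GI_", names(sets)), "G1"),
                     n_genes = c(vapply(sets, function(s)
                       length(s$gene_ids), 0L), length(working$gene_ids)))
utils::write.table(counts, file.path(RES, "selection", "counts.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

truth <- utils::read.delim(file.path(RES, "data", "truth_de_genes.tsv"))$gene_id
cat(sprintf("rank-sum selection at alpha = %g:\n", alpha))
print(counts, row.names = FALSE)
cat(sprintf("working set G1: %d genes, of which %d are planted DE genes\n",
            length(working$gene_ids),
            sum(working$gene_ids %in% truth)))
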