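#!/usr/bin/env Rscript
# 05: classify structural key genes.
#
# A gene is "key" in a condition when its cascade size-ratio reaches 0.5 at
# at least half of the sweep thresholds inside the separability window
# (0, 0.65).  Genes key somewhere get a type label spelling out their key
# conditions (T_C, T_II_III, ...); the annotation column marks disease-only
# and control-only patterns.

library(micascade)

RES <- file.path("results", "analysis")
md <- file.path(RES, "data", "metadata.tsv")
conds <- unique(utils::read.delim(md)$condition)
working <- read_gene_set(file.path(RES, "selection", "G1.tsv"))$gene_ids

sweeps <- lapply(conds, function(cc) {
  m <- read_expression(file.path(RES, "data", paste0(cc, ".tsv")),
                       metadata = md)[working, , drop = FALSE]
  threshold_sweep(nmi_matrix(discretize(m, n_bins = 20)))
})
names(sweeps) <- conds

profiles <- key_profiles(sweeps, d_key = 0.5, q = 0.5, window = c(0, 0.65))
skg <- classify_types(profiles, control = conds[1L])
utils::write.table(as.data.frame(skg), file.path(RES, "skg.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

cat(sprintf("structural key genes: %d of %d working genes\n",
            nrow(skg), length(working)))
if (nrow(skg)) {
  print(table(type = skg$type), zero.print = ".")
  print(table(annotation = skg$annotation))
}
cat(sprintf("table -> %s\n", file.path(RES, "skg.tsv")))
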