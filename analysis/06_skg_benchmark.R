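#!/usr/bin/env Rscript
# 06: structural-key-gene identifiability benchmark.
#
# At microarray-scale sample counts the 20-bin MI estimator's bias floor
# compresses the similarity range, and script 05 finds no key genes.  This
# benchmark re-runs the classifier on cohorts where the planted structure is
# resolvable: a 40-gene cohort whose single graded module (hub first) is
# wired only in the disease condition, with 3000 samples per group.  The
# hub should be labelled as a disease-only key gene.

library(micascade)

RES <- file.path("results", "analysis")
dir.create(RES, recursive = TRUE, showWarnings = FALSE)

n_seeds <- 5L
rows <- NULL
for (sd_ in seq_len(n_seeds)) {
  co <- generate_cohort(skg_benchmark_spec(seed = sd_))
  sweeps <- lapply(co$expr, function(m)
    threshold_sweep(nmi_matrix(discretize(m, n_bins = 20))))
  skg <- classify_types(key_profiles(sweeps), control = "C")
  hub <- skg[skg$gene_id == "g0001", ]
  rows <- rbind(rows, data.frame(
    seed = sd_,
    hub_type = if (nrow(hub)) hub$type else "(none)",
    hub_annotation = if (nrow(hub)) hub$annotation else "(none)",
    n_skg = nrow(skg),
    n_disease_only = sum(skg$annotation == "disease-only")))
}
utils::write.table(rows, file.path(RES, "skg_benchmark.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
print(rows, row.names = FALSE)
cat(sprintf("hub labelled disease-only in %d/%d seeds -> %s\n",
            sum(rows$hub_annotation == "disease-only"), n_seeds,
            file.path(RES, "skg_benchmark.tsv")))
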