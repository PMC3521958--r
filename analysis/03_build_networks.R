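#!/usr/bin/env Rscript
# 03: build mutual-information networks.
#
# For every condition: pool the working-set profiles, discretize them into
# 20 equal-frequency bins, compute pairwise normalized mutual information
# (I / min marginal entropy), and record how many edges survive each of the
# 18 coarse-graining thresholds.

library(micascade)

RES <- file.path("results", "analysis")
dir.create(file.path(RES, "networks"), recursive = TRUE, showWarnings = FALSE)
md <- file.path(RES, "data", "metadata.tsv")
conds <- unique(utils::read.delim(md)$condition)
working <- read_gene_set(file.path(RES, "selection", "G1.tsv"))$gene_ids

thr <- default_thresholds()
density <- NULL
for (cc in conds) {
  m <- read_expression(file.path(RES, "data", paste0(cc, ".tsv")),
                       metadata = md)[working, , drop = FALSE]
  net <- nmi_matrix(discretize(m, n_bins = 20))
  # full edge lists at representative thresholds; the density table below
  # covers the whole sweep
  for (T in c(0.3, 0.6, 0.9))
    write_network(net, T, file.path(RES, "networks",
                                    sprintf("%s_T%s.tsv", cc, format(T))))
  density <- rbind(density, data.frame(
    condition = cc, threshold = thr,
    n_edges = vapply(thr, function(T)
      nrow(threshold_and_distance(net, T)$edges), 0)))
  v <- net$nmi[upper.tri(net$nmi)]
  cat(sprintf("%s: %d nodes, nmi quartiles %.3f / %.3f / %.3f\n",
              cc, length(working),
              stats::quantile(v, 0.25), stats::median(v),
              stats::quantile(v, 0.75)))
}
utils::write.table(density, file.path(RES, "networks", "edge_density.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("wrote the sweep density table and %d edge lists -> %s\n",
            length(conds) * 3L, file.path(RES, "networks")))
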