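#' Collapse a probe-level matrix to gene level
#'
#' Probes mapping to no gene or to more than one gene are dropped; each
#' remaining gene's profile is the arithmetic mean of its probes' profiles.
#'
#' @param probes probe x sample numeric matrix with probe row names.
#' @param map named list: probe id -> character vector of gene ids (empty
#'   for orphan probes).  Every probe row must appear in the map.
#' @return gene x sample matrix, rows sorted by gene id.
#' @export
collapse_probes <- function(probes, map) {
  stopifnot(is.matrix(probes), !is.null(rownames(probes)))
  missing <- setdiff(rownames(probes), names(map))
  if (length(missing))
    stop(sprintf("probes absent from map: %s",
                 paste(missing, collapse = ", ")))
  ngenes <- vapply(map[rownames(probes)], length, 0L)
  keep <- which(ngenes == 1L)
  gene <- vapply(map[rownames(probes)[keep]], `[[`, "", 1L)
  genes <- sort(unique(gene))
  out <- matrix(0, length(genes), ncol(probes),
                dimnames = list(genes, colnames(probes)))
  for (gi in seq_along(genes)) {
    rows <- keep[gene == genes[gi]]
    out[gi, ] <- colMeans(probes[rows, , drop = FALSE])
  }
  attr(out, "condition") <- attr(probes, "condition")
  out
}

# Two-sided Wilcoxon rank-sum p-value.  Exact distribution for small
# untied groups (both sizes <= 20), otherwise the normal approximation with
# tie correction and continuity correction.
rank_sum_p <- function(x, y) {
  exact <- length(x) <= 20 && length(y) <= 20 && !anyDuplicated(c(x, y))
  suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided",
                       exact = exact, correct = TRUE)$p.value)
}

#' Select genes differing between two sample groups (rank-sum test)
#'
#' Per gene, a two-sided Wilcoxon rank-sum (Mann-Whitney) test comparing the
#' control and stage sample groups; a gene is retained iff its p-value is
#' below `alpha`.  No multiple-testing correction is applied by default
#' (raw significance levels); set `fdr = TRUE` to select on
#' Benjamini-Hochberg adjusted p-values instead.  Being rank-based, the
#' selection is invariant under strictly monotone transforms of the values.
#'
#' @param control,stage gene x sample matrices sharing the same gene rows.
#' @param alpha significance level in (0, 1).
#' @param label name for the resulting set (e.g. `"GI_II"`).
#' @param fdr logical; apply Benjamini-Hochberg adjustment before
#'   thresholding (default FALSE).
#' @return object of class `gene_set`: list with `label`, `alpha`,
#'   `gene_ids` (the retained set) and `p_values` (all genes, named).
#' @export
rank_sum_select <- function(control, stage, alpha, label = "G", fdr = FALSE) {
  if (is.null(rownames(control)) || is.null(rownames(stage)) ||
      !identical(rownames(control), rownames(stage)))
    stop("`control` and `stage` must share an identical gene universe")
  if (ncol(control) < 2 || ncol(stage) < 2)
    stop("each group needs at least 2 samples")
  if (alpha <= 0 || alpha >= 1) stop("`alpha` must be in (0, 1)")
  p <- vapply(seq_len(nrow(control)),
              function(i) rank_sum_p(control[i, ], stage[i, ]),
              numeric(1))
  names(p) <- rownames(control)
  crit <- if (fdr) stats::p.adjust(p, "BH") else p
  gene_set(label, alpha, names(p)[crit < alpha], p)
}

#' Construct a gene set
#'
#' @param label set name.
#' @param alpha significance level it was selected at.
#' @param gene_ids character vector of member genes.
#' @param p_values optional named per-gene p-values (sidecar).
#' @return object of class `gene_set`.
#' @export
gene_set <- function(label, alpha, gene_ids, p_values = NULL) {
  if (alpha <= 0 || alpha >= 1) stop("`alpha` must be in (0, 1)")
  structure(list(label = label, alpha = alpha,
                 gene_ids = as.character(gene_ids), p_values = p_values),
            class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("gene_set %s: %d genes (alpha = %g)\n",
              x$label, length(x$gene_ids), x$alpha))
  invisible(x)
}

#' Intersect per-stage gene sets
#'
#' The working set is the intersection of the stage-wise selections, e.g.
#' G1 = GI_II n GI_III n GI_IV.  An empty intersection is allowed (with a
#' warning) so the pipeline can continue.
#'
#' @param sets non-empty list of [gene_set()]s.
#' @param label name for the intersection.
#' @return a [gene_set()]; `alpha` is taken from the inputs (unique values).
#' @export
intersect_stages <- function(sets, label = "G") {
  if (!length(sets)) stop("`sets` must contain at least one gene_set")
  stopifnot(all(vapply(sets, inherits, TRUE, "gene_set")))
  ids <- Reduce(intersect, lapply(sets, `[[`, "gene_ids"))
  if (!length(ids))
    warning(sprintf("intersection '%s' is empty", label))
  alphas <- unique(vapply(sets, `[[`, 0, "alpha"))
  gene_set(label, alphas[1L], ids)
}
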