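#' Equal-frequency discretization of an expression matrix
#'
#' Pools all values of the matrix and partitions them into `n_bins` intervals
#' containing (almost) the same number of values, then replaces each value by
#' the index of its interval.  Tied values always receive the same label, so
#' bin occupancies are only approximately equal in the presence of ties.
#' Because the binning depends on the values only through their ranks, any
#' strictly increasing transform of the input yields identical labels.
#'
#' @param expr numeric matrix (genes x samples), finite, no missing values.
#' @param n_bins number of intervals (default 20).
#' @param scope `"pooled"` (default) bins all values of the matrix jointly;
#'   `"gene"` bins each row separately.
#' @return integer matrix of the same shape with entries in `1..n_bins` and
#'   attribute `n_bins`.
#' @export
discretize <- function(expr, n_bins = 20, scope = c("pooled", "gene")) {
  scope <- match.arg(scope)
  if (!is.matrix(expr) || !is.numeric(expr))
    stop("`expr` must be a numeric matrix")
  if (any(!is.finite(expr)))
    stop("`expr` contains non-finite values")
  if (n_bins < 2) stop("`n_bins` must be >= 2")
  bin1 <- function(v) {
    r <- rank(v, ties.method = "min")
    as.integer(floor((r - 1) * n_bins / length(v)) + 1L)
  }
  if (scope == "pooled") {
    if (length(unique(as.vector(expr))) == 1L)
      warning("constant matrix: all labels set to 1")
    lab <- matrix(bin1(as.vector(expr)), nrow(expr), ncol(expr),
                  dimnames = dimnames(expr))
  } else {
    lab <- t(apply(expr, 1L, bin1))
    dimnames(lab) <- dimnames(expr)
  }
  storage.mode(lab) <- "integer"
  attr(lab, "n_bins") <- as.integer(n_bins)
  lab
}

#' Plug-in Shannon entropy of a label vector, in bits
#'
#' Empirical frequencies, base-2 logarithm, with the convention
#' 0 log 0 = 0.
#'
#' @param labels non-empty vector of discrete labels.
#' @return entropy in bits.
#' @export
shannon_entropy <- function(labels) {
  if (length(labels) == 0L) stop("`labels` must be non-empty")
  p <- tabulate(match(labels, unique(labels)))
  p <- p / sum(p)
  -sum(p * log2(p))
}

#' Mutual information of two label vectors, in bits
#'
#' I(A, B) = H(A) + H(B) - H(A, B), with the joint entropy taken over the
#' observed label pairs.  Symmetric, and non-negative up to rounding; tiny
#' negative rounding residue is clipped at zero.
#'
#' @param a,b equal-length vectors of discrete labels.
#' @return mutual information in bits.
#' @export
mutual_information <- function(a, b) {
  if (length(a) != length(b))
    stop("`a` and `b` must have equal length")
  joint <- paste(a, b, sep = "\r")
  max(shannon_entropy(a) + shannon_entropy(b) - shannon_entropy(joint), 0)
}

entropy_from_counts <- function(cnt) {
  p <- cnt[cnt > 0L]
  p <- p / sum(p)
  -sum(p * log2(p))
}

#' Pairwise normalized mutual information network
#'
#' Computes raw mutual information for every gene pair of a discretized
#' matrix and normalizes it into \[0, 1\].  The default normalization divides
#' by the smaller marginal entropy, `I / min(H_i, H_j)`, which is exactly
#' bounded by 1 and reaches it for identical profiles; `"sqrt"` divides by
#' `sqrt(H_i * H_j)` instead.  Pairs where the smaller entropy is zero get
#' nmi 0, and the diagonal is set to 0 (no self-loops).
#'
#' @param disc integer label matrix from [discretize()].
#' @param normalization `"min"` (default) or `"sqrt"`.
#' @return an object of class `mi_network`: list with `gene_ids`, symmetric
#'   matrices `nmi` and `raw_mi` (bits), `n_bins`, and an unset `threshold`.
#' @export
nmi_matrix <- function(disc, normalization = c("min", "sqrt")) {
  normalization <- match.arg(normalization)
  if (!is.matrix(disc) || nrow(disc) < 2L)
    stop("`disc` must be a label matrix with at least 2 genes")
  K <- attr(disc, "n_bins")
  if (is.null(K)) K <- max(disc)
  K <- as.integer(K)
  n <- nrow(disc)
  gene_ids <- rownames(disc)
  if (is.null(gene_ids)) gene_ids <- paste0("g", seq_len(n))
  H <- numeric(n)
  for (i in seq_len(n)) H[i] <- entropy_from_counts(tabulate(disc[i, ], K))
  raw <- matrix(0, n, n, dimnames = list(gene_ids, gene_ids))
  nmi <- raw
  for (i in seq_len(n - 1L)) {
    ai <- (disc[i, ] - 1L) * K
    for (j in (i + 1L):n) {
      Hij <- entropy_from_counts(tabulate(ai + disc[j, ], K * K))
      I <- max(H[i] + H[j] - Hij, 0)
      raw[i, j] <- raw[j, i] <- I
      denom <- switch(normalization,
                      min  = min(H[i], H[j]),
                      sqrt = sqrt(H[i] * H[j]))
      nmi[i, j] <- nmi[j, i] <- if (denom <= 0) 0 else min(I / denom, 1)
    }
  }
  structure(list(gene_ids = gene_ids, nmi = nmi, raw_mi = raw,
                 marginal_entropy = stats::setNames(H, gene_ids),
                 n_bins = K, threshold = NA_real_),
            class = "mi_network")
}

#' @export
print.mi_network <- function(x, ...) {
  cat(sprintf("mi_network: %d genes, %d bins, nmi in [%.3f, %.3f]\n",
              length(x$gene_ids), x$n_bins,
              min(x$nmi[upper.tri(x$nmi)]), max(x$nmi[upper.tri(x$nmi)])))
  invisible(x)
}

#' The 18 coarse-graining thresholds of the standard sweep
#'
#' @return numeric vector of length 18.
#' @export
default_thresholds <- function() {
  c(0, 0.05, 0.1, 0.15, 0.2, 0.25, 0.3, 0.35, 0.4, 0.45,
    0.5, 0.55, 0.6, 0.65, 0.7, 0.8, 0.9, 0.99)
}

#' Threshold an MI network into a reciprocal-weight distance network
#'
#' An edge (i, j) is retained iff its similarity exceeds the threshold
#' strictly, and receives distance weight 1/similarity; pairs at or below the
#' threshold (in particular pairs with zero MI) have no edge, i.e. infinite
#' distance.  All genes remain as nodes, including those isolated at this
#' threshold.  The strict rule makes T = 0 select the positive-MI network
#' rather than the complete graph.
#'
#' @param net an `mi_network`.
#' @param threshold value in \[0, 1).
#' @param weight_on `"nmi"` (default) thresholds and weights on normalized
#'   MI; `"raw"` thresholds on normalized MI but weights edges by raw MI.
#' @return a [distance_network()].
#' @export
threshold_and_distance <- function(net, threshold, weight_on = c("nmi", "raw")) {
  weight_on <- match.arg(weight_on)
  stopifnot(inherits(net, "mi_network"))
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold < 0 || threshold >= 1)
    stop("`threshold` must be a single value in [0, 1)")
  m <- net$nmi
  sel <- which(m > threshold & upper.tri(m), arr.ind = TRUE)
  w <- switch(weight_on,
              nmi = 1 / m[sel],
              raw = 1 / net$raw_mi[sel])
  edges <- data.frame(source = net$gene_ids[sel[, 1L]],
                      target = net$gene_ids[sel[, 2L]],
                      weight = as.numeric(w),
                      stringsAsFactors = FALSE)
  distance_network(net$gene_ids, edges, threshold = threshold)
}
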