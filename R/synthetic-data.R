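#' Declare a planted correlated module
#'
#' Genes of a module block share a latent factor.  With `graded = FALSE`
#' every member has the same squared loading, so every within-block pair has
#' latent correlation `strength`.  With `graded = TRUE` the members' coupling
#' is graded from `strength` down to `floor`: member j receives the factor
#' correlation that makes the Gaussian-MI-implied normalized dependence
#' (relative to the log2(20)-bit ceiling of a 20-level discretization) equal
#' to the j-th value of `seq(strength, floor)`.  A graded block therefore
#' spreads its edge similarities evenly across a coarse-graining sweep, with
#' the first member — the hub — coupled most tightly.
#'
#' @param size number of member genes.
#' @param strength latent-correlation strength in \[0, 1\] (graded blocks:
#'   the hub's target normalized dependence).
#' @param conditions condition codes in which the block is active, or NULL
#'   (default) for all conditions.
#' @param graded logical; see above.
#' @param floor graded blocks only: the weakest member's target (default 0.1).
#' @return a `module_block` list.
#' @export
module_block <- function(size, strength, conditions = NULL,
                         graded = FALSE, floor = 0.1) {
  if (size < 2) stop("module_block: `size` must be >= 2")
  if (strength < 0 || strength > 1)
    stop("module_block: `strength` must be in [0, 1]")
  if (graded && (floor <= 0 || floor >= strength))
    stop("module_block: `floor` must be in (0, strength)")
  structure(list(size = as.integer(size), strength = strength,
                 conditions = conditions, graded = graded, floor = floor),
            class = "module_block")
}

graded_loadings <- function(strength, floor, size) {
  tgt <- seq(strength, floor, length.out = size)
  sqrt(1 - 4^(-tgt * log2(20)))
}

#' Specify a synthetic expression cohort
#'
#' One control group followed by disease-stage groups, with optional planted
#' differentially-expressed (DE) genes and planted correlated modules.
#' Values are generated as Gaussian latent-factor data and mapped through a
#' fixed monotone squashing function into (0, 1\], emulating detection-
#' p-value-like inputs; all downstream statistics are rank-based, so the
#' squashing is inconsequential for them.
#'
#' @param n_genes number of genes.
#' @param conditions ordered condition codes; the first is the control.
#' @param samples_per_condition sample counts, one per condition, all >= 2.
#' @param n_de_genes number of planted DE genes (shifted in every
#'   non-control condition).
#' @param de_shift effect size of the planted shift, in within-group
#'   standard-deviation units on the latent scale.
#' @param module_blocks list of [module_block()]s; block sizes must sum to
#'   at most `n_genes` (blocks occupy disjoint leading gene slots).
#' @param noise_sd within-group standard deviation on the latent scale.
#' @param gene_level_sd spread of per-gene baseline levels, in `noise_sd`
#'   units (between-gene heterogeneity; 0 = all genes share one level).
#' @param global_strength latent correlation shared by all genes (an
#'   array-wide factor emulating global co-regulation; default 0).
#' @param seed integer seed; identical specs generate identical cohorts.
#' @return a validated `cohort_spec` list.
#' @export
cohort_spec <- function(n_genes,
                        conditions = c("C", "II", "III", "IV"),
                        samples_per_condition = c(23, 45, 31, 81),
                        n_de_genes = 0, de_shift = 0,
                        module_blocks = list(),
                        noise_sd = 1, gene_level_sd = 0,
                        global_strength = 0, seed = 1L) {
  if (n_genes < 2) stop("invalid spec: `n_genes` must be >= 2")
  if (length(conditions) < 2 || anyDuplicated(conditions))
    stop("invalid spec: `conditions` must be >= 2 distinct codes")
  if (length(samples_per_condition) != length(conditions))
    stop("invalid spec: `samples_per_condition` must match `conditions`")
  if (any(samples_per_condition < 2))
    stop("invalid spec: `samples_per_condition` must all be >= 2")
  if (n_de_genes < 0 || n_de_genes > n_genes)
    stop("invalid spec: `n_de_genes` must be in [0, n_genes]")
  if (noise_sd <= 0) stop("invalid spec: `noise_sd` must be positive")
  if (gene_level_sd < 0) stop("invalid spec: `gene_level_sd` must be >= 0")
  if (global_strength < 0 || global_strength >= 1)
    stop("invalid spec: `global_strength` must be in [0, 1)")
  for (b in module_blocks) {
    if (!inherits(b, "module_block"))
      stop("invalid spec: `module_blocks` entries must be module_block()s")
    if (!is.null(b$conditions) && !all(b$conditions %in% conditions))
      stop("invalid spec: block `conditions` must be cohort conditions")
  }
  if (sum(vapply(module_blocks, `[[`, 0L, "size")) > n_genes)
    stop("invalid spec: block sizes sum to more than `n_genes`")
  structure(list(n_genes = as.integer(n_genes),
                 conditions = as.character(conditions),
                 samples_per_condition = as.integer(samples_per_condition),
                 n_de_genes = as.integer(n_de_genes), de_shift = de_shift,
                 module_blocks = module_blocks, noise_sd = noise_sd,
                 gene_level_sd = gene_level_sd,
                 global_strength = global_strength,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a synthetic expression cohort
#'
#' Draws, per condition, a global factor, one factor per module block, and
#' per-gene noise; combines them with the loadings implied by the spec;
#' shifts planted DE genes by `de_shift * noise_sd` (latent scale) in every
#' non-control condition; and squashes values into (0, 1\] with the logistic
#' function.  Gene baseline levels and the DE-gene set are shared across
#' conditions.  Ground truth (DE set, block membership) is returned as a
#' sidecar, never embedded in the matrices.
#'
#' @param spec a [cohort_spec()].
#' @return object of class `cohort`: list with `expr` (named list of
#'   gene x sample matrices in (0, 1\], one per condition, gene rows shared),
#'   `conditions`, `control`, `truth` (list with `de_genes` and `blocks`
#'   data frame) and `spec`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  n <- spec$n_genes
  gene_ids <- sprintf("g%04d", seq_len(n))
  mu <- stats::rnorm(n, 0, spec$gene_level_sd * spec$noise_sd)
  de_idx <- if (spec$n_de_genes > 0) sort(sample.int(n, spec$n_de_genes)) else integer()

  # block membership: blocks occupy disjoint leading gene slots
  blocks <- spec$module_blocks
  memb <- rep(0L, n)
  off <- 0L
  for (bi in seq_along(blocks)) {
    memb[(off + 1L):(off + blocks[[bi]]$size)] <- bi
    off <- off + blocks[[bi]]$size
  }

  g0 <- spec$global_strength
  expr <- vector("list", length(spec$conditions))
  names(expr) <- spec$conditions
  for (ci in seq_along(spec$conditions)) {
    cond <- spec$conditions[ci]
    ns <- spec$samples_per_condition[ci]
    h <- stats::rnorm(ns)
    fs <- lapply(blocks, function(b) stats::rnorm(ns))
    noise <- matrix(stats::rnorm(n * ns), n, ns)
    lam_g <- rep(sqrt(g0), n)     # loading on the global factor
    lam_b <- rep(0, n)            # loading on the gene's block factor
    for (bi in seq_along(blocks)) {
      b <- blocks[[bi]]
      active <- is.null(b$conditions) || cond %in% b$conditions
      if (!active) next
      rows <- which(memb == bi)
      if (b$graded) {
        lam_b[rows] <- graded_loadings(b$strength, b$floor, b$size)
        lam_g[rows] <- 0
      } else {
        lam_b[rows] <- sqrt(max(b$strength - g0, 0))
      }
    }
    lam_e <- sqrt(pmax(1 - lam_g^2 - lam_b^2, 0))
    z <- lam_g * matrix(rep(h, each = n), n, ns) + lam_e * noise
    for (bi in seq_along(blocks)) {
      rows <- which(memb == bi & lam_b > 0)
      if (length(rows))
        z[rows, ] <- z[rows, ] +
          lam_b[rows] * matrix(rep(fs[[bi]], each = length(rows)), length(rows), ns)
    }
    x <- mu + spec$noise_sd * z
    if (ci > 1L && length(de_idx))
      x[de_idx, ] <- x[de_idx, ] + spec$de_shift * spec$noise_sd
    m <- stats::plogis(x)
    dimnames(m) <- list(gene_ids, sprintf("%s_s%03d", cond, seq_len(ns)))
    attr(m, "condition") <- cond
    expr[[ci]] <- m
  }
  truth_blocks <- data.frame(
    gene_id = gene_ids[memb > 0L],
    block = memb[memb > 0L],
    strength = vapply(memb[memb > 0L], function(bi) blocks[[bi]]$strength, 0),
    conditions = vapply(memb[memb > 0L], function(bi) {
      cs <- blocks[[bi]]$conditions
      if (is.null(cs)) "all" else paste(cs, collapse = ",")
    }, ""),
    stringsAsFactors = FALSE)
  structure(list(expr = expr, conditions = spec$conditions,
                 control = spec$conditions[1L],
                 truth = list(de_genes = gene_ids[de_idx],
                              blocks = truth_blocks),
                 spec = spec),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("cohort: %d genes; conditions %s (samples %s); %d DE genes; %d blocks\n",
              x$spec$n_genes, paste(x$conditions, collapse = "/"),
              paste(x$spec$samples_per_condition, collapse = "/"),
              length(x$truth$de_genes), length(x$spec$module_blocks)))
  invisible(x)
}

#' Expand a gene-level matrix into a probe-level fixture
#'
#' Builds a probe matrix containing at least one probe per gene, plus
#' `n_dup` genes covered by exactly two probes whose values average back to
#' the gene value exactly, `n_multi` probes mapping to two genes, and
#' `n_orphan` probes mapping to no gene.  The returned probe map lists every
#' probe exactly once.
#'
#' @param expr gene x sample matrix with values in (0, 1).
#' @param n_orphan,n_multi,n_dup non-negative counts.
#' @param seed integer seed for choosing duplicated genes and filler values.
#' @return list with `probes` (probe x sample matrix) and `map` (named list:
#'   probe id -> character vector of gene ids, possibly empty).
#' @export
make_probe_table <- function(expr, n_orphan = 0, n_multi = 0, n_dup = 0,
                             seed = 1L) {
  stopifnot(is.matrix(expr), !is.null(rownames(expr)))
  if (n_orphan < 0 || n_multi < 0 || n_dup < 0) stop("counts must be >= 0")
  n <- nrow(expr); ns <- ncol(expr)
  if (n_dup > n) stop("`n_dup` cannot exceed the number of genes")
  set.seed(seed)
  dup_rows <- if (n_dup > 0) sort(sample.int(n, n_dup)) else integer()
  rows <- list(); map <- list()
  for (i in seq_len(n)) {
    v <- expr[i, ]
    gid <- rownames(expr)[i]
    if (i %in% dup_rows) {
      # two probes constructed so that (a + b) / 2 == v exactly in floating
      # point: b := 2 v - fl(v - delta) is exact by Sterbenz subtraction
      delta <- pmin(v, 1 - v) / 2
      a <- v - delta
      b <- 2 * v - a
      rows[[length(rows) + 1L]] <- a; map[[length(map) + 1L]] <- gid
      rows[[length(rows) + 1L]] <- b; map[[length(map) + 1L]] <- gid
    } else {
      rows[[length(rows) + 1L]] <- v; map[[length(map) + 1L]] <- gid
    }
  }
  for (i in seq_len(n_multi)) {
    rows[[length(rows) + 1L]] <- stats::runif(ns)
    map[[length(map) + 1L]] <- rownames(expr)[sample.int(n, 2)]
  }
  for (i in seq_len(n_orphan)) {
    rows[[length(rows) + 1L]] <- stats::runif(ns)
    map[[length(map) + 1L]] <- character()
  }
  probes <- do.call(rbind, rows)
  probe_ids <- sprintf("p%05d", seq_len(nrow(probes)))
  dimnames(probes) <- list(probe_ids, colnames(expr))
  attr(probes, "condition") <- attr(expr, "condition")
  names(map) <- probe_ids
  list(probes = probes, map = map)
}

#' Reference graph topologies with known cascade behaviour
#'
#' Small named topologies used as ground-truth fixtures for the cascade
#' model: `star` (node g1 is the centre), `path`, `clique`, `cycle`, and
#' `erdos_renyi` (each edge present independently with probability `p`).
#' All edges carry the same weight.
#'
#' @param kind one of `"star"`, `"path"`, `"clique"`, `"cycle"`,
#'   `"erdos_renyi"`.
#' @param n number of nodes, >= 2.
#' @param weight edge weight (positive; default 1).
#' @param p edge probability, required for `erdos_renyi`.
#' @param seed integer seed, used by `erdos_renyi`.
#' @return a [distance_network()] with nodes `g1`..`gn`.
#' @export
reference_graph <- function(kind, n, weight = 1, p = NULL, seed = NULL) {
  if (n < 2) stop("`n` must be >= 2")
  nodes <- paste0("g", seq_len(n))
  ij <- switch(kind,
    star   = cbind(1L, 2:n),
    path   = cbind(1:(n - 1L), 2:n),
    clique = t(utils::combn(n, 2L)),
    cycle  = cbind(1:n, c(2:n, 1L)),
    erdos_renyi = {
      if (is.null(p)) stop("`p` is required for erdos_renyi")
      if (!is.null(seed)) set.seed(seed)
      all_pairs <- t(utils::combn(n, 2L))
      all_pairs[stats::runif(nrow(all_pairs)) < p, , drop = FALSE]
    },
    stop(sprintf("unknown graph kind '%s'", kind)))
  edges <- data.frame(source = nodes[ij[, 1L]], target = nodes[ij[, 2L]],
                      weight = weight, stringsAsFactors = FALSE)
  distance_network(nodes, edges)
}

#' Benchmark cohort: planted-DE selection experiment
#'
#' Four condition groups of 30 samples, 30 planted DE genes shifted by 3
#' within-group standard deviations in every disease stage — conditions under
#' which the rank-sum selection step should recover essentially every
#' planted gene at the glioma significance level.
#'
#' @param n_genes cohort size (default 300).
#' @param seed integer seed.
#' @return a [cohort_spec()].
#' @export
selection_benchmark_spec <- function(n_genes = 300, seed = 1L) {
  cohort_spec(n_genes = n_genes,
              conditions = c("C", "II", "III", "IV"),
              samples_per_condition = rep(30L, 4),
              n_de_genes = 30, de_shift = 3, seed = seed)
}

#' Benchmark cohort: disease-wired hub identifiability experiment
#'
#' A 40-gene, two-condition cohort in which every gene belongs to a single
#' graded module (hub coupling 0.90, weakest member 0.15) that is active
#' only in the disease condition.  Sample sizes are large (3000 per group)
#' so that the mutual-information estimates resolve the planted similarity
#' gradient above the finite-sample bias floor; at microarray-scale sample
#' counts the 20-bin MI estimator's bias compresses the usable similarity
#' range and the hub's separability window narrows.
#'
#' @param seed integer seed.
#' @return a [cohort_spec()]; the hub is the first gene, `g0001`.
#' @export
skg_benchmark_spec <- function(seed = 1L) {
  cohort_spec(n_genes = 40,
              conditions = c("C", "II"),
              samples_per_condition = c(3000L, 3000L),
              module_blocks = list(
                module_block(40, 0.90, conditions = "II",
                             graded = TRUE, floor = 0.15)),
              seed = seed)
}

#' Benchmark cohort: threshold-trend experiment
#'
#' A study-shaped cohort (one control and three disease stages at
#' microarray-scale sample counts) with one all-condition and one
#' disease-only planted module, used to examine how the robustness
#' statistics P and R vary along the coarse-graining threshold sweep.
#'
#' @param n_genes cohort size (default 60).
#' @param seed integer seed.
#' @return a [cohort_spec()].
#' @export
trend_benchmark_spec <- function(n_genes = 60, seed = 1L) {
  cohort_spec(n_genes,
              conditions = c("C", "II", "III", "IV"),
              samples_per_condition = c(23L, 45L, 31L, 30L),
              module_blocks = list(
                module_block(10, 0.9),
                module_block(10, 0.9, conditions = c("II", "III", "IV"))),
              gene_level_sd = 0.5, global_strength = 0.2,
              seed = seed)
}

#' Default study-shaped cohort
#'
#' Emulates the shape of the glioma study data: one control group and three
#' disease stages with 23/45/31/81 samples, planted DE genes, one planted
#' all-condition module and one disease-only module, mild gene-level spread
#' and a weak global factor.
#'
#' @param n_genes cohort size (default 200).
#' @param seed integer seed.
#' @return a [cohort_spec()].
#' @export
glioma_like_spec <- function(n_genes = 200, seed = 1L) {
  cohort_spec(n_genes = n_genes,
              conditions = c("C", "II", "III", "IV"),
              samples_per_condition = c(23L, 45L, 31L, 81L),
              n_de_genes = max(20L, round(n_genes * 0.2)),
              de_shift = 3,
              module_blocks = list(
                module_block(10, 0.9),
                module_block(10, 0.9, conditions = c("II", "III", "IV"))),
              gene_level_sd = 0.5, global_strength = 0.2,
              seed = seed)
}
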