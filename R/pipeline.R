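#' Write / read an expression matrix as TSV
#'
#' Layout: first column `gene_id`, remaining columns one per sample; values
#' at full precision (round-trip lossless).  Leading `#` comment lines carry
#' the condition and, when written by the pipeline, the configuration hash.
#'
#' @param x gene x sample numeric matrix.
#' @param path output file.
#' @param condition condition code recorded in the header (default: the
#'   matrix's `condition` attribute).
#' @param config_hash optional hash string recorded in the header.
#' @export
write_expression <- function(x, path, condition = attr(x, "condition"),
                             config_hash = NULL) {
  stopifnot(is.matrix(x), !is.null(rownames(x)))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(config_hash))
    writeLines(sprintf("# config_hash: %s", config_hash), con)
  if (!is.null(condition))
    writeLines(sprintf("# condition: %s", condition), con)
  df <- data.frame(gene_id = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_expression
#' @param metadata optional data frame with columns `sample_id` and
#'   `condition` (or a path to such a TSV); when given, every sample column
#'   must appear in it, all mapped to one condition.
#' @return `read_expression()`: the matrix, with a `condition` attribute.
#' @export
read_expression <- function(path, metadata = NULL) {
  df <- utils::read.delim(path, comment.char = "#", check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (names(df)[1L] != "gene_id")
    stop(sprintf("%s: first column must be 'gene_id'", path))
  if (anyDuplicated(df$gene_id))
    stop(sprintf("duplicate gene id(s): %s",
                 paste(unique(df$gene_id[duplicated(df$gene_id)]),
                       collapse = ", ")))
  vals <- df[, -1L, drop = FALSE]
  bad <- names(vals)[!vapply(vals, is.numeric, TRUE)]
  if (length(bad))
    stop(sprintf("non-numeric values in column(s): %s",
                 paste(bad, collapse = ", ")))
  x <- as.matrix(vals)
  rownames(x) <- df$gene_id
  # condition from the header comment, if present
  head_lines <- grep("^#", readLines(path, n = 5L), value = TRUE)
  cond_line <- grep("^# condition:", head_lines, value = TRUE)
  if (length(cond_line))
    attr(x, "condition") <- sub("^# condition:\\s*", "", cond_line[1L])
  if (!is.null(metadata)) {
    md <- if (is.character(metadata))
      utils::read.delim(metadata, comment.char = "#",
                        stringsAsFactors = FALSE) else metadata
    missing <- setdiff(colnames(x), md$sample_id)
    if (length(missing))
      stop(sprintf("sample(s) missing from metadata: %s",
                   paste(missing, collapse = ", ")))
    conds <- unique(md$condition[match(colnames(x), md$sample_id)])
    if (length(conds) != 1L)
      stop("samples of one matrix must map to a single condition")
    attr(x, "condition") <- conds
  }
  x
}

#' Write / read a probe map as TSV
#'
#' Columns `probe_id` and `gene_ids` (comma-separated, possibly empty).
#'
#' @param map named list probe id -> character vector of gene ids.
#' @param path file path.
#' @export
write_probe_map <- function(map, path) {
  df <- data.frame(probe_id = names(map),
                   gene_ids = vapply(map, paste, "", collapse = ","),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_probe_map
#' @export
read_probe_map <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                          colClasses = "character", na.strings = NULL)
  map <- lapply(df$gene_ids, function(s)
    if (is.na(s) || !nzchar(s)) character() else strsplit(s, ",")[[1L]])
  names(map) <- df$probe_id
  map
}

#' Write / read a gene set as TSV with a JSON header line
#'
#' @param gs a [gene_set()].
#' @param path file path.
#' @export
write_gene_set <- function(gs, path) {
  stopifnot(inherits(gs, "gene_set"))
  con <- file(path, "w")
  on.exit(close(con))
  hdr <- jsonlite::toJSON(list(label = gs$label, alpha = gs$alpha,
                               n = length(gs$gene_ids)), auto_unbox = TRUE)
  writeLines(paste0("# ", hdr), con)
  p <- if (is.null(gs$p_values))
    stats::setNames(rep(NA_real_, length(gs$gene_ids)), gs$gene_ids) else
    gs$p_values[gs$gene_ids]
  df <- data.frame(gene_id = gs$gene_ids, p_value = as.numeric(p),
                   stringsAsFactors = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_gene_set
#' @export
read_gene_set <- function(path) {
  hdr <- jsonlite::fromJSON(sub("^#\\s*", "", readLines(path, n = 1L)))
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  gene_set(hdr$label, hdr$alpha, df$gene_id,
           stats::setNames(df$p_value, df$gene_id))
}

#' Write an MI network as a per-threshold edge list TSV
#'
#' Columns: `source`, `target`, `nmi`, `raw_mi_bits`, `distance`.
#'
#' @param net an `mi_network`.
#' @param threshold similarity threshold defining the edge set.
#' @param path file path.
#' @param config_hash optional hash recorded in the header.
#' @export
write_network <- function(net, threshold, path, config_hash = NULL) {
  dn <- threshold_and_distance(net, threshold)
  e <- dn$edges
  idx <- cbind(match(e$source, net$gene_ids), match(e$target, net$gene_ids))
  df <- data.frame(source = e$source, target = e$target,
                   nmi = net$nmi[idx], raw_mi_bits = net$raw_mi[idx],
                   distance = e$weight, stringsAsFactors = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(config_hash))
    writeLines(sprintf("# config_hash: %s", config_hash), con)
  writeLines(sprintf("# threshold: %s", format(threshold)), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an edge-list TSV as a distance network
#'
#' Accepts either fixture edge lists (`source`, `target`, `weight`) or
#' pipeline network files (`source`, `target`, ..., `distance`).  Node set =
#' all endpoint names, plus any extra `nodes` supplied (isolated nodes are
#' not representable in an edge list).
#'
#' @param path file path.
#' @param nodes optional full node set.
#' @return a [distance_network()].
#' @export
read_edge_list <- function(path, nodes = NULL) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  wcol <- if ("weight" %in% names(df)) "weight" else "distance"
  edges <- data.frame(source = as.character(df$source),
                      target = as.character(df$target),
                      weight = df[[wcol]], stringsAsFactors = FALSE)
  if (is.null(nodes)) nodes <- unique(c(edges$source, edges$target))
  distance_network(nodes, edges)
}

#' Pipeline configuration
#'
#' Collects every tunable of the simulate - select - network - sweep - SKG
#' pipeline, with defaults fixed at the model's standard operating point:
#' tolerance `alpha = 0`, collapse threshold `t_cf = 0.5`, 20 discretization
#' bins, and the 18-value threshold sweep.
#'
#' @param cohort a [cohort_spec()] (the simulated input), or NULL when
#'   `expr_paths` is given.
#' @param expr_paths optional named character vector of expression TSV paths
#'   (condition -> file), used instead of simulation.
#' @param metadata_path optional sample-metadata TSV path.
#' @param alpha cascade tolerance parameter (default 0).
#' @param t_cf collapse threshold (default 0.5).
#' @param n_bins discretization bins (default 20).
#' @param thresholds sweep thresholds (default [default_thresholds()]).
#' @param selection_alpha rank-sum significance level (default 2.5e-7, the
#'   glioma level; the renal level is 1.5e-8).
#' @param use_selection run the rank-sum selection stage (default TRUE);
#'   when FALSE all genes enter the networks.
#' @param d_key,q,skg_window key-gene rule parameters (see [key_profiles()]).
#' @param curve_grid grid for cumulative curves (default 0..1 step 0.01).
#' @param out_dir output directory.
#' @return a validated `pipeline_config` list.
#' @export
pipeline_config <- function(cohort = NULL, expr_paths = NULL,
                            metadata_path = NULL,
                            alpha = 0, t_cf = 0.5, n_bins = 20,
                            thresholds = default_thresholds(),
                            selection_alpha = 2.5e-7, use_selection = TRUE,
                            d_key = 0.5, q = 0.5, skg_window = c(0, 0.65),
                            curve_grid = seq(0, 1, by = 0.01),
                            out_dir = tempfile("micascade_run_")) {
  if (is.null(cohort) && is.null(expr_paths))
    stop("either `cohort` or `expr_paths` must be given")
  if (!is.null(cohort)) stopifnot(inherits(cohort, "cohort_spec"))
  if (!length(thresholds)) stop("`thresholds` must be non-empty")
  if (any(thresholds < 0 | thresholds >= 1))
    stop("thresholds must lie in [0, 1)")
  if (alpha < 0) stop("`alpha` must be >= 0")
  if (t_cf <= 0 || t_cf > 1) stop("`t_cf` must be in (0, 1]")
  if (selection_alpha <= 0 || selection_alpha >= 1)
    stop("`selection_alpha` must be in (0, 1)")
  structure(list(cohort = cohort, expr_paths = expr_paths,
                 metadata_path = metadata_path,
                 alpha = alpha, t_cf = t_cf, n_bins = n_bins,
                 thresholds = thresholds,
                 selection_alpha = selection_alpha,
                 use_selection = use_selection,
                 d_key = d_key, q = q, skg_window = skg_window,
                 curve_grid = curve_grid, out_dir = out_dir),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Stages: simulate (or read) the cohort; rank-sum gene selection against
#' the control group with stage intersection; per-condition discretization
#' and NMI network construction; cascading-failure threshold sweep;
#' structural-key-gene classification.  Every intermediate artifact is
#' written under `config$out_dir`, together with a JSON run manifest; given
#' the same configuration (including the cohort seed) the numeric outputs
#' are reproduced identically.
#'
#' @param config a [pipeline_config()].
#' @return (invisibly) a list with the cohort, gene sets, working set,
#'   networks, sweeps, curves, SKG table and manifest.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  t_start <- Sys.time()
  hash <- rlang::hash(config[setdiff(names(config), "out_dir")])
  out <- config$out_dir
  for (d in file.path(out, c("data", "selection", "networks", "cascades")))
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package = "micascade",
                   version = as.character(utils::packageVersion("micascade")),
                   r_version = R.version.string,
                   config_hash = hash,
                   seed = if (!is.null(config$cohort)) config$cohort$seed,
                   config = config_echo(config),
                   stages = list())
  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e) {
      manifest$stages[[name]] <<- list(status = "error",
                                       message = conditionMessage(e))
      write_manifest(manifest, out)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
    dt <- as.numeric(Sys.time() - t0, units = "secs")
    message(sprintf("[%s] done in %.1fs", name, dt))
    list(res = res, secs = dt)
  }

  ## -- simulate / load ------------------------------------------------
  sim <- stage("simulate", {
    if (!is.null(config$cohort)) generate_cohort(config$cohort)
    else {
      expr <- lapply(config$expr_paths, read_expression,
                     metadata = config$metadata_path)
      names(expr) <- names(config$expr_paths)
      structure(list(expr = expr, conditions = names(expr),
                     control = names(expr)[1L],
                     truth = NULL, spec = NULL), class = "cohort")
    }
  })
  cohort <- sim$res
  md <- do.call(rbind, lapply(cohort$conditions, function(cc)
    data.frame(sample_id = colnames(cohort$expr[[cc]]), condition = cc,
               stringsAsFactors = FALSE)))
  utils::write.table(md, file.path(out, "data", "metadata.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (cc in cohort$conditions)
    write_expression(cohort$expr[[cc]],
                     file.path(out, "data", paste0(cc, ".tsv")),
                     condition = cc, config_hash = hash)
  manifest$stages$simulate <- list(status = "ok", secs = sim$secs,
                                   n_genes = nrow(cohort$expr[[1L]]),
                                   conditions = cohort$conditions,
                                   samples = vapply(cohort$expr, ncol, 0L))

  ## -- selection -------------------------------------------------------
  control_cc <- cohort$control
  stages_cc <- setdiff(cohort$conditions, control_cc)
  sel <- stage("select", {
    if (!config$use_selection) {
      list(sets = NULL,
           working = gene_set("all", 0.5, rownames(cohort$expr[[1L]])))
    } else {
      sets <- lapply(stages_cc, function(cc)
        rank_sum_select(cohort$expr[[control_cc]], cohort$expr[[cc]],
                        alpha = config$selection_alpha,
                        label = paste0("GI_", cc)))
      names(sets) <- stages_cc
      working <- intersect_stages(sets, label = "G1")
      if (length(working$gene_ids) < 2L)
        stop("fewer than 2 genes survive selection")
      list(sets = sets, working = working)
    }
  })
  working <- sel$res$working
  if (!is.null(sel$res$sets)) {
    for (cc in names(sel$res$sets))
      write_gene_set(sel$res$sets[[cc]],
                     file.path(out, "selection", paste0("GI_", cc, ".tsv")))
    write_gene_set(working, file.path(out, "selection", "G1.tsv"))
  }
  manifest$stages$select <- list(
    status = "ok", secs = sel$secs,
    alpha = config$selection_alpha,
    n_per_stage = if (!is.null(sel$res$sets))
      vapply(sel$res$sets, function(s) length(s$gene_ids), 0L),
    n_working = length(working$gene_ids))

  ## -- networks --------------------------------------------------------
  nets <- stage("network", {
    lapply(cohort$conditions, function(cc) {
      m <- cohort$expr[[cc]][working$gene_ids, , drop = FALSE]
      nmi_matrix(discretize(m, n_bins = config$n_bins))
    })
  })
  networks <- stats::setNames(nets$res, cohort$conditions)
  for (cc in cohort$conditions)
    for (T in config$thresholds)
      write_network(networks[[cc]], T,
                    file.path(out, "networks",
                              sprintf("%s_T%s.tsv", cc, format(T))),
                    config_hash = hash)
  manifest$stages$network <- list(
    status = "ok", secs = nets$secs, n_bins = config$n_bins,
    n_nodes = length(working$gene_ids))

  ## -- cascade sweep ----------------------------------------------------
  sw <- stage("sweep", {
    lapply(networks, threshold_sweep, thresholds = config$thresholds,
           alpha = config$alpha, t_cf = config$t_cf)
  })
  sweeps <- sw$res
  curves <- list()
  for (cc in cohort$conditions) {
    dsub <- file.path(out, "cascades", cc)
    dir.create(dsub, showWarnings = FALSE)
    s <- sweeps[[cc]]
    for (k in seq_along(s$thresholds)) {
      r <- s$results[[k]]
      df <- data.frame(gene_id = names(r$d), s_i = as.integer(r$s),
                       d_i = r$d, collapse_flag = r$collapse,
                       stringsAsFactors = FALSE)
      f <- file.path(dsub, sprintf("T%s.tsv", format(s$thresholds[k])))
      con <- file(f, "w")
      writeLines(sprintf("# config_hash: %s", hash), con)
      utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
      close(con)
    }
    con <- file(file.path(dsub, "summary.tsv"), "w")
    writeLines(sprintf("# config_hash: %s", hash), con)
    utils::write.table(s$summary, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    close(con)
    cv <- do.call(rbind, lapply(seq_along(s$thresholds), function(k)
      cbind(threshold = s$thresholds[k],
            cumulative_curve(s$results[[k]], config$curve_grid))))
    curves[[cc]] <- cv
    con <- file(file.path(dsub, "curves.tsv"), "w")
    writeLines(sprintf("# config_hash: %s", hash), con)
    utils::write.table(cv, con, sep = "\t", quote = FALSE, row.names = FALSE)
    close(con)
  }
  manifest$stages$sweep <- list(
    status = "ok", secs = sw$secs,
    n_thresholds = length(config$thresholds),
    n_cascade_tables = length(cohort$conditions) * length(config$thresholds))

  ## -- SKG ---------------------------------------------------------------
  sk <- stage("skg", {
    pr <- key_profiles(sweeps, d_key = config$d_key, q = config$q,
                       window = config$skg_window)
    classify_types(pr, control = control_cc)
  })
  skg <- sk$res
  con <- file(file.path(out, "skg.tsv"), "w")
  writeLines(sprintf("# config_hash: %s", hash), con)
  utils::write.table(as.data.frame(skg), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  close(con)
  manifest$stages$skg <- list(status = "ok", secs = sk$secs,
                              n_skg = nrow(skg),
                              types = table(skg$type))

  manifest$total_secs <- as.numeric(Sys.time() - t_start, units = "secs")
  write_manifest(manifest, out)
  message(sprintf("[pipeline] complete in %.1fs -> %s",
                  manifest$total_secs, out))
  invisible(list(cohort = cohort, gene_sets = sel$res$sets,
                 working_set = working, networks = networks,
                 sweeps = sweeps, curves = curves, skg = skg,
                 manifest = manifest, out_dir = out))
}

config_echo <- function(config) {
  e <- config[setdiff(names(config), c("cohort", "out_dir"))]
  if (!is.null(config$cohort))
    e$cohort <- config$cohort[setdiff(names(config$cohort), "module_blocks")]
  e
}

write_manifest <- function(manifest, out) {
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
}
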