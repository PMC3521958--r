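# canonical spelling order for condition codes in type labels
order_conditions <- function(codes) {
  canon <- c("C", "I", "II", "III", "IV")
  c(intersect(canon, codes), setdiff(codes, canon))
}

#' Per-gene, per-condition key profiles from cascade sweeps
#'
#' A gene is "key" in a condition if its cascade size-ratio d_i reaches
#' `d_key` at a sufficient fraction (`q`) of the sweep thresholds inside the
#' evaluation window.  The window is open: thresholds T with
#' `window[1] < T < window[2]` are evaluated, following the separability
#' window (0, 0.65) within which control and disease networks are
#' distinguishable.
#'
#' @param sweeps named list: condition code -> [threshold_sweep()].  All
#'   sweeps must share the same gene universe and threshold list.
#' @param d_key size-ratio level that counts as a large cascade
#'   (default 0.5, the collapse threshold t_cf).
#' @param q minimum fraction of window thresholds at which d_i must reach
#'   `d_key` (default 0.5).
#' @param window evaluation window (open interval; default c(0, 0.65)).
#' @return object of class `key_profiles`: list with `gene_ids`,
#'   `conditions`, matrices `frac` and `key` (genes x conditions), and the
#'   rule parameters.
#' @export
key_profiles <- function(sweeps, d_key = 0.5, q = 0.5, window = c(0, 0.65)) {
  if (!length(sweeps) || is.null(names(sweeps)))
    stop("`sweeps` must be a named list (condition -> threshold_sweep)")
  stopifnot(all(vapply(sweeps, inherits, TRUE, "threshold_sweep")))
  if (d_key <= 0 || d_key > 1 || q <= 0 || q > 1)
    stop("`d_key` and `q` must be in (0, 1]")
  gene_ids <- sweeps[[1L]]$gene_ids
  thr <- sweeps[[1L]]$thresholds
  for (s in sweeps) {
    if (!identical(s$gene_ids, gene_ids))
      stop("sweeps do not share the same gene universe")
    if (!identical(s$thresholds, thr))
      stop("sweeps do not share the same threshold list")
  }
  inside <- thr > window[1L] & thr < window[2L]
  if (!any(inside))
    stop("no sweep thresholds inside the evaluation window")
  frac <- vapply(sweeps, function(s)
    rowMeans(s$d[, inside, drop = FALSE] >= d_key), numeric(length(gene_ids)))
  frac <- matrix(frac, nrow = length(gene_ids),
                 dimnames = list(gene_ids, names(sweeps)))
  structure(list(gene_ids = gene_ids, conditions = names(sweeps),
                 frac = frac, key = frac >= q,
                 d_key = d_key, q = q, window = window,
                 thresholds = thr[inside]),
            class = "key_profiles")
}

#' Classify structural key genes by their cross-condition cascade profile
#'
#' Every gene that is key in at least one condition becomes a structural key
#' gene (SKG) and receives the type label `"T_"` followed by its key
#' condition codes joined by `"_"` in the fixed order C < I < II < III < IV.
#' Genes key nowhere are excluded.  An annotation column summarises the
#' pattern relative to the control condition: `disease-only`,
#' `control-only`, `all-conditions`, or `mixed`.
#'
#' @param profiles a [key_profiles()] result.
#' @param control the control condition code (default: first condition).
#' @return data frame of class `skg_table`: `gene_id`, `type`, `annotation`,
#'   one `key_<cond>` flag and one `frac_<cond>` column per condition;
#'   sorted by type then gene id.
#' @export
classify_types <- function(profiles, control = profiles$conditions[1L]) {
  stopifnot(inherits(profiles, "key_profiles"))
  key <- profiles$key
  sel <- which(rowSums(key) > 0L)
  conds <- order_conditions(profiles$conditions)
  rec <- lapply(sel, function(i) {
    members <- conds[conds %in% profiles$conditions[key[i, ]]]
    type <- paste0("T_", paste(members, collapse = "_"))
    ann <- if (setequal(members, profiles$conditions)) "all-conditions"
           else if (identical(members, control)) "control-only"
           else if (!control %in% members) "disease-only"
           else "mixed"
    data.frame(gene_id = profiles$gene_ids[i], type = type,
               annotation = ann, stringsAsFactors = FALSE)
  })
  out <- if (length(rec)) do.call(rbind, rec) else
    data.frame(gene_id = character(), type = character(),
               annotation = character(), stringsAsFactors = FALSE)
  flags <- profiles$key[out$gene_id, , drop = FALSE]
  fracs <- profiles$frac[out$gene_id, , drop = FALSE]
  colnames(flags) <- paste0("key_", profiles$conditions)
  colnames(fracs) <- paste0("frac_", profiles$conditions)
  out <- cbind(out, as.data.frame(flags), as.data.frame(fracs))
  out <- out[order(out$type, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("skg_table", "data.frame")
  out
}
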