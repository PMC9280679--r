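#' Range/percentile separation rule
#'
#' TRUE when the two expression distributions are cleanly separated: the
#' whole signal range of the high-expression group lies above the 75th
#' percentile of the low group AND the whole range of the low group lies
#' below the 25th percentile of the high group (strict inequalities; a tie
#' at either boundary — including one only at floating-point resolution —
#' fails). Quantiles use linear interpolation (type 7).
#'
#' @param high_values Sample values of the group with the larger mean
#'   (>= 3 values).
#' @param low_values Sample values of the other group (>= 3 values).
#' @return Logical scalar.
#' @export
range_percentile_rule <- function(high_values, low_values) {
  if (length(high_values) < 3L || length(low_values) < 3L)
    stop("range_percentile_rule needs >= 3 values per group")
  q_low <- quantile(low_values, 0.75, names = FALSE, type = 7)
  q_high <- quantile(high_values, 0.25, names = FALSE, type = 7)
  # relative guard band so boundary ties fail regardless of the last-ulp
  # rounding of the interpolated quantile
  tol_low <- 1e-9 * max(1, abs(q_low))
  tol_high <- 1e-9 * max(1, abs(q_high))
  (min(high_values) - q_low) > tol_low &&
    (q_high - max(low_values)) > tol_high
}

#' Selection strategy 1: top expressed, then most significant, then
#' range-separated
#'
#' From the sepsis-vs-SIRS DEGs, two pools of the
#' `config$strategy1_pool_size` genes with the highest mean expression in
#' sepsis and in SIRS respectively are joined. The joined pool is ranked by
#' ascending sepsis-vs-SIRS FDR-adjusted p and the top
#' `config$strategy1_top_k` are retained; genes on
#' `config$exclusion_list` are dropped from that shortlist without
#' promoting lower-ranked genes. Finally, every remaining pool gene whose
#' sepsis/SIRS sample values pass [range_percentile_rule()] is added.
#'
#' @param table A `dge_table` from [fit_dge()].
#' @param expr The expression matrix the table was fitted on.
#' @param samples The matching [sample_table()].
#' @param config An [analysis_config()].
#' @return List of class `strategy1_selection`: `selected` (character),
#'   `core` (q-ranked shortlist after exclusions), `range_additions`,
#'   `pool`, `ranked_pool`.
#' @export
select_strategy1 <- function(table, expr, samples,
                             config = analysis_config()) {
  stopifnot(inherits(table, "dge_table"))
  degs <- table[table$deg_sepsis_vs_SIRS, , drop = FALSE]
  if (!nrow(degs))
    return(structure(list(selected = character(), core = character(),
                          range_additions = character(),
                          pool = character(), ranked_pool = character()),
                     class = "strategy1_selection"))
  top_by <- function(col) {
    ord <- order(-degs[[col]], degs$gene)
    degs$gene[head(ord, config$strategy1_pool_size)]
  }
  pool <- union(top_by("mean_sepsis"), top_by("mean_SIRS"))
  if (length(pool) < config$strategy1_top_k)
    warning("strategy-1 pool (", length(pool),
            ") smaller than top_k; taking all")
  pd <- table[match(pool, table$gene), , drop = FALSE]
  ranked_pool <- pool[order(pd$q_sepsis_vs_SIRS, pd$p_sepsis_vs_SIRS,
                            pd$gene)]
  core <- setdiff(head(ranked_pool, config$strategy1_top_k),
                  config$exclusion_list)

  sep_cols <- samples$sample_id[samples$group == "sepsis"]
  sirs_cols <- samples$sample_id[samples$group == "SIRS"]
  candidates <- setdiff(ranked_pool, c(core, config$exclusion_list))
  range_hit <- vapply(candidates, function(g) {
    a <- expr[g, sep_cols]
    b <- expr[g, sirs_cols]
    if (mean(a) >= mean(b)) range_percentile_rule(a, b)
    else range_percentile_rule(b, a)
  }, NA)
  additions <- candidates[range_hit]
  structure(list(selected = c(core, additions), core = core,
                 range_additions = additions, pool = pool,
                 ranked_pool = ranked_pool),
            class = "strategy1_selection")
}

#' Selection strategy 2: sepsis-specific fold-change gates
#'
#' Selects DEGs whose sepsis-vs-SIRS linear fold-change magnitude exceeds
#' `config$strategy2_fc_high` while the SIRS-vs-presurgical magnitude stays
#' below `config$strategy2_fc_low` (a sepsis effect absent from sterile
#' inflammation).
#'
#' @param table A `dge_table`.
#' @param config An [analysis_config()].
#' @return Character vector of gene ids.
#' @export
select_strategy2 <- function(table, config = analysis_config()) {
  stopifnot(inherits(table, "dge_table"))
  any_deg <- table$deg_sepsis_vs_presurgical | table$deg_SIRS_vs_presurgical |
    table$deg_sepsis_vs_SIRS
  hit <- any_deg &
    abs(table$fc_sepsis_vs_SIRS) > config$strategy2_fc_high &
    abs(table$fc_SIRS_vs_presurgical) < config$strategy2_fc_low
  table$gene[hit]
}

#' Selection strategy 3: lysosomal genes from the high-expression pool
#'
#' Intersects the strategy-1 joined top-expression pool with a lysosomal
#' gene list (hLGDB-style) and reports which members are new relative to
#' the genes already selected by the other strategies.
#'
#' @param pool Character vector: the joined top-expression pool
#'   (`$pool` of a [select_strategy1()] result).
#' @param lysosome_set A [gene_set_collection()] (all member sets are
#'   pooled) or a character vector of lysosomal gene ids.
#' @param already_selected Genes selected by strategies 1 and 2.
#' @return List of class `strategy3_selection`: `selected`, `new`.
#' @export
select_strategy3 <- function(pool, lysosome_set,
                             already_selected = character()) {
  if (inherits(lysosome_set, "gene_set_collection"))
    lysosome_set <- unique(unlist(lysosome_set, use.names = FALSE))
  lysosome_set <- as.character(lysosome_set)
  if (!length(lysosome_set)) stop("lysosome gene set is empty")
  selected <- intersect(pool, lysosome_set)
  structure(list(selected = selected,
                 new = setdiff(selected, already_selected)),
            class = "strategy3_selection")
}

#' Merge strategy selections into one nonredundant table
#'
#' @param s1,s2,s3 Gene lists (character vectors) or the structured results
#'   of the respective strategy functions.
#' @return data.frame of class `selection_table`: `gene`, logical flags
#'   `strategy1`, `strategy2`, `strategy3`, and strategy-1 provenance
#'   (`s1_rank`: position in the q-ranked pool, `s1_range_hit`).
#' @export
merge_selection <- function(s1, s2, s3 = character()) {
  prov_rank <- NULL
  prov_range <- NULL
  if (inherits(s1, "strategy1_selection")) {
    prov_rank <- stats::setNames(seq_along(s1$ranked_pool), s1$ranked_pool)
    prov_range <- s1$range_additions
    s1 <- s1$selected
  }
  if (inherits(s3, "strategy3_selection")) s3 <- s3$selected
  s1 <- as.character(s1); s2 <- as.character(s2); s3 <- as.character(s3)
  genes <- unique(c(s1, s2, s3))
  out <- data.frame(gene = genes,
                    strategy1 = genes %in% s1,
                    strategy2 = genes %in% s2,
                    strategy3 = genes %in% s3,
                    stringsAsFactors = FALSE)
  out$s1_rank <- if (is.null(prov_rank)) NA_integer_ else
    unname(prov_rank[out$gene])
  out$s1_range_hit <- if (is.null(prov_range)) NA else
    out$gene %in% prov_range
  class(out) <- c("selection_table", "data.frame")
  out
}
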