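#' Summarize granule-compartment signature expression per patient group
#'
#' For each compartment signature (AG, SG, GG, FG, SV, CM) present in the
#' expression universe: per-gene arithmetic group means on the linear
#' scale, per-gene pairwise mean differences for the three group
#' comparisons, and the compartment's global expression per group — the
#' unweighted mean over the complete signature genes-in-universe of the
#' per-gene group means — together with the between-group fold matrix.
#' When a `dge_table` is supplied, the heat-map gene list is additionally
#' restricted to DEGs (significant in any contrast) while global summaries
#' keep the full signature.
#'
#' @param expr Linear-scale expression matrix.
#' @param samples A [sample_table()].
#' @param sigs A [gene_set_collection()] of compartment signatures.
#' @param deg_filter Optional `dge_table` used to restrict heat-map genes.
#' @return List of class `signature_summary`; per compartment: `present`,
#'   `genes`, `heatmap_genes`, `n_deg`, `n_full`, `group_means` (gene x
#'   group), `mean_differences` (gene x contrast), `global_means` (named
#'   per group), `fold_matrix` (group x group, row/col ratio).
#' @export
summarize_compartment <- function(expr, samples, sigs, deg_filter = NULL) {
  validate_expression_matrix(expr)
  stopifnot(inherits(sigs, "gene_set_collection"))
  groups <- as.character(unique(samples$group))
  groups <- granulosig_groups[granulosig_groups %in% groups]
  deg_genes <- NULL
  if (!is.null(deg_filter)) {
    stopifnot(inherits(deg_filter, "dge_table"))
    flags <- as.matrix(deg_filter[paste0("deg_", granulosig_contrasts)])
    deg_genes <- deg_filter$gene[rowSums(flags) > 0L]
  }
  res <- lapply(names(sigs), function(comp) {
    genes <- intersect(sigs[[comp]], rownames(expr))
    if (!length(genes))
      return(list(present = FALSE, genes = character(),
                  n_full = length(sigs[[comp]])))
    gm <- vapply(groups, function(g) {
      ids <- samples$sample_id[samples$group == g]
      rowMeans(expr[genes, ids, drop = FALSE])
    }, numeric(length(genes)))
    gm <- matrix(gm, nrow = length(genes), dimnames = list(genes, groups))
    diffs <- vapply(granulosig_contrasts, function(ct) {
      gg <- split_contrast(ct)
      if (!all(gg %in% groups)) return(rep(NA_real_, length(genes)))
      gm[, gg[1L]] - gm[, gg[2L]]
    }, numeric(length(genes)))
    diffs <- matrix(diffs, nrow = length(genes),
                    dimnames = list(genes, granulosig_contrasts))
    global <- colMeans(gm)
    fold <- outer(global, global, "/")
    list(present = TRUE, genes = genes,
         heatmap_genes = if (is.null(deg_genes)) genes else
           intersect(genes, deg_genes),
         n_deg = if (is.null(deg_genes)) NA_integer_ else
           length(intersect(genes, deg_genes)),
         n_full = length(sigs[[comp]]),
         group_means = gm, mean_differences = diffs,
         global_means = global, fold_matrix = fold)
  })
  names(res) <- names(sigs)
  class(res) <- "signature_summary"
  res
}

#' Global compartment expression scalars and fold matrices
#'
#' Extracts from a [summarize_compartment()] result the per-compartment,
#' per-group global expression scalar (mean over signature genes of the
#' per-gene group means) and the pairwise between-group fold matrices.
#'
#' @param summary A `signature_summary`.
#' @return List: `global` (data.frame compartment x group scalars) and
#'   `folds` (named list of group x group fold matrices).
#' @export
global_compartment_expression <- function(summary) {
  stopifnot(inherits(summary, "signature_summary"))
  present <- names(summary)[vapply(summary, `[[`, TRUE, "present")]
  if (!length(present)) stop("no compartment present in the universe")
  groups <- names(summary[[present[1L]]]$global_means)
  global <- do.call(rbind, lapply(present, function(comp) {
    data.frame(compartment = comp,
               t(summary[[comp]]$global_means),
               check.names = FALSE, stringsAsFactors = FALSE)
  }))
  folds <- lapply(present, function(comp) summary[[comp]]$fold_matrix)
  names(folds) <- present
  list(global = global, folds = folds)
}
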