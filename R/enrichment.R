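#' Rank genes by a signed two-group contrast statistic
#'
#' Genes are ranked by the pooled-variance two-group t statistic on log2
#' intensities (first contrast group minus second), descending; ties are
#' broken by gene id. The statistic is identical to the contrast t used by
#' [fit_dge()].
#'
#' @param expr Linear-scale expression matrix.
#' @param samples A [sample_table()].
#' @param contrast Length-2 character vector of group names (high side
#'   first), or a contrast name from [granulosig_contrasts].
#' @return data.frame with columns `gene` and `stat`, sorted.
#' @export
rank_genes <- function(expr, samples, contrast = c("sepsis", "SIRS")) {
  validate_expression_matrix(expr)
  if (length(contrast) == 1L) contrast <- split_contrast(contrast)
  if (!all(contrast %in% granulosig_groups))
    stop("contrast groups must be in: ",
         paste(granulosig_groups, collapse = ", "))
  idx <- match(samples$sample_id, colnames(expr))
  if (anyNA(idx))
    stop("sample(s) missing from expression matrix: ",
         paste(samples$sample_id[is.na(idx)], collapse = ", "))
  expr <- expr[, idx, drop = FALSE]
  cols_a <- which(samples$group == contrast[1L])
  cols_b <- which(samples$group == contrast[2L])
  if (length(cols_a) < 2L || length(cols_b) < 2L)
    stop("both contrast groups need >= 2 samples")
  tt <- row_t(log2(expr), cols_a, cols_b)
  out <- data.frame(gene = rownames(expr), stat = tt$t,
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(-out$stat, out$gene), , drop = FALSE]
}

#' Weighted running-sum enrichment score
#'
#' With genes sorted by the ranking statistic, the running sum at position i
#' is the weighted cumulative fraction of set members encountered
#' (weight = |statistic|^`weight_exponent`) minus the uniform position
#' fraction i/N; the enrichment score is the running sum at its extreme
#' deviation. It always starts from and returns to 0, lies in [-1, 1], and
#' is 0 by convention when the set covers the whole universe (no
#' discriminating information).
#'
#' @param ranked Sorted data.frame from [rank_genes()] (columns `gene`,
#'   `stat`).
#' @param gene_set Character vector of member gene ids.
#' @param weight_exponent Exponent on |statistic| for the hit weights
#'   (default 1; 0 gives the unweighted score).
#' @return Scalar enrichment score.
#' @export
enrichment_score <- function(ranked, gene_set, weight_exponent = 1) {
  hits <- ranked$gene %in% gene_set
  nh <- sum(hits)
  n <- nrow(ranked)
  if (nh == 0L) stop("gene set has no members in the ranked universe")
  if (nh == n) return(0)
  w <- abs(ranked$stat)^weight_exponent
  wh <- w * hits
  tot <- sum(wh)
  if (tot == 0) {              # all member statistics are 0: fall back to
    wh <- as.numeric(hits)     # unweighted hits
    tot <- nh
  }
  s <- cumsum(wh) / tot - seq_len(n) / n
  s[which.max(abs(s))]
}

#' Rank-based gene-set enrichment with a permutation null
#'
#' Computes the weighted running-sum enrichment score per set, a null ES
#' distribution from label permutations, a normalized enrichment score
#' (NES = ES / mean |null ES| of matching sign), a permutation p-value, and
#' FDR-q values by the sign-pooled null convention. The default null
#' permutes sample labels between the two contrast groups and recomputes
#' the ranking (preserving inter-gene correlation); `null = "gene"`
#' permutes gene positions instead (for very small cohorts) and works from
#' `ranked` alone.
#'
#' @param sets A [gene_set_collection()].
#' @param config An [analysis_config()] (`n_permutations`, `seed`).
#' @param expr,samples,contrast Required for the sample-label null: the
#'   expression matrix, sample table and contrast passed to [rank_genes()].
#' @param ranked Pre-computed ranking (required for the gene null if `expr`
#'   is not given; recomputed internally otherwise).
#' @param null `"sample"` (default) or `"gene"`.
#' @param min_set_size Sets with fewer members in the universe are skipped
#'   with a warning (default 5).
#' @param weight_exponent Passed to [enrichment_score()].
#' @return data.frame of class `enrichment_table`: pathway, class, size,
#'   `ES`, `NES`, `p`, `fdr_q`, `enriched_group`.
#' @export
run_enrichment <- function(sets, config = analysis_config(),
                           expr = NULL, samples = NULL,
                           contrast = c("sepsis", "SIRS"),
                           ranked = NULL,
                           null = c("sample", "gene"),
                           min_set_size = 5L, weight_exponent = 1) {
  null <- match.arg(null)
  stopifnot(inherits(sets, "gene_set_collection"))
  if (length(contrast) == 1L) contrast <- split_contrast(contrast)
  if (null == "sample" && (is.null(expr) || is.null(samples)))
    stop("the sample-label null needs expr and samples")
  if (is.null(ranked)) {
    if (is.null(expr)) stop("provide ranked or expr+samples")
    ranked <- rank_genes(expr, samples, contrast)
  }
  universe <- ranked$gene
  sizes <- vapply(sets, function(g) sum(universe %in% g), 1L)
  keep <- sizes >= min_set_size
  if (any(!keep))
    warning("skipping set(s) below size floor ", min_set_size, ": ",
            paste(names(sets)[!keep], collapse = ", "))
  if (!any(keep)) stop("no gene set meets the size floor")
  set_names <- names(sets)[keep]

  es_obs <- vapply(set_names, function(nm)
    enrichment_score(ranked, sets[[nm]], weight_exponent), 0)

  set.seed(config$seed)
  nperm <- config$n_permutations
  es_null <- matrix(NA_real_, nperm, length(set_names),
                    dimnames = list(NULL, set_names))
  if (null == "sample") {
    in_ct <- samples$group %in% contrast
    sub <- samples[in_ct, , drop = FALSE]
    for (b in seq_len(nperm)) {
      perm <- sub
      perm$group <- sample(sub$group)
      rk <- rank_genes(expr, perm, contrast)
      for (nm in set_names)
        es_null[b, nm] <- enrichment_score(rk, sets[[nm]], weight_exponent)
    }
  } else {
    stat_sorted <- ranked$stat
    for (b in seq_len(nperm)) {
      rk <- data.frame(gene = sample(universe), stat = stat_sorted,
                       stringsAsFactors = FALSE)
      for (nm in set_names)
        es_null[b, nm] <- enrichment_score(rk, sets[[nm]], weight_exponent)
    }
  }

  # per-set sign-conditional normalization factors
  norm_pos <- apply(es_null, 2L, function(e) {
    m <- mean(e[e > 0]); if (!is.finite(m) || m == 0) mean(abs(e)) else m
  })
  norm_neg <- apply(es_null, 2L, function(e) {
    m <- mean(abs(e[e < 0])); if (!is.finite(m) || m == 0) mean(abs(e)) else m
  })
  nes_obs <- ifelse(es_obs >= 0, es_obs / norm_pos, es_obs / norm_neg)
  nes_null <- sweep(pmax(es_null, 0), 2L, norm_pos, "/") +
    sweep(pmin(es_null, 0), 2L, norm_neg, "/")

  p <- vapply(seq_along(set_names), function(j) {
    e <- es_obs[j]; nullj <- es_null[, j]
    same <- if (e >= 0) nullj[nullj >= 0] else nullj[nullj < 0]
    (sum(abs(same) >= abs(e)) + 1) / (length(same) + 1)
  }, 0)

  pooled <- as.vector(nes_null)
  fdr_q <- vapply(seq_along(set_names), function(j) {
    nes <- nes_obs[j]
    if (nes >= 0) {
      num_d <- sum(pooled >= 0)
      num <- if (num_d) sum(pooled >= nes) / num_d else 0
      den_d <- sum(nes_obs >= 0)
      den <- if (den_d) sum(nes_obs >= nes) / den_d else 1
    } else {
      num_d <- sum(pooled < 0)
      num <- if (num_d) sum(pooled <= nes) / num_d else 0
      den_d <- sum(nes_obs < 0)
      den <- if (den_d) sum(nes_obs <= nes) / den_d else 1
    }
    min(1, if (den > 0) num / den else 1)
  }, 0)

  classes <- attr(sets, "classes")[set_names]
  out <- data.frame(pathway = set_names,
                    class = unname(classes),
                    size = unname(sizes[set_names]),
                    ES = unname(es_obs), NES = unname(nes_obs),
                    p = p, fdr_q = fdr_q,
                    enriched_group = ifelse(es_obs >= 0, contrast[1L],
                                            contrast[2L]),
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("enrichment_table", "data.frame")
  out
}
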