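# Row-wise one-way fixed-effects ANOVA on a numeric matrix (rows = genes).
# Returns F p-values. Degenerate rows: all values equal -> p = 1; distinct
# group means with zero within-group variance -> MSE floored at 1e-8.
row_anova_p <- function(x, groups) {
  groups <- droplevels(factor(groups))
  k <- nlevels(groups)
  if (k < 2L) stop("ANOVA needs >= 2 groups")
  ns <- tabulate(groups)
  if (any(ns < 2L)) stop("each group needs >= 2 samples")
  n <- sum(ns)
  gm <- rowMeans(x)
  ssb <- numeric(nrow(x))
  ssw <- numeric(nrow(x))
  for (lev in seq_len(k)) {
    cols <- which(as.integer(groups) == lev)
    m <- rowMeans(x[, cols, drop = FALSE])
    ssb <- ssb + length(cols) * (m - gm)^2
    ssw <- ssw + rowSums((x[, cols, drop = FALSE] - m)^2)
  }
  msb <- ssb / (k - 1L)
  msw <- ssw / (n - k)
  msw[ssw <= 0 & ssb > 0] <- 1e-8
  p <- ifelse(ssb <= 0, 1, pf(msb / pmax(msw, .Machine$double.xmin),
                              k - 1L, n - k, lower.tail = FALSE))
  p
}

# Row-wise pooled-variance two-sample t on a numeric matrix.
# Returns list(t, p, df). Zero pooled variance with equal means -> t = 0,
# p = 1; with unequal means the variance is floored at 1e-8.
row_t <- function(x, cols_a, cols_b) {
  na <- length(cols_a); nb <- length(cols_b)
  if (na < 2L || nb < 2L) stop("each group needs >= 2 samples")
  ma <- rowMeans(x[, cols_a, drop = FALSE])
  mb <- rowMeans(x[, cols_b, drop = FALSE])
  va <- rowSums((x[, cols_a, drop = FALSE] - ma)^2)
  vb <- rowSums((x[, cols_b, drop = FALSE] - mb)^2)
  sp2 <- (va + vb) / (na + nb - 2L)
  sp2[sp2 <= 0 & ma != mb] <- 1e-8
  se <- sqrt(sp2 * (1 / na + 1 / nb))
  tt <- ifelse(se == 0, 0, (ma - mb) / ifelse(se == 0, 1, se))
  df <- na + nb - 2L
  p <- ifelse(tt == 0, 1, 2 * pt(abs(tt), df, lower.tail = FALSE))
  list(t = tt, p = p, df = df)
}

# signed linear fold change: magnitude max(r, 1/r) >= 1, sign + when the
# first group's mean is the larger
signed_fold <- function(mean_a, mean_b) {
  r <- mean_a / mean_b
  ifelse(r >= 1, r, -1 / r)
}

#' Three-group differential expression
#'
#' One-way fixed-effects ANOVA on log2 intensities gives the global F
#' p-value per gene; each of the three pairwise contrasts gets a
#' pooled-variance two-group t-test (on the two groups' log2 values),
#' Benjamini-Hochberg adjustment across all genes per contrast, a signed
#' linear fold change (ratio of arithmetic group means on the linear scale,
#' magnitude >= 1, negative when the second-named group is higher), and a
#' DEG flag at `config$alpha_fdr`.
#'
#' @param expr Linear-scale expression matrix (genes x samples).
#' @param samples A [sample_table()] covering the columns of `expr`; all
#'   three groups must have >= 2 samples.
#' @param config An [analysis_config()].
#' @return data.frame of class `dge_table`: per gene the linear group means,
#'   `F_p`, and per contrast `fc_*` (signed linear fold), `p_*`, `q_*`
#'   (BH-adjusted) and `deg_*` (logical, q <= alpha_fdr).
#' @export
fit_dge <- function(expr, samples, config = analysis_config()) {
  validate_expression_matrix(expr)
  idx <- match(samples$sample_id, colnames(expr))
  if (anyNA(idx))
    stop("sample(s) missing from expression matrix: ",
         paste(samples$sample_id[is.na(idx)], collapse = ", "))
  expr <- expr[, idx, drop = FALSE]
  grp <- samples$group
  ns <- table(grp)
  if (any(ns < 2L))
    stop("each group needs >= 2 samples; got ",
         paste(names(ns), ns, sep = "=", collapse = ", "))
  logx <- log2(expr)

  cols <- lapply(granulosig_groups, function(g) which(grp == g))
  names(cols) <- granulosig_groups
  lin_means <- vapply(granulosig_groups, function(g)
    rowMeans(expr[, cols[[g]], drop = FALSE]), numeric(nrow(expr)))

  out <- data.frame(gene = rownames(expr),
                    mean_presurgical = lin_means[, "presurgical"],
                    mean_SIRS = lin_means[, "SIRS"],
                    mean_sepsis = lin_means[, "sepsis"],
                    F_p = row_anova_p(logx, grp),
                    stringsAsFactors = FALSE, row.names = NULL)
  for (ct in granulosig_contrasts) {
    gg <- split_contrast(ct)
    tt <- row_t(logx, cols[[gg[1L]]], cols[[gg[2L]]])
    q <- p.adjust(tt$p, method = "BH")
    out[[paste0("fc_", ct)]] <- signed_fold(lin_means[, gg[1L]],
                                            lin_means[, gg[2L]])
    out[[paste0("p_", ct)]] <- tt$p
    out[[paste0("q_", ct)]] <- q
    out[[paste0("deg_", ct)]] <- q <= config$alpha_fdr
  }
  class(out) <- c("dge_table", "data.frame")
  out
}

#' Partition DEGs by the set of significant contrasts (Venn regions)
#'
#' Every gene significant in at least one contrast is assigned to exactly
#' one of the seven regions (non-empty subsets of the three contrasts).
#' Within a region, up/down tallies are reported per contrast in the region;
#' because a gene can move in opposite directions in different contrasts,
#' per-contrast tallies need not sum to the region size.
#'
#' @param table A `dge_table` from [fit_dge()].
#' @param config An [analysis_config()] (unused beyond validation; the DEG
#'   flags already encode alpha_fdr).
#' @return List of class `venn_partition` with `regions` (named list of
#'   gene-id vectors; names are contrast names joined by `+`), `summary`
#'   (data.frame: region, n, and up/down counts per member contrast) and
#'   `n_deg` (size of the DEG universe).
#' @export
venn_partition <- function(table, config = analysis_config()) {
  stopifnot(inherits(table, "dge_table"))
  flags <- as.matrix(table[paste0("deg_", granulosig_contrasts)])
  colnames(flags) <- granulosig_contrasts
  any_deg <- rowSums(flags) > 0L
  keys <- apply(flags, 1L, function(f)
    paste(granulosig_contrasts[f], collapse = "+"))
  all_keys <- unlist(lapply(1:3, function(k)
    apply(combn(granulosig_contrasts, k), 2L, paste, collapse = "+")))
  regions <- lapply(all_keys, function(k) table$gene[any_deg & keys == k])
  names(regions) <- all_keys

  summary <- do.call(rbind, lapply(all_keys, function(k) {
    members <- table$gene %in% regions[[k]]
    row <- data.frame(region = k, n = sum(members))
    for (ct in granulosig_contrasts) {
      in_ct <- ct %in% strsplit(k, "+", fixed = TRUE)[[1L]]
      fc <- table[[paste0("fc_", ct)]][members]
      row[[paste0("up_", ct)]] <- if (in_ct) sum(fc > 0) else NA_integer_
      row[[paste0("down_", ct)]] <- if (in_ct) sum(fc < 0) else NA_integer_
    }
    row
  }))
  structure(list(regions = regions, summary = summary,
                 n_deg = sum(any_deg)),
            class = "venn_partition")
}

#' Headline DEG proportions
#'
#' Computes the global fraction of the gene universe that is differentially
#' expressed, each contrast's share of the DEG universe, and the ratio of
#' the SIRS-vs-presurgical share to the sepsis-vs-presurgical share (how
#' many times more genes respond to sterile inflammation than to sepsis
#' relative to presurgical controls). Accepts either a fitted `dge_table`
#' or explicit counts (e.g. published tallies).
#'
#' @param table Optional `dge_table`; when given, counts are derived from it
#'   and the other arguments are ignored.
#' @param n_genes Size of the gene universe.
#' @param n_deg_total Number of genes significant in >= 1 contrast.
#' @param n_deg_by_contrast Named vector (names in
#'   [granulosig_contrasts]) of per-contrast DEG counts, or per-contrast
#'   percentage shares with `shares = TRUE`.
#' @param shares Interpret `n_deg_by_contrast` as percentage shares of the
#'   DEG universe rather than counts.
#' @return List: `deg_fraction_pct`, `contrast_share_pct` (named),
#'   `sirs_to_sepsis_presurgical_ratio`.
#' @export
deg_proportions <- function(table = NULL, n_genes = NULL, n_deg_total = NULL,
                            n_deg_by_contrast = NULL, shares = FALSE) {
  if (!is.null(table)) {
    stopifnot(inherits(table, "dge_table"))
    flags <- as.matrix(table[paste0("deg_", granulosig_contrasts)])
    n_genes <- nrow(table)
    n_deg_total <- sum(rowSums(flags) > 0L)
    n_deg_by_contrast <- colSums(flags)
    names(n_deg_by_contrast) <- granulosig_contrasts
    shares <- FALSE
  }
  if (is.null(n_genes) || is.null(n_deg_total))
    stop("provide a dge_table or explicit counts")
  share <- if (shares) n_deg_by_contrast else
    100 * n_deg_by_contrast / n_deg_total
  list(deg_fraction_pct = 100 * n_deg_total / n_genes,
       contrast_share_pct = share,
       sirs_to_sepsis_presurgical_ratio =
         unname(share["SIRS_vs_presurgical"] /
                  share["sepsis_vs_presurgical"]))
}
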