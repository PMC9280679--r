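#' Compare subpopulation blood counts between two groups
#'
#' Per maturation stage: arithmetic group means, the fold ratio of the
#' first group's mean over the second's, and the two-sided Mann-Whitney
#' p-value from [mann_whitney_exact()].
#'
#' @param counts Cell-count data.frame (columns `sample_id`, `group`, and
#'   the five stages; see [read_cell_counts()]).
#' @param groups Length-2 character vector, numerator group first
#'   (default sepsis vs SIRS).
#' @return data.frame: `population`, `mean_<g1>`, `mean_<g2>`, `fold`, `p`.
#' @export
compare_counts <- function(counts, groups = c("sepsis", "SIRS")) {
  stopifnot(all(granulosig_stages %in% colnames(counts)),
            "group" %in% colnames(counts))
  a_rows <- counts$group == groups[1L]
  b_rows <- counts$group == groups[2L]
  if (!any(a_rows) || !any(b_rows))
    stop("both groups must be present: ", paste(groups, collapse = ", "))
  out <- do.call(rbind, lapply(granulosig_stages, function(st) {
    a <- counts[[st]][a_rows]
    b <- counts[[st]][b_rows]
    data.frame(population = st, mean_a = mean(a), mean_b = mean(b),
               fold = mean(a) / mean(b),
               p = mann_whitney_exact(a, b)$p_value,
               stringsAsFactors = FALSE)
  }))
  colnames(out)[2:3] <- paste0("mean_", groups)
  out
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Two-sided p-value by the probability-mass rule: the sum of
#' hypergeometric probabilities of all tables with the observed margins
#' whose probability does not exceed that of the observed table (within a
#' small relative tolerance for floating-point ties).
#'
#' @param table 2x2 matrix of non-negative integer counts with positive
#'   row and column margins.
#' @return Two-sided p-value.
#' @export
fisher_exact_2x2 <- function(table) {
  tab <- as.matrix(table)
  if (!all(dim(tab) == c(2L, 2L)))
    stop("table must be 2x2")
  if (any(tab < 0) || any(tab != round(tab)) || any(!is.finite(tab)))
    stop("table entries must be non-negative integers")
  r <- rowSums(tab); cl <- colSums(tab)
  if (any(r == 0) || any(cl == 0))
    stop("all row and column margins must be positive")
  support <- max(0L, cl[1L] - r[2L]):min(r[1L], cl[1L])
  probs <- dhyper(support, r[1L], r[2L], cl[1L])
  p_obs <- dhyper(tab[1L, 1L], r[1L], r[2L], cl[1L])
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

#' Principal component analysis with centering and unit-variance scaling
#'
#' PCA on untransformed data by singular value decomposition after
#' centering and scaling each feature to unit variance. Constant features
#' (scale undefined) are dropped with a warning. Missing values either
#' raise an error or, under `zero_fill`, are set to 0 (the nominal
#' background) before scaling.
#'
#' @param x Samples x features numeric matrix or data.frame.
#' @param missing_policy `"error"` (default) or `"zero_fill"`.
#' @param scale Scale features to unit variance (default TRUE, the
#'   convention used throughout; FALSE gives covariance PCA).
#' @return List of class `pca_result`: `scores` (samples x components),
#'   `explained_variance` (fractions, all components retained), `loadings`,
#'   `dropped` (names of constant features removed).
#' @export
run_pca <- function(x, missing_policy = c("error", "zero_fill"),
                    scale = TRUE) {
  missing_policy <- match.arg(missing_policy)
  x <- as.matrix(x)
  if (nrow(x) < 2L || ncol(x) < 2L)
    stop("PCA needs >= 2 samples and >= 2 features")
  if (anyNA(x)) {
    if (missing_policy == "error")
      stop("missing values present; use missing_policy = 'zero_fill' ",
           "to set them to 0 before scaling")
    x[is.na(x)] <- 0
  }
  sds <- apply(x, 2L, sd)
  constant <- sds == 0 | !is.finite(sds)
  dropped <- colnames(x)[constant]
  if (any(constant) && scale) {
    warning("dropping constant feature(s): ",
            paste(dropped, collapse = ", "))
    x <- x[, !constant, drop = FALSE]
    if (ncol(x) < 2L) stop("fewer than 2 non-constant features remain")
  } else dropped <- character()
  fit <- prcomp(x, center = TRUE, scale. = scale)
  ev <- fit$sdev^2 / sum(fit$sdev^2)
  structure(list(scores = fit$x, explained_variance = ev,
                 loadings = fit$rotation, dropped = dropped),
            class = "pca_result")
}

#' Standardized group separation along a principal component
#'
#' Absolute difference of the two group means of the component scores,
#' divided by the pooled within-group standard deviation.
#'
#' @param pca A `pca_result` from [run_pca()].
#' @param groups Group label per sample (length = rows of the score
#'   matrix); exactly two distinct labels required.
#' @param component Component index (default 1).
#' @return Non-negative scalar separation.
#' @export
pc_separation <- function(pca, groups, component = 1L) {
  stopifnot(inherits(pca, "pca_result"))
  sc <- pca$scores[, component]
  groups <- as.character(groups)
  lv <- unique(groups)
  if (length(lv) != 2L) stop("exactly two groups required")
  a <- sc[groups == lv[1L]]; b <- sc[groups == lv[2L]]
  sp <- sqrt(((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
               (length(a) + length(b) - 2))
  if (sp == 0) return(Inf)
  abs(mean(a) - mean(b)) / sp
}
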