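#' Normalize a bead-array plate
#'
#' Technical duplicates are averaged; each gene's duplicate mean is divided
#' by the reference gene's duplicate mean in the same sample. Entries whose
#' duplicate mean is at or below the plate background are set missing
#' (reason `at_or_below_background`) rather than zero, conservatively
#' reducing the per-group sample size downstream. The reference gene must
#' be above background in every sample.
#'
#' @param plate A [qgp_plate()].
#' @return List of class `normalized_qgp`: `values` (gene x sample matrix,
#'   NA where missing; the reference gene is excluded), `missing_reason`
#'   (character matrix), `reference_gene`, `background`.
#' @export
normalize_qgp <- function(plate) {
  stopifnot(inherits(plate, "qgp_plate"))
  sig <- plate$signals
  dup_mean <- (sig$rep1 + sig$rep2) / 2
  genes <- setdiff(unique(sig$gene), plate$reference_gene)
  samps <- unique(sig$sample)

  ref <- sig$gene == plate$reference_gene
  ref_mean <- stats::setNames(dup_mean[ref], sig$sample[ref])[samps]
  low_ref <- samps[ref_mean <= plate$background]
  if (length(low_ref))
    stop("reference gene at or below background in sample(s): ",
         paste(low_ref, collapse = ", "))

  values <- matrix(NA_real_, length(genes), length(samps),
                   dimnames = list(genes, samps))
  reason <- matrix(NA_character_, length(genes), length(samps),
                   dimnames = list(genes, samps))
  idx <- cbind(match(sig$gene, genes), match(sig$sample, samps))
  keep <- !is.na(idx[, 1L])
  vals <- dup_mean[keep] / ref_mean[sig$sample[keep]]
  below <- dup_mean[keep] <= plate$background
  vals[below] <- NA_real_
  values[idx[keep, , drop = FALSE]] <- vals
  reason[idx[keep, , drop = FALSE][below, , drop = FALSE]] <-
    "at_or_below_background"
  structure(list(values = values, missing_reason = reason,
                 reference_gene = plate$reference_gene,
                 background = plate$background),
            class = "normalized_qgp")
}

#' Per-gene, per-group expression confirmation
#'
#' A gene's expression counts as confirmed in a patient group when at least
#' `config$confirm_min_n` samples of that group have an above-background
#' (non-missing) normalized signal.
#'
#' @param norm A [normalize_qgp()] result.
#' @param samples A [sample_table()] covering the plate's samples.
#' @param config An [analysis_config()].
#' @return Logical matrix genes x groups, with an `n_present` attribute
#'   holding the per-cell sample counts used.
#' @export
confirm_expression <- function(norm, samples, config = analysis_config()) {
  stopifnot(inherits(norm, "normalized_qgp"))
  groups <- levels(droplevels(samples$group))
  n_present <- vapply(groups, function(g) {
    ids <- intersect(samples$sample_id[samples$group == g],
                     colnames(norm$values))
    if (!length(ids)) return(numeric(nrow(norm$values)))
    rowSums(!is.na(norm$values[, ids, drop = FALSE]))
  }, numeric(nrow(norm$values)))
  n_present <- matrix(n_present, nrow = nrow(norm$values),
                      dimnames = list(rownames(norm$values), groups))
  confirmed <- n_present >= config$confirm_min_n
  attr(confirmed, "n_present") <- n_present
  confirmed
}

#' Mann-Whitney U test (exact for small samples)
#'
#' U is the number of (a, b) pairs with a > b (ties counting 1/2). For
#' min(n, m) <= 8 and n + m <= 20 the two-sided p-value is computed
#' exactly by enumerating all assignments of the pooled observations and
#' counting those at least as far from the null mean nm/2 as the observed
#' U. Larger samples use the tie-corrected normal approximation with
#' continuity correction.
#'
#' @param a,b Numeric vectors; NAs are removed, both must remain non-empty.
#' @return List with `U` (for sample `a`) and `p_value` (two-sided), plus
#'   `method` (`"exact"` or `"normal"`).
#' @export
mann_whitney_exact <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  n1 <- length(a); n2 <- length(b)
  if (!n1 || !n2) stop("both vectors must be non-empty after NA removal")
  pooled <- c(a, b)
  r <- rank(pooled)
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2

  if (min(n1, n2) <= 8L && n1 + n2 <= 20L) {
    splits <- combn(n1 + n2, n1)
    rs <- colSums(matrix(r[splits], nrow = n1))
    u_all <- rs - n1 * (n1 + 1) / 2
    p <- mean(abs(u_all - mu) >= abs(U - mu) - 1e-9)
    return(list(U = U, p_value = p, method = "exact"))
  }
  nties <- table(r)
  n <- n1 + n2
  sigma <- sqrt((n1 * n2 / 12) *
                  ((n + 1) - sum(nties^3 - nties) / (n * (n - 1))))
  z <- U - mu
  z <- (z - sign(z) * 0.5) / sigma
  p <- min(1, 2 * min(pnorm(z), pnorm(z, lower.tail = FALSE)))
  list(U = U, p_value = p, method = "normal")
}

#' Validate shortlisted genes on normalized bead-array data
#'
#' For every selected gene with confirmed expression in both sepsis and
#' SIRS, the sepsis and SIRS normalized values (missing removed) are
#' compared by [mann_whitney_exact()]. The raw p-value receives a
#' Bonferroni adjustment per selection strategy containing the gene (m =
#' number of confirmed genes on that strategy's list) and globally (m = all
#' confirmed selected genes); the gene is validated when any adjusted p is
#' below `config$alpha_validation`. The fold change is the ratio of
#' arithmetic group means of the available values (sepsis / SIRS).
#'
#' @param norm A [normalize_qgp()] result.
#' @param samples A [sample_table()].
#' @param selection A `selection_table` from [merge_selection()].
#' @param config An [analysis_config()].
#' @return data.frame of class `validation_table`: per selected gene the
#'   confirmation flags and group sample sizes, `fold_change`, `p_mwu`,
#'   `p_adj_strategy1/2/3`, `p_adj_global`, `validated`.
#' @export
validate_degs <- function(norm, samples, selection,
                          config = analysis_config()) {
  stopifnot(inherits(norm, "normalized_qgp"),
            inherits(selection, "selection_table"))
  on_plate <- selection$gene %in% rownames(norm$values)
  if (any(!on_plate))
    message("gene(s) absent from plate recorded unconfirmed: ",
            paste(selection$gene[!on_plate], collapse = ", "))
  conf <- confirm_expression(norm, samples, config)
  need <- c("sepsis", "SIRS")
  if (!all(need %in% colnames(conf)))
    stop("validation needs sepsis and SIRS samples on the plate")

  genes <- selection$gene
  confirmed_sep <- unname(on_plate &
                            conf[match(genes, rownames(conf)), "sepsis"])
  confirmed_sirs <- unname(on_plate &
                             conf[match(genes, rownames(conf)), "SIRS"])
  confirmed_sep[is.na(confirmed_sep)] <- FALSE
  confirmed_sirs[is.na(confirmed_sirs)] <- FALSE
  both <- confirmed_sep & confirmed_sirs

  m_strategy <- vapply(paste0("strategy", 1:3), function(s)
    sum(both & selection[[s]]), 1L)
  m_global <- sum(both)

  sep_ids <- samples$sample_id[samples$group == "sepsis"]
  sirs_ids <- samples$sample_id[samples$group == "SIRS"]
  sep_ids <- intersect(sep_ids, colnames(norm$values))
  sirs_ids <- intersect(sirs_ids, colnames(norm$values))

  k <- length(genes)
  out <- data.frame(gene = genes,
                    confirmed_sepsis = confirmed_sep,
                    confirmed_SIRS = confirmed_sirs,
                    n_sepsis = NA_integer_, n_SIRS = NA_integer_,
                    fold_change = NA_real_, p_mwu = NA_real_,
                    p_adj_strategy1 = NA_real_, p_adj_strategy2 = NA_real_,
                    p_adj_strategy3 = NA_real_, p_adj_global = NA_real_,
                    validated = FALSE, stringsAsFactors = FALSE)
  for (i in seq_len(k)) {
    if (!both[i]) next
    va <- norm$values[genes[i], sep_ids]
    vb <- norm$values[genes[i], sirs_ids]
    va <- va[!is.na(va)]; vb <- vb[!is.na(vb)]
    out$n_sepsis[i] <- length(va)
    out$n_SIRS[i] <- length(vb)
    out$fold_change[i] <- mean(va) / mean(vb)
    mw <- mann_whitney_exact(va, vb)
    out$p_mwu[i] <- mw$p_value
    for (s in 1:3) {
      col <- paste0("p_adj_strategy", s)
      if (selection[[paste0("strategy", s)]][i] && m_strategy[s] > 0L)
        out[[col]][i] <- min(1, m_strategy[s] * mw$p_value)
    }
    out$p_adj_global[i] <- min(1, m_global * mw$p_value)
    adj <- c(out$p_adj_strategy1[i], out$p_adj_strategy2[i],
             out$p_adj_strategy3[i], out$p_adj_global[i])
    out$validated[i] <- any(adj < config$alpha_validation, na.rm = TRUE)
  }
  attr(out, "m_strategy") <- m_strategy
  attr(out, "m_global") <- m_global
  class(out) <- c("validation_table", "data.frame")
  out
}
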