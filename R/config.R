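#' Analysis configuration
#'
#' Bundle of thresholds used across the pipeline. All defaults follow the
#' published analysis settings: FDR significance at alpha 0.05; strategy-1
#' shortlisting from two top-100 expression pools with the top 50 by
#' FDR-adjusted p retained; strategy-2 fold gates >2 (sepsis vs SIRS) and
#' <1.1 (SIRS vs presurgical); bead-array confirmation requiring signal above
#' background in at least 4 patients per group; validation significance at
#' Bonferroni-adjusted p < 0.05.
#'
#' @param alpha_fdr FDR significance threshold for differential expression.
#' @param strategy1_pool_size Size of each of the two top-mean-expression
#'   pools joined by selection strategy 1.
#' @param strategy1_top_k Number of pool genes, ranked by ascending
#'   FDR-adjusted p, retained by strategy 1 before range-rule additions.
#' @param strategy2_fc_high Lower bound (exclusive) on the sepsis-vs-SIRS
#'   linear fold-change magnitude for strategy 2.
#' @param strategy2_fc_low Upper bound (exclusive) on the SIRS-vs-presurgical
#'   fold-change magnitude for strategy 2.
#' @param confirm_min_n Minimum number of above-background samples per group
#'   for bead-array expression to count as confirmed.
#' @param alpha_validation Significance threshold applied to
#'   Bonferroni-adjusted validation p-values.
#' @param n_permutations Number of label permutations for the enrichment null.
#' @param seed Integer seed for seeded operations (enrichment permutations).
#' @param exclusion_list Character vector of gene ids dropped from
#'   strategy-1 selection (assay-level exclusions).
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(alpha_fdr = 0.05,
                            strategy1_pool_size = 100L,
                            strategy1_top_k = 50L,
                            strategy2_fc_high = 2.0,
                            strategy2_fc_low = 1.1,
                            confirm_min_n = 4L,
                            alpha_validation = 0.05,
                            n_permutations = 1000L,
                            seed = 1L,
                            exclusion_list = character()) {
  cfg <- list(alpha_fdr = alpha_fdr,
              strategy1_pool_size = as.integer(strategy1_pool_size),
              strategy1_top_k = as.integer(strategy1_top_k),
              strategy2_fc_high = strategy2_fc_high,
              strategy2_fc_low = strategy2_fc_low,
              confirm_min_n = as.integer(confirm_min_n),
              alpha_validation = alpha_validation,
              n_permutations = as.integer(n_permutations),
              seed = as.integer(seed),
              exclusion_list = as.character(exclusion_list))
  validate_analysis_config(cfg)
  class(cfg) <- "analysis_config"
  cfg
}

validate_analysis_config <- function(cfg) {
  for (nm in c("alpha_fdr", "alpha_validation")) {
    v <- cfg[[nm]]
    if (!is.numeric(v) || length(v) != 1L || v <= 0 || v >= 1)
      stop(nm, " must be a fraction in (0, 1), got ", format(v))
  }
  for (nm in c("strategy1_pool_size", "strategy1_top_k", "strategy2_fc_high",
               "strategy2_fc_low", "confirm_min_n", "n_permutations")) {
    v <- cfg[[nm]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v <= 0)
      stop(nm, " must be a positive scalar, got ", format(v))
  }
  invisible(cfg)
}

#' Read an analysis configuration from a YAML file
#'
#' Unknown keys are rejected; missing keys take their defaults.
#'
#' @param path Path to a YAML file whose keys are arguments of
#'   [analysis_config()].
#' @return An `analysis_config` object.
#' @export
read_analysis_config <- function(path) {
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  allowed <- names(formals(analysis_config))
  bad <- setdiff(names(vals), allowed)
  if (length(bad))
    stop("unknown configuration keys: ", paste(bad, collapse = ", "),
         "; allowed: ", paste(allowed, collapse = ", "))
  do.call(analysis_config, vals)
}
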