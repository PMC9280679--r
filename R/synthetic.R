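# Stage-program peak assignments. Azurophilic-granule genes transcribe at
# the promyelocyte stage, specific-granule genes at myelocyte/metamyelocyte,
# gelatinase at metamyelocyte/band, and the late compartments at band/PMN
# ("targeting by timing"). Proliferation/metabolic programs (cell cycle,
# mitochondrial, proteasome, ribosome, lysosome) are precursor programs that
# decline at the metamyelocyte stage.
program_peak_stages <- list(
  AG = "LPM", SG = c("MY", "MM"), GG = c("MM", "BC"),
  FG = c("BC", "PMN"), SV = c("BC", "PMN"), CM = c("BC", "PMN"),
  cellcycle = c("LPM", "MY"), mito = c("LPM", "MY"),
  proteasome = c("LPM", "MY"), ribosome = c("LPM", "MY"),
  lysosome = c("LPM", "MY"), housekeeping = character())

#' Synthetic-cohort configuration
#'
#' Defaults encode the published study conditions. Group mean stage
#' compositions and total CD15 counts are calibrated so that expected
#' sepsis/SIRS count folds reproduce the reported values (late promyelocytes
#' ~17x, myelocytes ~11x, metamyelocytes ~6.5x, band cells ~12x, PMN ~+23%
#' and non-significant); discovery-cohort group sizes are 11 presurgical,
#' 16 SIRS, 15 sepsis. See the methods vignette for the calibration algebra.
#'
#' @param n_genes Total number of genes (default 20000, a whole-genome-array
#'   scale universe).
#' @param n_per_group Named integer vector of samples per group
#'   (presurgical, SIRS, sepsis); a group may be 0 to omit it.
#' @param dirichlet_alpha Named list (per group) of positive length-5
#'   Dirichlet concentration vectors over the stages [granulosig_stages].
#' @param sigma_tech Log-scale (natural log) SD of multiplicative
#'   measurement noise on expression.
#' @param total_count_logmean Named per-group log mean of total CD15
#'   cells/uL.
#' @param total_count_logsd Log-scale SD of total counts.
#' @param n_program_genes Named integer vector: genes per stage program.
#' @param program_peak_ratio Named numeric vector: peak/off expression ratio
#'   per program label.
#' @param peak_ratio Fallback peak/off ratio for labels without an entry in
#'   `program_peak_ratio` (default 10).
#' @param baseline_logmean,baseline_logsd Log-normal parameters of per-gene
#'   baseline (off-stage) intensity.
#' @param qgp_gain Bead-array signal gain per unit expression.
#' @param qgp_background Plate background (fluorescence units).
#' @param qgp_background_sd SD of additive background noise on bead signals.
#' @param qgp_duplicate_cv Coefficient of variation between technical
#'   duplicates.
#' @param qgp_genes Gene ids to assay on the simulated plate (NULL: planted
#'   genes plus the 20 highest-baseline unlabelled genes).
#' @param reference_gene Id of the stable reference gene added to every
#'   cohort (constant high expression across stages).
#' @param planted_genes NULL or data.frame with columns `gene`, `group`,
#'   `effect` (> 0): multiplicative expression effects applied to one group.
#' @param seed Integer seed; all draws flow from it in a fixed order.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_genes = 20000L,
                          n_per_group = c(presurgical = 11L, SIRS = 16L,
                                          sepsis = 15L),
                          dirichlet_alpha = list(
                            presurgical = 600 * c(0.0005, 0.001, 0.003,
                                                  0.008, 0.9875),
                            SIRS = 600 * c(0.0015, 0.003, 0.008,
                                           0.015, 0.9725),
                            sepsis = 600 * c(0.0173, 0.0223, 0.0355,
                                             0.1185, 0.8064)),
                          sigma_tech = 0.3,
                          total_count_logmean = c(presurgical = log(4500),
                                                  SIRS = log(8000),
                                                  sepsis = log(11700)),
                          total_count_logsd = 0.4,
                          n_program_genes = c(AG = 30L, SG = 30L, GG = 12L,
                                              FG = 20L, SV = 20L, CM = 40L,
                                              cellcycle = 100L, mito = 100L,
                                              proteasome = 40L,
                                              ribosome = 80L,
                                              lysosome = 120L,
                                              housekeeping = 200L),
                          program_peak_ratio = c(AG = 40, SG = 12, GG = 10,
                                                 FG = 8, SV = 8, CM = 8,
                                                 cellcycle = 25, mito = 25,
                                                 proteasome = 25,
                                                 ribosome = 25,
                                                 lysosome = 25,
                                                 housekeeping = 1),
                          peak_ratio = 10,
                          baseline_logmean = log(100),
                          baseline_logsd = 1,
                          qgp_gain = 5,
                          qgp_background = 150,
                          qgp_background_sd = 15,
                          qgp_duplicate_cv = 0.1,
                          qgp_genes = NULL,
                          reference_gene = "REF1",
                          planted_genes = NULL,
                          seed = 1L) {
  cfg <- as.list(environment())
  cfg$n_per_group <- vapply(granulosig_groups, function(g) {
    v <- n_per_group[[g]]
    if (is.null(v) || is.na(v)) 0L else as.integer(v)
  }, 1L)
  names(cfg$n_per_group) <- granulosig_groups
  for (g in names(cfg$dirichlet_alpha)) {
    a <- cfg$dirichlet_alpha[[g]]
    if (length(a) != 5L || any(!is.finite(a)) || any(a <= 0))
      stop("dirichlet_alpha for group ", g,
           " must be 5 positive finite values")
    names(cfg$dirichlet_alpha[[g]]) <- granulosig_stages
  }
  if (cfg$sigma_tech < 0) stop("sigma_tech must be >= 0")
  if (!is.null(planted_genes)) {
    need <- c("gene", "group", "effect")
    if (!is.data.frame(planted_genes) ||
        !all(need %in% colnames(planted_genes)))
      stop("planted_genes must have columns: ", paste(need, collapse = ", "))
    if (any(planted_genes$effect <= 0))
      stop("planted effects must be > 0")
    bad <- setdiff(unique(planted_genes$group), granulosig_groups)
    if (length(bad)) stop("planted_genes group(s) unknown: ",
                          paste(bad, collapse = ", "))
  }
  if (sum(cfg$n_program_genes) + 1L > cfg$n_genes)
    stop("n_genes too small for the requested program genes")
  cfg$seed <- as.integer(seed)
  class(cfg) <- "cohort_config"
  cfg
}

#' Build the gene-by-stage expected-expression profile matrix
#'
#' Each labelled program gene receives a plateau profile: baseline intensity
#' at off stages, baseline times the program's peak ratio at its peak
#' stage(s). Housekeeping-labelled and unlabelled genes are constant across
#' stages. Baselines are drawn log-normally; deterministic given
#' `config$seed`.
#'
#' @param config A [cohort_config()].
#' @param reseed Reset the RNG to `config$seed` first (FALSE when called
#'   inside [simulate_cohort()], which manages one stream).
#' @return List of class `stage_profiles` with elements `stages`, `profiles`
#'   (gene x 5 matrix), `program_labels` (named character, NA for unlabelled
#'   genes) and `baselines`.
#' @export
build_stage_profiles <- function(config, reseed = TRUE) {
  stopifnot(inherits(config, "cohort_config"))
  if (reseed) set.seed(config$seed)
  npg <- config$n_program_genes
  labels <- rep(names(npg), npg)
  n_free <- config$n_genes - length(labels) - 1L  # minus reference gene
  gene_ids <- c(
    unlist(lapply(names(npg), function(p)
      sprintf("%s_%03d", toupper(p), seq_len(npg[[p]]))), use.names = FALSE),
    config$reference_gene,
    sprintf("G%05d", seq_len(n_free)))
  program_labels <- stats::setNames(
    c(labels, rep(NA_character_, n_free + 1L)), gene_ids)
  baselines <- stats::setNames(
    rlnorm(length(gene_ids), config$baseline_logmean, config$baseline_logsd),
    gene_ids)
  # the reference gene is a fixed, high, stage-constant transcript
  baselines[config$reference_gene] <- 500

  profiles <- matrix(rep(baselines, 5L), ncol = 5L,
                     dimnames = list(gene_ids, granulosig_stages))
  for (p in setdiff(names(npg), "housekeeping")) {
    ratio <- if (p %in% names(config$program_peak_ratio))
      config$program_peak_ratio[[p]] else config$peak_ratio
    peaks <- program_peak_stages[[p]]
    idx <- which(!is.na(program_labels) & program_labels == p)
    if (length(peaks) && length(idx))
      profiles[idx, peaks] <- baselines[idx] * ratio
  }
  structure(list(stages = granulosig_stages, profiles = profiles,
                 program_labels = program_labels, baselines = baselines),
            class = "stage_profiles")
}

# one Dirichlet draw per row
rdirichlet <- function(n, alpha) {
  if (any(alpha <= 0)) stop("Dirichlet concentration must be positive")
  g <- matrix(rgamma(n * length(alpha), shape = alpha), nrow = n,
              byrow = TRUE)
  sw <- rowSums(g)
  if (any(sw == 0)) {          # numerically degenerate draw: retry row-wise
    for (i in which(sw == 0)) {
      repeat {
        gi <- rgamma(length(alpha), shape = alpha)
        if (sum(gi) > 0) { g[i, ] <- gi; break }
      }
    }
    sw <- rowSums(g)
  }
  sweep(g, 1L, sw, "/")
}

#' Simulate a three-group CD15 cohort
#'
#' For sample j of group g, the stage composition pi_j is Dirichlet
#' distributed with the group's concentration vector; expected expression is
#' the composition-weighted average of the stage profiles, times any planted
#' group effects; observed expression adds multiplicative log-normal noise.
#' Subpopulation blood counts derive from the same composition:
#' counts_j = round(total_j * pi_j), coupling the expression and count
#' layers through one mechanism. A bead-array plate is simulated for the
#' configured assay genes. Byte-identical for identical seeds.
#'
#' @param config A [cohort_config()].
#' @return List with elements `expression` (matrix), `samples`
#'   ([sample_table()]), `counts` (cell-count data.frame), `qgp`
#'   ([qgp_plate()]) and `truth` (class `cohort_truth`: per-sample
#'   composition matrix `pi`, the `stage_profiles` used, planted genes and
#'   per-sample totals).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  prof <- build_stage_profiles(config, reseed = FALSE)

  groups <- granulosig_groups[config$n_per_group > 0L]
  tags <- c(presurgical = "pre", SIRS = "sirs", sepsis = "sep")
  sample_ids <- unlist(lapply(groups, function(g)
    sprintf("%s_%02d", tags[[g]], seq_len(config$n_per_group[[g]]))),
    use.names = FALSE)
  group_of <- rep(groups, config$n_per_group[groups])
  n <- length(sample_ids)
  if (!n) stop("no samples requested")

  pi <- matrix(NA_real_, n, 5L, dimnames = list(sample_ids,
                                                granulosig_stages))
  for (g in groups) {
    rows <- which(group_of == g)
    pi[rows, ] <- rdirichlet(length(rows), config$dirichlet_alpha[[g]])
  }

  mu <- prof$profiles %*% t(pi)                       # genes x samples
  if (!is.null(config$planted_genes)) {
    pg <- config$planted_genes
    missing <- setdiff(pg$gene, rownames(mu))
    if (length(missing))
      stop("planted gene(s) not in universe: ",
           paste(missing, collapse = ", "))
    for (i in seq_len(nrow(pg))) {
      cols <- which(group_of == pg$group[i])
      mu[pg$gene[i], cols] <- mu[pg$gene[i], cols] * pg$effect[i]
    }
  }
  noise <- matrix(rnorm(length(mu), 0, config$sigma_tech), nrow(mu))
  expr <- mu * exp(noise)
  dimnames(expr) <- dimnames(mu)

  totals <- stats::setNames(numeric(n), sample_ids)
  for (g in groups) {
    rows <- which(group_of == g)
    totals[rows] <- exp(rnorm(length(rows), config$total_count_logmean[[g]],
                              config$total_count_logsd))
  }
  counts <- cbind(sample_table(sample_ids, group_of),
                  as.data.frame(round(totals * pi)))

  qgp_genes <- config$qgp_genes
  if (is.null(qgp_genes)) {
    free <- names(prof$program_labels)[is.na(prof$program_labels)]
    free <- setdiff(free, config$reference_gene)
    qgp_genes <- c(unique(config$planted_genes$gene),
                   free[order(-prof$baselines[free])][seq_len(
                     min(20L, length(free)))])
  }
  qgp <- simulate_qgp(expr, config,
                      genes = unique(c(qgp_genes, config$reference_gene)),
                      reseed = FALSE)

  truth <- structure(list(pi = pi, profiles = prof,
                          planted_genes = config$planted_genes,
                          totals = totals, config = config),
                     class = "cohort_truth")
  list(expression = expr, samples = sample_table(sample_ids, group_of),
       counts = counts, qgp = qgp, truth = truth)
}

#' Simulate a bead-array plate from expression values
#'
#' Each duplicate signal is `gain * x * (1 + cv * z) + e`, with z standard
#' normal, e additive background noise, floored at the plate background so
#' that unexpressed transcripts read out at background (and are later
#' treated as missing by [normalize_qgp()]).
#'
#' @param expr Expression matrix covering at least `genes`.
#' @param config A [cohort_config()] (observation-layer parameters and
#'   seed).
#' @param genes Gene ids to assay; default all rows of `expr`. The
#'   configured reference gene is always included.
#' @param reseed Reset the RNG to `config$seed` first (FALSE inside
#'   [simulate_cohort()]).
#' @return A [qgp_plate()].
#' @export
simulate_qgp <- function(expr, config, genes = rownames(expr),
                         reseed = TRUE) {
  stopifnot(inherits(config, "cohort_config"))
  if (reseed) set.seed(config$seed)
  genes <- unique(c(genes, intersect(config$reference_gene,
                                     rownames(expr))))
  missing <- setdiff(genes, rownames(expr))
  if (length(missing))
    stop("assay gene(s) not in expression matrix: ",
         paste(missing, collapse = ", "))
  if (!(config$reference_gene %in% genes))
    stop("reference gene '", config$reference_gene,
         "' is not in the expression matrix")
  x <- expr[genes, , drop = FALSE]
  nobs <- length(x)
  dup <- function() {
    z <- matrix(rnorm(nobs), nrow(x))
    e <- matrix(rnorm(nobs, 0, config$qgp_background_sd), nrow(x))
    pmax(config$qgp_gain * x * (1 + config$qgp_duplicate_cv * z) + e,
         config$qgp_background)
  }
  r1 <- dup(); r2 <- dup()
  signals <- data.frame(
    gene = rep(genes, times = ncol(x)),
    sample = rep(colnames(x), each = length(genes)),
    rep1 = as.vector(r1), rep2 = as.vector(r2),
    stringsAsFactors = FALSE)
  qgp_plate(signals, config$qgp_background, config$reference_gene)
}
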