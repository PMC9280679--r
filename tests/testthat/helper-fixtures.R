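# shared fixture builders (everything generated in code at test time)

tiny_expr <- function() {
  m <- matrix(c(10, 12, 11, 9, 10, 11,
                20, 22, 19, 21, 20, 18,
                5, 6, 5.5, 5.2, 6.1, 5.8),
              nrow = 3, byrow = TRUE,
              dimnames = list(c("G1", "G2", "G3"), paste0("s", 1:6)))
  m
}

# a balanced three-group cohort with known log2 shifts applied to selected
# genes in selected groups
shifted_cohort <- function(n_per_group = 4, n_genes = 50, sigma = 0.5,
                           shifts = list(), seed = 42, base_log2 = 6) {
  set.seed(seed)
  ids <- paste0("g", sprintf("%03d", seq_len(n_genes)))
  samp <- sample_table(
    paste0("s", seq_len(3 * n_per_group)),
    rep(granulosig_groups, each = n_per_group))
  logx <- matrix(rnorm(n_genes * nrow(samp), base_log2, sigma),
                 n_genes, nrow(samp), dimnames = list(ids, samp$sample_id))
  for (sh in shifts) {
    cols <- samp$sample_id[samp$group == sh$group]
    logx[sh$gene, cols] <- logx[sh$gene, cols] + sh$delta
  }
  list(expr = 2^logx, samples = samp)
}

# gene-set collection of generator program labels (stage programs and
# compartments), from a cohort truth object
program_sets <- function(truth, programs) {
  labs <- truth$profiles$program_labels
  sets <- lapply(programs, function(p) names(labs)[!is.na(labs) & labs == p])
  names(sets) <- programs
  gene_set_collection(sets)
}

make_plate <- function(genes, values_sep, values_sirs, background = 20,
                       ref_value = 50, cv_jitter = 0) {
  # values_*: matrix genes x samples of duplicate means; duplicates split
  # symmetrically so their mean is exact
  n_sep <- ncol(values_sep); n_sirs <- ncol(values_sirs)
  samples <- c(paste0("sep", seq_len(n_sep)), paste0("sirs", seq_len(n_sirs)))
  vals <- cbind(values_sep, values_sirs)
  rows <- expand.grid(gene = c(genes, "REF1"), sample = samples,
                      stringsAsFactors = FALSE)
  mean_of <- function(g, s) {
    if (g == "REF1") ref_value else vals[match(g, genes), match(s, samples)]
  }
  m <- mapply(mean_of, rows$gene, rows$sample)
  d <- m * cv_jitter
  plate <- qgp_plate(data.frame(rows, rep1 = m - d, rep2 = m + d),
                     background, "REF1")
  st <- sample_table(samples, rep(c("sepsis", "SIRS"), c(n_sep, n_sirs)))
  list(plate = plate, samples = st)
}
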