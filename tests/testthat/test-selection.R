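test_that("range/percentile rule matches hand-computed type-7 quantiles", {
  # Q75(1,2,3) = 2.5 < 10 and Q25(10,11,12) = 10.5 > 3
  expect_true(range_percentile_rule(c(10, 11, 12), c(1, 2, 3)))
  # min(high) = 2 <= Q75(low) = 6
  expect_false(range_percentile_rule(c(2, 5, 9), c(1, 4, 8)))
  # identical vectors overlap completely
  expect_false(range_percentile_rule(c(3, 4, 5), c(3, 4, 5)))
  expect_error(range_percentile_rule(c(1, 2), c(1, 2, 3)), ">= 3")
})

test_that("range rule equals the independent quantile oracle on random pairs", {
  set.seed(14)
  for (i in 1:1000) {
    n1 <- sample(3:12, 1); n2 <- sample(3:12, 1)
    a <- rnorm(n1, mean = sample(0:2, 1))
    b <- rnorm(n2)
    hi <- if (mean(a) >= mean(b)) a else b
    lo <- if (mean(a) >= mean(b)) b else a
    expect_identical(range_percentile_rule(hi, lo),
                     oracle_range_rule(hi, lo))
  }
})

test_that("strategy 2 applies both fold gates on the dge table", {
  mk_row <- function(gene, m_sep, m_sirs, m_pre, deg = TRUE) {
    data.frame(gene = gene, mean_presurgical = m_pre, mean_SIRS = m_sirs,
               mean_sepsis = m_sep, F_p = 0.01,
               fc_sepsis_vs_presurgical =
                 granulosig:::signed_fold(m_sep, m_pre),
               p_sepsis_vs_presurgical = 0.01, q_sepsis_vs_presurgical = 0.01,
               deg_sepsis_vs_presurgical = deg,
               fc_SIRS_vs_presurgical =
                 granulosig:::signed_fold(m_sirs, m_pre),
               p_SIRS_vs_presurgical = 0.5, q_SIRS_vs_presurgical = 0.5,
               deg_SIRS_vs_presurgical = FALSE,
               fc_sepsis_vs_SIRS = granulosig:::signed_fold(m_sep, m_sirs),
               p_sepsis_vs_SIRS = 0.01, q_sepsis_vs_SIRS = 0.01,
               deg_sepsis_vs_SIRS = deg)
  }
  tab <- rbind(mk_row("pass", 10, 4, 3.8),     # 2.5x and 1.053x
               mk_row("failboth", 10, 6, 3.8), # 1.67x and 1.58x
               mk_row("flat", 5, 5, 5),
               mk_row("nondeg", 10, 4, 3.8, deg = FALSE))
  class(tab) <- c("dge_table", "data.frame")
  expect_identical(select_strategy2(tab), "pass")
})

test_that("strategy 1 returns empty without sepsis-vs-SIRS DEGs", {
  co <- shifted_cohort(n_genes = 20, sigma = 1, seed = 15)
  dge <- fit_dge(co$expr, co$samples)
  dge$deg_sepsis_vs_SIRS <- FALSE
  s1 <- select_strategy1(dge, co$expr, co$samples)
  expect_length(s1$selected, 0)
})

test_that("exclusions shrink the strategy-1 shortlist without promotion", {
  planted <- data.frame(gene = sprintf("G%05d", 1:60), group = "sepsis",
                        effect = 8)
  cfg <- cohort_config(n_genes = 600,
                       n_program_genes = c(AG = 5, SG = 5, GG = 5, FG = 5,
                                           SV = 5, CM = 5, cellcycle = 5,
                                           mito = 5, proteasome = 5,
                                           ribosome = 5, lysosome = 5,
                                           housekeeping = 5),
                       planted_genes = planted, seed = 16)
  co <- simulate_cohort(cfg)
  dge <- fit_dge(co$expression, co$samples)
  config0 <- analysis_config()
  s1 <- select_strategy1(dge, co$expression, co$samples, config0)
  expect_length(s1$core, config0$strategy1_top_k)

  drop_gene <- head(s1$ranked_pool, config0$strategy1_top_k)[50]
  rank51 <- s1$ranked_pool[51]
  config_x <- analysis_config(exclusion_list = drop_gene)
  s1x <- select_strategy1(dge, co$expression, co$samples, config_x)
  expect_length(s1x$core, 49L)
  expect_false(drop_gene %in% s1x$selected)
  expect_false(rank51 %in% s1x$core)
})

test_that("the full strategy chain equals an independent re-implementation", {
  for (seed in 1:3) {
    set.seed(100 + seed)
    planted <- data.frame(gene = sprintf("G%05d", 1:60), group = "sepsis",
                          effect = 2^runif(60, 1, 3.5))
    cfg <- cohort_config(n_genes = 600,
                         n_program_genes = c(AG = 5, SG = 5, GG = 5, FG = 5,
                                             SV = 5, CM = 5, cellcycle = 5,
                                             mito = 5, proteasome = 5,
                                             ribosome = 5, lysosome = 5,
                                             housekeeping = 5),
                         planted_genes = planted, seed = seed)
    co <- simulate_cohort(cfg)
    dge <- fit_dge(co$expression, co$samples)
    config0 <- analysis_config(exclusion_list = planted$gene[3])
    lys <- co$truth$profiles$program_labels
    lys_genes <- c(names(lys)[!is.na(lys) & lys == "lysosome"],
                   planted$gene[1:10])
    s1 <- select_strategy1(dge, co$expression, co$samples, config0)
    s2 <- select_strategy2(dge, config0)
    s3 <- select_strategy3(s1$pool, lys_genes, union(s1$selected, s2))
    orc <- oracle_selection_chain(dge, co$expression, co$samples, config0,
                                  lys_genes)
    expect_identical(s1$selected, orc$s1)
    expect_identical(s2, orc$s2)
    expect_identical(s3$selected, orc$s3)
    expect_identical(sort(s1$pool), sort(orc$pool))
  }
})

test_that("strategy 3 intersects the pool with the lysosome list", {
  pool <- c("A", "B", "C", "D", "E")
  s3 <- select_strategy3(pool, c("B", "D", "Z"))
  expect_identical(s3$selected, c("B", "D"))
  s3b <- select_strategy3(pool, c("B", "D"), already_selected = c("B", "D"))
  expect_length(s3b$new, 0)
  expect_error(select_strategy3(pool, character()), "empty")

  # published split: 14 lysosomal in the pool, 10 already selected, 4 new
  pool2 <- sprintf("P%02d", 1:100)
  lys <- c(sprintf("P%02d", 1:14), "OFFPOOL")
  already <- sprintf("P%02d", 1:10)
  s3c <- select_strategy3(pool2, lys, already)
  expect_length(s3c$selected, 14)
  expect_length(s3c$new, 4)
})

test_that("merging selections yields the nonredundant union with flags", {
  m <- merge_selection(c("A", "B"), c("C", "D", "E"), c("F", "G", "H", "I"))
  expect_equal(nrow(m), 9)
  m2 <- merge_selection(c("A", "B"), c("A", "B"), c("A", "B"))
  expect_equal(nrow(m2), 2)
  expect_true(all(m2$strategy1 & m2$strategy2 & m2$strategy3))

  # published sizes: |s1| = 55, |s2| = 54 with 9 shared, strategy 3 adds 4
  s1 <- sprintf("A%02d", 1:55)
  s2 <- c(sprintf("A%02d", 1:9), sprintf("B%02d", 1:45))
  s3 <- c(sprintf("A%02d", 1:5), sprintf("B%02d", 1:5), sprintf("C%02d", 1:4))
  m3 <- merge_selection(s1, s2, s3)
  expect_equal(nrow(m3), 104)
})

test_that("selection is deterministic in repeated runs", {
  co <- shifted_cohort(
    n_genes = 40, sigma = 0.4,
    shifts = lapply(sprintf("g%03d", 1:6), function(g)
      list(gene = g, group = "sepsis", delta = 2)),
    seed = 18)
  dge <- fit_dge(co$expr, co$samples)
  s1a <- suppressWarnings(select_strategy1(dge, co$expr, co$samples))
  s1b <- suppressWarnings(select_strategy1(dge, co$expr, co$samples))
  expect_identical(s1a, s1b)
})

test_that("strategy 2 is invariant to global rescaling of expression", {
  co <- shifted_cohort(
    n_genes = 40, sigma = 0.4,
    shifts = lapply(sprintf("g%03d", 1:6), function(g)
      list(gene = g, group = "sepsis", delta = 2)),
    seed = 19)
  dge1 <- fit_dge(co$expr, co$samples)
  dge2 <- fit_dge(co$expr * 37, co$samples)
  expect_identical(select_strategy2(dge1), select_strategy2(dge2))
})
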