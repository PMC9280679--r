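test_that("normalization divides duplicate means by the reference and masks background", {
  sig <- data.frame(gene = c("A", "B", "REF1"),
                    sample = "s1",
                    rep1 = c(100, 15, 50), rep2 = c(120, 18, 50))
  plate <- qgp_plate(sig, background = 20, reference_gene = "REF1")
  norm <- normalize_qgp(plate)
  expect_equal(norm$values["A", "s1"], 2.2)   # 110 / 50
  expect_true(is.na(norm$values["B", "s1"]))  # 16.5 <= 20
  expect_identical(norm$missing_reason["B", "s1"], "at_or_below_background")

  sig$rep1[3] <- 10; sig$rep2[3] <- 10
  plate_bad <- qgp_plate(sig, background = 20, reference_gene = "REF1")
  expect_error(normalize_qgp(plate_bad), "sample\\(s\\): s1")
})

test_that("confirmation needs at least confirm_min_n present samples per group", {
  genes <- "A"
  v_sep <- matrix(c(100, 100, 100, 100, rep(10, 14)), nrow = 1)  # 4 of 18
  v_sirs <- matrix(rep(100, 5), nrow = 1)
  mp <- make_plate(genes, v_sep, v_sirs, background = 20)
  conf <- confirm_expression(normalize_qgp(mp$plate), mp$samples)
  expect_true(conf["A", "sepsis"])
  expect_true(conf["A", "SIRS"])

  v_sep3 <- matrix(c(100, 100, 100, rep(10, 15)), nrow = 1)      # 3 of 18
  mp3 <- make_plate(genes, v_sep3, v_sirs, background = 20)
  conf3 <- confirm_expression(normalize_qgp(mp3$plate), mp3$samples)
  expect_false(conf3["A", "sepsis"])
})

test_that("Mann-Whitney exact p matches hand enumeration and conventions", {
  res <- mann_whitney_exact(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$U, 0)
  expect_equal(res$p_value, 0.1)   # 2 / C(6,3)
  expect_identical(res$method, "exact")

  same <- mann_whitney_exact(c(5, 7, 9), c(5, 7, 9))
  expect_equal(same$p_value, 1)

  expect_error(mann_whitney_exact(numeric(), 1:3), "non-empty")
})

test_that("exact Mann-Whitney agrees with the rank-sum DP oracle", {
  for (nm in list(c(3, 5), c(6, 7), c(7, 7))) {
    n <- nm[1]; m <- nm[2]
    # distinct values: p depends only on U; check every achievable U
    for (U in 0:(n * m)) {
      # build a concrete pair realizing this U with distinct values
      a <- numeric(n)
      u_left <- U
      for (i in seq_len(n)) {
        beat <- min(m, u_left)       # number of b's this a exceeds
        a[i] <- beat + 0.5 + i * 1e-4  # keep pooled values distinct
        u_left <- u_left - beat
      }
      b <- seq_len(m)
      got <- mann_whitney_exact(a, b)
      expect_equal(got$U, U)
      expect_equal(got$p_value, oracle_mwu_p(U, n, m), tolerance = 1e-12)
    }
  }
})

test_that("the normal approximation mirrors the tie-corrected reference test", {
  set.seed(44)
  for (i in 1:20) {
    a <- round(rnorm(15, 1), 1)   # rounding induces ties
    b <- round(rnorm(18), 1)
    got <- mann_whitney_exact(a, b)
    expect_identical(got$method, "normal")
    ref <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE,
                                               correct = TRUE))
    expect_equal(got$p_value, ref$p.value, tolerance = 1e-12)
  }
})

test_that("Bonferroni arithmetic and the shorter-list validation route", {
  # gene X: clearly separated => small raw p; with a strategy list of ~30
  # confirmed genes the adjusted p stays < 0.05
  set.seed(45)
  genes <- sprintf("gene%02d", 1:30)
  v_sep <- matrix(rep(200, 30 * 6), 30) * exp(matrix(rnorm(180, 0, 0.05), 30))
  v_sirs <- matrix(rep(100, 30 * 6), 30) * exp(matrix(rnorm(180, 0, 0.05), 30))
  mp <- make_plate(genes, v_sep, v_sirs)
  sel <- merge_selection(genes, character(), character())
  vt <- validate_degs(normalize_qgp(mp$plate), mp$samples, sel)
  expect_true(all(vt$confirmed_sepsis & vt$confirmed_SIRS))
  expect_equal(attr(vt, "m_strategy")[["strategy1"]], 30L)
  expect_equal(vt$p_adj_strategy1, pmin(1, 30 * vt$p_mwu))
  expect_equal(vt$p_adj_global, pmin(1, 30 * vt$p_mwu))

  # a gene on a long list misses significance globally but validates via a
  # short strategy-3 list (the less conservative adjustment)
  raw_p <- 0.003
  m_long <- 93; m_short <- 13
  expect_gte(min(1, m_long * raw_p), 0.05)
  expect_lt(min(1, m_short * raw_p), 0.05)
  sel2 <- merge_selection(genes, character(), genes[1:2])
  vt2 <- validate_degs(normalize_qgp(mp$plate), mp$samples, sel2)
  g1 <- vt2[vt2$gene == genes[1], ]
  expect_equal(g1$p_adj_strategy3, min(1, 2 * g1$p_mwu))
  expect_lte(g1$p_adj_strategy3, g1$p_adj_strategy1)
})

test_that("missing-as-missing reduces the samples used, never increases them", {
  set.seed(46)
  for (i in 1:10) {
    n_sep <- 8; n_sirs <- 8
    v_sep <- matrix(exp(rnorm(n_sep, log(60), 1)), 1)
    v_sirs <- matrix(exp(rnorm(n_sirs, log(25), 1)), 1)
    mp <- make_plate("A", v_sep, v_sirs, background = 30)
    norm <- normalize_qgp(mp$plate)
    used <- sum(!is.na(norm$values["A", ]))
    expect_lte(used, n_sep + n_sirs)
  }
})

test_that("the validated set is monotone in alpha and order-invariant", {
  set.seed(47)
  genes <- sprintf("g%02d", 1:12)
  v_sep <- matrix(exp(rnorm(12 * 8, log(150), 0.4)), 12)
  v_sep[1:4, ] <- v_sep[1:4, ] * 4
  v_sirs <- matrix(exp(rnorm(12 * 8, log(150), 0.4)), 12)
  mp <- make_plate(genes, v_sep, v_sirs)
  sel <- merge_selection(genes, character(), character())
  norm <- normalize_qgp(mp$plate)
  v_lo <- validate_degs(norm, mp$samples, sel, analysis_config(
    alpha_validation = 0.01))
  v_hi <- validate_degs(norm, mp$samples, sel, analysis_config(
    alpha_validation = 0.2))
  expect_true(all(v_lo$gene[v_lo$validated] %in% v_hi$gene[v_hi$validated]))

  # swapping duplicate columns and permuting plate rows changes nothing
  plate2 <- mp$plate
  plate2$signals <- plate2$signals[sample(nrow(plate2$signals)), ]
  tmp <- plate2$signals$rep1
  plate2$signals$rep1 <- plate2$signals$rep2
  plate2$signals$rep2 <- tmp
  v_b <- validate_degs(normalize_qgp(plate2), mp$samples, sel)
  v_a <- validate_degs(norm, mp$samples, sel)
  expect_equal(v_a$validated[match(v_b$gene, v_a$gene)], v_b$validated)
})

test_that("genes absent from the plate are recorded unconfirmed", {
  mp <- make_plate("A", matrix(rep(100, 5), 1), matrix(rep(100, 5), 1))
  sel <- merge_selection(c("A", "GHOST"), character(), character())
  expect_message(
    vt <- validate_degs(normalize_qgp(mp$plate), mp$samples, sel),
    "GHOST")
  expect_false(vt$confirmed_sepsis[vt$gene == "GHOST"])
  expect_false(vt$validated[vt$gene == "GHOST"])
})

test_that("planted bead-array effects are recovered end to end", {
  planted <- data.frame(gene = sprintf("G%05d", 1:20), group = "sepsis",
                        effect = 4)
  null_genes <- sprintf("G%05d", 21:40)
  cfg <- cohort_config(
    n_genes = 600,
    n_per_group = c(presurgical = 0, SIRS = 22, sepsis = 18),
    n_program_genes = c(AG = 5, SG = 5, GG = 5, FG = 5, SV = 5, CM = 5,
                        cellcycle = 5, mito = 5, proteasome = 5,
                        ribosome = 5, lysosome = 5, housekeeping = 5),
    planted_genes = planted, qgp_duplicate_cv = 0.1,
    qgp_genes = c(planted$gene, null_genes), seed = 51)
  co <- simulate_cohort(cfg)
  sel <- merge_selection(c(planted$gene, null_genes), character(),
                         character())
  vt <- validate_degs(normalize_qgp(co$qgp), co$samples, sel)
  hits <- vt$gene[vt$validated]
  expect_gte(sum(planted$gene %in% hits), 16)
  expect_length(intersect(null_genes, hits), 0)
})
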