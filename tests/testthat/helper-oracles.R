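# Independent brute-force oracles used to cross-check package operations.
# These deliberately avoid the implementation's code paths.

# type-7 quantile computed from first principles (sorted values, linear
# interpolation at h = (n-1) p)
oracle_quantile7 <- function(x, p) {
  s <- sort(x)
  h <- (length(s) - 1) * p
  lo <- floor(h)
  s[lo + 1] + (h - lo) * (s[min(lo + 2, length(s))] - s[lo + 1])
}

oracle_range_rule <- function(high, low) {
  q_low <- oracle_quantile7(low, 0.75)
  q_high <- oracle_quantile7(high, 0.25)
  min(high) - q_low > 1e-9 * max(1, abs(q_low)) &&
    q_high - max(low) > 1e-9 * max(1, abs(q_high))
}

# exact Mann-Whitney two-sided p by dynamic programming over the rank-sum
# distribution (distinct values only): number of n-subsets of 1..N with a
# given rank sum
oracle_mwu_ranksum_dist <- function(n, m) {
  N <- n + m
  smax <- sum((N - n + 1):N)
  # ways[k+1, s+1]: subsets of size k with rank sum s, built rank by rank
  ways <- matrix(0, n + 1, smax + 1)
  ways[1, 1] <- 1
  for (r in 1:N) {
    for (k in min(n, r):1) {
      srange <- r:smax
      ways[k + 1, srange + 1] <- ways[k + 1, srange + 1] +
        ways[k, srange - r + 1]
    }
  }
  ways[n + 1, ]  # index s+1 -> count of subsets with rank sum s
}

oracle_mwu_p <- function(U, n, m) {
  dist <- oracle_mwu_ranksum_dist(n, m)
  s_vals <- 0:(length(dist) - 1)
  u_vals <- s_vals - n * (n + 1) / 2
  keep <- dist > 0
  mu <- n * m / 2
  sum(dist[keep][abs(u_vals[keep] - mu) >= abs(U - mu) - 1e-9]) /
    sum(dist[keep])
}

# Fisher two-sided p recomputed from binomial coefficients only
oracle_fisher_p <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  N <- r1 + r2
  support <- max(0, c1 - r2):min(r1, c1)
  prob <- vapply(support, function(a)
    choose(r1, a) * choose(r2, c1 - a) / choose(N, c1), 0)
  p_obs <- prob[support == tab[1, 1]]
  sum(prob[prob <= p_obs * (1 + 1e-7)])
}

# direct loop evaluation of the weighted running sum (hit CDF minus uniform
# position CDF), reading off the extreme deviation
oracle_es <- function(genes, stats, set, exponent = 1) {
  ord <- order(-stats, genes)
  genes <- genes[ord]; stats <- stats[ord]
  hit <- genes %in% set
  if (all(hit)) return(0)
  w <- abs(stats)^exponent
  tot <- sum(w[hit])
  if (tot == 0) { w <- rep(1, length(w)); tot <- sum(w[hit]) }
  best <- 0; run_hit <- 0
  n <- length(genes)
  for (i in seq_len(n)) {
    if (hit[i]) run_hit <- run_hit + w[i] / tot
    s <- run_hit - i / n
    if (abs(s) > abs(best)) best <- s
  }
  best
}

# independent re-implementation of the strategy-1/2/3 chain, written with
# different idioms (data.frame sorting, explicit loops)
oracle_selection_chain <- function(table, expr, samples, config,
                                   lysosome_genes) {
  df <- as.data.frame(table)
  deg <- df[df$deg_sepsis_vs_SIRS, ]
  poolA <- character(); poolB <- character()
  if (nrow(deg)) {
    dA <- deg[order(deg$mean_sepsis, decreasing = TRUE), ]
    dA <- dA[order(-dA$mean_sepsis, dA$gene), ]
    poolA <- head(dA$gene, config$strategy1_pool_size)
    dB <- deg[order(-deg$mean_SIRS, deg$gene), ]
    poolB <- head(dB$gene, config$strategy1_pool_size)
  }
  pool <- unique(c(poolA, poolB))
  sub <- df[df$gene %in% pool, ]
  sub <- sub[order(sub$q_sepsis_vs_SIRS, sub$p_sepsis_vs_SIRS, sub$gene), ]
  core <- head(sub$gene, config$strategy1_top_k)
  core <- core[!(core %in% config$exclusion_list)]
  sep_ids <- samples$sample_id[samples$group == "sepsis"]
  sirs_ids <- samples$sample_id[samples$group == "SIRS"]
  additions <- character()
  for (g in setdiff(sub$gene, c(core, config$exclusion_list))) {
    a <- expr[g, sep_ids]; b <- expr[g, sirs_ids]
    hi <- if (mean(a) >= mean(b)) a else b
    lo <- if (mean(a) >= mean(b)) b else a
    if (oracle_range_rule(hi, lo)) additions <- c(additions, g)
  }
  s1 <- c(core, sub$gene[sub$gene %in% additions])
  any_deg <- df$deg_sepsis_vs_presurgical | df$deg_SIRS_vs_presurgical |
    df$deg_sepsis_vs_SIRS
  s2 <- df$gene[any_deg & abs(df$fc_sepsis_vs_SIRS) > config$strategy2_fc_high &
                  abs(df$fc_SIRS_vs_presurgical) < config$strategy2_fc_low]
  s3 <- pool[pool %in% lysosome_genes]
  list(s1 = s1, s2 = s2, s3 = s3, pool = pool)
}
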