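# Independent oracles and shared fixtures, kept deliberately simple and
# separate from the implementation paths they check.

# Exhaustive enumeration of the maximum Yates-corrected chi-square over all
# (r_s, r_t) threshold pairs, O(N^2); the production kernel must reproduce
# it exactly at grid_step = 1.
oracle_max_chisq <- function(tp_of_sam, min_expected = 10, min_cell = 5) {
  N <- length(tp_of_sam)
  best <- list(chi2 = 0, r_s = 0L, r_t = 0L)
  rt <- as.numeric(seq_len(N - 1L))
  for (rs in as.numeric(seq_len(N - 1L))) {
    av <- as.numeric(cumsum(tabulate(tp_of_sam[seq_len(rs)],
                                     nbins = N)))[rt]
    a <- av
    b <- rs - a; cc <- rt - a; d <- N - rs - rt + a
    u <- pmax(0, abs(a * d - b * cc) - N / 2)
    chi2 <- N * u^2 / ((a + b) * (cc + d) * (a + cc) * (b + d))
    bad <- rs * rt / N <= min_expected | a <= rs * rt / N |
      rs * (N - rt) / N < min_cell | (N - rs) * rt / N < min_cell |
      (N - rs) * (N - rt) / N < min_cell
    chi2[bad] <- 0
    j <- which.max(chi2)
    if (chi2[j] > best$chi2)
      best <- list(chi2 = chi2[j], r_s = as.integer(rs),
                   r_t = as.integer(rt[j]))
  }
  best
}

# Step-down q-value oracle with pi0 fixed: q_i = min_{t >= p_i} m t / #{p <= t},
# computed by direct double loop.
oracle_qvalues_pi0_1 <- function(p) {
  m <- length(p)
  vapply(p, function(pi) {
    ts <- p[p >= pi]
    min(1, min(vapply(ts, function(t) m * t / sum(p <= t), 0)))
  }, 0)
}

# Full-scale study-condition dataset (5000 genes, 200 targets, density
# ratio 5, effect size 3, 7 comparisons, planted regulator + 10 decoys);
# built once per test run and shared by the acceptance checks.
big_synth <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- synthetic_config(seed = 2024)
      pw <- make_regulator_pwm(2024, n_decoys = 10)
      pr <- generate_promoters(cfg, pw$regulator)
      comps <- generate_expression(cfg, pr$truth)
      gg <- generate_gene_groups(cfg, pr$truth)
      st <- gene_score_table(comps, pr$truth$regulator_gene)
      tpts <- lapply(pw$all, function(p)
        target_propensity_table(pr$promoters, p))
      cache <<- list(cfg = cfg, pw = pw, truth = gg$truth,
                     groups = gg$groups, st = st, tpts = tpts)
    }
    cache
  }
})

# Small shared synthetic dataset; built once per test run.
tiny_synth <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- synthetic_config(n_genes = 600, n_targets = 60,
                              n_comparisons = 4, n_groups = 20,
                              group_size = 30, n_enriched_groups = 3,
                              seed = 42)
      pw <- make_regulator_pwm(42, n_decoys = 2)
      pr <- generate_promoters(cfg, pw$regulator)
      comps <- generate_expression(cfg, pr$truth)
      gg <- generate_gene_groups(cfg, pr$truth)
      st <- gene_score_table(comps, pr$truth$regulator_gene)
      tpt <- target_propensity_table(pr$promoters, pw$regulator)
      cache <<- list(cfg = cfg, pw = pw, promoters = pr$promoters,
                     truth = gg$truth, comparisons = comps,
                     groups = gg$groups, st = st, tpt = tpt)
    }
    cache
  }
})
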