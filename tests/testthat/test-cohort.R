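test_that("score increment follows its definition", {
  expect_equal(score_increment(c(2, 2, 0, 0), c(6, 6, 1, 1), tau = 5), 1)
  expect_equal(score_increment(rep(3, 6), runif(6, 1, 9), tau = 5), 0)
  # tau below every member: above-set is the whole group, increment 0
  expect_equal(score_increment(c(1, 2, 3), c(4, 5, 6), tau = 1), 0)
  expect_equal(score_increment(c(1, 2, 3), c(4, 5, 6), tau = 10), NA_real_)
  expect_equal(score_increment(c(2, 2, 0, 0), c(6, 6, 1, 1), tau = 5,
                               baseline = "below"), 2)
})

test_that("interim p-values hit the extreme bound and are deterministic", {
  set.seed(5)
  pool <- rnorm(500)
  # group holding the top pool values above tau: no sample can beat it
  top <- sort(pool, decreasing = TRUE)[1:10]
  rest <- sort(pool)[1:10]
  grp <- c(top, rest)
  tp <- c(rep(9, 10), rep(1, 10))
  r1 <- interim_pvalues(grp, tp, pool, thresholds = 5, B = 1000, seed = 1)
  expect_equal(r1$interim_p, 1 / 1001)
  r2 <- interim_pvalues(grp, tp, pool, thresholds = 5, B = 1000, seed = 1)
  expect_identical(r1, r2)
  # seed sensitivity shows on a non-extreme group
  set.seed(6)
  idx <- sample(500, 20)
  tpg <- runif(20)
  m1 <- minp_final_pvalue(pool[idx], tpg, pool, B = 300, seed = 1)
  m2 <- minp_final_pvalue(pool[idx], tpg, pool, B = 300, seed = 2)
  expect_false(identical(m1$interim_p, m2$interim_p))
  expect_error(interim_pvalues(grp, tp, pool, B = 10), "B must be")
  expect_error(interim_pvalues(rnorm(600), runif(600), pool, B = 100),
               "larger than the gene universe")
})

test_that("final p is conservative relative to the minimum interim p", {
  set.seed(8)
  pool <- rnorm(400)
  for (rep in 1:5) {
    grp_idx <- sample(400, 25)
    res <- minp_final_pvalue(pool[grp_idx], runif(25), pool, B = 200,
                             seed = rep)
    expect_gte(res$final_p, res$min_interim_p)
    expect_true(all(na.omit(res$interim_p) >= 1 / 201))
    expect_true(all(na.omit(res$interim_p) <= 1))
    expect_equal(res$min_interim_p, min(res$interim_p, na.rm = TRUE))
  }
})

test_that("planted enriched groups are detected, null groups are not", {
  ts <- tiny_synth()
  cr <- run_target_cohort(ts$groups, ts$st, ts$tpt, B = 400, seed = 3)
  expect_s3_class(cr, "cohort_results")
  de <- cr$results[cr$results$metric == "de", ]
  enr <- de$group %in% ts$truth$enriched_group_ids
  expect_true(all(de$final_p[enr] <= 0.05))
  # enriched groups essentially lead the ranking; at moderate B a lucky
  # null group can reach the permutation floor 1/(B+1)
  expect_lte(sum(de$final_p[!enr] < max(de$final_p[enr])), 1)
  expect_lt(median(de$final_p[enr]), median(de$final_p[!enr]))
  # rerun is identical
  cr2 <- run_target_cohort(ts$groups, ts$st, ts$tpt, B = 400, seed = 3)
  expect_identical(cr$results, cr2$results)
})

test_that("undersized and unknown groups are skipped with messages", {
  ts <- tiny_synth()
  gs <- list(small = ts$st$genes[1:3],
             alien = paste0("ZZZ", 1:20),
             ok = ts$st$genes[10:40])
  suppressWarnings(
    expect_message(cr <- run_target_cohort(gs, ts$st, ts$tpt, B = 100,
                                           seed = 1),
                   "below min_size|no scored members"))
  expect_setequal(unique(cr$results$group), "ok")
})

test_that("q-values match the independent step-down oracle at pi0 = 1", {
  expect_equal(storey_qvalues(rep(1, 20)), rep(1, 20))
  expect_equal(storey_qvalues(c(0.01, 0.02, 0.03, 0.04), pi0 = 1),
               rep(0.04, 4))
  set.seed(11)
  for (rep in 1:50) {
    p <- runif(sample(10:60, 1))
    q <- storey_qvalues(p, pi0 = 1)
    expect_equal(q, oracle_qvalues_pi0_1(p), tolerance = 1e-9)
    expect_true(all(diff(q[order(p)]) >= -1e-12))
  }
  expect_error(storey_qvalues(c(0, 0.5)), "\\(0, 1\\]")
})

test_that("pi0 smoother stays inside (0, 1] and warns on tiny inputs", {
  set.seed(2)
  p <- c(runif(300), runif(300)^4)       # mixture with signal
  q <- storey_qvalues(p)
  expect_true(all(q > 0 & q <= 1))
  expect_warning(storey_qvalues(runif(5)), "pi0 fixed at 1")
})

test_that("separation threshold finds the plateau onset from above", {
  prof <- data.frame(threshold = 1:10,
                     interim_p_de = c(10^-c(5, 5, 5, 5, 4.9, 3, 2, 1, .5, .2)))
  sep <- separation_threshold(prof)
  # values within 10% of the max (5): thresholds 1-5 -> onset at 5
  expect_equal(sep$tau_star, 5)
  expect_false(sep$flat)
  sep2 <- separation_threshold(prof, manual_override = 4.9)
  expect_equal(sep2$tau_star, 4.9)
  flat <- data.frame(threshold = 1:5, interim_p_de = rep(0.2, 5))
  expect_warning(sep3 <- separation_threshold(flat), "flat")
  expect_true(is.na(sep3$tau_star) && sep3$flat)
})

test_that("envelope cutoffs exclude IQR outliers below the threshold", {
  gdf <- data.frame(tp = c(1, 1, 1, 1, 9, 9),
                    de = c(0.2, 0.5, 0.9, 0.8, 2, 3),
                    dp = c(0.05, 0.10, 0.13, 2.0, 4, 5),
                    cov = c(0.05, 0.10, 0.13, 2.0, 4, 5))
  cuts <- envelope_cutoffs(gdf, tau_star = 5)
  expect_equal(cuts$de_cutoff, 0.9)
  expect_equal(cuts$dp_cutoff, 0.13)    # 2.0 flagged as outlier
  expect_equal(cuts$cov_cutoff, 0.13)
  expect_error(envelope_cutoffs(gdf[5:6, ], 5), ">= 2 members below")
})

test_that("cohort identification applies the cutoff logic symmetrically", {
  gdf <- data.frame(gene = c("a", "b", "c", "d"),
                    tp = c(6, 6, 6, 1),
                    de = c(1.0, 1.0, 0.5, 3.0),
                    dp = c(4.0, 0.1, 4.0, 9.0),
                    cov = c(0.0, -0.2, 0.5, 9.0))
  cuts <- list(de_cutoff = 0.9, dp_cutoff = 3.2, cov_cutoff = 0.135)
  # a: dp passes; b: |cov| 0.2 passes; c: de fails; d: below tau
  expect_equal(identify_cohort(gdf, 5, cuts), c("a", "b"))
  # permutation of rows changes nothing
  expect_equal(identify_cohort(gdf[c(3, 1, 4, 2), ], 5, cuts), c("a", "b"))
  # no member above tau
  expect_equal(identify_cohort(gdf, 100, cuts), character(0))
  # shipped reference configurations expose the documented values
  ref <- reference_cutoffs()
  expect_equal(ref$wnt$tau_star, 4.9)
  expect_equal(ref$fgf$de_cutoff, 0.617)
})

test_that("synthetic enriched cohorts recover planted targets", {
  ts <- tiny_synth()
  st <- ts$st; tpt <- ts$tpt
  tp <- setNames(tpt$tp, tpt$gene)
  grp <- ts$groups[[ts$truth$enriched_group_ids[1]]]
  members <- intersect(grp, st$genes)
  gdf <- data.frame(gene = members, tp = tp[members],
                    de = st$de_score[match(members, st$genes)],
                    dp = st$dp[match(members, st$genes)],
                    cov = st$cov[match(members, st$genes)])
  cr <- suppressWarnings(
    run_target_cohort(ts$groups[ts$truth$enriched_group_ids[1]],
                      st, tpt, B = 300, seed = 2))
  sep <- separation_threshold(cr$profiles[[1]])
  expect_false(sep$flat)
  cuts <- envelope_cutoffs(gdf, sep$tau_star)
  cohort <- identify_cohort(gdf, sep$tau_star, cuts)
  truth_targets <- names(which(ts$truth$target_flags[members]))
  expect_gt(length(cohort), 0)
  precision <- mean(cohort %in% truth_targets)
  recall <- mean(truth_targets %in% cohort)
  expect_gte(precision, 0.5)
  expect_gte(recall, 0.3)
})
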