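test_that("probe filtering drops the three cross-hybridizing suffixes", {
  expect_equal(filter_probes(c("1007_s_at", "1053_at")), "1053_at")
  expect_equal(filter_probes(character(0)), character(0))
  expect_equal(filter_probes(c("X_at", "X_a_at", "X_x_at", "X_s_at")),
               "X_at")
  # same symbol at different loci stays distinct
  expect_equal(filter_probes(c("DDR1_1", "DDR1_2")), c("DDR1_1", "DDR1_2"))
})

make_comparison <- function(m, id = "c1") {
  expression_comparison(m, rep(c("case", "control"), each = ncol(m) / 2), id)
}

test_that("SAM statistic matches hand computations", {
  m <- rbind(g1 = c(3, 3, 3, 1, 1, 1),       # zero pooled SE
             g2 = c(5, 6, 7, 5, 6, 7))       # identical class means
  cc <- make_comparison(m)
  d <- sam_statistic(cc, s0_rule = 1)
  expect_equal(unname(d["g1"]), 2)           # d = (3-1)/(0+1)
  expect_equal(unname(d["g2"]), 0)
  # monotone in s0: doubling s0 never increases |d|
  m2 <- matrix(rnorm(60), 10,
               dimnames = list(paste0("g", 1:10), NULL))
  cc2 <- make_comparison(m2)
  expect_true(all(abs(sam_statistic(cc2, s0_rule = 2)) <=
                    abs(sam_statistic(cc2, s0_rule = 1)) + 1e-12))
  # zero variance everywhere with s0 = 0 is an error with guidance
  flat <- make_comparison(rbind(g1 = c(2, 2, 2, 1, 1, 1)))
  expect_error(sam_statistic(flat, s0_rule = 0), "positive s0")
})

test_that("score scaling is exact and affine-invariant", {
  expect_equal(scale_scores(c(1, 2, 3)), c(-1, 0, 1))
  set.seed(1)
  d <- rnorm(100)
  z <- scale_scores(d)
  expect_equal(mean(z), 0, tolerance = 1e-9)
  expect_equal(sd(z), 1, tolerance = 1e-9)
  expect_equal(scale_scores(3 * d + 7), z)
  expect_error(scale_scores(rep(1, 5)), "zero standard deviation")
})

test_that("pooled DE score is the mean absolute scaled score", {
  expect_equal(unname(pooled_de_score(rbind(c(0, 0, 0)))), 0)
  expect_equal(unname(pooled_de_score(rbind(c(1, -1, 2, -2)))), 1.5)
  z <- matrix(rnorm(40), 10)
  flip <- z; flip[, 2] <- -flip[, 2]
  expect_equal(pooled_de_score(z), pooled_de_score(flip))
})

test_that("similarity metrics match their closed forms", {
  expect_equal(similarity_dot(c(1, 0), c(0, 1)), 0)
  expect_equal(similarity_dot(c(1, 1, 1), c(1, 1, 1)), 3)
  a <- rnorm(7); b <- rnorm(7)
  expect_equal(similarity_dot(a, b), similarity_dot(b, a))
  expect_error(similarity_dot(1:3, 1:4), "mismatch")
  expect_equal(similarity_cov(c(1, 2, 3), c(5, 5, 5)), 0)
  expect_equal(similarity_cov(c(1, 2, 3), c(2, 4, 6)), 4 / 3)
  expect_equal(similarity_cov(a, a), mean(a^2) - mean(a)^2)
})

test_that("score table columns are standardized and reproducible", {
  ts <- tiny_synth()
  st <- ts$st
  expect_equal(unname(colMeans(st$z)), rep(0, st$n_comparisons),
               tolerance = 1e-9)
  expect_equal(unname(apply(st$z, 2, sd)), rep(1, st$n_comparisons),
               tolerance = 1e-9)
  expect_true(all(st$de_score >= 0))
  expect_true(all(is.finite(st$dp)) && all(is.finite(st$cov)))
  # regulator similarity with itself: dp = sum a^2, cov = population var
  a <- st$z[st$regulator_gene, ]
  i <- match(st$regulator_gene, st$genes)
  expect_equal(st$dp[i], sum(a^2))
  expect_equal(st$cov[i], mean(a^2) - mean(a)^2)
})

test_that("score table round-trips through TSV", {
  ts <- tiny_synth()
  f <- withr::local_tempfile(fileext = ".tsv")
  write_score_table(ts$st, f)
  back <- read_score_table(f)
  expect_equal(back$genes, ts$st$genes)
  expect_equal(back$de_score, ts$st$de_score, tolerance = 1e-9)
  expect_equal(back$regulator_gene, ts$st$regulator_gene)
})

test_that("group similarity is the unweighted member mean", {
  ts <- tiny_synth()
  st <- ts$st
  g1 <- st$genes[1]
  expect_equal(group_similarity(st, g1, "de"),
               st$de_score[match(g1, st$genes)])
  expect_equal(group_similarity(st, st$genes, "cov"), mean(st$cov))
  # merged disjoint groups give the size-weighted mean
  a <- st$genes[1:5]; b <- st$genes[6:15]
  expect_equal(group_similarity(st, c(a, b), "dp"),
               (5 * group_similarity(st, a, "dp") +
                  10 * group_similarity(st, b, "dp")) / 15)
  expect_error(group_similarity(st, "NOT_A_GENE", "de"), "NOT_A_GENE")
})

test_that("null comparisons put ~5% of genes beyond 1.96", {
  cfg <- synthetic_config(n_genes = 4000, n_targets = 0, n_comparisons = 2,
                          effect_size = 0, seed = 9)
  pw <- make_regulator_pwm(9, n_decoys = 0)
  pr <- generate_promoters(cfg, pw$regulator)
  comps <- generate_expression(cfg, pr$truth)
  st <- gene_score_table(comps, pr$truth$regulator_gene)
  frac <- mean(abs(st$z[, 1]) > 1.96)
  se <- sqrt(0.05 * 0.95 / nrow(st$z))
  expect_lt(abs(frac - 0.05), 3 * se + 0.01)
})

test_that("rank profile handles constants, perfect monotony and planted data", {
  tp <- setNames(seq(100, 1, length.out = 100), sprintf("g%03d", 1:100))
  const <- setNames(rep(2, 100), names(tp))
  rp <- rank_profile(const, tp, window = 10)
  expect_true(all(abs(na.omit(rp$profile$moving_avg) - 2) < 1e-12))
  # value equal to the descending-propensity rank: perfect negative rho
  val <- setNames(rank(-tp), names(tp))
  expect_equal(rank_profile(val, tp, window = 10)$rho, -1)
  expect_error(rank_profile(val, tp, window = 1), "window")
  # planted construction: propensity and DE score positively correlated
  ts <- tiny_synth()
  rp2 <- rank_profile(setNames(ts$st$de_score, ts$st$genes),
                      setNames(ts$tpt$tp, ts$tpt$gene))
  expect_gt(rp2$rho, 0)
  expect_lt(rp2$p_value, 0.05)
})

test_that("metric multisets are equivariant under gene relabeling", {
  ts <- tiny_synth()
  comps <- ts$comparisons
  set.seed(4)
  shuffled <- lapply(comps, function(cc) {
    p <- sample(nrow(cc$matrix))
    m <- cc$matrix[p, ]
    expression_comparison(m, cc$class_labels, cc$comparison_id)
  })
  st1 <- ts$st
  st2 <- gene_score_table(shuffled, st1$regulator_gene)
  expect_equal(sort(st2$de_score), sort(st1$de_score), tolerance = 1e-9)
  expect_equal(sort(st2$dp), sort(st1$dp), tolerance = 1e-9)
  expect_equal(sort(st2$cov), sort(st1$cov), tolerance = 1e-9)
})
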