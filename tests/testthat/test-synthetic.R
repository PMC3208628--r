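test_that("config invariants are enforced", {
  expect_error(synthetic_config(n_genes = 100, n_targets = 100))
  expect_error(synthetic_config(site_density_ratio = 0.5))
  expect_error(synthetic_config(enriched_group_target_fraction = 1.2))
  expect_error(synthetic_config(noise_sd = 0))
  cfg <- synthetic_config(n_genes = 100, n_targets = 10)
  expect_s3_class(cfg, "synthetic_config")
})

test_that("promoter generation is deterministic and records truth", {
  cfg <- synthetic_config(n_genes = 80, n_targets = 10, seed = 5)
  pw <- make_regulator_pwm(5, n_decoys = 0)
  a <- generate_promoters(cfg, pw$regulator)
  b <- generate_promoters(cfg, pw$regulator)
  expect_identical(a$promoters, b$promoters)
  expect_identical(a$truth$planted_site_counts, b$truth$planted_site_counts)
  expect_equal(sum(a$truth$target_flags), 10)
  expect_false(a$truth$target_flags[[a$truth$regulator_gene]])
  expect_true(all(nchar(a$promoters) == cfg$promoter_len))
  J <- table(a$truth$promoter_gene)
  expect_true(all(J >= 1 & J <= 3))
})

test_that("ratio 1 removes the planted density difference", {
  cfg <- synthetic_config(n_genes = 500, n_targets = 100,
                          site_density_ratio = 1, seed = 21)
  pw <- make_regulator_pwm(21, n_decoys = 0)
  pr <- generate_promoters(cfg, pw$regulator)
  tg <- pr$truth$target_flags[pr$truth$promoter_gene]
  mt <- mean(pr$truth$planted_site_counts[tg])
  mn <- mean(pr$truth$planted_site_counts[!tg])
  lambda <- cfg$background_site_rate * cfg$promoter_len
  se <- sqrt(lambda / sum(tg) + lambda / sum(!tg))
  expect_lt(abs(mt - mn), 3 * se)
})

test_that("zero rate plants nothing anywhere", {
  cfg <- synthetic_config(n_genes = 50, n_targets = 0,
                          background_site_rate = 0, seed = 2)
  pw <- make_regulator_pwm(2, n_decoys = 0)
  pr <- generate_promoters(cfg, pw$regulator)
  expect_true(all(pr$truth$planted_site_counts == 0))
})

test_that("planted counts follow the configured Poisson mean", {
  cfg <- synthetic_config(n_genes = 2000, n_targets = 0,
                          background_site_rate = 0.002, seed = 13)
  pw <- make_regulator_pwm(13, n_decoys = 0)
  pr <- generate_promoters(cfg, pw$regulator)
  lambda <- 0.002 * 600              # 1.2 expected sites per promoter
  n <- length(pr$truth$planted_site_counts)
  se <- sqrt(lambda / n)
  expect_lt(abs(mean(pr$truth$planted_site_counts) - lambda), 3 * se)
})

test_that("site insertion overflow names the promoter", {
  cfg <- synthetic_config(n_genes = 10, n_targets = 5, promoter_len = 30,
                          background_site_rate = 0.2,
                          site_density_ratio = 3, seed = 3)
  pw <- make_regulator_pwm(3, n_decoys = 0)
  expect_error(generate_promoters(cfg, pw$regulator),
               "promoter G000[0-9]+\\|P[0-9]")
})

test_that("expression matrices are deterministic with planted shifts", {
  cfg <- synthetic_config(n_genes = 300, n_targets = 40, n_comparisons = 3,
                          seed = 8)
  pw <- make_regulator_pwm(8, n_decoys = 0)
  pr <- generate_promoters(cfg, pw$regulator)
  a <- generate_expression(cfg, pr$truth)
  b <- generate_expression(cfg, pr$truth)
  expect_identical(a, b)
  expect_length(a, 3)
  expect_equal(dim(a[[1]]$matrix), c(300, 6))
  # SAM dominance of targets in every comparison (effect 3, noise 1)
  for (cc in a) {
    d <- sam_statistic(cc)
    tg <- pr$truth$target_flags[names(d)]
    expect_gt(mean(d[tg]), mean(d[!tg]))
  }
})

test_that("effect size 0 leaves targets and non-targets exchangeable", {
  cfg <- synthetic_config(n_genes = 5000, n_targets = 500,
                          n_comparisons = 1, effect_size = 0, seed = 31)
  pw <- make_regulator_pwm(31, n_decoys = 0)
  pr <- generate_promoters(cfg, pw$regulator)
  comps <- generate_expression(cfg, pr$truth)
  m <- comps[[1]]$matrix
  tstat <- apply(m, 1, function(x) t.test(x[1:3], x[4:6])$statistic)
  tg <- pr$truth$target_flags[rownames(m)]
  tg[names(tg) == pr$truth$regulator_gene] <- NA  # regulator is shifted
  ks <- suppressWarnings(ks.test(tstat[which(tg)], tstat[which(!tg)]))
  expect_gt(ks$p.value, 0.01)
})

test_that("gene groups honour the enrichment fraction and round-trip GMT", {
  cfg <- synthetic_config(n_genes = 1000, n_targets = 300, n_groups = 40,
                          group_size = 50, n_enriched_groups = 20,
                          enriched_group_target_fraction = 0.4, seed = 17)
  pw <- make_regulator_pwm(17, n_decoys = 0)
  pr <- generate_promoters(cfg, pw$regulator)
  gg <- generate_gene_groups(cfg, pr$truth)
  expect_length(gg$groups, 40)
  expect_length(gg$truth$enriched_group_ids, 20)
  n_targets_per <- vapply(gg$groups[gg$truth$enriched_group_ids],
                          function(g) sum(pr$truth$target_flags[g]), 0)
  expect_equal(mean(n_targets_per), 20, tolerance = 1e-9)  # 0.4 * 50 exact
  f <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(gg$groups, f)
  back <- read_gmt(f)
  expect_identical(lapply(back, sort), lapply(gg$groups, sort))
  # a fraction at the background target rate removes the planted
  # enrichment signal: group target counts are indistinguishable
  cfg0 <- synthetic_config(n_genes = 1000, n_targets = 300, n_groups = 40,
                           group_size = 50, n_enriched_groups = 20,
                           enriched_group_target_fraction = 0.3, seed = 18)
  pr0 <- generate_promoters(cfg0, pw$regulator)
  gg0 <- generate_gene_groups(cfg0, pr0$truth)
  cnt <- vapply(gg0$groups, function(g) sum(pr0$truth$target_flags[g]), 0)
  enr <- names(gg0$groups) %in% gg0$truth$enriched_group_ids
  expect_gt(suppressWarnings(
    wilcox.test(cnt[enr], cnt[!enr])$p.value), 0.01)
})

test_that("group size beyond the universe is rejected", {
  cfg <- synthetic_config(n_genes = 30, n_targets = 5, group_size = 50,
                          n_groups = 2, n_enriched_groups = 0, seed = 1)
  pw <- make_regulator_pwm(1, n_decoys = 0)
  pr <- generate_promoters(cfg, pw$regulator)
  expect_error(generate_gene_groups(cfg, pr$truth), "exceeds")
})

test_that("FASTA and truth files round-trip the emitted artifacts", {
  ts <- tiny_synth()
  f <- withr::local_tempfile(fileext = ".fasta")
  write_promoters_fasta(ts$promoters, f)
  back <- read_promoters_fasta(f)
  expect_identical(back, ts$promoters)
  pre <- withr::local_tempfile()
  files <- write_truth_tsv(ts$truth, pre)
  g <- read.delim(files[1])
  expect_equal(sum(g$is_target), sum(ts$truth$target_flags))
})
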