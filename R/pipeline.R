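#' Pipeline configuration
#'
#' Builds the resolved configuration driving [run_simulate()],
#' [run_screen()], [run_cohort()] and [run_all()]. The global seed
#' propagates to every stochastic stage; `quick = TRUE` reduces the
#' permutation budgets for fast exploratory runs.
#'
#' @param outdir output directory.
#' @param seed global integer seed.
#' @param synthetic list of [synthetic_config()] arguments (plus `n_decoys`)
#'   for simulated runs; ignored when `paths` supplies user data.
#' @param paths optional named list pointing at user data: `expression`
#'   (vector of comparison TSVs), `promoters` (FASTA), `pwms` (TRANSFAC
#'   flat file), `groups` (GMT).
#' @param regulator_gene gene anchoring the similarity metrics (default the
#'   synthetic regulator).
#' @param regulator_pwm matrix used for the cohort analysis (default the
#'   synthetic regulator matrix).
#' @param scoring,tfa,cohort stage parameter lists; unset entries take the
#'   package defaults.
#' @param quick reduce n_perm/B for a fast end-to-end run.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(outdir = "tfcohort_out", seed = 1,
                            synthetic = list(), paths = NULL,
                            regulator_gene = "G00001",
                            regulator_pwm = "REG_SYNTH",
                            scoring = list(), tfa = list(),
                            cohort = list(), quick = FALSE) {
  cfg <- list(
    outdir = outdir, seed = as.integer(seed),
    synthetic = utils::modifyList(list(n_decoys = 10), synthetic),
    paths = paths,
    regulator_gene = regulator_gene, regulator_pwm = regulator_pwm,
    scoring = utils::modifyList(list(s0_rule = "median"), scoring),
    tfa = utils::modifyList(
      list(n_perm = if (quick) 1000 else 10000, min_expected = 10,
           min_cell_expected = 5, grid_step = NULL, removal_step = NULL,
           significance = 2, quorum = 6, directions = c("up", "down"),
           share_null = TRUE),
      tfa),
    cohort = utils::modifyList(
      list(B = if (quick) 100 else 1000, min_size = 10, baseline = "all",
           null_mode = "values", q_cutoff = 0.267), cohort),
    quick = quick)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Load a pipeline configuration from YAML
#'
#' @param path YAML file whose top-level keys are [pipeline_config()]
#'   arguments.
#' @param ... overrides applied after reading.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path, ...) {
  raw <- yaml::read_yaml(path)
  over <- list(...)
  for (nm in names(over)) raw[[nm]] <- over[[nm]]
  do.call(pipeline_config, raw)
}

pipeline_log <- function(...) {
  message(format(Sys.time(), "[%H:%M:%S] "), ...)
}

# Header comment carried by every pipeline output table. The checksum
# identifies the scientific configuration, not its location: outdir is
# excluded so identical analyses in different directories match.
output_header <- function(config) {
  cfg <- config
  cfg$outdir <- NULL
  chk <- substr(tools::md5sum(write_config(cfg, tempfile()))[[1]], 1, 12)
  sprintf("# tfcohort %s config_checksum=%s",
          as.character(utils::packageVersion("tfcohort")), chk)
}

write_config <- function(config, path) {
  cfg <- unclass(config)
  yaml::write_yaml(cfg, path)
  path
}

write_pipeline_tsv <- function(df, path, config) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(output_header(config), con)
  suppressWarnings(write.table(df, con, sep = "\t", quote = FALSE,
                               row.names = FALSE))
  invisible(path)
}

#' Simulate a ground-truthed synthetic dataset on disk
#'
#' Emits the promoter FASTA, the regulator + decoy matrices in TRANSFAC
#' flat format, one expression TSV per comparison, the GMT group file, the
#' truth tables, the resolved configuration and a checksum manifest.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list with the generated objects (`pwms`,
#'   `promoters`, `truth`, `comparisons`, `groups`) and `files`.
#' @export
run_simulate <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$outdir
  if (!dir.exists(out) && !dir.create(out, recursive = TRUE))
    stop("cannot create output directory ", out)
  syn_args <- config$synthetic
  n_decoys <- syn_args$n_decoys %||% 10
  syn_args$n_decoys <- NULL
  syn_args$seed <- syn_args$seed %||% config$seed
  scfg <- do.call(synthetic_config, syn_args)
  pipeline_log("simulate: ", scfg$n_genes, " genes, ", scfg$n_comparisons,
               " comparisons, ", scfg$n_targets, " targets")
  pw <- make_regulator_pwm(scfg$seed, n_decoys = n_decoys)
  pr <- generate_promoters(scfg, pw$regulator)
  comparisons <- generate_expression(scfg, pr$truth)
  gg <- generate_gene_groups(scfg, pr$truth)
  files <- character(0)
  f <- file.path(out, "promoters.fasta")
  write_promoters_fasta(pr$promoters, f); files <- c(files, f)
  f <- file.path(out, "pwms.transfac")
  write_pwm_transfac(pw$all, f); files <- c(files, f)
  for (cc in comparisons) {
    f <- file.path(out, paste0(cc$comparison_id, ".tsv"))
    write_expression_tsv(cc, f); files <- c(files, f)
  }
  f <- file.path(out, "groups.gmt")
  write_gmt(gg$groups, f); files <- c(files, f)
  files <- c(files, write_truth_tsv(gg$truth, file.path(out, "truth")))
  files <- c(files, write_config(config, file.path(out, "config.yaml")))
  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)))
  write.table(manifest, file.path(out, "manifest.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  pipeline_log("simulate: wrote ", length(files), " files to ", out)
  invisible(list(pwms = pw$all, promoters = pr$promoters,
                 truth = gg$truth, comparisons = comparisons,
                 groups = gg$groups,
                 files = c(files, file.path(out, "manifest.tsv"))))
}

# Resolve pipeline inputs: user paths when configured, else the artifacts
# written by run_simulate() in outdir.
load_pipeline_inputs <- function(config) {
  out <- config$outdir
  p <- config$paths
  expr_files <- p$expression %||%
    sort(list.files(out, pattern = "^comparison_[0-9]+\\.tsv$",
                    full.names = TRUE))
  if (length(expr_files) == 0) stop("no expression TSVs found; run simulate ",
                                    "first or configure paths$expression")
  comparisons <- lapply(expr_files, read_expression_tsv)
  promoters <- read_promoters_fasta(p$promoters %||%
                                      file.path(out, "promoters.fasta"))
  pwms <- read_pwm_transfac(p$pwms %||% file.path(out, "pwms.transfac"))
  groups <- read_gmt(p$groups %||% file.path(out, "groups.gmt"))
  list(comparisons = comparisons, promoters = promoters, pwms = pwms,
       groups = groups)
}

#' Run the transcription factor activity screen
#'
#' Expression scoring, promoter scanning for every matrix, and the
#' max-chi-square TFA screen with extrapolated significance. Writes the
#' gene score table, per-matrix propensity tables, per-screen results,
#' the per-matrix summary and the null-fit diagnostics.
#'
#' @param config a [pipeline_config()].
#' @param resume reuse existing stage outputs when present (default FALSE).
#' @return invisibly, the [tfa_screen()] result list plus `score_table` and
#'   `tp_tables`.
#' @export
run_screen <- function(config, resume = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$outdir
  res_file <- file.path(out, "tfa_results.tsv")
  if (resume && file.exists(res_file) &&
      file.exists(file.path(out, "score_table.tsv"))) {
    pipeline_log("screen: outputs present, resuming without recompute")
    return(invisible(NULL))
  }
  inputs <- load_pipeline_inputs(config)
  pipeline_log("screen: scoring ", length(inputs$comparisons),
               " comparisons")
  st <- gene_score_table(inputs$comparisons, config$regulator_gene,
                         s0_rule = config$scoring$s0_rule)
  write_score_table(st, file.path(out, "score_table.tsv"))
  pipeline_log("screen: scanning ", length(inputs$pwms), " matrices over ",
               length(inputs$promoters), " promoters")
  tp_tables <- lapply(inputs$pwms, function(p)
    target_propensity_table(inputs$promoters, p))
  for (nm in names(tp_tables))
    write_propensity_table(tp_tables[[nm]],
                           file.path(out, paste0("propensity_", nm, ".tsv")))
  tfa <- config$tfa
  pipeline_log("screen: TFA, n_perm = ", tfa$n_perm)
  scr <- tfa_screen(st, tp_tables, directions = tfa$directions,
                    n_perm = tfa$n_perm, seed = config$seed,
                    min_expected = tfa$min_expected,
                    grid_step = tfa$grid_step,
                    removal_step = tfa$removal_step,
                    min_cell_expected = tfa$min_cell_expected,
                    significance = tfa$significance, quorum = tfa$quorum,
                    share_null = tfa$share_null)
  write_pipeline_tsv(scr$results, res_file, config)
  write_pipeline_tsv(scr$summary, file.path(out, "tfa_summary.tsv"), config)
  write_pipeline_tsv(scr$null_fit, file.path(out, "tfa_null_fit.tsv"),
                     config)
  pipeline_log("screen: done; top matrix (up): ",
               scr$summary$pwm_id[scr$summary$direction == "up"][1])
  invisible(c(scr, list(score_table = st, tp_tables = tp_tables)))
}

#' Run the target-cohort analysis
#'
#' The min-P permutation screen of the configured gene groups against the
#' regulator matrix's propensity table, with q-values, per-group separation
#' diagnostics and cohort gene lists for groups passing the q cutoff.
#'
#' @inheritParams run_screen
#' @return invisibly, the [run_target_cohort()] result plus
#'   `cohort_genes`.
#' @export
run_cohort <- function(config, resume = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$outdir
  res_file <- file.path(out, "cohort_results.tsv")
  if (resume && file.exists(res_file)) {
    pipeline_log("cohort: outputs present, resuming without recompute")
    return(invisible(NULL))
  }
  st_file <- file.path(out, "score_table.tsv")
  tp_file <- file.path(out, paste0("propensity_", config$regulator_pwm,
                                   ".tsv"))
  if (!file.exists(st_file) || !file.exists(tp_file)) {
    pipeline_log("cohort: screen outputs missing; running screen first")
    run_screen(config, resume = resume)
  }
  st <- read_score_table(st_file)
  if (!(config$regulator_gene %in% st$genes))
    stop("regulator gene '", config$regulator_gene,
         "' missing from the expression data")
  tpt <- read_propensity_table(tp_file)
  inputs <- load_pipeline_inputs(config)
  ch <- config$cohort
  pipeline_log("cohort: testing ", length(inputs$groups), " groups, B = ",
               ch$B)
  cr <- run_target_cohort(inputs$groups, st, tpt, B = ch$B,
                          seed = config$seed, min_size = ch$min_size,
                          baseline = ch$baseline,
                          null_mode = ch$null_mode)
  if (is.null(cr$results)) {
    warning("no testable groups; writing empty results")
    write_pipeline_tsv(data.frame(group = character(0),
                                  metric = character(0),
                                  size = integer(0),
                                  min_interim_p = numeric(0),
                                  final_p = numeric(0), q = numeric(0)),
                       res_file, config)
    return(invisible(list(results = NULL, cohort_genes = list())))
  }
  write_pipeline_tsv(cr$results, res_file, config)
  prof_rows <- do.call(rbind, lapply(names(cr$profiles), function(g)
    data.frame(group = g, cr$profiles[[g]])))
  write_pipeline_tsv(prof_rows, file.path(out, "cohort_profiles.tsv"),
                     config)
  # separation diagnostics + cohort genes for groups passing the q cutoff
  tp <- setNames(tpt$tp, tpt$gene)
  hits <- unique(cr$results$group[cr$results$metric == "de" &
                                    cr$results$q <= ch$q_cutoff])
  sep_rows <- list()
  cohort_genes <- list()
  for (g in hits) {
    members <- intersect(inputs$groups[[g]], st$genes)
    gdf <- data.frame(gene = members, tp = tp[members],
                      de = st$de_score[match(members, st$genes)],
                      dp = st$dp[match(members, st$genes)],
                      cov = st$cov[match(members, st$genes)])
    sep <- separation_threshold(cr$profiles[[g]])
    if (is.na(sep$tau_star) || sum(gdf$tp < sep$tau_star) < 2) next
    cuts <- envelope_cutoffs(gdf, sep$tau_star)
    cohort_genes[[g]] <- identify_cohort(gdf, sep$tau_star, cuts)
    sep_rows[[g]] <- data.frame(group = g, tau_star = sep$tau_star,
                                de_cutoff = cuts$de_cutoff,
                                dp_cutoff = cuts$dp_cutoff,
                                cov_cutoff = cuts$cov_cutoff,
                                n_cohort = length(cohort_genes[[g]]))
  }
  if (length(sep_rows) > 0) {
    write_pipeline_tsv(do.call(rbind, sep_rows),
                       file.path(out, "cohort_separation.tsv"), config)
    write_pipeline_tsv(
      do.call(rbind, lapply(names(cohort_genes), function(g)
        if (length(cohort_genes[[g]]) > 0)
          data.frame(group = g, gene = cohort_genes[[g]]))),
      file.path(out, "cohort_genes.tsv"), config)
  }
  pipeline_log("cohort: ", length(hits), " group(s) at q <= ", ch$q_cutoff)
  invisible(c(cr, list(cohort_genes = cohort_genes)))
}

#' Run the full pipeline
#'
#' [run_simulate()] (unless user paths are configured), then
#' [run_screen()], then [run_cohort()].
#'
#' @inheritParams run_screen
#' @return invisibly, a list with the stage results.
#' @export
run_all <- function(config, resume = FALSE) {
  sim <- if (is.null(config$paths)) run_simulate(config) else NULL
  scr <- run_screen(config, resume = resume)
  coh <- run_cohort(config, resume = resume)
  invisible(list(simulate = sim, screen = scr, cohort = coh))
}
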