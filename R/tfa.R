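#' Yates-corrected chi-square for a 2x2 table
#'
#' \eqn{\chi^2 = N (\max(0, |ad - bc| - N/2))^2 /
#' ((a+b)(c+d)(a+c)(b+d))}. Tables with a zero margin return 0 with a
#' message (the screen's admissibility constraints exclude them anyway).
#'
#' @param a,b,c,d non-negative cell counts.
#' @return the corrected statistic.
#' @export
yates_chi_square <- function(a, b, c, d) {
  n <- a + b + c + d
  if (n <= 0) stop("empty table")
  m <- c(a + b, c + d, a + c, b + d)
  if (any(m == 0)) {
    message("zero margin: chi-square set to 0")
    return(0)
  }
  u <- max(0, abs(a * d - b * c) - n / 2)
  n * u^2 / prod(m)
}

#' Ranked input for the TFA screen
#'
#' Pairs the SAM ordering of one comparison with the target-propensity
#' ordering of one matrix over a shared gene universe. The up-regulated
#' screen ranks by descending signed scaled SAM score, the down-regulated
#' screen by ascending; propensity always ranks descending. Ties are broken
#' by gene ID, identically in observed and null runs.
#'
#' @param sam_scores named per-gene scaled SAM scores (one comparison).
#' @param tp named per-gene target propensity.
#' @param direction `"up"` or `"down"`.
#' @return a `ranked_input`: list with `genes`, `tp_of_sam` (propensity rank
#'   of the gene at each SAM rank), `N`, `direction`.
#' @export
ranked_input <- function(sam_scores, tp, direction = c("up", "down")) {
  direction <- match.arg(direction)
  genes <- names(sam_scores)
  if (is.null(genes) || is.null(names(tp)))
    stop("sam_scores and tp must be named by gene")
  missing <- setdiff(genes, names(tp))
  extra <- setdiff(names(tp), genes)
  if (length(missing) > 0 || length(extra) > 0)
    stop("gene universe mismatch; missing from tp: ",
         paste(head(missing, 5), collapse = ", "),
         if (length(missing) > 5) " ...", "; absent from scores: ",
         paste(head(extra, 5), collapse = ", "),
         if (length(extra) > 5) " ...")
  tp <- tp[genes]
  s <- if (direction == "up") -sam_scores else sam_scores
  sam_ord <- order(s, genes)             # best-ranked first
  tp_rank <- rank_desc(as.numeric(tp), genes)
  structure(list(genes = genes, tp_of_sam = tp_rank[sam_ord],
                 N = length(genes), direction = direction),
            class = "ranked_input")
}

default_grid_step <- function(N) if (N <= 2000) 1L else as.integer(ceiling(N / 2000))

#' Maximum chi-square over all rank-threshold pairs
#'
#' Scans every pair of thresholds (r_s over the SAM ranking, r_t over the
#' propensity ranking) on a grid, keeping the maximum Yates-corrected
#' chi-square among tables whose expected overlap `r_s r_t / N` exceeds
#' `min_expected` and whose observed overlap exceeds expected. With
#' `grid_step = 1` the scan is exhaustive.
#'
#' @param input a [ranked_input()].
#' @param min_expected minimum expected overlap for an admissible table
#'   (default 10, strict).
#' @param grid_step rank grid spacing; default 1 for N <= 2000, else
#'   `ceiling(N / 2000)`.
#' @param min_cell_expected chi-square validity floor: every cell's expected
#'   count must reach this value (default 5). Near-degenerate corner tables
#'   otherwise dominate the null maximum and break the linearity of
#'   \eqn{-\log p} in the statistic that the extrapolation relies on.
#' @return list with `chi2`, `r_s`, `r_t`, `admissible` (FALSE when no table
#'   passed the constraints, in which case `chi2` is 0).
#' @export
max_chi_square <- function(input, min_expected = 10, grid_step = NULL,
                           min_cell_expected = 5) {
  stopifnot(inherits(input, "ranked_input"))
  if (input$N < 4 * min_expected)
    stop("gene universe too small for min_expected = ", min_expected)
  gs <- as.integer(grid_step %||% default_grid_step(input$N))
  cpp_max_chisq(input$tp_of_sam, gs, min_expected, min_cell_expected)
}

#' Incremental-removal refinement of the maximum chi-square
#'
#' True targets need not top the SAM ranking: the scan removes the top-k
#' SAM-ranked genes (k = 0, step, 2 step, ... up to `max_depth`, default the
#' base maximizer's r_s) and re-runs [max_chi_square()] on the reduced
#' universe; the statistic is the maximum over depths. The identical
#' schedule runs inside the permutation null, keeping observed and null
#' exchangeable.
#'
#' @inheritParams max_chi_square
#' @param removal_step depth increment; default `ceiling(max_depth / 3)`
#'   (at most 4 depths are evaluated).
#' @param max_depth deepest removal; default the base maximizer's r_s.
#' @return list with `chi2`, `r_s`, `r_t`, `removal_depth`, the base-scan
#'   `base_chi2`/`base_r_s`/`base_r_t`, and `admissible`.
#' @export
removal_scan <- function(input, min_expected = 10, grid_step = NULL,
                         removal_step = NULL, max_depth = NULL,
                         min_cell_expected = 5) {
  stopifnot(inherits(input, "ranked_input"))
  gs <- as.integer(grid_step %||% default_grid_step(input$N))
  md <- as.integer(max_depth %||% -1L)
  cap <- input$N - as.integer(4 * min_expected)
  if (md > cap) {
    warning("max_depth truncated to ", cap)
    md <- cap
  }
  cpp_removal_stat(input$tp_of_sam, gs, min_expected, min_cell_expected,
                   as.integer(removal_step %||% -1L), md)
}

#' Permutation null of the screen statistic
#'
#' Permutes the propensity ordering relative to the SAM ordering `n_perm`
#' times and recomputes the full statistic (constraints and removal
#' schedule included) for each draw.
#'
#' @inheritParams removal_scan
#' @param n_perm number of permutations (default 10000).
#' @param seed RNG seed for the permutation stream.
#' @param use_removal apply the removal schedule inside the null
#'   (default TRUE; must match how the observed statistic is computed).
#' @return sorted numeric vector of null statistics.
#' @export
null_distribution <- function(input, n_perm = 10000, seed = 1,
                              min_expected = 10, grid_step = NULL,
                              removal_step = NULL, max_depth = NULL,
                              min_cell_expected = 5, use_removal = TRUE) {
  N <- if (inherits(input, "ranked_input")) input$N else as.integer(input)
  if (n_perm < 100) stop("n_perm must be >= 100")
  gs <- as.integer(grid_step %||% default_grid_step(N))
  sort(cpp_null_stats(N, as.integer(n_perm), gs, min_expected,
                      min_cell_expected,
                      as.integer(removal_step %||% -1L),
                      as.integer(max_depth %||% -1L),
                      as.integer(seed), use_removal))
}

#' Extrapolated significance from a permutation null
#'
#' Empirical tail probabilities are computed at null sample points with
#' \eqn{\hat p \in [10/n_{perm}, 0.5]} (unsmoothed counts) and
#' \eqn{-\log_{10}\hat p} is regressed on the statistic by ordinary least
#' squares. Where the empirical tail probability is reliably measurable
#' (\eqn{\hat p \ge 10/n_{perm}}) the empirical value itself is reported,
#' keeping permuted inputs uniformly calibrated; beyond that window the
#' fitted line takes over, floored at the empirical value so extrapolation
#' never reduces significance inside the sampled range.
#'
#' @param null_sample numeric null statistics (>= 100 draws).
#' @param observed the observed statistic.
#' @return list with `neg_log10_p`, `fit_r2`, `slope`, `intercept`,
#'   `n_fit_points`, `empirical_neg_log10_p`.
#' @export
extrapolate_logp <- function(null_sample, observed) {
  n <- length(null_sample)
  if (n < 100) stop("null sample must have >= 100 draws")
  xs <- sort(null_sample)
  # tail probability at each sampled point: #(null >= x) / n
  ux <- unique(xs)
  tail_ge <- n - findInterval(ux, xs, left.open = TRUE)
  p_hat <- tail_ge / n
  keep <- p_hat >= 10 / n & p_hat <= 0.5
  emp_p <- (n - findInterval(observed, xs, left.open = TRUE)) / n
  emp_nl <- if (emp_p > 0) -log10(emp_p) else Inf
  if (sum(keep) < 10) {
    warning("fewer than 10 points in the fitting window; ",
            "falling back to the empirical p-value")
    return(list(neg_log10_p = if (is.finite(emp_nl)) emp_nl
                else -log10(1 / n),
                fit_r2 = NA_real_, slope = NA_real_, intercept = NA_real_,
                n_fit_points = sum(keep), empirical_neg_log10_p = emp_nl))
  }
  fit <- lm(y ~ x, data = data.frame(x = ux[keep], y = -log10(p_hat[keep])))
  r2 <- summary(fit)$r.squared
  fitted_nl <- unname(coef(fit)[1] + coef(fit)[2] * observed)
  nl <- if (emp_p >= 10 / n) emp_nl                  # measurable region
  else max(fitted_nl, min(emp_nl, log10(n)), 0)      # extrapolation region
  list(neg_log10_p = nl, fit_r2 = r2,
       slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       n_fit_points = sum(keep), empirical_neg_log10_p = emp_nl)
}

#' Genome-wide transcription factor activity screen
#'
#' One result per (matrix, comparison, direction): the removal-refined
#' maximum chi-square with its extrapolated \eqn{-\log_{10}} P-value, plus a
#' per-matrix summary with the mean and median significance per direction,
#' the number of comparisons exceeding `significance`, and the
#' quorum-consistency flag.
#'
#' The null distribution of the statistic depends only on the universe size
#' and scan settings, so by default one null sample per universe size is
#' shared across matrices, comparisons and directions.
#'
#' @param score_table a [gene_score_table()].
#' @param tp_tables named list of [target_propensity_table()] objects (one
#'   per matrix).
#' @param directions screen directions, subset of `c("up", "down")`.
#' @param n_perm null sample size (default 10000).
#' @param seed RNG seed.
#' @param min_expected,grid_step,removal_step,max_depth see
#'   [removal_scan()].
#' @param significance \eqn{-\log_{10} p} threshold counting a comparison as
#'   significant (default 2).
#' @param quorum comparisons required for the consistency flag (default 6).
#' @param share_null share one null per universe size (default TRUE); when
#'   FALSE every (matrix, comparison, direction) draws its own null.
#' @return list with `results` (data.frame, one row per screen), `summary`
#'   (per matrix x direction), and `null_fit` (per-null fit diagnostics).
#' @export
tfa_screen <- function(score_table, tp_tables,
                       directions = c("up", "down"),
                       n_perm = 10000, seed = 1, min_expected = 10,
                       grid_step = NULL, removal_step = NULL,
                       max_depth = NULL, min_cell_expected = 5,
                       significance = 2, quorum = 6,
                       share_null = TRUE) {
  stopifnot(inherits(score_table, "gene_score_table"),
            length(tp_tables) >= 1)
  directions <- match.arg(directions, several.ok = TRUE)
  if (is.null(names(tp_tables)))
    names(tp_tables) <- vapply(tp_tables, attr, "", "pwm_id")
  genes <- score_table$genes
  nulls <- list()
  rows <- list()
  null_id <- 0L
  for (pwm_id in names(tp_tables)) {
    tpt <- tp_tables[[pwm_id]]
    tp <- setNames(tpt$tp, tpt$gene)
    for (ci in seq_len(score_table$n_comparisons)) {
      comp_id <- colnames(score_table$z)[ci]
      z <- setNames(score_table$z[, ci], genes)
      for (dir in directions) {
        inp <- ranked_input(z, tp, dir)
        obs <- removal_scan(inp, min_expected, grid_step, removal_step,
                            max_depth, min_cell_expected)
        key <- if (share_null) sprintf("N%d", inp$N)
        else sprintf("%s|%s|%s", pwm_id, comp_id, dir)
        if (is.null(nulls[[key]])) {
          null_id <- null_id + 1L
          nulls[[key]] <- list(
            sample = null_distribution(inp, n_perm,
                                       derive_seed(seed, null_id),
                                       min_expected, grid_step,
                                       removal_step, max_depth,
                                       min_cell_expected),
            id = key)
        }
        ex <- extrapolate_logp(nulls[[key]]$sample, obs$chi2)
        rows[[length(rows) + 1L]] <- data.frame(
          pwm_id = pwm_id, comparison_id = comp_id, direction = dir,
          chi2_max = obs$chi2, r_s = obs$r_s, r_t = obs$r_t,
          removal_depth = obs$removal_depth,
          base_chi2 = obs$base_chi2, admissible = obs$admissible,
          neg_log10_p = ex$neg_log10_p, fit_r2 = ex$fit_r2,
          null_id = key)
      }
    }
  }
  results <- do.call(rbind, rows)
  summary <- do.call(rbind, lapply(split(
    results, list(results$pwm_id, results$direction), drop = TRUE),
    function(d) data.frame(
      pwm_id = d$pwm_id[1], direction = d$direction[1],
      n_comparisons = nrow(d),
      mean_neg_log10_p = mean(d$neg_log10_p),
      median_neg_log10_p = median(d$neg_log10_p),
      n_significant = sum(d$neg_log10_p >= significance),
      consistent = sum(d$neg_log10_p >= significance) >= quorum)))
  rownames(summary) <- NULL
  summary <- summary[order(summary$direction,
                           -summary$mean_neg_log10_p), ]
  null_fit <- do.call(rbind, lapply(nulls, function(nl) {
    # fit diagnostics of each null against itself (R^2 of the linear tail)
    ex <- extrapolate_logp(nl$sample, max(nl$sample))
    data.frame(null_id = nl$id, n_perm = length(nl$sample),
               fit_r2 = ex$fit_r2, slope = ex$slope,
               intercept = ex$intercept, n_fit_points = ex$n_fit_points)
  }))
  rownames(null_fit) <- NULL
  list(results = results, summary = summary, null_fit = null_fit)
}
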