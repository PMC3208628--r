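#' Score increment of a group at a propensity threshold
#'
#' \eqn{\Delta(\tau)} = mean metric over members with `tp >= tau` minus the
#' baseline mean (the whole-group mean by default; `baseline = "below"` uses
#' the below-threshold mean instead). Thresholds leaving either side empty
#' are inadmissible and are skipped by the permutation test.
#'
#' @param metric_values per-member metric values.
#' @param tp per-member target propensity (same order).
#' @param tau propensity threshold.
#' @param baseline `"all"` or `"below"`.
#' @return the increment, or `NA` when `tau` is inadmissible.
#' @export
score_increment <- function(metric_values, tp, tau, baseline = c("all", "below")) {
  baseline <- match.arg(baseline)
  stopifnot(length(metric_values) == length(tp))
  above <- tp >= tau
  if (!any(above)) return(NA_real_)
  if (all(above))
    return(if (baseline == "all") 0 else NA_real_)
  ref <- if (baseline == "all") mean(metric_values)
  else mean(metric_values[!above])
  mean(metric_values[above]) - ref
}

# Default threshold grid: the deciles of the group's propensity values,
# restricted to admissible cuts (>= 1 member on each side).
default_thresholds <- function(tp) {
  qs <- unique(quantile(tp, probs = seq(0.1, 0.9, by = 0.1), names = FALSE,
                        type = 7))
  qs[vapply(qs, function(t) any(tp >= t) && any(tp < t), TRUE)]
}

# Core permutation engine for one group and one metric.
#
# The group's propensity values stay fixed; each of the B sampled groups
# assigns its members metric values drawn without replacement from the
# global per-gene pool (idx_matrix: m x B pool indices; can be shared
# across metrics to preserve inter-metric correlation).
#
# All B+1 units (observed group + samples) are ranked jointly at every
# threshold: each unit's interim p is the fraction of units (including
# itself — for the observed group this self-count is exactly the +1
# smoothing term) whose increment reaches its own. This keeps the units
# exchangeable, so the min-P final p of a null group is uniform up to
# tie-induced conservatism; every sampled group's min interim p is computed
# leave-self-in, and the final p is the min-P family-wise adjustment over
# thresholds.
cohort_perm_test <- function(metric_group, tp_group, metric_pool,
                             thresholds, idx_matrix, baseline = "all") {
  m <- length(metric_group)
  B <- ncol(idx_matrix)
  ord <- order(-tp_group)
  tp_sorted <- tp_group[ord]
  x_obs <- metric_group[ord]
  ks <- vapply(thresholds, function(t) sum(tp_sorted >= t), 0L)
  ok <- ks >= 1L & ks <= m - 1L
  if (!any(ok))
    return(list(thresholds = thresholds, interim_p = rep(NA_real_,
                length(thresholds)), min_interim_p = NA_real_,
                final_p = NA_real_, delta_obs = rep(NA_real_,
                length(thresholds))))
  samp <- matrix(metric_pool[idx_matrix], nrow = m)
  cs <- apply(samp, 2, cumsum)                     # m x B prefix sums
  tot <- cs[m, ] / m
  cs_obs <- cumsum(x_obs)
  tot_obs <- cs_obs[m] / m
  nt <- length(thresholds)
  delta_obs <- rep(NA_real_, nt)
  interim_p <- rep(NA_real_, nt)
  minp_samp <- rep(Inf, B)
  min_interim <- Inf
  for (ti in seq_len(nt)) {
    if (!ok[ti]) next
    k <- ks[ti]
    if (baseline == "all") {
      d_obs <- cs_obs[k] / k - tot_obs
      d_b <- cs[k, ] / k - tot
    } else {
      d_obs <- cs_obs[k] / k - (cs_obs[m] - cs_obs[k]) / (m - k)
      d_b <- cs[k, ] / k - (cs[m, ] - cs[k, ]) / (m - k)
    }
    delta_obs[ti] <- d_obs
    # joint rank of all B+1 increments: p_u = #(units >= u) / (B+1)
    all_d <- c(d_obs, d_b)
    p_all <- (B + 2 - rank(all_d, ties.method = "min")) / (B + 1)
    interim_p[ti] <- p_all[1]
    minp_samp <- pmin(minp_samp, p_all[-1])
    min_interim <- min(min_interim, interim_p[ti])
  }
  final_p <- (1 + sum(minp_samp <= min_interim)) / (B + 1)
  list(thresholds = thresholds, interim_p = interim_p,
       min_interim_p = min_interim, final_p = final_p,
       delta_obs = delta_obs)
}

#' Interim permutation p-values across propensity thresholds
#'
#' For each threshold, the interim p-value is the (+1-smoothed) proportion
#' of sampled groups whose score increment reaches the tested group's. The
#' sampled groups keep the group's propensity values and draw metric values
#' without replacement from the global pool.
#'
#' @param metric_group per-member metric values of the tested group.
#' @param tp_group per-member target propensity (same order).
#' @param metric_pool global per-gene metric pool (the scored universe).
#' @param thresholds propensity thresholds; default the group's deciles.
#' @param B number of sampled groups (>= 100).
#' @param seed RNG seed.
#' @param baseline see [score_increment()].
#' @return list with `thresholds`, `interim_p`, `delta_obs`.
#' @export
interim_pvalues <- function(metric_group, tp_group, metric_pool,
                            thresholds = NULL, B = 1000, seed = 1,
                            baseline = "all") {
  if (B < 100) stop("B must be >= 100")
  m <- length(metric_group)
  if (m > length(metric_pool)) stop("group larger than the gene universe")
  thresholds <- thresholds %||% default_thresholds(tp_group)
  idx <- with_seed(seed, vapply(seq_len(B), function(b)
    sample.int(length(metric_pool), m), integer(m)))
  res <- cohort_perm_test(metric_group, tp_group, metric_pool, thresholds,
                          idx, baseline)
  res[c("thresholds", "interim_p", "delta_obs")]
}

#' Min-P final p-value over propensity thresholds
#'
#' Computes every sampled group's own minimum interim p-value against the
#' full sample (leave-self-in) and reports the proportion whose minimum is
#' at or below the tested group's: a min-P family-wise adjustment that keeps
#' the test valid for any threshold grid.
#'
#' @inheritParams interim_pvalues
#' @return list with `thresholds`, `interim_p`, `min_interim_p`, `final_p`,
#'   `delta_obs`.
#' @export
minp_final_pvalue <- function(metric_group, tp_group, metric_pool,
                              thresholds = NULL, B = 1000, seed = 1,
                              baseline = "all") {
  if (B < 100) stop("B must be >= 100")
  m <- length(metric_group)
  if (m > length(metric_pool)) stop("group larger than the gene universe")
  thresholds <- thresholds %||% default_thresholds(tp_group)
  idx <- with_seed(seed, vapply(seq_len(B), function(b)
    sample.int(length(metric_pool), m), integer(m)))
  cohort_perm_test(metric_group, tp_group, metric_pool, thresholds, idx,
                   baseline)
}

#' Screen gene groups for regulator-controlled target cohorts
#'
#' Runs the min-P permutation test for every group and metric, then attaches
#' Storey-Tibshirani q-values per metric across groups. Groups are
#' intersected with the scored universe; undersized groups are dropped with
#' a message.
#'
#' @param groups named list of member vectors (e.g. from [read_gmt()]).
#' @param score_table a [gene_score_table()].
#' @param tp_table a [target_propensity_table()] on the same universe.
#' @param B sampled groups per test (default 1000).
#' @param seed RNG seed.
#' @param metrics metrics to test (default de, dp, cov; similarity metrics
#'   enter signed).
#' @param min_size minimum group size after intersection (default 10).
#' @param baseline see [score_increment()].
#' @param null_mode `"values"` draws each metric's null independently;
#'   `"rows"` draws one set of genes per sampled group and reuses their
#'   values across metrics, preserving inter-metric correlation.
#' @param lambda_grid passed to [storey_qvalues()].
#' @return a `cohort_results` list: `results` (data.frame: group, metric,
#'   size, min_interim_p, final_p, q), `profiles` (per group: thresholds and
#'   per-metric interim p), `settings`.
#' @export
run_target_cohort <- function(groups, score_table, tp_table, B = 1000,
                              seed = 1, metrics = c("de", "dp", "cov"),
                              min_size = 10, baseline = "all",
                              null_mode = c("values", "rows"),
                              lambda_grid = seq(0.05, 0.95, by = 0.05)) {
  null_mode <- match.arg(null_mode)
  stopifnot(inherits(score_table, "gene_score_table"))
  tp <- setNames(tp_table$tp, tp_table$gene)
  universe <- intersect(score_table$genes, names(tp))
  pools <- lapply(setNames(metrics, metrics), function(mt)
    score_metric(score_table, mt)[match(universe, score_table$genes)])
  undefined <- vapply(pools, function(p) all(is.na(p)), TRUE)
  if (any(undefined)) {
    message("metric(s) undefined on this input, dropped: ",
            paste(metrics[undefined], collapse = ", "))
    metrics <- metrics[!undefined]
    pools <- pools[!undefined]
  }
  rows <- list()
  profiles <- list()
  gi <- 0L
  for (gname in names(groups)) {
    gi <- gi + 1L
    members <- intersect(groups[[gname]], universe)
    if (length(members) == 0) {
      message("group '", gname, "' has no scored members; skipped")
      next
    }
    if (length(members) < min_size) {
      message("group '", gname, "' below min_size after intersection (",
              length(members), "); skipped")
      next
    }
    tp_g <- tp[members]
    thresholds <- default_thresholds(tp_g)
    if (length(thresholds) == 0) {
      message("group '", gname, "' has a degenerate propensity profile; ",
              "skipped")
      next
    }
    idx_shared <- if (null_mode == "rows")
      with_seed(derive_seed(seed, gi), vapply(seq_len(B), function(b)
        sample.int(length(universe), length(members)),
        integer(length(members))))
    else NULL
    prof <- data.frame(threshold = thresholds)
    for (mi in seq_along(metrics)) {
      mt <- metrics[mi]
      pool <- pools[[mt]]
      vals <- pool[match(members, universe)]
      idx <- idx_shared %||%
        with_seed(derive_seed(seed, gi * 131L + mi),
                  vapply(seq_len(B), function(b)
                    sample.int(length(universe), length(members)),
                    integer(length(members))))
      res <- cohort_perm_test(vals, tp_g, pool, thresholds, idx, baseline)
      rows[[length(rows) + 1L]] <- data.frame(
        group = gname, metric = mt, size = length(members),
        min_interim_p = res$min_interim_p, final_p = res$final_p)
      prof[[paste0("interim_p_", mt)]] <- res$interim_p
    }
    profiles[[gname]] <- prof
  }
  results <- do.call(rbind, rows)
  if (!is.null(results)) {
    results$q <- NA_real_
    for (mt in unique(results$metric)) {
      sel <- results$metric == mt
      results$q[sel] <- storey_qvalues(results$final_p[sel], lambda_grid)
    }
  }
  structure(list(results = results, profiles = profiles,
                 settings = list(B = B, seed = seed, metrics = metrics,
                                 min_size = min_size, baseline = baseline,
                                 null_mode = null_mode)),
            class = "cohort_results")
}

#' Storey-Tibshirani q-values
#'
#' \eqn{\hat\pi_0} is estimated by the natural-cubic-spline smoother of
#' \eqn{\hat\pi_0(\lambda) = \#\{p > \lambda\} / (m(1-\lambda))} over the
#' lambda grid, evaluated at the largest lambda;
#' \eqn{q_i = \min_{t \ge p_i} \hat\pi_0 m t / \#\{p \le t\}}.
#'
#' @param pvals p-values in (0, 1].
#' @param lambda_grid tuning grid (default 0.05 to 0.95 by 0.05).
#' @param pi0 optional fixed null proportion overriding the estimate.
#' @return q-values, monotone non-decreasing in p.
#' @export
storey_qvalues <- function(pvals, lambda_grid = seq(0.05, 0.95, by = 0.05),
                           pi0 = NULL) {
  m <- length(pvals)
  if (any(pvals <= 0 | pvals > 1)) stop("p-values must lie in (0, 1]")
  if (is.null(pi0)) {
    if (m < 10) {
      warning("fewer than 10 p-values; pi0 fixed at 1")
      pi0 <- 1
    } else {
      pi0_l <- vapply(lambda_grid, function(l) mean(pvals > l) / (1 - l), 0)
      fit <- smooth.spline(lambda_grid, pi0_l, df = 3)
      pi0 <- predict(fit, x = max(lambda_grid))$y
      pi0 <- min(max(pi0, 1 / m), 1)
    }
  }
  ord <- order(pvals, decreasing = TRUE)
  q <- numeric(m)
  q[ord] <- cummin(pi0 * m * pvals[ord] / rank(pvals, ties.method = "max")[ord])
  pmin(q, 1)
}

#' Target-propensity separation threshold
#'
#' Averages \eqn{-\log_{10}} interim p across metrics at each threshold and
#' reports the plateau onset: the largest threshold whose profile value is
#' within `tolerance` of the maximum (significance rises as the threshold
#' decreases, then plateaus). A manual override wins when supplied, since
#' reference analyses chose separation thresholds by inspection.
#'
#' @param profile data.frame from [run_target_cohort()]'s `profiles`:
#'   column `threshold` plus `interim_p_*` columns.
#' @param tolerance relative tolerance defining the plateau (default 0.10).
#' @param manual_override optional threshold that bypasses the rule.
#' @return list with `tau_star` (NA when the profile is flat), `profile`
#'   (threshold and averaged \eqn{-\log_{10}} p), `flat`.
#' @export
separation_threshold <- function(profile, tolerance = 0.10,
                                 manual_override = NULL) {
  pcols <- grep("^interim_p_", names(profile), value = TRUE)
  if (length(pcols) == 0) stop("profile has no interim_p_* columns")
  v <- rowMeans(-log10(as.matrix(profile[pcols])), na.rm = TRUE)
  out_profile <- data.frame(threshold = profile$threshold,
                            avg_neg_log10_p = v)
  if (!is.null(manual_override))
    return(list(tau_star = manual_override, profile = out_profile,
                flat = FALSE))
  keep <- is.finite(v)
  if (!any(keep) || diff(range(v[keep])) < 1e-9) {
    warning("flat significance profile: separation threshold undefined")
    return(list(tau_star = NA_real_, profile = out_profile, flat = TRUE))
  }
  vmax <- max(v[keep])
  plateau <- keep & v >= vmax * (1 - tolerance)
  list(tau_star = max(profile$threshold[plateau]), profile = out_profile,
       flat = FALSE)
}

#' Envelope cutoffs from below-threshold members
#'
#' For each metric the cutoff is the maximum over members below the
#' separation threshold after excluding outliers (values above
#' Q3 + 1.5 IQR of the below-set); similarity cutoffs are taken on absolute
#' values. When every below-member is an outlier the unfiltered maximum is
#' used with a warning.
#'
#' @param group_df data.frame with columns `tp`, `de`, `dp`, `cov` for the
#'   group members.
#' @param tau_star separation threshold.
#' @return list with `de_cutoff`, `dp_cutoff`, `cov_cutoff`.
#' @export
envelope_cutoffs <- function(group_df, tau_star) {
  below <- group_df$tp < tau_star
  if (sum(below) < 2) stop("need >= 2 members below the separation threshold")
  cut_one <- function(vals) {
    vals <- vals[is.finite(vals)]
    if (length(vals) == 0) return(Inf)   # metric undefined: no constraint
    q3 <- quantile(vals, 0.75, names = FALSE)
    iqr <- q3 - quantile(vals, 0.25, names = FALSE)
    keep <- vals <= q3 + 1.5 * iqr
    if (!any(keep)) {
      warning("all below-threshold members are outliers; ",
              "using the unfiltered maximum")
      return(max(vals))
    }
    max(vals[keep])
  }
  list(de_cutoff = cut_one(group_df$de[below]),
       dp_cutoff = cut_one(abs(group_df$dp[below])),
       cov_cutoff = cut_one(abs(group_df$cov[below])))
}

#' Identify the target cohort of a group
#'
#' Members with `tp >= tau_star`, `de > de_cutoff`, and either
#' `|dp| > dp_cutoff` or `|cov| > cov_cutoff`.
#'
#' @param group_df data.frame with columns `gene`, `tp`, `de`, `dp`, `cov`.
#' @param tau_star separation threshold.
#' @param cutoffs list from [envelope_cutoffs()] (or a
#'   [reference_cutoffs()] entry).
#' @return character vector of cohort gene IDs (possibly empty).
#' @export
identify_cohort <- function(group_df, tau_star, cutoffs) {
  pass <- function(x) { x[is.na(x)] <- FALSE; x }   # undefined metric fails
  sel <- group_df$tp >= tau_star &
    pass(group_df$de > cutoffs$de_cutoff) &
    (pass(abs(group_df$dp) > cutoffs$dp_cutoff) |
       pass(abs(group_df$cov) > cutoffs$cov_cutoff))
  sort(group_df$gene[sel])
}

#' Documented reference cutoff configurations
#'
#' Separation thresholds and envelope cutoffs used in published E2F
#' target-cohort analyses of the WNT pathway (strict and exploratory) and
#' the FGF pathway, shipped for reproducing those gene selections on user
#' data.
#'
#' @return named list of configurations, each with `tau_star`, `de_cutoff`,
#'   `dp_cutoff`, `cov_cutoff`.
#' @export
reference_cutoffs <- function() {
  list(
    wnt = list(tau_star = 4.9, de_cutoff = 0.9, dp_cutoff = 3.2,
               cov_cutoff = 0.135),
    wnt_exploratory = list(tau_star = 4.0, de_cutoff = 0.55,
                           dp_cutoff = 2.0, cov_cutoff = 0.1),
    fgf = list(tau_star = 5.1, de_cutoff = 0.617, dp_cutoff = 1.87,
               cov_cutoff = 0.126))
}

#' Write cohort screen results as TSV
#'
#' @param cohort_results output of [run_target_cohort()].
#' @param path output file for the per-group results table.
#' @return the path, invisibly.
#' @export
write_cohort_results <- function(cohort_results, path) {
  write.table(cohort_results$results, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
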