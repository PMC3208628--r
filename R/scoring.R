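#' Two-class expression comparison
#'
#' @param matrix genes x samples numeric matrix with gene IDs as row names.
#' @param class_labels per-sample `"case"`/`"control"` labels.
#' @param comparison_id name of the comparison.
#' @return an `expression_comparison` object.
#' @export
expression_comparison <- function(matrix, class_labels, comparison_id) {
  stopifnot(is.matrix(matrix), is.numeric(matrix),
            length(class_labels) == ncol(matrix),
            all(class_labels %in% c("case", "control")))
  if (is.null(rownames(matrix)) || anyDuplicated(rownames(matrix)))
    stop("comparison '", comparison_id, "': gene IDs must be unique row names")
  if (sum(class_labels == "case") < 2 || sum(class_labels == "control") < 2)
    stop("comparison '", comparison_id, "': need >= 2 samples per class")
  structure(list(matrix = matrix, class_labels = class_labels,
                 comparison_id = comparison_id),
            class = "expression_comparison")
}

#' Write / read an expression comparison as TSV
#'
#' First column `gene`, then samples labelled `case_*` / `control_*`.
#'
#' @param comparison an [expression_comparison()].
#' @param path TSV file path.
#' @return the path / the comparison object.
#' @export
write_expression_tsv <- function(comparison, path) {
  df <- data.frame(gene = rownames(comparison$matrix), comparison$matrix,
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_expression_tsv
#' @param comparison_id name for the comparison read from `path`; defaults to
#'   the file name.
#' @export
read_expression_tsv <- function(path, comparison_id = NULL) {
  df <- read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  labels <- ifelse(grepl("^case", colnames(m)), "case", "control")
  expression_comparison(m, labels,
                        comparison_id %||% sub("\\.tsv$", "", basename(path)))
}

#' Drop cross-hybridizing probe identifiers
#'
#' Removes identifiers ending with `_a_at`, `_s_at` or `_x_at`; identical
#' gene symbols at different loci remain distinct entries.
#'
#' @param gene_ids character vector of probe/gene identifiers.
#' @return retained identifiers, in input order.
#' @export
filter_probes <- function(gene_ids) {
  gene_ids[!grepl("(_a_at|_s_at|_x_at)$", gene_ids)]
}

# Per-gene pooled standard error of the case-control mean difference.
pooled_se <- function(m, case, control) {
  n1 <- length(case); n2 <- length(control)
  ss1 <- rowSums((m[, case, drop = FALSE] -
                    rowMeans(m[, case, drop = FALSE]))^2)
  ss2 <- rowSums((m[, control, drop = FALSE] -
                    rowMeans(m[, control, drop = FALSE]))^2)
  sqrt((1 / n1 + 1 / n2) * (ss1 + ss2) / (n1 + n2 - 2))
}

# Tusher-style exchangeability factor: the alpha-quantile of s minimizing the
# coefficient of variation of the median absolute deviation of d across
# s-quantile bins.
tusher_s0 <- function(dm, s, n_bins = 100) {
  alphas <- seq(0, 1, by = 0.05)
  qs <- quantile(s, alphas, names = FALSE)
  br <- unique(quantile(s, seq(0, 1, length.out = n_bins + 1), names = FALSE))
  bin <- cut(s, br, include.lowest = TRUE)
  cvs <- vapply(qs, function(s0) {
    d <- dm / (s + s0)
    v <- tapply(d, bin, mad)
    v <- v[is.finite(v)]
    if (length(v) < 2 || mean(v) == 0) return(Inf)
    sd(v) / mean(v)
  }, 0)
  qs[which.min(cvs)]
}

#' SAM moderated difference statistic
#'
#' \eqn{d = (\bar{x}_{case} - \bar{x}_{control}) / (s + s_0)} with the pooled
#' standard error \eqn{s} and an exchangeability constant \eqn{s_0}. The
#' default rule sets \eqn{s_0} to the median of the per-gene standard errors;
#' `s0_rule = "tusher"` selects the quantile of \eqn{s} minimizing the
#' coefficient of variation of the statistic's spread across \eqn{s} bins,
#' and a number fixes \eqn{s_0} directly.
#'
#' @param comparison an [expression_comparison()].
#' @param s0_rule `"median"`, `"tusher"`, or a non-negative number.
#' @return named per-gene vector of d statistics.
#' @export
sam_statistic <- function(comparison, s0_rule = "median") {
  stopifnot(inherits(comparison, "expression_comparison"))
  m <- comparison$matrix
  case <- which(comparison$class_labels == "case")
  control <- which(comparison$class_labels == "control")
  dm <- rowMeans(m[, case, drop = FALSE]) -
    rowMeans(m[, control, drop = FALSE])
  s <- pooled_se(m, case, control)
  s0 <- if (is.numeric(s0_rule)) s0_rule
  else if (identical(s0_rule, "median")) median(s)
  else if (identical(s0_rule, "tusher")) tusher_s0(dm, s)
  else stop("unknown s0_rule: ", s0_rule)
  if (any(s + s0 == 0))
    stop("genes with zero variance in both classes and s0 = 0; ",
         "use a positive s0")
  dm / (s + s0)
}

#' Scale scores to mean 0, standard deviation 1
#'
#' @param d numeric vector (>= 2 values, non-constant).
#' @return scaled vector z with `mean(z) = 0`, `sd(z) = 1`.
#' @export
scale_scores <- function(d) {
  if (length(d) < 2) stop("need >= 2 scores to scale")
  s <- sd(d)
  if (!is.finite(s) || s == 0) stop("scores have zero standard deviation")
  (d - mean(d)) / s
}

#' Pooled differential-expression score
#'
#' Mean absolute scaled SAM score across comparisons.
#'
#' @param z genes x comparisons matrix of scaled scores.
#' @return non-negative per-gene vector.
#' @export
pooled_de_score <- function(z) {
  z <- as.matrix(z)
  rowMeans(abs(z))
}

#' Similarity of two scaled-score profiles
#'
#' `similarity_dot` is the raw sum \eqn{\sum_c a_c b_c} over comparisons;
#' `similarity_cov` is the population covariance
#' \eqn{\frac{1}{n}\sum_c (a_c - \bar a)(b_c - \bar b)}.
#'
#' @param a,b equal-length numeric profiles (regulator and gene).
#' @return a single number.
#' @export
similarity_dot <- function(a, b) {
  if (length(a) != length(b)) stop("profile length mismatch")
  sum(a * b)
}

#' @rdname similarity_dot
#' @export
similarity_cov <- function(a, b) {
  if (length(a) != length(b)) stop("profile length mismatch")
  if (length(a) < 2) stop("covariance needs profiles of length >= 2")
  mean(a * b) - mean(a) * mean(b)
}

#' Per-gene score table for a designated regulator
#'
#' Computes scaled SAM scores per comparison, the pooled
#' differential-expression score, and each gene's dot-product and covariance
#' similarity with the regulator's profile. The gene universe is the
#' intersection of genes present in all comparisons after probe filtering;
#' genes missing anywhere are dropped with a message.
#'
#' @param comparisons list of [expression_comparison()] objects.
#' @param regulator_gene gene ID whose profile anchors the similarities.
#' @param s0_rule passed to [sam_statistic()].
#' @param filter apply [filter_probes()] to the universe (default TRUE).
#' @return a `gene_score_table`: list with `genes`, `z` (genes x
#'   comparisons), `de_score`, `dp`, `cov`, `regulator_gene`,
#'   `n_comparisons`.
#' @export
gene_score_table <- function(comparisons, regulator_gene,
                             s0_rule = "median", filter = TRUE) {
  stopifnot(length(comparisons) >= 1)
  universes <- lapply(comparisons, function(cc) rownames(cc$matrix))
  genes <- Reduce(intersect, universes)
  if (filter) genes <- filter_probes(genes)
  dropped <- length(unique(unlist(universes))) - length(genes)
  if (dropped > 0)
    message(dropped, " gene(s) dropped (probe filter or missing from ",
            "some comparison)")
  if (!(regulator_gene %in% genes))
    stop("regulator gene '", regulator_gene, "' absent from the universe")
  z <- vapply(comparisons, function(cc) {
    sub <- cc$matrix[genes, , drop = FALSE]
    scale_scores(sam_statistic(
      expression_comparison(sub, cc$class_labels, cc$comparison_id), s0_rule))
  }, numeric(length(genes)))
  z <- matrix(z, nrow = length(genes),
              dimnames = list(genes, vapply(comparisons, `[[`, "",
                                            "comparison_id")))
  a <- z[regulator_gene, ]
  covs <- if (ncol(z) >= 2) apply(z, 1, similarity_cov, a)
  else {
    message("covariance similarity undefined with a single comparison; ",
            "set to NA")
    rep(NA_real_, nrow(z))
  }
  structure(list(genes = genes, z = z,
                 de_score = unname(pooled_de_score(z)),
                 dp = as.numeric(z %*% a),
                 cov = unname(covs),
                 regulator_gene = regulator_gene,
                 n_comparisons = ncol(z)),
            class = "gene_score_table")
}

#' @export
print.gene_score_table <- function(x, ...) {
  cat("gene_score_table:", length(x$genes), "genes,", x$n_comparisons,
      "comparisons, regulator", x$regulator_gene, "\n")
  invisible(x)
}

#' @export
as.data.frame.gene_score_table <- function(x, ...) {
  zc <- x$z
  colnames(zc) <- sprintf("z_%d", seq_len(ncol(zc)))
  data.frame(gene = x$genes, zc, de_score = x$de_score,
             dp = x$dp, cov = x$cov, row.names = NULL)
}

#' Write / read a gene score table as TSV
#'
#' @param table a `gene_score_table`.
#' @param path TSV file.
#' @return the path, invisibly.
#' @export
write_score_table <- function(table, path) {
  df <- as.data.frame(table)
  attr <- sprintf("# regulator=%s n_comparisons=%d",
                  table$regulator_gene, table$n_comparisons)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(attr, con)
  suppressWarnings(write.table(df, con, sep = "\t", quote = FALSE,
                               row.names = FALSE))
  invisible(path)
}

#' @rdname write_score_table
#' @export
read_score_table <- function(path) {
  header <- readLines(path, n = 1)
  reg <- sub(".*regulator=(\\S+).*", "\\1", header)
  df <- read.delim(path, comment.char = "#")
  zc <- as.matrix(df[, grep("^z_", names(df)), drop = FALSE])
  rownames(zc) <- df$gene
  structure(list(genes = df$gene, z = zc, de_score = df$de_score,
                 dp = df$dp, cov = df$cov, regulator_gene = reg,
                 n_comparisons = ncol(zc)),
            class = "gene_score_table")
}

#' Group-level similarity measure
#'
#' Unweighted arithmetic mean of a per-gene metric over the group members.
#'
#' @param table a [gene_score_table()].
#' @param genes group member IDs.
#' @param metric `"de"`, `"dp"` or `"cov"`.
#' @return the group mean.
#' @export
group_similarity <- function(table, genes, metric = c("de", "dp", "cov")) {
  metric <- match.arg(metric)
  if (length(genes) == 0) stop("empty group")
  missing <- setdiff(genes, table$genes)
  if (length(missing) > 0)
    stop("unknown gene(s): ", paste(missing, collapse = ", "))
  v <- score_metric(table, metric)
  mean(v[match(genes, table$genes)])
}

score_metric <- function(table, metric) {
  switch(metric, de = table$de_score, dp = table$dp, cov = table$cov,
         stop("unknown metric: ", metric))
}

#' Moving-average profile of a score over the propensity ranking
#'
#' Orders genes by descending target propensity (ties broken by gene ID),
#' computes a moving average of `values` along that ranking, and reports the
#' Spearman correlation (with two-sided p) between propensity and the score.
#'
#' @param values named per-gene score vector.
#' @param tp named per-gene target propensity.
#' @param window moving-average window (default 250 genes).
#' @return list with `profile` (data.frame: rank, gene, value, moving_avg),
#'   `rho` and `p_value`.
#' @export
rank_profile <- function(values, tp, window = 250) {
  if (window < 2) stop("window must be >= 2")
  genes <- intersect(names(values), names(tp))
  if (window > length(genes)) stop("window larger than the gene universe")
  v <- values[genes]; t <- tp[genes]
  ord <- order(-t, genes)
  ma <- as.numeric(stats::filter(v[ord], rep(1 / window, window),
                                 sides = 2))
  ct <- suppressWarnings(cor.test(t, v, method = "spearman",
                                  alternative = "two.sided", exact = FALSE))
  list(profile = data.frame(rank = seq_along(ord), gene = genes[ord],
                            value = as.numeric(v[ord]), moving_avg = ma),
       rho = unname(ct$estimate), p_value = ct$p.value)
}
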