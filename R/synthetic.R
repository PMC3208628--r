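#' Configuration for the synthetic ground-truth generator
#'
#' The generator emulates the structure of the study conditions the pipeline
#' is designed for: several two-class expression comparisons with few
#' replicates, promoters of roughly the -500/+100 window size, a minority of
#' planted regulator targets whose promoters carry binding sites at a
#' multiple of the background rate and whose expression is up-shifted in the
#' case class proportionally to site density, and gene groups with
#' controlled target enrichment.
#'
#' @param n_genes number of genes in the universe.
#' @param n_comparisons number of case/control comparisons (default 7).
#' @param samples_per_class replicates per class per comparison (default 3).
#' @param promoter_len promoter length in bases (default 600, the ~-500/+100
#'   transcription start site window).
#' @param alt_promoters_range inclusive range of alternative promoters per
#'   gene, drawn uniformly (default 1-3).
#' @param n_targets number of planted target genes.
#' @param site_density_ratio planted-target site rate divided by background
#'   rate (>= 1).
#' @param background_site_rate background planted-site rate, sites per base.
#' @param effect_size mean case-class up-shift for targets, in noise-sd units.
#' @param noise_sd expression noise standard deviation.
#' @param n_groups number of gene groups emitted.
#' @param group_size genes per group.
#' @param n_enriched_groups number of groups enriched in planted targets.
#' @param enriched_group_target_fraction fraction of an enriched group's
#'   members drawn from the planted targets, in [0, 1].
#' @param seed integer seed; all outputs are pure functions of the config.
#' @return a validated `synthetic_config` list.
#' @export
synthetic_config <- function(n_genes = 5000, n_comparisons = 7,
                             samples_per_class = 3, promoter_len = 600,
                             alt_promoters_range = c(1, 3), n_targets = 200,
                             site_density_ratio = 5,
                             background_site_rate = 0.002,
                             effect_size = 3, noise_sd = 1,
                             n_groups = 100, group_size = 50,
                             n_enriched_groups = 5,
                             enriched_group_target_fraction = 0.4,
                             seed = 1) {
  cfg <- list(n_genes = as.integer(n_genes),
              n_comparisons = as.integer(n_comparisons),
              samples_per_class = as.integer(samples_per_class),
              promoter_len = as.integer(promoter_len),
              alt_promoters_range = as.integer(alt_promoters_range),
              n_targets = as.integer(n_targets),
              site_density_ratio = site_density_ratio,
              background_site_rate = background_site_rate,
              effect_size = effect_size, noise_sd = noise_sd,
              n_groups = as.integer(n_groups),
              group_size = as.integer(group_size),
              n_enriched_groups = as.integer(n_enriched_groups),
              enriched_group_target_fraction = enriched_group_target_fraction,
              seed = as.integer(seed))
  stopifnot(cfg$n_genes >= 2, cfg$n_comparisons >= 1,
            cfg$samples_per_class >= 2, cfg$promoter_len > 0,
            length(cfg$alt_promoters_range) == 2,
            all(cfg$alt_promoters_range >= 1),
            diff(cfg$alt_promoters_range) >= 0,
            cfg$n_targets >= 0, cfg$n_targets <= cfg$n_genes - 1,
            cfg$site_density_ratio >= 1, cfg$background_site_rate >= 0,
            cfg$effect_size >= 0, cfg$noise_sd > 0,
            cfg$n_groups >= 0, cfg$group_size > 0,
            cfg$n_enriched_groups >= 0,
            cfg$n_enriched_groups <= cfg$n_groups,
            cfg$enriched_group_target_fraction >= 0,
            cfg$enriched_group_target_fraction <= 1)
  class(cfg) <- "synthetic_config"
  cfg
}

synth_gene_ids <- function(n) sprintf("G%05d", seq_len(n))

#' Generate promoters with planted binding sites
#'
#' Each gene receives its drawn number of alternative promoters of
#' `promoter_len` i.i.d. uniform ACGT bases. Sites sampled from the matrix's
#' base frequencies (rejection-sampled to pass its own cutoffs) are inserted
#' at non-overlapping uniform positions, on a uniformly drawn strand, at
#' Poisson rate `background_site_rate` per base for non-targets and
#' `site_density_ratio` times that for targets. Gene 1 is reserved as the
#' regulator gene (never a target). The returned truth records planted
#' per-promoter site counts and target flags.
#'
#' @param config a [synthetic_config()].
#' @param pwm the regulator matrix sites are drawn from.
#' @return list with `promoters` (named character vector, names
#'   `gene|promoter`) and `truth` (class `synthetic_truth`: `target_flags`,
#'   `planted_site_counts`, `regulator_gene`, `promoter_gene`,
#'   `promoter_len`).
#' @export
generate_promoters <- function(config, pwm) {
  stopifnot(inherits(config, "synthetic_config"), inherits(pwm, "pwm"))
  L <- ncol(pwm$counts)
  if (config$promoter_len < L)
    stop("promoter_len shorter than the motif")
  with_seed(derive_seed(config$seed, 1), {
    genes <- synth_gene_ids(config$n_genes)
    regulator <- genes[1L]
    targets <- sort(sample(genes[-1L], config$n_targets))
    is_target <- setNames(genes %in% targets, genes)
    J <- sample(seq(config$alt_promoters_range[1], config$alt_promoters_range[2]),
                config$n_genes, replace = TRUE)
    prom_gene <- rep(genes, J)
    prom_id <- unlist(lapply(J, function(j) sprintf("P%d", seq_len(j))))
    prom_names <- paste(prom_gene, prom_id, sep = "|")
    n_prom <- length(prom_names)
    plen <- config$promoter_len
    rate <- config$background_site_rate *
      ifelse(is_target[prom_gene], config$site_density_ratio, 1)
    n_sites <- rpois(n_prom, rate * plen)
    seqs <- character(n_prom)
    for (p in seq_len(n_prom)) {
      s <- paste(sample(DNA_BASES, plen, replace = TRUE), collapse = "")
      k <- n_sites[p]
      if (k > 0) {
        if (k * L > plen)
          stop("promoter ", prom_names[p], ": ", k,
               " requested sites exceed promoter capacity")
        occupied <- matrix(numeric(0), ncol = 2)
        for (site_i in seq_len(k)) {
          word <- sample_site(pwm)
          if (runif(1) < 0.5) word <- reverse_complement(word)
          placed <- FALSE
          for (try in seq_len(100L)) {
            pos <- sample.int(plen - L + 1L, 1L)
            if (nrow(occupied) == 0L ||
                all(pos + L - 1L < occupied[, 1] | pos > occupied[, 2])) {
              substr(s, pos, pos + L - 1L) <- word
              occupied <- rbind(occupied, c(pos, pos + L - 1L))
              placed <- TRUE
              break
            }
          }
          if (!placed)
            stop("promoter ", prom_names[p],
                 ": could not place a non-overlapping site after 100 tries")
        }
      }
      seqs[p] <- s
    }
    names(seqs) <- prom_names
    truth <- structure(list(
      target_flags = is_target,
      planted_site_counts = setNames(n_sites, prom_names),
      regulator_gene = regulator,
      promoter_gene = setNames(prom_gene, prom_names),
      promoter_len = setNames(rep.int(plen, n_prom), prom_names),
      enriched_group_ids = character(0)), class = "synthetic_truth")
    list(promoters = seqs, truth = truth)
  })
}

# Per-gene planted site density (sites per base across alternative promoters).
planted_density <- function(truth) {
  tapply(truth$planted_site_counts, truth$promoter_gene, sum) /
    tapply(truth$promoter_len, truth$promoter_gene, sum)
}

#' Generate two-class expression comparisons with planted up-regulation
#'
#' Non-targets are Normal(0, noise_sd) in both classes. Each target's case
#' class is shifted up by `effect_size` scaled by the gene's planted site
#' density relative to the mean target density, so downstream
#' propensity/expression associations are positive by construction. The
#' regulator gene itself is shifted by `effect_size` in every comparison,
#' giving the similarity metrics a signed reference.
#'
#' @param config a [synthetic_config()].
#' @param truth the `synthetic_truth` from [generate_promoters()] under the
#'   same config.
#' @return list of `n_comparisons` `expression_comparison` objects (see
#'   [expression_comparison()]).
#' @export
generate_expression <- function(config, truth) {
  stopifnot(inherits(config, "synthetic_config"),
            inherits(truth, "synthetic_truth"))
  genes <- synth_gene_ids(config$n_genes)
  if (!identical(sort(names(truth$target_flags)), sort(genes)))
    stop("gene universe mismatch between truth and config")
  dens <- planted_density(truth)[genes]
  tflag <- truth$target_flags[genes]
  shift <- numeric(config$n_genes)
  if (any(tflag)) {
    md <- mean(dens[tflag])
    if (md > 0) shift[tflag] <- config$effect_size * dens[tflag] / md
  }
  shift[genes == truth$regulator_gene] <- config$effect_size
  s <- config$samples_per_class
  labels <- rep(c("case", "control"), each = s)
  cols <- c(sprintf("case_%d", seq_len(s)), sprintf("control_%d", seq_len(s)))
  with_seed(derive_seed(config$seed, 2), {
    lapply(seq_len(config$n_comparisons), function(ci) {
      m <- matrix(rnorm(config$n_genes * 2 * s, sd = config$noise_sd),
                  nrow = config$n_genes,
                  dimnames = list(genes, cols))
      m[, seq_len(s)] <- m[, seq_len(s)] + shift
      expression_comparison(m, labels, sprintf("comparison_%d", ci))
    })
  })
}

#' Generate gene groups with controlled target enrichment
#'
#' Enriched groups draw `enriched_group_target_fraction` of their members
#' from planted targets and the rest uniformly from non-targets; null groups
#' draw uniformly from all genes. The returned truth copy records the
#' enriched group names.
#'
#' @inheritParams generate_expression
#' @return list with `groups` (named list of member vectors, GMT records) and
#'   `truth` (input truth with `enriched_group_ids` filled in).
#' @export
generate_gene_groups <- function(config, truth) {
  stopifnot(inherits(config, "synthetic_config"),
            inherits(truth, "synthetic_truth"))
  genes <- names(truth$target_flags)
  if (config$group_size > length(genes))
    stop("group_size exceeds the number of genes")
  targets <- genes[truth$target_flags]
  nontargets <- genes[!truth$target_flags]
  n_t <- round(config$enriched_group_target_fraction * config$group_size)
  if (config$n_enriched_groups > 0 && n_t > length(targets))
    stop("enriched groups require more targets than were planted")
  with_seed(derive_seed(config$seed, 3), {
    groups <- list()
    for (g in seq_len(config$n_groups)) {
      if (g <= config$n_enriched_groups) {
        nm <- sprintf("GRP_ENR_%03d", g)
        members <- c(sample(targets, n_t),
                     sample(nontargets, config$group_size - n_t))
      } else {
        nm <- sprintf("GRP_NULL_%03d", g - config$n_enriched_groups)
        members <- sample(genes, config$group_size)
      }
      groups[[nm]] <- sort(members)
    }
    truth$enriched_group_ids <- head(names(groups), config$n_enriched_groups)
    list(groups = groups, truth = truth)
  })
}

#' Write synthetic promoters as FASTA
#'
#' Headers carry `gene|promoter` so alternative promoters group by prefix.
#'
#' @param promoters named character vector from [generate_promoters()].
#' @param path output FASTA file.
#' @return `path`, invisibly.
#' @export
write_promoters_fasta <- function(promoters, path) {
  x <- Biostrings::DNAStringSet(promoters)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read promoters from FASTA
#'
#' @param path FASTA file with `gene|promoter` headers.
#' @return named character vector of promoter sequences.
#' @export
read_promoters_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' Write gene groups in GMT format
#'
#' @param groups named list of member vectors.
#' @param path output file.
#' @param description optional per-group description column (defaults to the
#'   group name).
#' @return `path`, invisibly.
#' @export
write_gmt <- function(groups, path, description = NULL) {
  desc <- description %||% names(groups)
  lines <- vapply(seq_along(groups), function(i)
    paste(c(names(groups)[i], desc[i], groups[[i]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' Read gene groups from a GMT file
#'
#' Thin wrapper over [fgsea::gmtPathways()].
#'
#' @param path GMT file.
#' @return named list of member vectors.
#' @export
read_gmt <- function(path) {
  if (file.size(path) == 0) return(setNames(list(), character(0)))
  fgsea::gmtPathways(path)
}

#' Write the synthetic ground truth as TSV files
#'
#' Emits `<prefix>_genes.tsv` (per-gene target flag, regulator flag),
#' `<prefix>_promoters.tsv` (per-promoter planted site count) and
#' `<prefix>_groups.tsv` (enriched group names).
#'
#' @param truth a `synthetic_truth`.
#' @param prefix output path prefix.
#' @return character vector of the files written, invisibly.
#' @export
write_truth_tsv <- function(truth, prefix) {
  f1 <- paste0(prefix, "_genes.tsv")
  write.table(data.frame(gene = names(truth$target_flags),
                         is_target = truth$target_flags,
                         is_regulator = names(truth$target_flags) ==
                           truth$regulator_gene),
              f1, sep = "\t", quote = FALSE, row.names = FALSE)
  f2 <- paste0(prefix, "_promoters.tsv")
  write.table(data.frame(promoter = names(truth$planted_site_counts),
                         gene = truth$promoter_gene,
                         planted_sites = truth$planted_site_counts,
                         length = truth$promoter_len),
              f2, sep = "\t", quote = FALSE, row.names = FALSE)
  f3 <- paste0(prefix, "_groups.tsv")
  write.table(data.frame(enriched_group = truth$enriched_group_ids),
              f3, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(f1, f2, f3))
}
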