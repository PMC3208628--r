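#' Scan a promoter with a position weight matrix
#'
#' MATCH-style scan of every offset on both strands. The information-weighted
#' score at an offset is rescaled between the worst and best attainable
#' scores to the matrix similarity score (MSS), and likewise over the
#' 5-position core block (CSS); hits must pass both of the matrix's cutoffs.
#' `N` bases contribute a position's minimum frequency, so masked sequence
#' degrades rather than truncates scores. A minus-strand hit at offset `o`
#' means the reverse complement of `sequence[o..o+L-1]` matches the motif.
#'
#' @param sequence promoter DNA string (or named length-1 character vector).
#' @param pwm a [new_pwm()] object.
#' @param both_strands scan the reverse complement too (default TRUE).
#' @return data.frame with columns `offset` (0-based), `strand`, `mss`,
#'   `css`; empty when the promoter is shorter than the motif.
#' @export
match_scan <- function(sequence, pwm, both_strands = TRUE) {
  stopifnot(inherits(pwm, "pwm"))
  seq_int <- encode_dna(as.character(sequence))
  if (length(seq_int) < ncol(pwm$counts))
    return(data.frame(offset = integer(0), strand = character(0),
                      mss = numeric(0), css = numeric(0)))
  cpp_pwm_hits(seq_int, pwm_weights(pwm), pwm$core_start - 1L,
               pwm$mss_cutoff, pwm$css_cutoff, both_strands)
}

#' Count binding sites per promoter
#'
#' Counts all passing offsets on both strands; overlapping hits are each
#' counted.
#'
#' @param promoters named character vector of promoter sequences
#'   (`gene|promoter` names).
#' @param pwm a [new_pwm()] object.
#' @param both_strands scan both strands (default TRUE).
#' @return named integer vector of per-promoter hit counts.
#' @export
count_sites <- function(promoters, pwm, both_strands = TRUE) {
  stopifnot(inherits(pwm, "pwm"))
  seqs <- lapply(unname(promoters), encode_dna)
  n <- cpp_pwm_count_many(seqs, pwm_weights(pwm), pwm$core_start - 1L,
                          pwm$mss_cutoff, pwm$css_cutoff, both_strands)
  setNames(n, names(promoters))
}

#' Global background binding-site density
#'
#' \eqn{\rho = \sum_i n_i / \sum_i l_i} over the global promoter set.
#'
#' @param lengths per-promoter sequence lengths.
#' @param counts per-promoter site counts (same order).
#' @return sites per base.
#' @export
background_density <- function(lengths, counts) {
  if (length(lengths) != length(counts)) stop("length/count size mismatch")
  tl <- sum(lengths)
  if (tl <= 0) stop("total promoter length is zero")
  rho <- sum(counts) / tl
  if (rho == 0)
    stop("no binding sites anywhere: background density is zero and ",
         "target propensity is undefined")
  rho
}

#' Target propensity of one gene
#'
#' Mean, over the gene's J alternative promoters, of the observed site
#' density relative to the global background density:
#' \eqn{tp = \frac{1}{J}\sum_j n_j / (\rho\, l_j)}.
#'
#' @param counts per-promoter site counts for the gene.
#' @param lengths matching promoter lengths.
#' @param rho global background density from [background_density()].
#' @return non-negative propensity score.
#' @export
target_propensity <- function(counts, lengths, rho) {
  if (length(counts) == 0) stop("gene has no promoters")
  if (any(lengths <= 0)) stop("promoter of zero length")
  if (rho <= 0) stop("background density must be positive")
  mean(counts / (rho * lengths))
}

#' Per-gene target propensity table for one matrix
#'
#' Scans every promoter, computes the global background density and the
#' per-gene propensity, and ranks genes by descending propensity (ties
#' broken by gene ID).
#'
#' @inheritParams count_sites
#' @return a `target_propensity_table`: data.frame with columns `gene`, `J`,
#'   `total_sites`, `tp`, `tp_rank`, plus attributes `background_density`
#'   and `pwm_id`.
#' @export
target_propensity_table <- function(promoters, pwm, both_strands = TRUE) {
  counts <- count_sites(promoters, pwm, both_strands)
  lengths <- nchar(promoters)
  genes <- sub("\\|.*$", "", names(promoters))
  rho <- background_density(lengths, counts)
  by_gene <- split(seq_along(counts), genes)
  tp <- vapply(by_gene, function(i)
    target_propensity(counts[i], lengths[i], rho), 0)
  df <- data.frame(gene = names(by_gene),
                   J = vapply(by_gene, length, 0L),
                   total_sites = vapply(by_gene, function(i)
                     sum(counts[i]), 0),
                   tp = as.numeric(tp), row.names = NULL)
  df <- df[order(df$gene), ]
  df$tp_rank <- rank_desc(df$tp, df$gene)
  attr(df, "background_density") <- rho
  attr(df, "pwm_id") <- pwm$id
  class(df) <- c("target_propensity_table", "data.frame")
  df
}

# Descending rank with ties broken by a secondary key (stable ID order).
rank_desc <- function(x, id) {
  ord <- order(-x, id)
  r <- integer(length(x))
  r[ord] <- seq_along(x)
  r
}

#' Write a target propensity table as TSV
#'
#' @param table a [target_propensity_table()].
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_propensity_table <- function(table, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# pwm=%s background_density=%.10g",
                     attr(table, "pwm_id"),
                     attr(table, "background_density")), con)
  suppressWarnings(write.table(as.data.frame(table), con, sep = "\t",
                               quote = FALSE, row.names = FALSE))
  invisible(path)
}

#' @rdname write_propensity_table
#' @export
read_propensity_table <- function(path) {
  header <- readLines(path, n = 1)
  df <- read.delim(path, comment.char = "#")
  attr(df, "pwm_id") <- sub(".*pwm=(\\S+).*", "\\1", header)
  attr(df, "background_density") <-
    as.numeric(sub(".*background_density=(\\S+).*", "\\1", header))
  class(df) <- c("target_propensity_table", "data.frame")
  df
}

#' Extract promoter windows around transcription start sites
#'
#' Builds `[TSS - upstream, TSS + downstream)` windows on the annotated
#' strand (0-based half-open genomic coordinates; minus-strand windows are
#' reverse complemented), truncating windows that run off a contig end with
#' a warning.
#'
#' @param tss BED6 file path or a `GRanges` of single-base TSS positions
#'   with strand.
#' @param genome FASTA file path or a named `DNAStringSet` of contigs.
#' @param upstream,downstream window extent in bases (defaults 500 / 100).
#' @return named character vector of promoter sequences (`gene|P1` names,
#'   one window per TSS record).
#' @export
extract_promoter_windows <- function(tss, genome, upstream = 500,
                                     downstream = 100) {
  gr <- if (is.character(tss)) rtracklayer::import(tss, format = "BED")
  else tss
  contigs <- if (is.character(genome)) Biostrings::readDNAStringSet(genome)
  else genome
  names(contigs) <- sub("\\s.*$", "", names(contigs))
  chr <- as.character(GenomicRanges::seqnames(gr))
  if (!all(chr %in% names(contigs)))
    stop("TSS contig(s) missing from the genome: ",
         paste(setdiff(chr, names(contigs)), collapse = ", "))
  win <- GenomicRanges::promoters(gr, upstream = upstream,
                                  downstream = downstream)
  clen <- setNames(Biostrings::width(contigs), names(contigs))
  s <- pmax(GenomicRanges::start(win), 1L)
  e <- pmin(GenomicRanges::end(win), clen[chr])
  n_trunc <- sum(s > GenomicRanges::start(win) | e < GenomicRanges::end(win))
  if (n_trunc > 0)
    warning(n_trunc, " window(s) truncated at contig ends")
  seqs <- Biostrings::subseq(contigs[chr], start = s, end = e)
  minus <- as.character(GenomicRanges::strand(win)) == "-"
  if (any(minus))
    seqs[minus] <- Biostrings::reverseComplement(seqs[minus])
  nm <- gr$name
  if (is.null(nm)) nm <- sprintf("TSS%05d", seq_along(gr))
  setNames(as.character(seqs), paste0(nm, "|P1"))
}
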