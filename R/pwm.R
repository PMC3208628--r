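#' Position weight matrix objects
#'
#' A `pwm` is a list with base counts (4 x L, rows A/C/G/T), pseudo-count
#' smoothed frequencies, the per-position information vector
#' \eqn{I(i) = \sum_b f(i,b) \ln(4 f(i,b))}, the 5-position core block that
#' maximizes summed information, and the matrix/core similarity cutoffs used
#' when scanning.
#'
#' @param id matrix identifier.
#' @param counts numeric 4 x L matrix of base counts (or frequencies); rows
#'   must be A, C, G, T.
#' @param mss_cutoff minimum matrix similarity score for a reported hit.
#' @param css_cutoff minimum core similarity score for a reported hit.
#' @param pseudocount added to every count before frequency normalization so
#'   no frequency is zero.
#' @return an object of class `pwm`.
#' @export
new_pwm <- function(id, counts, mss_cutoff = 0.75, css_cutoff = 0.90,
                    pseudocount = 1) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 4L)
    stop("PWM '", id, "': counts must have 4 rows (A, C, G, T)")
  if (ncol(counts) < 1L)
    stop("PWM '", id, "': empty matrix")
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("PWM '", id, "': counts must be finite and non-negative")
  dimnames(counts) <- list(DNA_BASES, NULL)
  freq <- sweep(counts + pseudocount, 2, colSums(counts + pseudocount), "/")
  info <- apply(freq, 2, function(f) sum(f * log(4 * f)))
  # core: contiguous window (length 5, or the whole matrix when shorter)
  # with maximal summed information; ties resolved toward the first window
  L <- ncol(counts)
  core_len <- min(5L, L)
  wsum <- vapply(seq_len(L - core_len + 1L),
                 function(s) sum(info[s:(s + core_len - 1L)]), 0)
  core_start <- which.max(wsum > max(wsum) - 1e-12) # first within tie tolerance
  structure(list(id = id, counts = counts, freq = freq, info = info,
                 core_start = as.integer(core_start),
                 mss_cutoff = mss_cutoff, css_cutoff = css_cutoff),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat("PWM", x$id, "length", ncol(x$counts),
      "core", x$core_start, "-",
      min(x$core_start + 4L, ncol(x$counts)),
      sprintf("cutoffs mss>=%.2f css>=%.2f\n", x$mss_cutoff, x$css_cutoff))
  cat("consensus:", pwm_consensus(x), "\n")
  invisible(x)
}

#' Consensus string of a matrix
#'
#' Argmax base per position; near-uniform positions (frequency range below
#' `n_tol`) are written `N`.
#'
#' @param pwm a [new_pwm()] object.
#' @param n_tol frequency range below which a position is called `N`.
#' @return character consensus of the matrix length.
#' @export
pwm_consensus <- function(pwm, n_tol = 0.10) {
  f <- pwm$freq
  base <- DNA_BASES[apply(f, 2, which.max)]
  base[apply(f, 2, function(x) diff(range(x))) < n_tol] <- "N"
  paste(base, collapse = "")
}

# Information-weighted scoring matrix handed to the C++ scanner.
pwm_weights <- function(pwm) {
  sweep(pwm$freq, 2, pwm$info, "*")
}

#' Read matrices in TRANSFAC flat format
#'
#' Parses records of the form `AC`/`ID`, a `P0` (or `PO`) column header with
#' base order, numbered count rows, and a `//` terminator. Counts are
#' pseudo-count smoothed before frequency normalization, the information
#' vector is computed from the smoothed frequencies, and the core is the
#' 5-consecutive-position window maximizing summed information.
#'
#' @param path file in TRANSFAC flat format.
#' @inheritParams new_pwm
#' @return list of [new_pwm()] objects, named by matrix identifier.
#' @export
read_pwm_transfac <- function(path, mss_cutoff = 0.75, css_cutoff = 0.90,
                              pseudocount = 1) {
  lines <- readLines(path)
  out <- list()
  ac <- id <- NULL
  base_order <- DNA_BASES
  rows <- list()
  flush <- function(line_no) {
    if (is.null(ac) && is.null(id) && length(rows) == 0L) return(invisible())
    if (length(rows) == 0L)
      stop("TRANSFAC record ending at line ", line_no, " has an empty matrix")
    m <- do.call(rbind, rows)
    counts <- t(m)[match(DNA_BASES, base_order), , drop = FALSE]
    nm <- id %||% ac %||% paste0("MATRIX_", length(out) + 1L)
    out[[nm]] <<- new_pwm(nm, counts, mss_cutoff, css_cutoff, pseudocount)
    ac <<- NULL; id <<- NULL; rows <<- list(); base_order <<- DNA_BASES
  }
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (ln == "" || grepl("^XX", ln)) next
    if (grepl("^//", ln)) { flush(i); next }
    tag <- sub("^(\\S+).*", "\\1", ln)
    rest <- trimws(sub("^\\S+", "", ln))
    if (tag == "AC") { ac <- rest }
    else if (tag == "ID") { id <- rest }
    else if (tag %in% c("P0", "PO")) {
      base_order <- toupper(strsplit(rest, "\\s+")[[1L]])[1:4]
      if (!setequal(base_order, DNA_BASES))
        stop("line ", i, ": P0 header must name bases A, C, G, T")
    } else if (grepl("^[0-9]+$", tag)) {
      vals <- strsplit(rest, "\\s+")[[1L]]
      num <- suppressWarnings(as.numeric(vals[1:4]))
      if (length(vals) < 4L || anyNA(num))
        stop("line ", i, ": malformed matrix row (expected 4 numeric counts)")
      rows[[length(rows) + 1L]] <- num
    }
    # other tags (NA, DE, BF, ...) are annotation; ignored
  }
  flush(length(lines))
  if (length(out) == 0L) stop("no TRANSFAC matrices found in ", path)
  out
}

#' Write matrices in TRANSFAC flat format
#'
#' @param pwms a `pwm` or list of `pwm` objects.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_pwm_transfac <- function(pwms, path) {
  if (inherits(pwms, "pwm")) pwms <- list(pwms)
  con <- file(path, "w")
  on.exit(close(con))
  for (p in pwms) {
    writeLines(c(paste("AC", p$id), "XX", paste("ID", p$id), "XX",
                 "P0      A      C      G      T"), con)
    cons <- strsplit(pwm_consensus(p), "")[[1L]]
    for (i in seq_len(ncol(p$counts))) {
      writeLines(sprintf("%02d %6g %6g %6g %6g %s", i,
                         p$counts[1, i], p$counts[2, i],
                         p$counts[3, i], p$counts[4, i], cons[i]), con)
    }
    writeLines(c("XX", "//"), con)
  }
  invisible(path)
}

#' Synthetic regulator matrix with column-shuffled decoys
#'
#' Builds a 10-position matrix whose consensus follows the degenerate E2F-like
#' pattern `NTTTSSCGSS` (S = C or G): position 1 uniform, single-base
#' positions carry 94 of 100 counts, S positions split 47/47 between C and G.
#' Decoys are column permutations of the same counts, so they preserve
#' composition and information content but scramble the recognized word.
#'
#' @param seed integer seed driving the decoy column shuffles.
#' @param n_decoys number of decoy matrices.
#' @inheritParams new_pwm
#' @return list with elements `regulator` (a `pwm`) and `decoys` (list of
#'   `pwm`), plus `all` containing regulator followed by decoys.
#' @export
make_regulator_pwm <- function(seed = 1, n_decoys = 10,
                               mss_cutoff = 0.75, css_cutoff = 0.90) {
  col_for <- function(code) {
    switch(code,
           N = c(25, 25, 25, 25),
           A = c(94, 2, 2, 2), C = c(2, 94, 2, 2),
           G = c(2, 2, 94, 2), T = c(2, 2, 2, 94),
           S = c(3, 47, 47, 3))
  }
  pattern <- c("N", "T", "T", "T", "S", "S", "C", "G", "S", "S")
  counts <- vapply(pattern, col_for, numeric(4))
  reg <- new_pwm("REG_SYNTH", counts, mss_cutoff, css_cutoff)
  decoys <- with_seed(derive_seed(seed, 17), {
    lapply(seq_len(n_decoys), function(k) {
      perm <- sample.int(ncol(counts))
      # reject permutations that leave the word intact
      while (all(perm == seq_along(perm))) perm <- sample.int(ncol(counts))
      new_pwm(sprintf("DECOY_%02d", k), counts[, perm, drop = FALSE],
              mss_cutoff, css_cutoff)
    })
  })
  names(decoys) <- vapply(decoys, `[[`, "", "id")
  all <- c(list(REG_SYNTH = reg), decoys)
  list(regulator = reg, decoys = decoys, all = all)
}

# Draw one site from the matrix's per-position base frequencies, rejection
# sampled to pass the matrix's own cutoffs: a planted site is a bona fide
# detectable binding site. Falls back to the consensus after max_try draws.
sample_site <- function(pwm, max_try = 50) {
  w <- pwm_weights(pwm)
  for (k in seq_len(max_try)) {
    idx <- apply(pwm$freq, 2, function(f) sample.int(4L, 1L, prob = f))
    sc <- cpp_pwm_score_at(idx - 1L, w, pwm$core_start - 1L, 0L)
    if (sc[["mss"]] >= pwm$mss_cutoff && sc[["css"]] >= pwm$css_cutoff)
      return(paste(DNA_BASES[idx], collapse = ""))
  }
  gsub("N", "A", pwm_consensus(pwm))
}
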