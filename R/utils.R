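# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# Derive a deterministic sub-seed for stage k; stays inside 32-bit range.
derive_seed <- function(seed, k) {
  s <- (as.numeric(seed) + k * 1000003) %% 2147483629
  as.integer(s + 1)
}

DNA_BASES <- c("A", "C", "G", "T")

# Encode a DNA string as integers 0=A,1=C,2=G,3=T,4=N (any other char -> 4).
encode_dna <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  lut <- rep.int(4L, 256L)
  lut[utf8ToInt("A") + 1L] <- 0L; lut[utf8ToInt("a") + 1L] <- 0L
  lut[utf8ToInt("C") + 1L] <- 1L; lut[utf8ToInt("c") + 1L] <- 1L
  lut[utf8ToInt("G") + 1L] <- 2L; lut[utf8ToInt("g") + 1L] <- 2L
  lut[utf8ToInt("T") + 1L] <- 3L; lut[utf8ToInt("t") + 1L] <- 3L
  lut[utf8ToInt(x) + 1L]
}

reverse_complement <- function(x) {
  chartr("ACGTacgt", "TGCAtgca", vapply(x, function(s)
    paste(rev(strsplit(s, "", fixed = TRUE)[[1L]]), collapse = ""), ""))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
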