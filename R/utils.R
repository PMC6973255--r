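# Internal helpers shared across modules.

# Evaluate expr with a temporary RNG state seeded by `seed`; the caller's
# RNG state is restored afterwards. seed = NULL uses the current stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Random DNA strings with no homopolymer run longer than `max_run`.
random_dna <- function(n, len, max_run = 3L) {
  vapply(seq_len(n), function(i) {
    b <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
    repeat {
      r <- rle(b)
      bad <- which(r$lengths > max_run)
      if (!length(bad)) break
      pos <- cumsum(r$lengths)[bad[1L]]
      b[pos] <- sample(setdiff(c("A", "C", "G", "T"), b[pos]), 1L)
    }
    paste(b, collapse = "")
  }, character(1))
}

# Substitution errors at per-base rate `rate` over a character vector of
# sequences; substituted bases are drawn uniformly from the 3 other bases.
inject_errors <- function(seqs, rate) {
  if (rate <= 0 || !length(seqs)) return(seqs)
  nch <- nchar(seqs)
  total <- sum(nch)
  nerr <- stats::rbinom(1L, total, rate)
  if (nerr == 0L) return(seqs)
  flat <- strsplit(paste(seqs, collapse = ""), "", fixed = TRUE)[[1L]]
  idx <- sample.int(total, nerr)
  bases <- c("A", "C", "G", "T")
  shift <- sample.int(3L, nerr, replace = TRUE)
  flat[idx] <- bases[((match(flat[idx], bases) - 1L + shift) %% 4L) + 1L]
  ends <- cumsum(nch)
  substring(paste(flat, collapse = ""), ends - nch + 1L, ends)
}

# Distinct random barcodes (sampled without replacement from the 4^len
# space): one template, one barcode, so barcode counts measure template
# counts exactly on error-free data.
random_umis <- function(n, len) {
  if (n == 0L) return(character(0))
  space <- 4^len
  if (n > space) stop("more templates than distinct barcodes")
  idx <- sample.int(space, n) - 1L
  m <- matrix("", n, len)
  for (j in seq_len(len)) {
    m[, j] <- c("A", "C", "G", "T")[(idx %% 4L) + 1L]
    idx <- idx %/% 4L
  }
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}
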