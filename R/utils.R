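# Internal helpers shared across modules.

DNA_BASES <- c("A", "C", "G", "T")

# Reverse complement for plain character vectors (internal alphabet is DNA).
revcomp <- function(x) {
  chartr("ACGTN", "TGCAN", vapply(x, function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE))
}

# Fast reverse complement via Biostrings when many/long sequences are involved.
revcomp_fast <- function(x) {
  if (length(x) == 0) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

random_dna <- function(n, width) {
  if (n == 0) return(character(0))
  vapply(seq_len(n), function(i) {
    paste(sample(DNA_BASES, width, replace = TRUE), collapse = "")
  }, character(1))
}

# Hamming distance for paired equal-length strings, vectorized over pairs.
# Works on the concatenation so cost is O(total characters).
hamming_pairs <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) == 0) return(integer(0))
  nx <- nchar(x)
  if (any(nx != nchar(y))) {
    abort("hamming_pairs() requires equal-length string pairs.")
  }
  a <- charToRaw(paste(x, collapse = ""))
  b <- charToRaw(paste(y, collapse = ""))
  cs <- c(0L, cumsum(a != b))
  ends <- cumsum(nx)
  prev <- c(0, head(ends, -1L))
  as.integer(cs[ends + 1L] - cs[prev + 1L])
}

# Mutate sequences by planting a fixed number of substitutions at distinct
# positions; substituted bases always differ from the original.
plant_substitutions <- function(seq, n_sub) {
  if (n_sub == 0L) return(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  pos <- sample.int(length(chars), n_sub)
  for (p in pos) {
    chars[p] <- sample(setdiff(DNA_BASES, chars[p]), 1L)
  }
  paste(chars, collapse = "")
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

check_seq_column <- function(df, col = "seq", what = "records") {
  if (!col %in% names(df)) {
    abort(sprintf("Expected a `%s` column in the %s data frame.", col, what))
  }
  invisible(df)
}
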