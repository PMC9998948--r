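# Shared test fixtures and independent oracles.

rand_dna <- function(n, width) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), width, replace = TRUE), collapse = "")
  }, character(1))
}

rand_tx <- function(n = 20, width = 1500, seed = 99) {
  withr::with_seed(seed, tibble::tibble(
    id = sprintf("tx%02d", seq_len(n)),
    seq = rand_dna(n, width)
  ))
}

rc_chr <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# Independent brute-force oracle for full-length ungapped mapping:
# per-offset character comparison, no seeding, no shared internals.
brute_map <- function(qseq, targets, k) {
  qc <- strsplit(qseq, "")[[1]]
  w <- length(qc)
  out <- list()
  for (ti in seq_len(nrow(targets))) {
    tc <- strsplit(targets$seq[ti], "")[[1]]
    L <- length(tc)
    if (L < w) next
    for (off in 0:(L - w)) {
      mm <- sum(tc[(off + 1):(off + w)] != qc)
      if (mm <= k) {
        out[[length(out) + 1L]] <- tibble::tibble(
          target_id = targets$id[ti], offset = off, mismatches = mm
        )
      }
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(target_id = character(), offset = integer(),
                          mismatches = integer()))
  }
  dplyr::arrange(dplyr::bind_rows(out), target_id, offset)
}

# Brute-force exact-duplicate equivalence classes (oracle for identity-1
# clustering of equal-or-substring-free inputs).
brute_duplicate_classes <- function(seqs) {
  cls <- match(seqs, unique(seqs))
  split(seq_along(seqs), cls)
}

expect_same_hits <- function(got, oracle) {
  got <- dplyr::arrange(got[, c("target_id", "offset", "mismatches")],
                        target_id, offset)
  expect_equal(as.data.frame(got), as.data.frame(oracle),
               ignore_attr = TRUE)
}
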