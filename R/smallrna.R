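#' Filter a small-RNA read pool
#'
#' Applies the standard preprocessing cascade for small-RNA libraries, in
#' order: length bounds, N-content, contaminant removal (full-length
#' exact match to any contaminant reference sequence, either strand).
#' Inputs are assumed adapter-trimmed.
#'
#' @param reads Tibble with `id`, `seq` columns (e.g. from
#'   [read_fastq()]).
#' @param min_len,max_len Length bounds in nt (inclusive).
#' @param contaminants Optional tibble (`id`, `seq`) of contaminant
#'   references (mitochondrial genome, rRNAs).
#' @return A list with `reads` (the retained subset) and `stats` (tibble
#'   `step`, `removed`); the per-step removals sum to input minus output.
#' @export
filter_small_rna <- function(reads, min_len = 18, max_len = 40,
                             contaminants = NULL) {
  if (min_len > max_len) abort("`min_len` must not exceed `max_len`.")
  check_seq_column(reads, what = "reads")
  n0 <- nrow(reads)
  len <- nchar(reads$seq)
  keep <- len >= min_len & len <= max_len
  n_len <- sum(!keep)
  reads <- reads[keep, , drop = FALSE]

  has_n <- grepl("N", reads$seq, fixed = TRUE)
  n_ncontent <- sum(has_n)
  reads <- reads[!has_n, , drop = FALSE]

  n_contam <- 0L
  if (!is.null(contaminants) && nrow(reads) > 0) {
    hs <- map_with_mismatches(reads, contaminants, k = 0, orientation = "sense")
    ha <- map_with_mismatches(reads, contaminants, k = 0, orientation = "antisense")
    bad_ids <- unique(c(hs$read_id, ha$read_id))
    n_contam <- sum(reads$id %in% bad_ids)
    reads <- reads[!reads$id %in% bad_ids, , drop = FALSE]
  }
  stats <- tibble(
    step = c("length", "n_content", "contaminant"),
    removed = c(n_len, n_ncontent, n_contam)
  )
  stopifnot(sum(stats$removed) == n0 - nrow(reads))
  list(reads = reads, stats = stats)
}

#' Read-length spectrum
#'
#' @param reads Tibble with a `seq` column.
#' @return Tibble with columns `length`, `n` (classed `length_spectrum`
#'   for plotting); the modal length (ties break to the smaller length) is
#'   attached as attribute `modal_length` (`NA` for empty input).
#' @export
length_spectrum <- function(reads) {
  check_seq_column(reads, what = "reads")
  out <- count(tibble(length = nchar(reads$seq)), .data$length, name = "n") |>
    arrange(.data$length)
  mode_len <- if (nrow(out) == 0) NA_integer_ else out$length[which.max(out$n)]
  attr(out, "modal_length") <- mode_len
  class(out) <- c("length_spectrum", class(out))
  out
}

#' Modal read length of a spectrum
#' @param spectrum A [length_spectrum()] result.
#' @return Integer modal length (ties break to the smaller length).
#' @export
modal_length <- function(spectrum) attr(spectrum, "modal_length")

#' First-nucleotide composition by read length
#'
#' Fractions of A/C/G/U at position 1, per read length. The package's
#' internal alphabet is DNA, so the reported `"U"` rows count reads whose
#' first base is T internally.
#'
#' @param reads Tibble with a `seq` column.
#' @param by_length Group by read length (default) or pool all reads.
#' @return Tibble `length` (absent when `by_length = FALSE`), `base`
#'   (A/C/G/U), `n`, `fraction`; fractions sum to 1 within each length.
#'   The overall 1U fraction is attached as attribute `u_fraction`.
#' @export
first_nt_composition <- function(reads, by_length = TRUE) {
  check_seq_column(reads, what = "reads")
  first <- substr(reads$seq, 1, 1)
  base <- chartr("T", "U", first)
  u_frac <- if (length(base)) mean(base == "U") else NA_real_
  df <- tibble(length = nchar(reads$seq), base = base)
  df <- df[df$base %in% c("A", "C", "G", "U"), , drop = FALSE]
  out <- if (by_length) {
    df |>
      count(.data$length, .data$base, name = "n") |>
      group_by(.data$length) |>
      mutate(fraction = .data$n / sum(.data$n)) |>
      ungroup()
  } else {
    df |>
      count(.data$base, name = "n") |>
      mutate(fraction = .data$n / sum(.data$n))
  }
  attr(out, "u_fraction") <- u_frac
  out
}

#' Select putative piRNAs by length
#'
#' The conservative length-window definition of the putative piRNA pool:
#' reads of 25-30 nt (inclusive) by default.
#'
#' @param reads Tibble with `id`, `seq`.
#' @param min_len,max_len piRNA length window (nt, inclusive).
#' @return The subset tibble, with attributes `n_total` (reads kept) and
#'   `n_unique` (distinct sequences among them).
#' @export
select_putative_pirnas <- function(reads, min_len = 25, max_len = 30) {
  check_seq_column(reads, what = "reads")
  len <- nchar(reads$seq)
  out <- reads[len >= min_len & len <= max_len, , drop = FALSE]
  attr(out, "n_total") <- nrow(out)
  attr(out, "n_unique") <- length(unique(out$seq))
  out
}

#' Annotate miRNA reads by exact match to a reference
#'
#' Reads in the miRNA length window that map full length with zero
#' mismatches (either strand) to any reference entry are flagged.
#'
#' @param reads Tibble with `id`, `seq`.
#' @param mirna_ref Reference tibble (`id`, `seq`); must be non-empty.
#' @param min_len,max_len The miRNA length window (nt) over which the
#'   flagged fraction is computed.
#' @return `reads` with an added logical `is_mirna` column; the flagged
#'   fraction among reads of `min_len`-`max_len` nt is attached as
#'   attribute `mirna_fraction`.
#' @export
annotate_mirnas <- function(reads, mirna_ref, min_len = 21, max_len = 24) {
  if (is.null(mirna_ref) || nrow(mirna_ref) == 0) abort("Empty miRNA reference.")
  check_seq_column(reads, what = "reads")
  hs <- map_with_mismatches(reads, mirna_ref, k = 0, orientation = "sense")
  ha <- map_with_mismatches(reads, mirna_ref, k = 0, orientation = "antisense")
  flagged <- unique(c(hs$read_id, ha$read_id))
  reads$is_mirna <- reads$id %in% flagged
  len <- nchar(reads$seq)
  in_win <- len >= min_len & len <= max_len
  attr(reads, "mirna_fraction") <- if (any(in_win)) mean(reads$is_mirna[in_win]) else NA_real_
  reads
}
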