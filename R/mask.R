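#' Mask shotgun reads against a repeat consensus library
#'
#' A desk-scale repeat masker: each read is screened against every library
#' consensus on both strands by exact k-mer seeding followed by ungapped
#' extension along the seed diagonal. Per read, hits are accepted greedily
#' by decreasing score (score = aligned length - 2 x mismatches; ties break
#' to the lower consensus id, then lower read coordinate), and later hits
#' may not overlap already-attributed read positions, so every read
#' position belongs to at most one hit. Percent divergence is the Hamming
#' mismatch fraction over the aligned region (no substitution-model
#' correction).
#'
#' @param reads Tibble with `id`, `seq` columns.
#' @param library Tibble with `id`, `seq` columns (the consensus library).
#' @param min_hit_len Minimum reported hit length (bp).
#' @param max_div Maximum reported percent divergence; alignments more
#'   diverged than this are indistinguishable from chance and are dropped.
#' @param seed_width Exact seed k-mer width.
#' @param seed_stride Offset between successive seed positions along a read.
#' @return Tibble of hits: `read_id`, `consensus_id`, `read_start`,
#'   `read_end`, `cons_start`, `cons_end` (0-based half-open, consensus
#'   coordinates always on its forward strand), `strand`, `pct_div`,
#'   `score`. Reads with no hit are absent.
#' @export
mask_reads <- function(reads, library, min_hit_len = 30, max_div = 40,
                       seed_width = 11, seed_stride = 4) {
  if (is.null(library) || nrow(library) == 0) abort("Empty consensus library.")
  check_seq_column(reads, what = "reads")
  check_seq_column(library, what = "library")
  empty <- tibble(read_id = character(), consensus_id = character(),
                  read_start = integer(), read_end = integer(),
                  cons_start = integer(), cons_end = integer(),
                  strand = character(), pct_div = double(), score = double())
  if (nrow(reads) == 0) return(empty)

  k <- as.integer(seed_width)
  # k-mer index over both strands of every consensus
  idx <- list()
  for (ci in seq_len(nrow(library))) {
    for (strand in c("+", "-")) {
      s <- if (strand == "+") library$seq[ci] else revcomp_fast(library$seq[ci])
      L <- nchar(s)
      if (L < k) next
      pos <- seq_len(L - k + 1L)
      idx[[length(idx) + 1L]] <- tibble(
        kmer = substring(s, pos, pos + k - 1L),
        ci = ci, strand = strand, cpos = pos - 1L
      )
    }
  }
  index <- bind_rows(idx)

  rl <- nchar(reads$seq)
  seed_starts <- lapply(rl, function(L) {
    if (L < k) integer(0) else unique(c(seq(0L, L - k, by = seed_stride), L - k))
  })
  n_seeds <- lengths(seed_starts)
  ri <- rep.int(seq_len(nrow(reads)), n_seeds)
  rpos <- unlist(seed_starts, use.names = FALSE)
  read_kmers <- tibble(
    ri = ri, rpos = rpos,
    kmer = substring(reads$seq[ri], rpos + 1L, rpos + k)
  )
  cand <- inner_join(read_kmers, index, by = "kmer",
                     relationship = "many-to-many")
  if (nrow(cand) == 0) return(empty)
  cand$diag <- cand$cpos - cand$rpos
  cand <- distinct(cand, .data$ri, .data$ci, .data$strand, .data$diag)

  # ungapped extension: aligned region is the read/consensus overlap on the diagonal
  clen <- nchar(library$seq)[cand$ci]
  rlen <- rl[cand$ri]
  r_from <- pmax(0L, -cand$diag)
  r_to <- pmin(rlen, clen - cand$diag) # half-open
  len <- r_to - r_from
  keep <- len >= min_hit_len
  cand <- cand[keep, , drop = FALSE]
  if (nrow(cand) == 0) return(empty)
  r_from <- r_from[keep]; r_to <- r_to[keep]; len <- len[keep]

  read_part <- substring(reads$seq[cand$ri], r_from + 1L, r_to)
  cons_seq_oriented <- character(nrow(cand))
  plus <- cand$strand == "+"
  cons_seq_oriented[plus] <- library$seq[cand$ci[plus]]
  if (any(!plus)) {
    # cache reverse complements once per consensus
    rc <- revcomp_fast(library$seq)
    cons_seq_oriented[!plus] <- rc[cand$ci[!plus]]
  }
  cons_part <- substring(cons_seq_oriented, r_from + cand$diag + 1L, r_to + cand$diag)
  mm <- hamming_pairs(read_part, cons_part)
  score <- len - 2 * mm
  pct_div <- 100 * mm / len
  keep_div <- pct_div <= max_div
  cand <- cand[keep_div, , drop = FALSE]
  if (nrow(cand) == 0) return(empty)
  r_from <- r_from[keep_div]; r_to <- r_to[keep_div]; len <- len[keep_div]
  mm <- mm[keep_div]; score <- score[keep_div]; pct_div <- pct_div[keep_div]

  hits <- tibble(
    ri = cand$ri, ci = cand$ci, cons_id = library$id[cand$ci],
    strand = cand$strand,
    read_start = r_from, read_end = r_to,
    ostart = r_from + cand$diag, oend = r_to + cand$diag, # oriented consensus coords
    pct_div = pct_div, score = score, len = len
  )
  # greedy per-read attribution: best score, tie -> lower consensus id, lower start
  hits <- arrange(hits, .data$ri, desc(.data$score), .data$cons_id, .data$read_start)
  multi <- hits$ri %in% hits$ri[duplicated(hits$ri)]
  chosen <- hits[!multi, , drop = FALSE]
  if (any(multi)) {
    extra <- hits[multi, , drop = FALSE] |>
      group_by(.data$ri) |>
      group_modify(~ .select_nonoverlapping(.x)) |>
      ungroup()
    chosen <- bind_rows(chosen, extra)
  }

  clen_sel <- nchar(library$seq)[chosen$ci]
  cons_start <- ifelse(chosen$strand == "+", chosen$ostart, clen_sel - chosen$oend)
  cons_end <- ifelse(chosen$strand == "+", chosen$oend, clen_sel - chosen$ostart)
  out <- tibble(
    read_id = reads$id[chosen$ri],
    consensus_id = library$id[chosen$ci],
    read_start = as.integer(chosen$read_start),
    read_end = as.integer(chosen$read_end),
    cons_start = as.integer(cons_start),
    cons_end = as.integer(cons_end),
    strand = chosen$strand,
    pct_div = chosen$pct_div,
    score = chosen$score
  )
  arrange(out, .data$read_id, .data$read_start)
}

.select_nonoverlapping <- function(h) {
  taken_start <- integer(0)
  taken_end <- integer(0)
  keep <- logical(nrow(h))
  for (i in seq_len(nrow(h))) {
    s <- h$read_start[i]; e <- h$read_end[i]
    if (!any(s < taken_end & e > taken_start)) {
      keep[i] <- TRUE
      taken_start <- c(taken_start, s)
      taken_end <- c(taken_end, e)
    }
  }
  h[keep, , drop = FALSE]
}
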