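#' Map short reads to targets, full length and ungapped, with up to k mismatches
#'
#' Finds every full-length ungapped placement of each query on each target
#' with at most `k` substitutions — the Bowtie-v-style semantics used for
#' small-RNA work. Antisense queries are reverse-complemented before
#' matching, so reported offsets are always on the forward strand of the
#' target. The search is seeded by the pigeonhole principle: each query is
#' split into `k + 1` contiguous blocks, any placement with at most `k`
#' mismatches must match one block exactly, and candidate placements from
#' each exact block (a `Biostrings` trusted-band `PDict`) are verified by
#' Hamming count. The result is identical to a brute-force sliding-window
#' search.
#'
#' @param queries Tibble with columns `id` and `seq`, or a character vector
#'   (optionally named) of sequences. Queries containing symbols outside
#'   `A,C,G,T` are matched by a direct sliding-window scan instead of the
#'   seeded path.
#' @param targets Tibble with columns `id` and `seq`, or a named character
#'   vector.
#' @param k Maximum number of mismatches (0-5).
#' @param orientation `"sense"` (query as given) or `"antisense"`
#'   (reverse-complemented query).
#' @return Tibble with columns `read_id`, `target_id`, `offset` (0-based
#'   placement of the query's leftmost base on the target forward strand),
#'   `width`, `orientation`, `mismatches`. Zero rows when nothing maps.
#' @examples
#' map_with_mismatches(c(r1 = "ACGT"), c(t1 = "TTACGTTT"), k = 0)
#' @export
map_with_mismatches <- function(queries, targets, k = 0,
                                orientation = c("sense", "antisense")) {
  orientation <- match.arg(orientation)
  if (!is_scalar_number(k) || k < 0 || k > 5) abort("`k` must be a single integer in 0..5.")
  k <- as.integer(k)
  q <- .as_seq_tbl(queries, "queries")
  t <- .as_seq_tbl(targets, "targets")
  empty <- tibble(read_id = character(), target_id = character(),
                  offset = integer(), width = integer(),
                  orientation = character(), mismatches = integer())
  if (nrow(q) == 0 || nrow(t) == 0) return(empty)

  seq_to_match <- if (orientation == "antisense") revcomp_fast(q$seq) else q$seq
  clean <- !grepl("[^ACGT]", seq_to_match)

  hits <- list()
  if (any(clean)) {
    # identical sequences are mapped once and the hits fanned back out
    useq <- unique(seq_to_match[clean])
    # seeding has a fixed per-call index-build cost; small problems are
    # cheaper as a direct scan (identical results either way)
    small <- length(useq) * sum(nchar(t$seq)) < 1e4
    uhits <- if (small) .map_scan(as.character(seq_along(useq)), useq, t, k)
             else .map_pdict(as.character(seq_along(useq)), useq, t, k)
    if (nrow(uhits) > 0) {
      fan <- tibble(read_id = q$id[clean],
                    uid = as.character(match(seq_to_match[clean], useq)))
      uhits <- rename(uhits, uid = "read_id")
      hits[[length(hits) + 1L]] <-
        inner_join(fan, uhits, by = "uid", relationship = "many-to-many") |>
        select(-"uid")
    }
  }
  if (any(!clean)) {
    hits[[length(hits) + 1L]] <-
      .map_scan(q$id[!clean], seq_to_match[!clean], t, k)
  }
  out <- bind_rows(hits)
  if (nrow(out) == 0) return(empty)
  out$orientation <- orientation
  out <- arrange(out, .data$read_id, .data$target_id, .data$offset)
  out[, c("read_id", "target_id", "offset", "width", "orientation", "mismatches")]
}

.as_seq_tbl <- function(x, what) {
  if (is.character(x)) {
    ids <- names(x) %||% paste0(substr(what, 1, 1), seq_along(x))
    x <- tibble(id = ids, seq = unname(x))
  }
  if (!all(c("id", "seq") %in% names(x))) {
    abort(sprintf("`%s` must have `id` and `seq` columns.", what))
  }
  tibble(id = as.character(x$id), seq = toupper(as.character(x$seq)))
}

# Pigeonhole-seeded search over all targets; queries must be pure ACGT.
# Targets are concatenated with N spacers into one subject so a single
# matchPDict scan covers them all; N never matches an ACGT pattern, and
# candidate placements are bounds-checked per target, so no hit can span a
# target boundary.
.map_pdict <- function(ids, seqs, targets, k) {
  widths <- nchar(seqs)
  tlen <- nchar(targets$seq)
  spacer <- 40L
  tstart <- cumsum(c(1L, head(tlen, -1L) + spacer)) # global 1-based start per target
  subject <- Biostrings::DNAString(paste(targets$seq, collapse = strrep("N", spacer)))

  if (k == 0L) {
    res <- list()
    for (w in sort(unique(widths))) {
      sel <- which(widths == w)
      pd <- Biostrings::PDict(Biostrings::DNAStringSet(seqs[sel]))
      m <- Biostrings::matchPDict(pd, subject)
      starts <- Biostrings::startIndex(m)
      npm <- lengths(starts)
      if (sum(npm) == 0) next
      g <- unlist(starts, use.names = FALSE)
      ti <- findInterval(g, tstart)
      res[[length(res) + 1L]] <- tibble(
        read_id = ids[sel[rep.int(seq_along(npm), npm)]],
        target_id = targets$id[ti],
        offset = g - tstart[ti],
        width = w,
        mismatches = 0L
      )
    }
    return(bind_rows(res))
  }

  # k + 1 disjoint exact seeds of constant width s = width %/% (k + 1) per
  # seed-width group; any placement with <= k mismatches leaves at least
  # one seed mismatch-free (pigeonhole).
  s_all <- as.integer(widths %/% (k + 1L))
  scan_sel <- s_all < 4L # too short to seed usefully: scan directly
  out_scan <- if (any(scan_sel)) .map_scan(ids[scan_sel], seqs[scan_sel], targets, k)
              else NULL
  qi_list <- list(); gstart_list <- list()
  for (s in unique(s_all[!scan_sel])) {
    grp <- which(s_all == s)
    block_off <- (0:k) * s
    seed_q <- rep(grp, times = k + 1L)
    seed_b <- rep(block_off, each = length(grp))
    seeds <- substring(seqs[seed_q], seed_b + 1L, seed_b + s)
    pd <- Biostrings::PDict(Biostrings::DNAStringSet(seeds))
    m <- Biostrings::matchPDict(pd, subject)
    starts <- Biostrings::startIndex(m)
    npm <- lengths(starts)
    if (sum(npm) == 0) next
    si <- rep.int(seq_along(npm), npm)
    qi_list[[length(qi_list) + 1L]] <- seed_q[si]
    gstart_list[[length(gstart_list) + 1L]] <-
      unlist(starts, use.names = FALSE) - seed_b[si]
  }
  if (length(qi_list) == 0) return(out_scan %||% tibble())
  qi <- unlist(qi_list, use.names = FALSE)
  gstart <- unlist(gstart_list, use.names = FALSE)

  key <- qi * (length(subject) + 2) + gstart
  keep1 <- !duplicated(key) & gstart >= 1L
  qi <- qi[keep1]; gstart <- gstart[keep1]
  ti <- findInterval(gstart, tstart)
  local <- gstart - tstart[ti] # 0-based offset within target
  w_cc <- widths[qi]
  ok <- local >= 0L & (local + w_cc) <= tlen[ti]
  if (!any(ok)) return(out_scan %||% tibble())
  qi <- qi[ok]; ti <- ti[ok]; local <- local[ok]; w_cc <- w_cc[ok]
  sub_seq <- substring(targets$seq[ti], local + 1L, local + w_cc)
  mm <- hamming_pairs(seqs[qi], sub_seq)
  keep <- mm <= k
  if (!any(keep)) return(out_scan %||% tibble())
  out <- tibble(
    read_id = ids[qi[keep]],
    target_id = targets$id[ti[keep]],
    offset = local[keep],
    width = w_cc[keep],
    mismatches = as.integer(mm[keep])
  )
  if (!is.null(out_scan) && nrow(out_scan) > 0) out <- bind_rows(out, out_scan)
  out
}

# Direct sliding-window scan (fallback for queries with ambiguous symbols).
.map_scan <- function(ids, seqs, targets, k) {
  res <- list()
  for (i in seq_along(seqs)) {
    w <- nchar(seqs[i])
    for (ti in seq_len(nrow(targets))) {
      L <- nchar(targets$seq[ti])
      if (L < w) next
      starts <- seq_len(L - w + 1L)
      mm <- hamming_pairs(rep(seqs[i], length(starts)),
                          substring(targets$seq[ti], starts, starts + w - 1L))
      keep <- which(mm <= k)
      if (length(keep) == 0) next
      res[[length(res) + 1L]] <- tibble(
        read_id = ids[i], target_id = targets$id[ti],
        offset = starts[keep] - 1L, width = w,
        mismatches = as.integer(mm[keep])
      )
    }
  }
  bind_rows(res)
}
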