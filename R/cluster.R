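#' Validate a repeat library
#'
#' Applies the standard minimum-length filter for repeat consensus
#' libraries: entries shorter than `min_length` (default 100 bp) are
#' rejected and reported. Entry ids must be unique.
#'
#' @param entries Tibble with columns `id`, `seq` and optionally
#'   annotation columns (`te_class`, `order`, `superfamily`, `provenance`).
#' @param min_length Minimum entry length in bp.
#' @return The filtered tibble; the number of rejected entries is attached
#'   as attribute `n_rejected`.
#' @export
repeat_library <- function(entries, min_length = 100) {
  check_seq_column(entries, what = "library")
  if (anyDuplicated(entries$id)) abort("Library entry ids must be unique.")
  short <- nchar(entries$seq) < min_length
  if (any(short)) {
    warn(sprintf("repeat_library(): rejected %d entr%s shorter than %d bp.",
                 sum(short), if (sum(short) == 1) "y" else "ies", min_length))
  }
  out <- entries[!short, , drop = FALSE]
  attr(out, "n_rejected") <- sum(short)
  out
}

#' Greedy redundancy clustering of repeat contigs
#'
#' CD-HIT-style greedy incremental clustering: entries are sorted by
#' decreasing length (ties by id) and each entry joins the first existing
#' cluster whose representative matches it at `>= identity`, otherwise it
#' founds a new cluster. Cluster representatives are therefore always the
#' longest member. Identity between two sequences is the maximum, over all
#' ungapped offsets of one sequence against the other (forward strands),
#' of `matches / length of the shorter sequence`.
#'
#' @param library Tibble with `id` and `seq` columns (see
#'   [repeat_library()]).
#' @param identity Identity threshold in (0, 1].
#' @return Tibble with columns `id`, `cluster` (integer, in founding
#'   order), `representative` (id of the cluster representative) and
#'   `is_representative`. The threshold used is attached as attribute
#'   `identity`.
#' @examples
#' lib <- tibble::tibble(id = c("a", "b"), seq = c("ACGTACGT", "ACGTACGT"))
#' cluster_contigs(lib, identity = 0.95)
#' @export
cluster_contigs <- function(library, identity = 0.95) {
  if (!is_scalar_number(identity) || identity <= 0 || identity > 1) {
    abort("`identity` must be a single number in (0, 1].")
  }
  empty <- tibble(id = character(), cluster = integer(),
                  representative = character(), is_representative = logical())
  if (is.null(library) || nrow(library) == 0) {
    attr(empty, "identity") <- identity
    return(empty)
  }
  check_seq_column(library, what = "library")
  ord <- order(-nchar(library$seq), library$id)
  ids <- library$id[ord]
  seqs <- library$seq[ord]
  enc <- lapply(seqs, function(s) utf8ToInt(s))

  rep_idx <- integer(0)  # index (into sorted order) of each cluster's representative
  assignment <- integer(length(ids))
  for (i in seq_along(ids)) {
    placed <- FALSE
    for (ci in seq_along(rep_idx)) {
      if (.pair_identity(enc[[rep_idx[ci]]], enc[[i]]) >= identity) {
        assignment[i] <- ci
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      rep_idx <- c(rep_idx, i)
      assignment[i] <- length(rep_idx)
    }
  }
  out <- tibble(
    id = ids,
    cluster = assignment,
    representative = ids[rep_idx[assignment]],
    is_representative = seq_along(ids) %in% rep_idx
  )
  attr(out, "identity") <- identity
  out
}

# Best ungapped-offset identity over the shorter sequence; `a` and `b` are
# utf8ToInt encodings. Offsets that cannot reach the current best are
# skipped via the overlap-length bound.
.pair_identity <- function(a, b) {
  la <- length(a); lb <- length(b)
  short <- min(la, lb)
  best <- 0L
  for (off in seq(-(lb - 1L), la - 1L)) {
    a_from <- max(1L, 1L + off); a_to <- min(la, lb + off)
    len <- a_to - a_from + 1L
    if (len < best || len <= 0L) next
    b_from <- a_from - off
    m <- sum(a[a_from:a_to] == b[b_from:(b_from + len - 1L)])
    if (m > best) best <- m
  }
  best / short
}
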