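#' Per-superfamily masked base pairs and genome proportions
#'
#' Sums masked base pairs per repeat category after merging overlapping hit
#' intervals on each read, and expresses them as a percentage of the total
#' sequencing effort. Run once with a library including unclassified
#' ("unknown") repeats and once excluding them to bracket the contribution
#' of degraded, unrecognizable TE copies.
#'
#' @param hits Tibble of hits from [mask_reads()] or
#'   [parse_repeatmasker_table()].
#' @param annotation Tibble mapping `consensus_id` (or `id`) to
#'   `superfamily`; hits on consensuses absent from the annotation are
#'   labelled `"unknown"`.
#' @param total_bp Total base pairs screened (> 0); the denominator for
#'   percentages.
#' @param read_lengths Optional named vector of read lengths; when given,
#'   hits extending past the end of their read raise an error.
#' @return Tibble with columns `superfamily`, `masked_bp`, `pct_genome`,
#'   sorted by decreasing `masked_bp`. Total masked bp never exceeds
#'   `total_bp` contribution of the reads involved.
#' @export
genome_proportions <- function(hits, annotation, total_bp, read_lengths = NULL) {
  if (!is_scalar_number(total_bp) || total_bp <= 0) abort("`total_bp` must be positive.")
  ann <- .norm_annotation(annotation)
  if (!is.null(read_lengths)) {
    over <- hits$read_end > unname(read_lengths[hits$read_id])
    if (any(over, na.rm = TRUE)) {
      abort(sprintf("%d hit(s) extend beyond their read bounds.", sum(over, na.rm = TRUE)))
    }
  }
  if (nrow(hits) == 0) {
    return(tibble(superfamily = character(), masked_bp = integer(),
                  pct_genome = double()))
  }
  h <- left_join(hits, ann, by = "consensus_id")
  h$superfamily[is.na(h$superfamily)] <- "unknown"
  # merge overlapping intervals within read x superfamily before summing
  grp <- paste(h$read_id, h$superfamily, sep = "\r")
  ir <- IRanges::IRanges(start = h$read_start + 1L, end = h$read_end)
  merged <- IRanges::reduce(S4Vectors::split(ir, grp))
  bp <- sum(IRanges::width(merged))
  sfam <- sub("^.*\r", "", names(bp))
  out <- tibble(superfamily = sfam, bp = as.integer(bp)) |>
    group_by(.data$superfamily) |>
    summarise(masked_bp = sum(.data$bp), .groups = "drop") |>
    mutate(pct_genome = 100 * .data$masked_bp / total_bp) |>
    arrange(desc(.data$masked_bp))
  out
}

.norm_annotation <- function(annotation) {
  ann <- as_tibble(annotation)
  if (!"consensus_id" %in% names(ann) && "id" %in% names(ann)) {
    ann <- rename(ann, consensus_id = "id")
  }
  if (!all(c("consensus_id", "superfamily") %in% names(ann))) {
    abort("`annotation` needs `consensus_id` (or `id`) and `superfamily` columns.")
  }
  distinct(ann[, c("consensus_id", "superfamily")])
}

#' Simpson and Shannon diversity of a TE community
#'
#' Treats TE superfamilies as species and masked base pairs (or any
#' abundance) as individuals. Simpson's index uses the finite-sample form
#' `D = sum n_i (n_i - 1) / (N (N - 1))`; the Gini-Simpson index is
#' `1 - D`; Shannon's index is `H = -sum p_i log(p_i)` with `0 log 0 = 0`.
#' Unclassified categories should be excluded before calling (pass only the
#' labels that count as species).
#'
#' @param abundance Named numeric vector, or a tibble with columns
#'   `superfamily` (or `label`) and one numeric abundance column.
#' @return One-row tibble: `n_labels`, `total`, `simpson_d`,
#'   `gini_simpson`, `shannon_h`.
#' @examples
#' diversity_indices(c(A = 50, B = 50))
#' @export
diversity_indices <- function(abundance) {
  if (is.data.frame(abundance)) {
    lab_col <- intersect(c("superfamily", "label"), names(abundance))[1]
    if (is.na(lab_col)) abort("Need a `superfamily` or `label` column.")
    num_col <- setdiff(names(abundance)[vapply(abundance, is.numeric, logical(1))], lab_col)[1]
    x <- setNames(abundance[[num_col]], abundance[[lab_col]])
  } else {
    x <- abundance
  }
  if (any(x < 0)) abort("Abundances must be non-negative.")
  x <- x[x > 0]
  if (length(x) == 0) abort("At least one positive abundance is required.")
  N <- sum(x)
  if (N < 2) abort("Simpson's finite-sample index requires a total of at least 2.")
  p <- x / N
  D <- sum(x * (x - 1)) / (N * (N - 1))
  H <- -sum(p * log(p))
  tibble(
    n_labels = length(x), total = N,
    simpson_d = D, gini_simpson = 1 - D, shannon_h = H
  )
}

#' Per-superfamily divergence histograms (amplification landscapes)
#'
#' Bins each read's percent divergence from its closest (least divergent)
#' consensus of a superfamily into 1-percent bins. A read contributes once
#' per superfamily, via its least-divergent hit to that superfamily.
#'
#' @param hits Tibble of hits carrying `pct_div` (from [mask_reads()] or
#'   [parse_repeatmasker_table()]).
#' @param annotation Consensus-to-superfamily map (see
#'   [genome_proportions()]).
#' @param bin_width Bin width in percent (default 1).
#' @return Tibble with columns `superfamily`, `bin` (left edge, percent),
#'   `n`; bins are contiguous from 0 to each superfamily's maximum, and
#'   per-superfamily counts sum to the number of contributing reads.
#' @export
divergence_histogram <- function(hits, annotation, bin_width = 1) {
  if (any(hits$pct_div < 0)) abort("Negative divergence encountered.")
  ann <- .norm_annotation(annotation)
  h <- left_join(hits, ann, by = "consensus_id")
  h$superfamily[is.na(h$superfamily)] <- "unknown"
  best <- h |>
    group_by(.data$superfamily, .data$read_id) |>
    summarise(pct_div = min(.data$pct_div), .groups = "drop") |>
    mutate(bin = floor(.data$pct_div / bin_width) * bin_width)
  counts <- count(best, .data$superfamily, .data$bin, name = "n")
  # complete bins from 0 to the per-superfamily maximum
  counts |>
    group_by(.data$superfamily) |>
    tidyr::complete(bin = seq(0, max(.data$bin), by = bin_width),
                    fill = list(n = 0L)) |>
    ungroup() |>
    arrange(.data$superfamily, .data$bin)
}

#' Classify a divergence landscape for ongoing activity and shape
#'
#' A superfamily is called "ongoing" when any read sits in the first bin
#' (less than `bin_width` percent diverged from a consensus). The histogram
#' shape is classified after 3-bin moving-average smoothing (partial means
#' at the edges): `recent-peak-decreasing` when the smoothed maximum is in
#' bin 0, otherwise `past-peak-unimodal` or `past-peak-multimodal` by the
#' number of smoothed local maxima; a perfectly flat smoothed histogram is
#' `flat/other`.
#'
#' @param hist Tibble from [divergence_histogram()] (one or several
#'   superfamilies), or a bare numeric vector of counts for contiguous bins
#'   starting at 0.
#' @return Tibble with columns `superfamily` (absent for vector input),
#'   `ongoing`, `shape`, `argmax_bin` (left edge of the smoothed modal
#'   bin), `n_reads`.
#' @export
classify_activity <- function(hist) {
  if (is.numeric(hist)) {
    return(.classify_counts(hist, bins = seq_along(hist) - 1))
  }
  if (nrow(hist) == 0) abort("Empty histogram.")
  hist |>
    group_by(.data$superfamily) |>
    group_modify(~ .classify_counts(.x$n[order(.x$bin)], bins = sort(.x$bin))) |>
    ungroup()
}

.classify_counts <- function(counts, bins) {
  if (length(counts) == 0 || sum(counts) == 0) abort("Empty histogram.")
  n <- length(counts)
  sm <- vapply(seq_len(n), function(i) {
    mean(counts[max(1, i - 1):min(n, i + 1)])
  }, numeric(1))
  argmax <- which.max(sm) # ties break to the lowest bin
  ongoing <- counts[1] > 0 && bins[1] == 0
  if (n == 1L) {
    # a single occupied bin at 0 is the extreme recent-activity landscape
    shape <- if (ongoing) "recent-peak-decreasing" else "flat/other"
  } else if (all(sm == sm[1])) {
    shape <- "flat/other"
  } else if (argmax == 1L) {
    shape <- "recent-peak-decreasing"
  } else {
    n_peaks <- .count_local_maxima(sm)
    shape <- if (n_peaks <= 1L) "past-peak-unimodal" else "past-peak-multimodal"
  }
  tibble(ongoing = ongoing, shape = shape,
         argmax_bin = bins[argmax], n_reads = sum(counts))
}

# local maxima of a smoothed profile; plateaus count once
.count_local_maxima <- function(x) {
  r <- rle(x)
  v <- r$values
  n <- length(v)
  if (n == 1) return(0L)
  peaks <- 0L
  for (i in seq_len(n)) {
    left_ok <- i == 1 || v[i - 1] < v[i]
    right_ok <- i == n || v[i + 1] < v[i]
    if (left_ok && right_ok) peaks <- peaks + 1L
  }
  peaks
}

#' Percentage share of a count within a total
#'
#' The ratio summaries used for repeat-mining yields, annotation-category
#' expression budgets and sequencing coverage: `100 * count / total`,
#' optionally rounded to the precision such tables are reported at.
#'
#' @param count,total Non-negative numbers, `total > 0`.
#' @param digits Rounding digits (`NULL` to skip rounding).
#' @return The percentage.
#' @examples
#' percent_share(75381, 109909) # 68.6
#' @export
percent_share <- function(count, total, digits = 1) {
  if (any(total <= 0)) abort("`total` must be positive.")
  out <- 100 * count / total
  if (!is.null(digits)) out <- round(out, digits)
  out
}
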