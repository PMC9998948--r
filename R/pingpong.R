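#' Map putative piRNAs to TE transcripts in both orientations
#'
#' Sense mapping allows 0 mismatches (a piRNA processed directly from a
#' transcript should match it exactly); antisense mapping allows up to 3
#' (target cleavage tolerates imperfect pairing). Transcripts that are not
#' hit by both sense- and antisense-mapping piRNAs are excluded from the
#' returned hit sets, as required before computing an overlap signature.
#'
#' @param pirnas Tibble with `id`, `seq` (e.g. from
#'   [select_putative_pirnas()]).
#' @param transcripts Tibble with `id`, `seq` of TE transcripts.
#' @param sense_k,antisense_k Mismatch allowances.
#' @return List with `sense` and `antisense` hit tibbles (see
#'   [map_with_mismatches()]) restricted to transcripts with hits in both
#'   orientations, and `transcripts_kept` (character).
#' @export
map_pirnas_to_tes <- function(pirnas, transcripts, sense_k = 0, antisense_k = 3) {
  sense <- map_with_mismatches(pirnas, transcripts, k = sense_k,
                               orientation = "sense")
  antisense <- map_with_mismatches(pirnas, transcripts, k = antisense_k,
                                   orientation = "antisense")
  keep <- intersect(unique(sense$target_id), unique(antisense$target_id))
  list(
    sense = sense[sense$target_id %in% keep, , drop = FALSE],
    antisense = antisense[antisense$target_id %in% keep, , drop = FALSE],
    transcripts_kept = keep
  )
}

#' 5'-to-5' overlap distribution of sense/antisense piRNA pairs
#'
#' For every transcript, every (sense, antisense) hit pair whose 5' ends
#' overlap by `1 <= l <= max_overlap` nucleotides is counted. With a sense
#' 5' end at 0-based transcript offset `s` and an antisense 5' end at
#' `a = offset + width - 1` (the rightmost base of the antisense
#' placement), the overlap is `l = a - s + 1`. Ping-pong amplification
#' produces an excess at `l = 10`.
#'
#' @param sense,antisense Hit tibbles from [map_pirnas_to_tes()] (or
#'   [map_with_mismatches()]).
#' @param max_overlap Largest overlap length tallied.
#' @return Tibble `overlap` (1..`max_overlap`), `n_pairs`, `fraction`
#'   (classed `overlap_distribution`); `fraction` sums to 1 when any pair
#'   exists and is `NaN` otherwise (flagged by attribute
#'   `total_pairs == 0`).
#' @export
overlap_distribution <- function(sense, antisense, max_overlap = 25) {
  s_tab <- count(sense, .data$target_id, pos = .data$offset, name = "n_s")
  a_tab <- count(antisense, .data$target_id,
                 pos = .data$offset + .data$width - 1L, name = "n_a")
  counts <- integer(max_overlap)
  if (nrow(s_tab) > 0 && nrow(a_tab) > 0) {
    for (l in seq_len(max_overlap)) {
      joined <- inner_join(
        s_tab,
        mutate(a_tab, pos = .data$pos - l + 1L),
        by = c("target_id", "pos")
      )
      counts[l] <- sum(joined$n_s * joined$n_a)
    }
  }
  total <- sum(counts)
  out <- tibble(
    overlap = seq_len(max_overlap),
    n_pairs = counts,
    fraction = if (total > 0) counts / total else rep(NaN, max_overlap)
  )
  attr(out, "total_pairs") <- total
  class(out) <- c("overlap_distribution", class(out))
  out
}

#' Ping-pong Z-score at a focal overlap length
#'
#' Standardized excess of the focal overlap fraction over the background
#' of all other overlap lengths:
#' `Z = (f_focal - mean(f_bg)) / sd(f_bg)` with the sample (n-1) standard
#' deviation. `NA` (with a warning) when the background sd is zero.
#'
#' @param dist An [overlap_distribution()] tibble.
#' @param focal Focal overlap length (default 10, the ping-pong length).
#' @return A single numeric Z-score, or `NA` when undefined.
#' @export
pingpong_zscore <- function(dist, focal = 10) {
  if (!focal %in% dist$overlap) abort("`focal` is outside the tallied overlap range.")
  bg <- dist$fraction[dist$overlap != focal]
  if (length(bg) < 3) abort("Need at least 3 background overlap lengths.")
  if (isTRUE(all.equal(attr(dist, "total_pairs"), 0)) || anyNA(dist$fraction) ||
      any(is.nan(dist$fraction))) {
    abort("Overlap distribution has no pairs; Z-score undefined.")
  }
  s <- sd(bg)
  if (s == 0) {
    warn("Background sd is zero; Z-score undefined.")
    return(NA_real_)
  }
  (dist$fraction[dist$overlap == focal] - mean(bg)) / s
}

#' One-call ping-pong signature for a piRNA pool
#'
#' Convenience wrapper: maps putative piRNAs to TE transcripts
#' ([map_pirnas_to_tes()]), tallies the 5'-5' overlap distribution and
#' computes the Z-score at the focal length.
#'
#' @inheritParams map_pirnas_to_tes
#' @inheritParams overlap_distribution
#' @param focal Focal overlap length for the Z-score.
#' @return Object of class `pingpong_signature`: list with `distribution`,
#'   `z`, `focal`, `n_sense`, `n_antisense`, `transcripts_kept`. Supports
#'   [tidy()], [glance()] and [autoplot()].
#' @export
pingpong_signature <- function(pirnas, transcripts, sense_k = 0, antisense_k = 3,
                               max_overlap = 25, focal = 10) {
  maps <- map_pirnas_to_tes(pirnas, transcripts, sense_k, antisense_k)
  dist <- overlap_distribution(maps$sense, maps$antisense, max_overlap)
  z <- if (attr(dist, "total_pairs") > 0) pingpong_zscore(dist, focal) else NA_real_
  structure(
    list(
      distribution = dist, z = z, focal = focal,
      n_sense = length(unique(maps$sense$read_id)),
      n_antisense = length(unique(maps$antisense$read_id)),
      transcripts_kept = maps$transcripts_kept
    ),
    class = "pingpong_signature"
  )
}

#' @export
print.pingpong_signature <- function(x, ...) {
  cat("Ping-pong signature\n")
  cat(sprintf("  mapped reads: %d sense, %d antisense on %d transcript(s)\n",
              x$n_sense, x$n_antisense, length(x$transcripts_kept)))
  tot <- attr(x$distribution, "total_pairs")
  cat(sprintf("  overlapping 5'-5' pairs: %s\n", format(tot, big.mark = ",")))
  if (tot > 0) {
    cat(sprintf("  modal overlap: %d nt; Z(%d) = %.2f\n",
                x$distribution$overlap[which.max(x$distribution$n_pairs)],
                x$focal, x$z))
  }
  invisible(x)
}

#' Ping-pong pair counts per TE superfamily
#'
#' Counts (sense, antisense) pairs at exactly the focal overlap length,
#' assigned to the superfamily of the transcript they lie on.
#' Unannotated transcripts are bucketed as `"unknown"`.
#'
#' @param sense,antisense Hit tibbles.
#' @param annotation Transcript annotation: tibble with `transcript` (or
#'   `id`/`consensus_id`) and `superfamily`.
#' @param focal Overlap length counted (default 10).
#' @return Tibble `superfamily`, `n_pairs`.
#' @export
pingpong_pairs_by_superfamily <- function(sense, antisense, annotation, focal = 10) {
  s_tab <- count(sense, .data$target_id, pos = .data$offset, name = "n_s")
  a_tab <- count(antisense, .data$target_id,
                 pos = .data$offset + .data$width - 1L, name = "n_a")
  joined <- inner_join(
    s_tab, mutate(a_tab, pos = .data$pos - focal + 1L),
    by = c("target_id", "pos")
  )
  ann <- .norm_tx_annotation(annotation)
  joined <- left_join(joined, ann, by = c(target_id = "transcript"))
  joined$superfamily[is.na(joined$superfamily)] <- "unknown"
  joined |>
    group_by(.data$superfamily) |>
    summarise(n_pairs = sum(.data$n_s * .data$n_a), .groups = "drop") |>
    arrange(desc(.data$n_pairs))
}

.norm_tx_annotation <- function(annotation) {
  ann <- as_tibble(annotation)
  for (alias in c("id", "consensus_id")) {
    if (!"transcript" %in% names(ann) && alias %in% names(ann)) {
      ann <- rename(ann, transcript = dplyr::all_of(alias))
    }
  }
  if (!all(c("transcript", "superfamily") %in% names(ann))) {
    abort("Annotation needs `transcript` (or `id`) and `superfamily` columns.")
  }
  distinct(ann[, c("transcript", "superfamily")])
}

#' piRNA abundance (RPM) per TE superfamily
#'
#' Normalizes mapped piRNA read counts per transcript to reads per million
#' (RPM) of each sample's filtered library, sums within superfamily, and
#' averages across same-sex individuals when sample metadata is given.
#' A read is counted once per transcript it maps to, regardless of how
#' many placements it has there.
#'
#' @param hits Hit tibble (sense and/or antisense concatenated; an
#'   `orientation` column is used when present). May carry a `sample`
#'   column for multi-individual input.
#' @param annotation Transcript-to-superfamily map.
#' @param library_size Named numeric vector of filtered library sizes per
#'   sample (or a single number for single-sample input). Must be > 0.
#' @param samples Optional tibble `sample`, `sex` for same-sex averaging.
#' @return Tibble with `superfamily`, optionally `sex` (else `sample`),
#'   and `rpm_sense`, `rpm_antisense`, `rpm_total`.
#' @export
pirna_rpm_by_superfamily <- function(hits, annotation, library_size,
                                     samples = NULL) {
  if (any(library_size <= 0)) abort("Library sizes must be positive.")
  h <- as_tibble(hits)
  if (!"sample" %in% names(h)) h$sample <- "sample1"
  if (!"orientation" %in% names(h)) h$orientation <- "sense"
  if (is.null(names(library_size))) {
    if (length(library_size) != 1) abort("Unnamed `library_size` must be length 1.")
    library_size <- setNames(rep(library_size, length(unique(h$sample))),
                             unique(h$sample))
  }
  miss <- setdiff(unique(h$sample), names(library_size))
  if (length(miss)) abort(sprintf("No library size for sample(s): %s",
                                  paste(miss, collapse = ", ")))
  ann <- .norm_tx_annotation(annotation)
  per_tx <- h |>
    distinct(.data$sample, .data$orientation, .data$target_id, .data$read_id) |>
    count(.data$sample, .data$orientation, .data$target_id, name = "n_reads") |>
    mutate(rpm = 1e6 * .data$n_reads / unname(library_size[.data$sample])) |>
    left_join(ann, by = c(target_id = "transcript"))
  per_tx$superfamily[is.na(per_tx$superfamily)] <- "unknown"
  by_sf <- per_tx |>
    group_by(.data$sample, .data$superfamily, .data$orientation) |>
    summarise(rpm = sum(.data$rpm), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "orientation", values_from = "rpm",
                       names_prefix = "rpm_", values_fill = 0)
  for (col in c("rpm_sense", "rpm_antisense")) {
    if (!col %in% names(by_sf)) by_sf[[col]] <- 0
  }
  by_sf$rpm_total <- by_sf$rpm_sense + by_sf$rpm_antisense
  # superfamilies unseen in a sample count as 0 RPM when averaging
  by_sf <- tidyr::complete(by_sf, .data$sample, .data$superfamily,
                           fill = list(rpm_sense = 0, rpm_antisense = 0,
                                       rpm_total = 0))
  if (!is.null(samples)) {
    by_sf <- by_sf |>
      left_join(as_tibble(samples), by = "sample") |>
      group_by(.data$superfamily, .data$sex) |>
      summarise(across(c("rpm_sense", "rpm_antisense", "rpm_total"), mean),
                .groups = "drop")
  }
  arrange(by_sf, desc(.data$rpm_total))
}
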