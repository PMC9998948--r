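#' Parse a RepeatMasker annotation table into alignment hits
#'
#' Supports the 15-column `.out` summary table and the `.align` alignment
#' dump (only alignment-header lines are consumed from the latter).
#' RepeatMasker's 1-based inclusive coordinates are converted to 0-based
#' half-open; minus-strand ("C") hits keep forward-strand coordinates on the
#' consensus with `strand == "-"`. Header and other unparseable lines are
#' skipped and counted, not fatal; a file yielding no hits at all is an
#' error.
#'
#' @param path Path to a RepeatMasker `.out` or `.align` file.
#' @param dialect `"out"` (default) or `"align"`.
#' @return A tibble of hits with columns `read_id`, `consensus_id`,
#'   `read_start`, `read_end`, `cons_start`, `cons_end`, `strand`,
#'   `pct_div`, `score` and `repeat_label` (the class/family string as
#'   printed). The number of skipped lines is attached as attribute
#'   `skipped_lines`.
#' @export
parse_repeatmasker_table <- function(path, dialect = c("out", "align")) {
  dialect <- match.arg(dialect)
  lines <- readLines(path, warn = FALSE)
  skipped <- 0L
  rows <- list()
  for (ln in lines) {
    t <- trimws(ln)
    if (t == "" || grepl("^(SW|score|Matrix|Gap_init|Transitions|Kimura|#)", t)) {
      next # blank and well-known header/footer lines are not counted
    }
    f <- strsplit(t, "\\s+")[[1]]
    hit <- .parse_rm_fields(f, dialect)
    if (is.null(hit)) {
      skipped <- skipped + 1L
    } else {
      rows[[length(rows) + 1L]] <- hit
    }
  }
  if (length(rows) == 0) {
    abort(sprintf("No parseable RepeatMasker %s lines in '%s'.", dialect, path))
  }
  if (skipped > 0) {
    inform(sprintf("parse_repeatmasker_table(): skipped %d unparseable line(s).", skipped))
  }
  out <- bind_rows(rows)
  attr(out, "skipped_lines") <- skipped
  out
}

# One .out row:
#  score div del ins query qbeg qend (qleft) strand repeat class/family
#  rbeg rend (rleft) id          [+ orientation]
#  score div del ins query qbeg qend (qleft) C      repeat class/family
#  (rleft) rend rbeg id          [C orientation]
.parse_rm_fields <- function(f, dialect) {
  if (length(f) < 14) return(NULL)
  num <- suppressWarnings(as.numeric(f[1:4]))
  if (any(is.na(num))) return(NULL)
  qbeg <- suppressWarnings(as.integer(f[6]))
  qend <- suppressWarnings(as.integer(f[7]))
  if (is.na(qbeg) || is.na(qend) || qbeg > qend) return(NULL)
  strand_field <- f[9]
  unparen <- function(x) suppressWarnings(as.integer(gsub("[()]", "", x)))
  if (dialect == "out") {
    cons_id <- f[10]; label <- f[11]; r1 <- f[12]; r2 <- f[13]; r3 <- f[14]
  } else {
    # .align header: query coords then strand then "name#class/family" then coords
    if (strand_field %in% c("C", "+")) {
      nm <- f[10]; r1 <- f[11]; r2 <- f[12]; r3 <- f[13]
    } else {
      # plus-strand .align lines may omit the strand column
      nm <- f[9]; r1 <- f[10]; r2 <- f[11]; r3 <- f[12]
      strand_field <- "+"
    }
    parts <- strsplit(nm, "#", fixed = TRUE)[[1]]
    cons_id <- parts[1]
    label <- if (length(parts) > 1) parts[2] else "Unknown"
  }
  if (strand_field == "C") {
    cons_beg <- unparen(r3); cons_end <- unparen(r2); strand <- "-"
  } else if (strand_field == "+") {
    cons_beg <- unparen(r1); cons_end <- unparen(r2); strand <- "+"
  } else {
    return(NULL)
  }
  if (is.na(cons_beg) || is.na(cons_end) || cons_beg > cons_end) return(NULL)
  tibble(
    read_id = f[5], consensus_id = cons_id,
    read_start = qbeg - 1L, read_end = qend,
    cons_start = cons_beg - 1L, cons_end = cons_end,
    strand = strand, pct_div = num[2], score = num[1],
    repeat_label = label
  )
}

#' Write alignment hits as a RepeatMasker-style `.out` table
#'
#' The inverse of [parse_repeatmasker_table()]: internal 0-based half-open
#' coordinates are converted back to RepeatMasker's 1-based inclusive
#' convention, with the minus-strand column order ("C" orientation)
#' restored.
#'
#' @param hits Tibble of hits as returned by [mask_reads()] or
#'   [parse_repeatmasker_table()].
#' @param path Output path.
#' @param read_lengths,cons_lengths Named integer vectors giving sequence
#'   lengths, used to fill the "(left)" fields; unknown ids get 0.
#' @return `path`, invisibly.
#' @export
write_repeatmasker_out <- function(hits, path, read_lengths = NULL, cons_lengths = NULL) {
  len_of <- function(tbl, ids) {
    if (is.null(tbl)) return(rep(0L, length(ids)))
    out <- unname(tbl[ids])
    out[is.na(out)] <- 0L
    out
  }
  label <- if ("repeat_label" %in% names(hits)) hits$repeat_label else rep("Unknown", nrow(hits))
  qleft <- pmax(0L, len_of(read_lengths, hits$read_id) - hits$read_end)
  rleft <- pmax(0L, len_of(cons_lengths, hits$consensus_id) - hits$cons_end)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "   SW   perc perc perc  query       position in query     matching repeat            position in repeat",
    "score   div. del. ins.  sequence    begin end    (left)   repeat   class/family   begin end    (left)  ID",
    ""
  ), con)
  for (i in seq_len(nrow(hits))) {
    if (hits$strand[i] == "-") {
      rep_cols <- c(sprintf("(%d)", rleft[i]), hits$cons_end[i], hits$cons_start[i] + 1L)
      ori <- "C"
    } else {
      rep_cols <- c(hits$cons_start[i] + 1L, hits$cons_end[i], sprintf("(%d)", rleft[i]))
      ori <- "+"
    }
    writeLines(paste(
      format(hits$score[i]), sprintf("%.1f", hits$pct_div[i]), "0.0", "0.0",
      hits$read_id[i], hits$read_start[i] + 1L, hits$read_end[i],
      sprintf("(%d)", qleft[i]), ori, hits$consensus_id[i], label[i],
      rep_cols[1], rep_cols[2], rep_cols[3], i
    ), con)
  }
  invisible(path)
}
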