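#' Read a FASTA file into a tibble of sequence records
#'
#' Sequences are uppercased and restricted to the alphabet `A,C,G,T,U,N`.
#' RNA input (containing `U`) is normalized to the internal DNA alphabet
#' (`U -> T`) and flagged in the `alphabet` column so writers can restore it.
#' Records containing any other symbol are rejected and reported via a
#' warning.
#'
#' @param path Path to a FASTA file. Multi-line (wrapped) sequences are
#'   concatenated.
#' @return A tibble with columns `id`, `seq`, `desc` (text after the first
#'   whitespace in the header, `""` when absent) and `alphabet`
#'   (`"DNA"` or `"RNA"`).
#' @examples
#' tf <- tempfile(fileext = ".fa")
#' writeLines(c(">a first record", "ACGT", ">b", "ACG", "TT"), tf)
#' read_fasta(tf)
#' @export
read_fasta <- function(path) {
  lines <- readLines(path, warn = FALSE)
  .check_fasta_lines(lines, path)
  set <- Biostrings::readBStringSet(path, format = "fasta")
  .records_from_stringset(set)
}

.check_fasta_lines <- function(lines, path) {
  nonempty <- which(nzchar(trimws(lines)))
  if (length(nonempty) == 0) abort(sprintf("'%s' is empty.", path))
  first <- nonempty[1]
  if (!startsWith(lines[first], ">")) {
    abort(sprintf("FASTA parse error at line %d of '%s': expected '>' header.",
                  first, path))
  }
  headers <- which(startsWith(lines, ">"))
  for (i in seq_along(headers)) {
    h <- headers[i]
    if (trimws(sub("^>", "", lines[h])) == "") {
      abort(sprintf("FASTA parse error at line %d of '%s': empty header.", h, path))
    }
    to <- if (i < length(headers)) headers[i + 1] - 1 else length(lines)
    body <- lines[seq(h + 1, length.out = max(0, to - h))]
    if (sum(nchar(trimws(body))) == 0) {
      abort(sprintf("FASTA parse error at line %d of '%s': record '%s' has an empty sequence.",
                    h, path, sub("^>\\s*", "", lines[h])))
    }
  }
  invisible(NULL)
}

.records_from_stringset <- function(set, qualities = NULL) {
  full <- names(set) %||% rep("", length(set))
  id <- sub("\\s.*$", "", full)
  desc <- ifelse(grepl("\\s", full), sub("^\\S+\\s+", "", full), "")
  seq <- unname(toupper(as.character(set)))
  out <- tibble(id = id, seq = seq, desc = desc)
  if (!is.null(qualities)) out$qual <- unname(as.character(qualities))

  bad <- grepl("[^ACGTUN]", out$seq)
  if (any(bad)) {
    warn(sprintf(
      "Rejected %d record(s) with symbols outside {A,C,G,T,U,N}: %s",
      sum(bad), paste(head(out$id[bad], 5), collapse = ", ")
    ))
    out <- out[!bad, , drop = FALSE]
  }
  out$alphabet <- ifelse(grepl("U", out$seq, fixed = TRUE), "RNA", "DNA")
  out$seq <- chartr("U", "T", out$seq)
  out
}

#' Write sequence records to a FASTA file
#'
#' Records flagged `alphabet == "RNA"` are written back with `T -> U`.
#'
#' @param records Tibble with columns `id`, `seq` and optionally `desc`,
#'   `alphabet`.
#' @param path Output path.
#' @param line_width Sequence line wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, line_width = 60) {
  check_seq_column(records)
  seq <- records$seq
  if ("alphabet" %in% names(records)) {
    rna <- records$alphabet == "RNA"
    seq[rna] <- chartr("T", "U", seq[rna])
  }
  desc <- if ("desc" %in% names(records)) records$desc else ""
  header <- paste0(">", records$id, ifelse(nzchar(desc), paste0(" ", desc), ""))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seq)) {
    writeLines(header[i], con)
    starts <- seq(1, nchar(seq[i]), by = line_width)
    writeLines(substring(seq[i], starts, pmin(starts + line_width - 1, nchar(seq[i]))), con)
  }
  invisible(path)
}

#' Read a 4-line-record FASTQ file
#'
#' @param path Path to a FASTQ file (Sanger qualities).
#' @return A tibble with columns `id`, `seq`, `desc`, `qual`, `alphabet`;
#'   per record, `nchar(seq) == nchar(qual)`.
#' @export
read_fastq <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[seq_len(length(lines))]
  if (length(lines) %% 4 != 0) {
    abort(sprintf("FASTQ parse error in '%s': %d lines is not a multiple of 4 (truncated record?).",
                  path, length(lines)))
  }
  n <- length(lines) / 4
  for (i in seq_len(n)) {
    b <- (i - 1) * 4
    if (!startsWith(lines[b + 1], "@")) {
      abort(sprintf("FASTQ parse error at line %d of '%s': expected '@' header.", b + 1, path))
    }
    if (!startsWith(lines[b + 3], "+")) {
      abort(sprintf("FASTQ parse error at line %d of '%s': expected '+' separator.", b + 3, path))
    }
    if (nchar(lines[b + 2]) != nchar(lines[b + 4])) {
      abort(sprintf("FASTQ parse error at line %d of '%s': sequence and quality lengths differ.",
                    b + 2, path))
    }
  }
  set <- Biostrings::readBStringSet(path, format = "fastq", with.qualities = TRUE)
  .records_from_stringset(set, qualities = S4Vectors::mcols(set)$qualities)
}

#' Write sequence records to a FASTQ file
#'
#' @inheritParams write_fasta
#' @param records Tibble with columns `id`, `seq`, `qual` (and optionally
#'   `desc`, `alphabet`).
#' @return `path`, invisibly.
#' @export
write_fastq <- function(records, path) {
  check_seq_column(records)
  if (!"qual" %in% names(records)) abort("FASTQ output requires a `qual` column.")
  if (any(nchar(records$seq) != nchar(records$qual))) {
    abort("Sequence and quality lengths differ.")
  }
  seq <- records$seq
  if ("alphabet" %in% names(records)) {
    rna <- records$alphabet == "RNA"
    seq[rna] <- chartr("T", "U", seq[rna])
  }
  desc <- if ("desc" %in% names(records)) records$desc else ""
  header <- paste0("@", records$id, ifelse(nzchar(desc), paste0(" ", desc), ""))
  writeLines(rbind(header, seq, "+", records$qual), path)
  invisible(path)
}
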