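#' Bundled repeat-landscape summary for the Siberian salamander study
#'
#' The per-superfamily summary of the Ranodon sibiricus (~21 Gb genome)
#' repeat landscape bundled with the package: Wicker-style classification,
#' percent of the genome masked with repeat libraries including
#' (`pct_genome_incl`) and excluding (`pct_genome_excl`) unclassified
#' repeats, genomic contig counts after redundancy clustering at
#' 100/95/80 percent identity, contig length summaries, transcriptome
#' contig counts, and summed expression (TPM) in ovaries and testes.
#' `category` separates named superfamilies from retrotransposon/transposon
#' derivatives (TRIM, LARD, MITE) and order-level unknowns.
#'
#' @return Tibble with one row per repeat category.
#' @export
te_landscape_table <- function() {
  path <- system.file("extdata", "ranodon_repeat_landscape.tsv",
                      package = "tescape", mustWork = TRUE)
  readr::read_tsv(path, show_col_types = FALSE, na = "NA")
}

#' Bundled repeat-mining yield table
#'
#' Counts of repeat contigs (>= 100 bp, collapsed at 100 percent identity)
#' recovered by each mining approach in the Siberian salamander shotgun
#' data, with the grand total as the last row.
#'
#' @return Tibble `approach`, `software`, `n_contigs`.
#' @export
te_mining_table <- function() {
  path <- system.file("extdata", "ranodon_mining_methods.tsv",
                      package = "tescape", mustWork = TRUE)
  readr::read_tsv(path, show_col_types = FALSE)
}

#' Bundled gonad transcriptome annotation/expression summary
#'
#' Per annotation category (endogenous gene, autonomous/non-autonomous TE,
#' co-transcribed gene/TE, unannotated): contig counts and summed TPM in
#' each sex, with totals.
#'
#' @return Tibble `category`, `contigs_ovary`, `tpm_ovary`,
#'   `contigs_testis`, `tpm_testis`.
#' @export
transcriptome_summary_table <- function() {
  path <- system.file("extdata", "ranodon_transcriptome_summary.tsv",
                      package = "tescape", mustWork = TRUE)
  readr::read_tsv(path, show_col_types = FALSE)
}

#' Bundled shotgun sequencing summary
#'
#' Key constants of the genomic shotgun dataset: read counts before/after
#' filtering, total filtered bases, and the haploid genome size estimate.
#'
#' @return Named numeric vector.
#' @export
sequencing_summary <- function() {
  c(
    reads_raw = 11960858,
    reads_filtered = 11168678,
    filtered_bp = 2314096923,
    genome_size_gb = 21.3
  )
}

#' Bundled vertebrate genome-size panel
#'
#' The 15-species comparative panel (1 to ~130 Gb haploid genome sizes)
#' used for silencing-pathway-versus-genome-size analyses.
#'
#' @return Tibble `species`, `genome_size_gb`.
#' @export
species_panel_table <- function() {
  path <- system.file("extdata", "vertebrate_genome_sizes.tsv",
                      package = "tescape", mustWork = TRUE)
  readr::read_tsv(path, show_col_types = FALSE)
}
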