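#' TE-silencing pathway gene sets
#'
#' The curated gene sets used for silencing-pathway expression ratios:
#' 21 piRNA-processing genes, 14 genes of the NuRD-centred transcriptional
#' repression machinery recruited by PIWI or KRAB-ZFP proteins, the TRIM28
#' bridge, and 14 miRNA-processing genes that serve as the normalizing
#' pathway. Shipped as a YAML resource.
#'
#' @return Named list of character vectors: `pirna`, `repressive`,
#'   `trim28`, `mirna`.
#' @export
pathway_gene_sets <- function() {
  path <- system.file("extdata", "silencing_pathway_genes.yml",
                      package = "tescape", mustWork = TRUE)
  sets <- yaml::read_yaml(path)
  lapply(sets, toupper)
}

#' Pathway-to-miRNA expression ratios per individual
#'
#' For each individual (sample), sums TPM within each silencing gene set
#' and divides by the summed TPM of the miRNA-processing set:
#' `ratio_pirna`, `ratio_repressive`, `ratio_trim28`. In full mode,
#' genes missing from a species' table contribute 0 to the sums; in
#' conservative mode, all sets are first restricted to genes present in
#' every species of the panel (no missing genes allowed).
#'
#' @param expr Long tibble with columns `species`, `sample`, `sex`,
#'   `gene`, `tpm` (see [simulate_species_panel()]); a `genome_size_gb`
#'   column is carried through when present.
#' @param gene_sets Named list as from [pathway_gene_sets()].
#' @param conservative Restrict sets to panel-wide shared genes.
#' @return Tibble with one row per sample: `species`, `sample`, `sex`,
#'   `ratio_pirna`, `ratio_repressive`, `ratio_trim28`, and
#'   `genome_size_gb` when available. Individuals with a zero miRNA
#'   denominator get `NA` ratios and `denominator_zero = TRUE`.
#' @export
pathway_ratios <- function(expr, gene_sets = pathway_gene_sets(),
                           conservative = FALSE) {
  expr <- as_tibble(expr)
  need <- c("species", "sample", "sex", "gene", "tpm")
  if (!all(need %in% names(expr))) {
    abort(sprintf("`expr` needs columns: %s", paste(need, collapse = ", ")))
  }
  expr$gene <- toupper(expr$gene)
  sets <- gene_sets
  if (conservative) {
    n_species <- length(unique(expr$species))
    shared <- expr |>
      distinct(.data$species, .data$gene) |>
      count(.data$gene) |>
      filter(n == n_species) |>
      pull(.data$gene)
    sets <- lapply(sets, intersect, y = shared)
  }
  sum_set <- function(d, genes) sum(d$tpm[d$gene %in% genes])
  meta_cols <- intersect(c("species", "sample", "sex", "genome_size_gb"), names(expr))
  expr |>
    group_by(across(dplyr::all_of(meta_cols))) |>
    group_modify(function(d, key) {
      denom <- sum_set(d, sets$mirna)
      if (denom == 0) {
        return(tibble(ratio_pirna = NA_real_, ratio_repressive = NA_real_,
                      ratio_trim28 = NA_real_, denominator_zero = TRUE))
      }
      tibble(
        ratio_pirna = sum_set(d, sets$pirna) / denom,
        ratio_repressive = sum_set(d, sets$repressive) / denom,
        ratio_trim28 = sum_set(d, sets$trim28) / denom,
        denominator_zero = FALSE
      )
    }) |>
    ungroup()
}

#' Regression of a pathway ratio on genome size
#'
#' OLS of the per-species mean ratio on `log10(genome size in Gb)`; the
#' 95 percent confidence interval on the slope is the test for any
#' association between silencing-pathway investment and genome size.
#'
#' @param ratios Tibble from [pathway_ratios()] including a
#'   `genome_size_gb` column.
#' @param ratio Unquoted ratio column (default `ratio_pirna`).
#' @return Object of class `gsize_fit`; [glance()] gives `slope`,
#'   `slope_lo`, `slope_hi`, `r`, `p_value`, `n_species`. A panel with
#'   constant ratios returns slope 0 and `r = 0` by convention.
#' @export
ratio_vs_genome_size <- function(ratios, ratio = ratio_pirna) {
  if (!"genome_size_gb" %in% names(ratios)) {
    abort("`ratios` must carry a `genome_size_gb` column.")
  }
  per_species <- ratios |>
    mutate(.ratio = {{ ratio }}) |>
    filter(is.finite(.data$.ratio)) |>
    group_by(.data$species, .data$genome_size_gb) |>
    summarise(ratio = mean(.data$.ratio), .groups = "drop")
  if (nrow(per_species) < 4) abort("Need at least 4 species.")
  df <- tibble(x = log10(per_species$genome_size_gb), y = per_species$ratio)
  fit <- lm(y ~ x, data = df)
  structure(list(model = fit, data = df, species = per_species$species),
            class = "gsize_fit")
}

#' @export
print.gsize_fit <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "ratio ~ log10(genome size): slope = %.4f [%.4f, %.4f], R = %.3f, p = %.3g, n = %d species\n",
    g$slope, g$slope_lo, g$slope_hi, g$r, g$p_value, g$n_species))
  invisible(x)
}
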