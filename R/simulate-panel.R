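#' Simulate a cross-species pathway expression panel
#'
#' Emits per-individual TPM values for a configured gene set in each
#' species, log-normally distributed around species-level means:
#' `TPM = exp(log(mean) + rnorm(0, noise_sd))`. Genes listed in
#' `missing_genes` for a species are absent from that species' rows,
#' emulating incomplete annotations in de novo assemblies.
#'
#' @param species Tibble with columns `species` and `genome_size_gb`.
#' @param gene_means Tibble with columns `gene` and `mean_tpm`, or a named
#'   numeric vector. The same means are used for every species unless a
#'   `species` column is present.
#' @param noise_sd Standard deviation of the log-scale noise (0 gives the
#'   configured means exactly).
#' @param n_female,n_male Individuals per sex and species.
#' @param missing_genes Optional named list: `species -> character vector`
#'   of genes absent from that species' table.
#' @param seed Integer seed.
#' @return Tibble with columns `species`, `genome_size_gb`, `sample`,
#'   `sex`, `gene`, `tpm`.
#' @export
simulate_species_panel <- function(species, gene_means, noise_sd = 0.2,
                                   n_female = 2, n_male = 2,
                                   missing_genes = NULL, seed = 1) {
  if (is.numeric(gene_means)) {
    gene_means <- tibble(gene = names(gene_means), mean_tpm = unname(gene_means))
  }
  if (any(gene_means$mean_tpm <= 0)) abort("Gene mean TPM values must be positive.")
  withr::with_seed(seed, {
    sexes <- c(rep("female", n_female), rep("male", n_male))
    out <- list()
    for (i in seq_len(nrow(species))) {
      sp <- species$species[i]
      gm <- if ("species" %in% names(gene_means)) {
        gene_means[gene_means$species == sp, , drop = FALSE]
      } else gene_means
      drop <- missing_genes[[sp]] %||% character(0)
      gm <- gm[!gm$gene %in% drop, , drop = FALSE]
      gsz <- species$genome_size_gb[i]
      for (j in seq_along(sexes)) {
        tpm <- exp(log(gm$mean_tpm) + rnorm(nrow(gm), 0, noise_sd))
        out[[length(out) + 1L]] <- tibble(
          species = sp, genome_size_gb = gsz,
          sample = sprintf("%s_%s%d", sp, substr(sexes[j], 1, 1),
                           j - if (sexes[j] == "male") n_female else 0L),
          sex = sexes[j], gene = gm$gene, tpm = tpm
        )
      }
    }
    bind_rows(out)
  })
}
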