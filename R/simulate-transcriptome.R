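#' Simulate a gonadal transcriptome with sex-biased TE expression
#'
#' Builds random transcript sequences for a configured transcript table and
#' draws per-replicate read counts multinomially, with sampling probability
#' proportional to `expression * length` (longer transcripts attract more
#' reads at equal molar expression, the standard RNA-seq length effect that
#' TPM undoes). The ground truth records the expected TPM of every
#' transcript, which is `expression / sum(expression) * 1e6` per sex.
#'
#' @param transcripts Tibble with columns `id`, `length` (bp),
#'   `expr_female`, `expr_male` (relative molar expression, any positive
#'   scale) and optionally annotation columns (`superfamily`, `order`,
#'   `te_class`) that are carried through.
#' @param n_reads Reads per replicate library.
#' @param n_female,n_male Number of replicates per sex.
#' @param seed Integer seed.
#' @return A list with `transcripts` (input plus `seq`), `counts` (tibble:
#'   `transcript` + one column per sample), `samples` (tibble `sample`,
#'   `sex`), and `truth` (tibble of expected TPM per transcript and sex).
#' @export
simulate_transcriptome <- function(transcripts, n_reads = 1e6,
                                   n_female = 3, n_male = 4, seed = 1) {
  if (any(transcripts$length <= 0)) abort("Zero-length transcript in config.")
  if (any(transcripts$expr_female < 0 | transcripts$expr_male < 0)) {
    abort("Expression levels must be non-negative.")
  }
  withr::with_seed(seed, {
    tx <- transcripts
    tx$seq <- vapply(tx$length, function(w) random_dna(1, w), character(1))
    samples <- tibble(
      sample = c(sprintf("F%d", seq_len(n_female)), sprintf("M%d", seq_len(n_male))),
      sex = c(rep("female", n_female), rep("male", n_male))
    )
    counts <- tibble(transcript = tx$id)
    for (i in seq_len(nrow(samples))) {
      expr <- if (samples$sex[i] == "female") tx$expr_female else tx$expr_male
      p <- expr * tx$length
      if (sum(p) == 0) abort("All-zero expression configuration.")
      counts[[samples$sample[i]]] <- as.integer(rmultinom(1, n_reads, p / sum(p)))
    }
    truth <- bind_rows(
      tibble(transcript = tx$id, sex = "female",
             expected_tpm = tx$expr_female / sum(tx$expr_female) * 1e6),
      tibble(transcript = tx$id, sex = "male",
             expected_tpm = tx$expr_male / sum(tx$expr_male) * 1e6)
    )
    list(transcripts = tx, counts = counts, samples = samples, truth = truth)
  })
}
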