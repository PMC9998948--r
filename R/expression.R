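#' Transcripts-per-million normalization
#'
#' Standard TPM: per sample, `rate_i = count_i / length_i`,
#' `TPM_i = 1e6 * rate_i / sum(rate)`. Effective length is the transcript
#' length (no fragment-length correction). Every nonzero column sums to
#' 1e6.
#'
#' @param counts Tibble with a `transcript` id column and one numeric
#'   column per sample (non-negative counts).
#' @param lengths Named numeric vector of transcript lengths (> 0), or a
#'   tibble with `transcript` and `length` columns.
#' @return Tibble of the same shape in TPM units.
#' @examples
#' tpm(tibble::tibble(transcript = c("a", "b"), s1 = c(10, 20)),
#'     c(a = 1000, b = 500))
#' @export
tpm <- function(counts, lengths) {
  if (is.data.frame(lengths)) {
    lengths <- setNames(lengths$length, lengths$transcript)
  }
  if (!"transcript" %in% names(counts)) abort("`counts` needs a `transcript` column.")
  len <- unname(lengths[counts$transcript])
  if (anyNA(len)) abort("Missing lengths for some transcripts.")
  if (any(len <= 0)) abort("Transcript lengths must be positive.")
  out <- counts
  for (col in setdiff(names(counts), "transcript")) {
    v <- counts[[col]]
    if (any(v < 0)) abort(sprintf("Negative counts in column '%s'.", col))
    rate <- v / len
    tot <- sum(rate)
    if (tot == 0) {
      warn(sprintf("Column '%s' has no counts; TPM set to 0.", col))
      out[[col]] <- rate
    } else {
      out[[col]] <- 1e6 * rate / tot
    }
  }
  out
}

#' Per-superfamily expression by sex
#'
#' Averages each transcript's TPM across same-sex replicates, then sums
#' the averages within each TE superfamily — the standard aggregation for
#' superfamily-level expression.
#'
#' @param tpm_table TPM tibble (`transcript` + sample columns), e.g. from
#'   [tpm()].
#' @param annotation Transcript-to-superfamily map (tibble `transcript`
#'   or `id`, `superfamily`). Unannotated transcripts are dropped.
#' @param samples Tibble `sample`, `sex`; every sample column must appear
#'   here with a known sex.
#' @return Tibble `superfamily`, `sex`, `tpm` (summed mean TPM),
#'   `n_transcripts`.
#' @export
superfamily_expression <- function(tpm_table, annotation, samples) {
  samples <- as_tibble(samples)
  cols <- setdiff(names(tpm_table), "transcript")
  miss <- setdiff(cols, samples$sample)
  if (length(miss) || anyNA(samples$sex)) {
    abort(sprintf("Samples with unknown sex: %s",
                  paste(c(miss, samples$sample[is.na(samples$sex)]), collapse = ", ")))
  }
  ann <- .norm_tx_annotation(annotation)
  long <- tidyr::pivot_longer(tpm_table, -"transcript",
                              names_to = "sample", values_to = "tpm") |>
    left_join(samples, by = "sample") |>
    inner_join(ann, by = "transcript")
  long |>
    group_by(.data$superfamily, .data$sex, .data$transcript) |>
    summarise(mean_tpm = mean(.data$tpm), .groups = "drop") |>
    group_by(.data$superfamily, .data$sex) |>
    summarise(tpm = sum(.data$mean_tpm), n_transcripts = n(), .groups = "drop")
}

#' Log-log regression of expression on genomic abundance
#'
#' Ordinary least squares of `log10(y)` on `log10(x)`, the standard test
#' for whether more abundant TE superfamilies are also more expressed.
#' Non-positive values in either variable are excluded with a warning.
#'
#' @param data Tibble containing the two variables.
#' @param abundance,expression Unquoted column names of the genomic
#'   abundance and the expression measure.
#' @return Object of class `loglog_fit` wrapping the `lm`; use [tidy()]
#'   for coefficients and [glance()] for `r`, `slope` (with 95 percent
#'   CI), `intercept`, `p_value`, `n`.
#' @export
abundance_expression_regression <- function(data, abundance, expression) {
  x <- dplyr::pull(data, {{ abundance }})
  y <- dplyr::pull(data, {{ expression }})
  ok <- is.finite(x) & is.finite(y) & x > 0 & y > 0
  if (sum(!ok) > 0) {
    warn(sprintf("Excluded %d observation(s) with non-positive or missing values.",
                 sum(!ok)))
  }
  if (sum(ok) < 3) abort("Need at least 3 positive (x, y) pairs.")
  df <- tibble(lx = log10(x[ok]), ly = log10(y[ok]))
  fit <- lm(ly ~ lx, data = df)
  structure(list(model = fit, data = df, n_dropped = sum(!ok)),
            class = "loglog_fit")
}

#' @export
print.loglog_fit <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("log-log OLS: slope = %.3f [%.3f, %.3f], R = %.3f, p = %.3g, n = %d\n",
              g$slope, g$slope_lo, g$slope_hi, g$r, g$p_value, g$n))
  invisible(x)
}

#' Welch t-tests for sex-biased superfamily expression
#'
#' Per superfamily, compares per-transcript mean TPM between the sexes
#' with Welch's unequal-variance t-test on `log10(TPM + 1)` (or the raw
#' values). Superfamilies represented by fewer than `min_transcripts`
#' transcripts are skipped, mirroring the usual
#' "at least 10 transcripts" rule.
#'
#' @param data Tibble with columns `transcript`, `superfamily`, `sex`,
#'   `mean_tpm` (one row per transcript and sex).
#' @param min_transcripts Minimum transcripts per superfamily.
#' @param transform `"log10p1"` (default) or `"none"`.
#' @return Tibble `superfamily`, `n_transcripts`, `t`, `df`, `p_value`,
#'   `mean_female`, `mean_male` (group means on the transformed scale).
#' @export
sex_bias_ttest <- function(data, min_transcripts = 10,
                           transform = c("log10p1", "none")) {
  transform <- match.arg(transform)
  f <- if (transform == "log10p1") function(v) log10(v + 1) else identity
  data |>
    group_by(.data$superfamily) |>
    group_modify(function(d, key) {
      xf <- f(d$mean_tpm[d$sex == "female"])
      xm <- f(d$mean_tpm[d$sex == "male"])
      n_tx <- length(unique(d$transcript))
      if (n_tx < min_transcripts || length(xf) < 2 || length(xm) < 2) {
        return(tibble(n_transcripts = n_tx, t = NA_real_, df = NA_real_,
                      p_value = NA_real_, mean_female = mean(xf),
                      mean_male = mean(xm), skipped = TRUE))
      }
      if (sd(xf) == 0 && sd(xm) == 0) {
        eq <- isTRUE(all.equal(mean(xf), mean(xm)))
        return(tibble(n_transcripts = n_tx,
                      t = if (eq) 0 else NA_real_,
                      df = NA_real_,
                      p_value = if (eq) 1 else NA_real_,
                      mean_female = mean(xf), mean_male = mean(xm),
                      skipped = FALSE))
      }
      tt <- t.test(xm, xf) # Welch by default
      tibble(n_transcripts = n_tx, t = unname(tt$statistic),
             df = unname(tt$parameter), p_value = tt$p.value,
             mean_female = mean(xf), mean_male = mean(xm), skipped = FALSE)
    }) |>
    ungroup()
}
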