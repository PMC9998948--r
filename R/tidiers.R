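# broom-style tidiers for the package's fitted objects.

.lm_glance_core <- function(model, df) {
  co <- coef(model)
  ci <- suppressWarnings(confint(model))
  r <- suppressWarnings(stats::cor(df[[1]], df[[2]]))
  if (is.na(r)) r <- 0 # constant response: no correlation by convention
  sm <- suppressWarnings(summary(model))
  p <- if (nrow(sm$coefficients) >= 2) sm$coefficients[2, 4] else NA_real_
  list(slope = unname(co[2]), slope_lo = ci[2, 1], slope_hi = ci[2, 2],
       intercept = unname(co[1]), r = r, r_squared = sm$r.squared, p_value = p)
}

#' @rdname abundance_expression_regression
#' @param x A `loglog_fit` object.
#' @param ... Unused.
#' @method tidy loglog_fit
#' @export
tidy.loglog_fit <- function(x, ...) {
  sm <- summary(x$model)$coefficients
  tibble(
    term = c("intercept", "log10_abundance"),
    estimate = sm[, 1], std_error = sm[, 2],
    statistic = sm[, 3], p_value = sm[, 4]
  )
}

#' @rdname abundance_expression_regression
#' @method glance loglog_fit
#' @export
glance.loglog_fit <- function(x, ...) {
  g <- .lm_glance_core(x$model, x$data[, c("lx", "ly")])
  tibble(
    r = g$r, r_squared = g$r_squared, slope = g$slope,
    slope_lo = g$slope_lo, slope_hi = g$slope_hi,
    intercept = g$intercept, p_value = g$p_value,
    n = nrow(x$data), n_dropped = x$n_dropped
  )
}

#' @rdname ratio_vs_genome_size
#' @param x A `gsize_fit` object.
#' @param ... Unused.
#' @method tidy gsize_fit
#' @export
tidy.gsize_fit <- function(x, ...) {
  sm <- summary(x$model)$coefficients
  tibble(
    term = c("intercept", "log10_genome_size_gb"),
    estimate = sm[, 1], std_error = sm[, 2],
    statistic = sm[, 3], p_value = sm[, 4]
  )
}

#' @rdname ratio_vs_genome_size
#' @method glance gsize_fit
#' @export
glance.gsize_fit <- function(x, ...) {
  g <- .lm_glance_core(x$model, x$data[, c("x", "y")])
  tibble(
    slope = g$slope, slope_lo = g$slope_lo, slope_hi = g$slope_hi,
    r = g$r, p_value = g$p_value, n_species = nrow(x$data)
  )
}

#' @rdname pingpong_signature
#' @param x A `pingpong_signature` object.
#' @param ... Unused.
#' @method tidy pingpong_signature
#' @export
tidy.pingpong_signature <- function(x, ...) {
  as_tibble(x$distribution)
}

#' @rdname pingpong_signature
#' @method glance pingpong_signature
#' @export
glance.pingpong_signature <- function(x, ...) {
  tot <- attr(x$distribution, "total_pairs")
  tibble(
    z = x$z, focal = x$focal, total_pairs = tot,
    modal_overlap = if (tot > 0) x$distribution$overlap[which.max(x$distribution$n_pairs)]
                    else NA_integer_,
    n_sense = x$n_sense, n_antisense = x$n_antisense,
    n_transcripts = length(x$transcripts_kept)
  )
}
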