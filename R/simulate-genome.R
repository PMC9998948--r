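#' Simulate a low-coverage shotgun read set over a planted repeat landscape
#'
#' Generates a repeat library of random consensus sequences labelled with a
#' Wicker-style class/order/superfamily hierarchy, and a pool of shotgun
#' reads drawn from mutated copies of those consensuses plus random
#' non-repeat background. Per-superfamily read counts are allocated
#' deterministically from the configured genome proportions
#' (`round(proportion * n_reads)`), so the planted landscape is exactly the
#' configured one; the stochastic parts are read positions, strands and the
#' per-read divergence draws.
#'
#' The mutation model is substitution-only: a read at divergence `d` carries
#' `Binomial(read_length, d/100)` substitutions at distinct positions, so
#' downstream Hamming divergence is an unbiased estimate of `d`.
#'
#' @param superfamilies Tibble with one row per repeat category and columns
#'   `superfamily`, `order`, `te_class`, `proportion` (of the genome),
#'   `consensus_length` (bp), `div_model` (`"point"`, `"exponential"`,
#'   `"normal"` or `"mixture"`), `div_mean` (percent), and optionally
#'   `div_sd` (percent, for `"normal"`), `div_means`/`div_sds`/`div_weights`
#'   (list-columns, for `"mixture"`). Use `superfamily = "unknown"` rows for
#'   unclassified repeats.
#' @param read_length Read length in bp.
#' @param total_bp Total sequencing effort in bp; `n_reads =
#'   round(total_bp / read_length)`.
#' @param seed Integer seed; identical seeds give identical output.
#' @return A list with elements `reads` (tibble `id`, `seq`, `desc`),
#'   `library` (tibble `id`, `seq`, `desc`, `te_class`, `order`,
#'   `superfamily`), and `truth` (list with `reads`: per-read source,
#'   strand, drawn and realized divergence; `proportions`: the planted
#'   per-category genome proportions).
#' @examples
#' cfg <- tibble::tibble(
#'   superfamily = c("Gypsy", "L1"), order = c("LTR", "LINE"),
#'   te_class = "I", proportion = c(0.5, 0.3), consensus_length = 2000,
#'   div_model = "exponential", div_mean = 4
#' )
#' sim <- simulate_repeat_genome(cfg, read_length = 100, total_bp = 5e4, seed = 1)
#' @export
simulate_repeat_genome <- function(superfamilies, read_length = 200,
                                   total_bp = 4e6, seed = 1) {
  if (sum(superfamilies$proportion) > 1 + 1e-9) {
    abort("Configured proportions sum to more than 1.")
  }
  if (any(superfamilies$consensus_length < read_length)) {
    abort("Each consensus must be at least one read length long.")
  }
  if (read_length <= 0 || total_bp <= 0) abort("Lengths must be positive.")
  withr::with_seed(seed, {
    n_reads <- round(total_bp / read_length)
    cons <- superfamilies
    cons$id <- sprintf("cons_%02d_%s", seq_len(nrow(cons)), cons$superfamily)
    cons$seq <- vapply(cons$consensus_length, function(w) random_dna(1, w), character(1))

    read_rows <- list()
    truth_rows <- list()
    counter <- 0L
    for (i in seq_len(nrow(cons))) {
      n_i <- round(cons$proportion[i] * n_reads)
      if (n_i == 0) next
      L <- cons$consensus_length[i]
      starts <- sample.int(L - read_length + 1L, n_i, replace = TRUE)
      frag <- substring(cons$seq[i], starts, starts + read_length - 1L)
      d <- .draw_divergence(cons[i, ], n_i)
      n_sub <- rbinom(n_i, read_length, pmin(d, 100) / 100)
      mut <- vapply(seq_len(n_i), function(j) plant_substitutions(frag[j], n_sub[j]),
                    character(1))
      minus <- runif(n_i) < 0.5
      mut[minus] <- revcomp_fast(mut[minus])
      ids <- sprintf("read_%06d", counter + seq_len(n_i))
      counter <- counter + n_i
      read_rows[[i]] <- tibble(id = ids, seq = mut, desc = "")
      truth_rows[[i]] <- tibble(
        read_id = ids, source = cons$id[i], superfamily = cons$superfamily[i],
        start = starts - 1L, strand = ifelse(minus, "-", "+"),
        div_drawn = d, div_realized = 100 * n_sub / read_length
      )
    }
    n_bg <- n_reads - sum(vapply(truth_rows, nrow, integer(1)))
    if (n_bg > 0) {
      ids <- sprintf("read_%06d", counter + seq_len(n_bg))
      read_rows[[length(read_rows) + 1L]] <- tibble(
        id = ids, seq = random_dna(n_bg, read_length), desc = ""
      )
      truth_rows[[length(truth_rows) + 1L]] <- tibble(
        read_id = ids, source = "background", superfamily = "background",
        start = NA_integer_, strand = NA_character_,
        div_drawn = NA_real_, div_realized = NA_real_
      )
    }
    list(
      reads = bind_rows(read_rows),
      library = tibble(
        id = cons$id, seq = cons$seq, desc = "",
        te_class = cons$te_class, order = cons$order, superfamily = cons$superfamily
      ),
      truth = list(
        reads = bind_rows(truth_rows),
        proportions = tibble(superfamily = cons$superfamily,
                             proportion = cons$proportion)
      )
    )
  })
}

.draw_divergence <- function(row, n) {
  switch(row$div_model,
    point = rep(row$div_mean, n),
    exponential = rexp(n, rate = 1 / row$div_mean),
    normal = pmax(0, rnorm(n, row$div_mean, row$div_sd)),
    mixture = {
      means <- row$div_means[[1]]; sds <- row$div_sds[[1]]; w <- row$div_weights[[1]]
      comp <- sample.int(length(means), n, replace = TRUE, prob = w)
      pmax(0, rnorm(n, means[comp], sds[comp]))
    },
    abort(sprintf("Unknown divergence model '%s'.", row$div_model))
  )
}
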