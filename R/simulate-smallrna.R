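#' Synthetic miRNA reference set
#'
#' A bundled stand-in for a miRNA catalogue: `n` distinct random mature
#' miRNA sequences of the given width. Annotation against it is exact-match,
#' so tests can plant known miRNA reads.
#'
#' @param n Number of reference entries.
#' @param width Mature miRNA length (nt).
#' @param seed Integer seed.
#' @return Tibble with columns `id`, `seq`.
#' @export
synthetic_mirna_reference <- function(n = 50, width = 22, seed = 42) {
  withr::with_seed(seed, {
    seqs <- unique(random_dna(n * 2, width))[seq_len(n)]
    tibble(id = sprintf("mir_%03d", seq_len(n)), seq = seqs)
  })
}

#' Synthetic contaminant reference (rRNA and mitochondrial stand-ins)
#'
#' @param seed Integer seed.
#' @param widths Named widths (bp) of the contaminant sequences.
#' @return Tibble with columns `id`, `seq`.
#' @export
synthetic_contaminant_reference <- function(seed = 43,
                                            widths = c(rRNA = 1500, mito = 2000)) {
  withr::with_seed(seed, {
    tibble(id = names(widths), seq = vapply(widths, function(w) random_dna(1, w),
                                            character(1)))
  })
}

#' Simulate a gonadal small-RNA library with a planted ping-pong signature
#'
#' Emulates the composition of a germline small-RNA pool: a piRNA
#' population with a length mode near 29 nt and a tunable 5'-U bias,
#' sense/antisense piRNA pairs with an exact 10-nt 5'-to-5' overlap planted
#' at a tunable fraction, a miRNA population (which creates the secondary
#' ~22-nt peak seen in ovaries), and rRNA/mitochondrial contaminant
#' fragments.
#'
#' Antisense ("primary") piRNAs are reverse-complement fragments of the TE
#' transcripts; with probability `u_bias` the first nucleotide is forced to
#' U (T internally), otherwise it is drawn from A/C/G, so the planted 1U
#' fraction is exactly `u_bias`. With probability `pingpong_rho` an
#' antisense read at 5' transcript coordinate `a` emits a sense partner
#' whose 5' end sits at `a - 9`, producing a 10-nt 5'-5' overlap exactly.
#' Sense partners and background sense piRNAs are exact transcript
#' substrings, so they map at 0 mismatches.
#'
#' @param transcripts Tibble of TE transcripts (`id`, `seq`, optional
#'   `weight` for sampling; defaults to sequence length).
#' @param n_reads Total reads to emit.
#' @param pirna_frac,mirna_frac,contaminant_frac Pool composition; must sum
#'   to 1.
#' @param len_mode,len_sd piRNA length distribution: lengths are
#'   `round(rnorm(len_mode, len_sd))` clamped to 25-30 nt.
#' @param u_bias Probability that a primary piRNA starts with U.
#' @param pingpong_rho Fraction of antisense piRNAs with a planted
#'   ping-pong sense partner.
#' @param sense_antisense_ratio Target ratio of sense to antisense piRNA
#'   read counts.
#' @param mirna_ref,contaminant_ref Reference tibbles (`id`, `seq`);
#'   defaults are the bundled synthetic references.
#' @param seed Integer seed.
#' @return List with `reads` (tibble `id`, `seq`, `qual`, `desc`) and
#'   `truth` (tibble `read_id`, `category`, `transcript`, `pos5`, `length`;
#'   categories partition the reads). The planted `u_bias` and
#'   `pingpong_rho` are attached as attributes of `truth`.
#' @export
simulate_small_rna <- function(transcripts, n_reads = 50000,
                               pirna_frac = 0.8, mirna_frac = 0.15,
                               contaminant_frac = 0.05,
                               len_mode = 29, len_sd = 1,
                               u_bias = 0.9, pingpong_rho = 0.3,
                               sense_antisense_ratio = 1,
                               mirna_ref = NULL, contaminant_ref = NULL,
                               seed = 1) {
  if (nrow(transcripts) == 0) abort("Empty transcript set.")
  fr <- c(pirna_frac, mirna_frac, contaminant_frac)
  if (abs(sum(fr) - 1) > 1e-8) abort("Pool fractions must sum to 1.")
  check_seq_column(transcripts, what = "transcript")
  mirna_ref <- mirna_ref %||% synthetic_mirna_reference()
  contaminant_ref <- contaminant_ref %||% synthetic_contaminant_reference()

  withr::with_seed(seed, {
    tlen <- nchar(transcripts$seq)
    wts <- if ("weight" %in% names(transcripts)) transcripts$weight else tlen
    if (any(tlen < 60)) abort("Transcripts must be at least 60 bp for piRNA simulation.")

    n_pi <- round(n_reads * pirna_frac)
    n_mi <- round(n_reads * mirna_frac)
    n_ct <- n_reads - n_pi - n_mi
    n_anti <- round(n_pi / (1 + sense_antisense_ratio))

    draw_len <- function(n) pmin(30L, pmax(25L, as.integer(round(rnorm(n, len_mode, len_sd)))))

    # primary antisense piRNAs; positions leave room for a sense partner
    ti <- sample.int(nrow(transcripts), n_anti, replace = TRUE, prob = wts)
    w <- draw_len(n_anti)
    p <- floor(runif(n_anti) * (tlen[ti] - w - 21)) # 0-based window start
    a <- p + w - 1L                                  # antisense 5' coordinate
    anti_seq <- revcomp_fast(substring(transcripts$seq[ti], p + 1L, p + w))
    forced <- runif(n_anti) < u_bias
    first <- ifelse(forced, "T", sample(c("A", "C", "G"), n_anti, replace = TRUE))
    anti_seq <- paste0(first, substring(anti_seq, 2))

    # ping-pong sense partners: 5' at a - 9 => 10-nt 5'-5' overlap
    has_partner <- runif(n_anti) < pingpong_rho
    pp_i <- which(has_partner)
    w2 <- draw_len(length(pp_i))
    s2 <- a[pp_i] - 9L
    pp_seq <- substring(transcripts$seq[ti[pp_i]], s2 + 1L, s2 + w2)

    # background sense piRNAs: uniform exact substrings
    n_sense_bg <- max(0L, n_pi - n_anti - length(pp_i))
    ti_s <- sample.int(nrow(transcripts), n_sense_bg, replace = TRUE, prob = wts)
    w_s <- draw_len(n_sense_bg)
    p_s <- floor(runif(n_sense_bg) * (tlen[ti_s] - w_s + 1))
    sense_seq <- substring(transcripts$seq[ti_s], p_s + 1L, p_s + w_s)

    # miRNAs (the ~22-nt secondary peak) and contaminant fragments
    mi_i <- sample.int(nrow(mirna_ref), n_mi, replace = TRUE)
    mi_seq <- mirna_ref$seq[mi_i]
    ct_i <- sample.int(nrow(contaminant_ref), n_ct, replace = TRUE)
    ct_w <- sample(18:40, n_ct, replace = TRUE)
    ct_len <- nchar(contaminant_ref$seq)[ct_i]
    ct_p <- floor(runif(n_ct) * (ct_len - ct_w + 1))
    ct_seq <- substring(contaminant_ref$seq[ct_i], ct_p + 1L, ct_p + ct_w)

    seqs <- c(anti_seq, pp_seq, sense_seq, mi_seq, ct_seq)
    n_tot <- length(seqs)
    ids <- sprintf("sr_%06d", seq_len(n_tot))
    category <- rep(c("pirna_antisense", "pingpong_partner", "pirna_sense",
                      "mirna", "contaminant"),
                    c(n_anti, length(pp_i), n_sense_bg, n_mi, n_ct))
    truth <- tibble(
      read_id = ids,
      category = category,
      transcript = c(transcripts$id[ti], transcripts$id[ti[pp_i]],
                     transcripts$id[ti_s], rep(NA_character_, n_mi + n_ct)),
      pos5 = c(a, s2, p_s, rep(NA_integer_, n_mi + n_ct)),
      length = nchar(seqs)
    )
    attr(truth, "u_bias") <- u_bias
    attr(truth, "pingpong_rho") <- pingpong_rho
    list(
      reads = tibble(id = ids, seq = seqs, qual = strrep("I", nchar(seqs)), desc = ""),
      truth = truth
    )
  })
}
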