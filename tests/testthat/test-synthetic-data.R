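genome_cfg <- function(...) {
  tibble::tibble(
    superfamily = c("Gypsy", "L1"), order = c("LTR", "LINE"), te_class = "I",
    proportion = c(0.5, 0.3), consensus_length = 1000,
    div_model = "exponential", div_mean = 4, ...
  )
}

test_that("zero-divergence genome reads are exact consensus substrings", {
  cfg <- genome_cfg()
  cfg$div_model <- "point"
  cfg$div_mean <- 0
  sim <- simulate_repeat_genome(cfg, read_length = 100, total_bp = 200 * 100, seed = 5)
  tr <- sim$truth$reads
  te <- tr[tr$superfamily != "background", ]
  expect_true(all(te$div_realized == 0))
  # every TE read matches its source consensus verbatim (either strand)
  lib <- setNames(sim$library$seq, sim$library$id)
  reads <- setNames(sim$reads$seq, sim$reads$id)
  for (i in sample(nrow(te), 25)) {
    r <- reads[[te$read_id[i]]]
    cons <- lib[[te$source[i]]]
    expect_true(grepl(r, cons, fixed = TRUE) || grepl(rc_chr(r), cons, fixed = TRUE))
  }
})

test_that("genome simulation is deterministic and validates proportions", {
  cfg <- genome_cfg()
  a <- simulate_repeat_genome(cfg, read_length = 100, total_bp = 2e4, seed = 7)
  b <- simulate_repeat_genome(cfg, read_length = 100, total_bp = 2e4, seed = 7)
  expect_identical(a$reads, b$reads)
  expect_identical(a$library, b$library)
  cfg_bad <- genome_cfg()
  cfg_bad$proportion <- c(0.8, 0.4)
  expect_error(simulate_repeat_genome(cfg_bad, seed = 1), "more than 1")
})

test_that("planted divergence draws follow the configured distribution", {
  cfg <- tibble::tibble(
    superfamily = "Gypsy", order = "LTR", te_class = "I", proportion = 1,
    consensus_length = 2000, div_model = "exponential", div_mean = 4
  )
  sim <- simulate_repeat_genome(cfg, read_length = 100, total_bp = 1e4 * 100, seed = 13)
  d <- sim$truth$reads$div_drawn
  expect_length(d, 10000)
  ks <- ks.test(d, stats::pexp, rate = 1 / 4)
  expect_gt(ks$p.value, 0.01)
})

test_that("transcriptome counts follow the planted multinomial", {
  tx1 <- tibble::tibble(id = "t1", length = 500, expr_female = 1, expr_male = 1)
  sim <- simulate_transcriptome(tx1, n_reads = 1000, n_female = 1, n_male = 0, seed = 1)
  expect_equal(sim$counts$F1, 1000L)

  tx4 <- tibble::tibble(id = paste0("t", 1:4), length = 500,
                        expr_female = 1, expr_male = 1)
  sim <- simulate_transcriptome(tx4, n_reads = 1e6, n_female = 1, n_male = 0, seed = 2)
  sd_bin <- sqrt(1e6 * 0.25 * 0.75)
  expect_true(all(abs(sim$counts$F1 - 250000) < 3 * sd_bin))

  expect_error(simulate_transcriptome(
    tibble::tibble(id = "t", length = 0, expr_female = 1, expr_male = 1)
  ), "Zero-length")
})

test_that("a planted male expression multiplier is recovered in TPM", {
  tx <- tibble::tibble(
    id = paste0("te", 1:30), length = 600, superfamily = "Gypsy",
    expr_female = 1, expr_male = 3
  )
  bg <- tibble::tibble(
    id = paste0("g", 1:70), length = 600, superfamily = NA_character_,
    expr_female = 100, expr_male = 100
  )
  sim <- simulate_transcriptome(dplyr::bind_rows(tx, bg), n_reads = 5e5,
                                n_female = 3, n_male = 3, seed = 3)
  tt <- tpm(sim$counts, setNames(rep(600, 100), sim$transcripts$id))
  sf <- superfamily_expression(
    tt, tibble::tibble(transcript = tx$id, superfamily = "Gypsy"), sim$samples
  )
  ratio <- sf$tpm[sf$sex == "male"] / sf$tpm[sf$sex == "female"]
  # TEs are a small library share, so the TPM ratio tracks the planted 3x
  # multiplier closely (expected 2.97 after renormalization)
  expect_gt(ratio, 2.8)
  expect_lt(ratio, 3.2)
})

test_that("small-RNA truth categories partition the reads", {
  tx <- rand_tx(5, 400)
  sim <- simulate_small_rna(tx, n_reads = 2000, seed = 4)
  expect_equal(nrow(sim$reads), nrow(sim$truth))
  expect_setequal(sim$reads$id, sim$truth$read_id)
  expect_equal(sum(table(sim$truth$category)), nrow(sim$reads))
  a <- simulate_small_rna(tx, n_reads = 2000, seed = 4)
  expect_identical(a$reads, sim$reads)
  expect_error(simulate_small_rna(tx[0, ], n_reads = 10), "Empty transcript")
})

test_that("forced ping-pong pairs overlap by exactly 10 nt", {
  tx <- rand_tx(4, 500)
  sim <- simulate_small_rna(tx, n_reads = 4000, pirna_frac = 1, mirna_frac = 0,
                            contaminant_frac = 0, pingpong_rho = 1, seed = 5)
  tr <- sim$truth
  anti <- tr[tr$category == "pirna_antisense", ]
  part <- tr[tr$category == "pingpong_partner", ]
  # rho = 1: one partner per antisense read, in emission order
  expect_equal(nrow(part), nrow(anti))
  expect_true(all(anti$pos5 - part$pos5 + 1 == 10))
})

test_that("the planted 5'-U bias is exact at u = 1 and recovered at u = 0.9", {
  tx <- rand_tx(4, 500)
  sim1 <- simulate_small_rna(tx, n_reads = 3000, pirna_frac = 1, mirna_frac = 0,
                             contaminant_frac = 0, u_bias = 1, seed = 6)
  anti <- sim1$truth$read_id[sim1$truth$category == "pirna_antisense"]
  first <- substr(sim1$reads$seq[sim1$reads$id %in% anti], 1, 1)
  expect_true(all(first == "T"))

  sim9 <- simulate_small_rna(tx, n_reads = 20000, pirna_frac = 1, mirna_frac = 0,
                             contaminant_frac = 0, u_bias = 0.9, seed = 7)
  anti <- sim9$truth$read_id[sim9$truth$category == "pirna_antisense"]
  u_hat <- mean(substr(sim9$reads$seq[sim9$reads$id %in% anti], 1, 1) == "T")
  n <- length(anti)
  expect_lt(abs(u_hat - 0.9), 3 * sqrt(0.9 * 0.1 / n))
})

test_that("species panel: zero noise reproduces configured ratios exactly", {
  sp <- tibble::tibble(species = c("a", "b", "c", "d"),
                       genome_size_gb = c(1, 5, 20, 80))
  gs <- pathway_gene_sets()
  gm <- setNames(rep(10, length(unlist(gs))), unlist(gs))
  pan <- simulate_species_panel(sp, gm, noise_sd = 0, seed = 1)
  pr <- pathway_ratios(pan)
  expect_equal(pr$ratio_pirna, rep(21 / 14, nrow(pr)))
  expect_equal(pr$ratio_trim28, rep(1 / 14, nrow(pr)))
})

test_that("species panel drops configured missing genes", {
  sp <- tibble::tibble(species = c("a", "b"), genome_size_gb = c(1, 10))
  gm <- c(PIWIL1 = 5, DICER1 = 5, TDRD1 = 5)
  pan <- simulate_species_panel(sp, gm, noise_sd = 0, seed = 1,
                                missing_genes = list(a = c("TDRD1")))
  expect_false("TDRD1" %in% pan$gene[pan$species == "a"])
  expect_true("TDRD1" %in% pan$gene[pan$species == "b"])
})
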