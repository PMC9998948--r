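test_that("repeat_library applies the 100 bp length filter", {
  lib <- tibble::tibble(id = c("a", "b"), seq = c(strrep("A", 99), strrep("C", 100)))
  expect_warning(out <- repeat_library(lib), "rejected 1")
  expect_equal(out$id, "b")
  expect_equal(attr(out, "n_rejected"), 1L)
})

test_that("clustering merges identical sequences and respects the threshold", {
  s <- paste(rep(c("A", "C", "G", "T"), 25), collapse = "") # 100 bp
  lib <- tibble::tibble(id = c("b", "a"), seq = c(s, s))
  cs <- cluster_contigs(lib, identity = 0.95)
  expect_equal(length(unique(cs$cluster)), 1)
  expect_equal(unique(cs$representative), "a") # id tie-break at equal length

  # exactly 10 mismatches in 100 bp: identity 0.90
  s2 <- strsplit(s, "")[[1]]
  pos <- seq(5, 95, by = 10)
  s2[pos] <- ifelse(s2[pos] == "A", "C", "A")
  lib2 <- tibble::tibble(id = c("x", "y"), seq = c(s, paste(s2, collapse = "")))
  expect_equal(max(cluster_contigs(lib2, identity = 0.95)$cluster), 2)
  expect_equal(max(cluster_contigs(lib2, identity = 0.80)$cluster), 1)
})

test_that("clustering at identity 1 recovers exact-duplicate classes", {
  withr::with_seed(8, {
    base <- rand_dna(12, 120)
    seqs <- sample(c(base, base[sample(12, 18, replace = TRUE)])) # 30 with dups
  })
  lib <- tibble::tibble(id = sprintf("c%02d", seq_along(seqs)), seq = seqs)
  cs <- cluster_contigs(lib, identity = 1)
  got <- split(cs$id, cs$cluster)
  oracle <- brute_duplicate_classes(seqs)
  # same partition of ids, compared as sets of sets
  got_sets <- sort(vapply(got, function(g) paste(sort(g), collapse = ","), ""))
  oracle_sets <- sort(vapply(oracle, function(ix) {
    paste(sort(lib$id[ix]), collapse = ",")
  }, ""))
  expect_equal(unname(got_sets), unname(oracle_sets))
  # representatives are members of their own cluster and maximal in length
  len <- setNames(nchar(lib$seq), lib$id)
  expect_true(all(len[cs$representative] >= len[cs$id]))
  expect_true(all(cs$is_representative[match(unique(cs$representative), cs$id)]))
})

test_that("masking recovers exact and mutated substrings with Hamming divergence", {
  withr::with_seed(9, cons <- rand_dna(1, 500))
  lib <- tibble::tibble(id = "cons1", seq = cons)
  read_exact <- substring(cons, 101, 200)
  reads <- tibble::tibble(id = "r1", seq = read_exact)
  h <- mask_reads(reads, lib)
  expect_equal(nrow(h), 1)
  expect_equal(h$pct_div, 0)
  expect_equal(h$cons_start, 100L)
  expect_equal(h$cons_end, 200L)
  expect_equal(h$read_start, 0L)

  ch <- strsplit(read_exact, "")[[1]]
  ch[c(10, 60)] <- vapply(ch[c(10, 60)], function(b) setdiff(c("A", "C", "G", "T"), b)[1], "")
  h2 <- mask_reads(tibble::tibble(id = "r2", seq = paste(ch, collapse = "")), lib)
  expect_equal(h2$pct_div, 2.0)

  # a minus-strand read is found and reported on forward consensus coords
  h3 <- mask_reads(tibble::tibble(id = "r3", seq = rc_chr(read_exact)), lib)
  expect_equal(h3$strand, "-")
  expect_equal(h3$cons_start, 100L)
  expect_equal(h3$cons_end, 200L)
})

test_that("genome proportions merge intervals and validate bounds", {
  hits <- tibble::tibble(
    read_id = "r1", consensus_id = "c1",
    read_start = 0L, read_end = 50L, cons_start = 0L, cons_end = 50L,
    strand = "+", pct_div = 0, score = 50
  )
  ann <- tibble::tibble(consensus_id = "c1", superfamily = "Gypsy")
  gp <- genome_proportions(hits, ann, total_bp = 100)
  expect_equal(gp$pct_genome, 50)

  hits2 <- dplyr::bind_rows(hits, dplyr::mutate(hits, read_start = 5L, read_end = 15L))
  hits2$read_end[1] <- 10L
  gp2 <- genome_proportions(hits2, ann, total_bp = 100)
  expect_equal(gp2$masked_bp, 15L)

  expect_error(
    genome_proportions(hits, ann, total_bp = 100, read_lengths = c(r1 = 40)),
    "beyond"
  )
})

test_that("diversity indices match closed forms and degenerate limits", {
  one <- diversity_indices(c(A = 100))
  expect_equal(one$gini_simpson, 0)
  expect_equal(one$shannon_h, 0)

  two <- diversity_indices(c(A = 50, B = 50))
  expect_equal(two$shannon_h, log(2))
  expect_equal(two$simpson_d, 2 * (50 * 49) / (100 * 99))
  expect_equal(two$gini_simpson, 1 - 0.49494949494949, tolerance = 1e-10)

  expect_error(diversity_indices(c(A = 1)), "at least 2")
  expect_error(diversity_indices(c(A = -1, B = 3)), "non-negative")
})

test_that("diversity is invariant to rescaling abundances", {
  x <- c(A = 12, B = 30, C = 5, D = 53)
  h1 <- diversity_indices(x)$shannon_h
  h2 <- diversity_indices(x * 1000)$shannon_h
  expect_equal(h1, h2)
  g_small <- diversity_indices(x * 1e5)$gini_simpson # N = 1e7
  g_limit <- 1 - sum((x / sum(x))^2)
  expect_equal(g_small, g_limit, tolerance = 1e-4)
  # H <= ln K with equality iff proportions are equal
  expect_lt(h1, log(4))
  expect_equal(diversity_indices(c(A = 7, B = 7, C = 7))$shannon_h, log(3))
})

test_that("divergence histograms bin by least-divergent hit", {
  hits <- tibble::tibble(
    read_id = c("r1", "r2", "r3", "r4"), consensus_id = "c1",
    read_start = 0L, read_end = 10L, cons_start = 0L, cons_end = 10L,
    strand = "+", pct_div = c(0.2, 1.5, 2.5, 2.7), score = 10
  )
  ann <- tibble::tibble(consensus_id = "c1", superfamily = "Gypsy")
  h <- divergence_histogram(hits, ann)
  expect_equal(h$n, c(1L, 1L, 2L))
  expect_equal(h$bin, c(0, 1, 2))

  # same read hits two consensuses of one superfamily: least divergent wins
  hits2 <- tibble::tibble(
    read_id = "r1", consensus_id = c("cX", "cY"),
    read_start = 0L, read_end = 10L, cons_start = 0L, cons_end = 10L,
    strand = "+", pct_div = c(3, 1.2), score = 10
  )
  ann2 <- tibble::tibble(consensus_id = c("cX", "cY"), superfamily = "Gypsy")
  h2 <- divergence_histogram(hits2, ann2)
  expect_equal(sum(h2$n), 1L)
  expect_equal(h2$bin[h2$n == 1], 1)

  hits_bad <- dplyr::mutate(hits, pct_div = -1)
  expect_error(divergence_histogram(hits_bad, ann), "Negative")
})

test_that("activity classification follows the smoothed-shape rules", {
  a <- classify_activity(c(10, 7, 4, 2, 1))
  expect_true(a$ongoing)
  expect_equal(a$shape, "recent-peak-decreasing")

  b <- classify_activity(c(3, 5, 9, 12, 6, 2))
  expect_true(b$ongoing)
  expect_equal(b$shape, "past-peak-unimodal")
  expect_equal(b$argmax_bin, 3)

  c3 <- classify_activity(c(0, 4, 8, 3))
  expect_false(c3$ongoing)

  expect_error(classify_activity(integer(0)), "Empty")
})

test_that("percent_share reproduces simple ratio arithmetic", {
  expect_equal(percent_share(1, 3, digits = 2), 33.33)
  expect_equal(percent_share(0, 5), 0)
  expect_error(percent_share(1, 0), "positive")
})
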