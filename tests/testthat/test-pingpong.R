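mk_hits <- function(target, offsets, widths, orientation) {
  tibble::tibble(
    read_id = sprintf("%s_%d", orientation, seq_along(offsets)),
    target_id = target, offset = as.integer(offsets),
    width = as.integer(widths), orientation = orientation,
    mismatches = 0L
  )
}

test_that("the 5'-5' overlap definition matches the coordinate convention", {
  # sense 5' at 100; antisense placement chosen so its 5' (offset+width-1) is 109
  sense <- mk_hits("t1", 100, 28, "sense")
  anti <- mk_hits("t1", 109 - 27, 28, "antisense")
  d <- overlap_distribution(sense, anti)
  expect_equal(d$n_pairs[d$overlap == 10], 1L)
  expect_equal(sum(d$n_pairs), 1L)

  # antisense 5' equal to sense 5': overlap 1
  anti1 <- mk_hits("t1", 100 - 27, 28, "antisense")
  d1 <- overlap_distribution(sense, anti1)
  expect_equal(d1$n_pairs[d1$overlap == 1], 1L)

  # pairs on different transcripts never combine
  anti_other <- mk_hits("t2", 109 - 27, 28, "antisense")
  d2 <- overlap_distribution(sense, anti_other)
  expect_equal(attr(d2, "total_pairs"), 0L)
  expect_true(all(is.nan(d2$fraction)))
})

test_that("overlap fractions sum to one whenever pairs exist", {
  withr::with_seed(11, {
    sense <- mk_hits("t1", sample(0:300, 60, TRUE), sample(25:30, 60, TRUE), "sense")
    anti <- mk_hits("t1", sample(0:300, 60, TRUE), sample(25:30, 60, TRUE), "antisense")
  })
  d <- overlap_distribution(sense, anti)
  if (attr(d, "total_pairs") > 0) expect_equal(sum(d$fraction), 1)
})

test_that("the Z-score matches hand-computed values and degenerate rules", {
  # fractions: focal 0.30, background 0.02 0.04 0.06 0.04 0.04
  d <- tibble::tibble(
    overlap = 1:6,
    n_pairs = c(15L, 1L, 2L, 3L, 2L, 2L),
    fraction = c(0.30, 0.02, 0.04, 0.06, 0.04, 0.04)
  )
  attr(d, "total_pairs") <- 25L
  z <- pingpong_zscore(d, focal = 1)
  expect_equal(z, (0.30 - 0.04) / stats::sd(c(0.02, 0.04, 0.06, 0.04, 0.04)))
  expect_equal(z, 18.3848, tolerance = 1e-4)

  d0 <- d
  d0$fraction <- c(0.04, 0.02, 0.04, 0.06, 0.04, 0.04) # focal equals bg mean
  attr(d0, "total_pairs") <- 24L
  expect_equal(pingpong_zscore(d0, focal = 1), 0)

  flat <- tibble::tibble(overlap = 1:6, n_pairs = 2L, fraction = 1 / 6)
  attr(flat, "total_pairs") <- 12L
  expect_warning(expect_true(is.na(pingpong_zscore(flat, focal = 1))), "sd is zero")

  short <- tibble::tibble(overlap = 1:3, n_pairs = 1L, fraction = c(0.5, 0.25, 0.25))
  attr(short, "total_pairs") <- 4L
  expect_error(pingpong_zscore(short, focal = 1), "at least 3 background")
})

test_that("piRNA-to-TE mapping keeps only transcripts hit in both orientations", {
  tx <- tibble::tibble(
    id = c("both", "senseonly"),
    seq = c(rand_dna(1, 300), rand_dna(1, 300))
  )
  pir <- tibble::tibble(
    id = c("s1", "a1", "s2"),
    seq = c(
      substring(tx$seq[1], 50, 77),          # sense on "both"
      rc_chr(substring(tx$seq[1], 100, 127)), # antisense on "both"
      substring(tx$seq[2], 10, 37)            # sense on "senseonly"
    )
  )
  maps <- map_pirnas_to_tes(pir, tx)
  expect_equal(maps$transcripts_kept, "both")
  expect_false("senseonly" %in% maps$sense$target_id)

  # an antisense piRNA with 2 substitutions still maps at k = 3, not as sense
  a2 <- rc_chr(substring(tx$seq[1], 100, 127))
  ch <- strsplit(a2, "")[[1]]
  ch[c(4, 9)] <- vapply(ch[c(4, 9)], function(b) setdiff(c("A", "C", "G", "T"), b)[1], "")
  a2 <- paste(ch, collapse = "")
  h <- map_with_mismatches(c(x = a2), setNames(tx$seq[1], tx$id[1]),
                           k = 3, orientation = "antisense")
  expect_equal(h$mismatches, 2L)
  expect_equal(nrow(map_with_mismatches(c(x = a2), setNames(tx$seq[1], tx$id[1]), k = 0)), 0)
})

test_that("simulated ping-pong pools give modal overlap 10 and a large Z", {
  tx <- rand_tx(10, 800, seed = 12)
  sim <- simulate_small_rna(tx, n_reads = 6000, pirna_frac = 1, mirna_frac = 0,
                            contaminant_frac = 0, pingpong_rho = 0.4, seed = 13)
  sig <- pingpong_signature(sim$reads, tx)
  g <- glance(sig)
  expect_equal(g$modal_overlap, 10L)
  expect_gt(g$z, 5)
  expect_equal(sum(sig$distribution$fraction), 1)
})

test_that("ping-pong pairs are assigned to superfamilies at the focal length only", {
  sense <- dplyr::bind_rows(
    mk_hits("g1", c(100, 150, 200), 28, "sense"),
    mk_hits("l1", 50, 28, "sense")
  )
  anti <- dplyr::bind_rows(
    mk_hits("g1", c(100, 150, 200) + 9 - 27, 28, "antisense"), # overlap 10
    mk_hits("l1", 50 + 9 - 27, 28, "antisense"),               # overlap 10
    mk_hits("g1", 300, 28, "antisense")                         # no partner
  )
  ann <- tibble::tibble(transcript = c("g1", "l1"), superfamily = c("Gypsy", "L1"))
  pp <- pingpong_pairs_by_superfamily(sense, anti, ann)
  expect_equal(pp$n_pairs[pp$superfamily == "Gypsy"], 3L)
  expect_equal(pp$n_pairs[pp$superfamily == "L1"], 1L)

  # an overlap-9 pair is not counted
  anti9 <- mk_hits("g1", 100 + 8 - 27, 28, "antisense")
  pp9 <- pingpong_pairs_by_superfamily(mk_hits("g1", 100, 28, "sense"), anti9, ann)
  expect_equal(nrow(pp9), 0)
})

test_that("piRNA RPM normalizes by library size and averages within sex", {
  hits <- tibble::tibble(
    read_id = sprintf("r%03d", 1:500), target_id = "t1",
    offset = 0L, width = 28L, orientation = "sense", mismatches = 0L
  )
  ann <- tibble::tibble(transcript = "t1", superfamily = "Gypsy")
  r <- pirna_rpm_by_superfamily(hits, ann, library_size = 1e6)
  expect_equal(r$rpm_sense, 500)

  hits2 <- dplyr::bind_rows(
    dplyr::mutate(hits[1:100, ], sample = "f1"),
    dplyr::mutate(hits[1:300, ], sample = "f2")
  )
  samples <- tibble::tibble(sample = c("f1", "f2"), sex = "female")
  r2 <- pirna_rpm_by_superfamily(hits2, ann, c(f1 = 1e6, f2 = 1e6), samples)
  expect_equal(r2$rpm_total, 200)
  expect_error(pirna_rpm_by_superfamily(hits, ann, 0), "positive")
})
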