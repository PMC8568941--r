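toy_network <- function() {
  # one SE region per TF on its own chromosome stretch
  regions <- tibble::tibble(
    tf_id = c("A", "B", "C"), chrom = "chr1",
    start = c(0L, 10000L, 20000L), end = c(1000L, 11000L, 21000L)
  )
  # A hits regions of B and C, B hits A, C hits nothing
  hits <- tibble::tibble(
    tf_id = c("A", "A", "B"), chrom = "chr1",
    start = c(10100L, 20100L, 100L), end = c(10110L, 20110L, 110L)
  )
  list(regions = regions, hits = hits)
}

test_that("compute_degrees matches the worked 3-TF example", {
  net <- toy_network()
  deg <- compute_degrees(net$regions, net$hits)
  expect_equal(deg$tf_id, c("A", "B", "C"))
  expect_equal(deg$in_degree, c(1L, 1L, 1L))
  expect_equal(deg$out_degree, c(2L, 1L, 0L))
  expect_equal(deg$total_degree, deg$in_degree + deg$out_degree)
  # duplicate identical hits leave degrees unchanged
  dup <- compute_degrees(net$regions, dplyr::bind_rows(net$hits, net$hits))
  expect_equal(dup, deg)
  # unknown TF in hits: warning, hit ignored
  bad <- dplyr::bind_rows(net$hits,
                          tibble::tibble(tf_id = "Z", chrom = "chr1",
                                         start = 150L, end = 160L))
  expect_warning(deg2 <- compute_degrees(net$regions, bad), "unknown")
  expect_equal(deg2, deg)
})

test_that("compute_degrees agrees with exhaustive double-loop counting on random networks", {
  withr::with_seed(23, {
    for (rep in 1:50) {
      n_tf <- sample(3:10, 1)
      tfs <- LETTERS[seq_len(n_tf)]
      regions <- tibble::tibble(
        tf_id = rep(tfs, each = 2),
        chrom = "chr1",
        start = as.integer((seq_len(2 * n_tf) - 1) * 10000),
        region_type = rep(c("se", "promoter"), n_tf)
      )
      regions$end <- regions$start + 2000L
      n_hits <- sample(0:25, 1)
      hits <- tibble::tibble(
        tf_id = sample(tfs, n_hits, replace = TRUE),
        chrom = "chr1",
        start = as.integer(sample(0:(2 * n_tf * 10000), n_hits, replace = TRUE))
      )
      hits$end <- hits$start + 10L
      got <- compute_degrees(regions, hits)
      for (tfi in tfs) {
        own <- regions[regions$tf_id == tfi, ]
        hitters <- character()
        for (tfj in tfs) {
          hj <- hits[hits$tf_id == tfj, ]
          ov <- FALSE
          for (a in seq_len(nrow(own))) {
            for (b in seq_len(nrow(hj))) {
              if (hj$start[b] < own$end[a] && hj$end[b] > own$start[a]) ov <- TRUE
            }
          }
          if (ov) hitters <- c(hitters, tfj)
        }
        se_regions <- regions[regions$region_type == "se", ]
        hi <- hits[hits$tf_id == tfi, ]
        out <- 0L
        for (a in seq_len(nrow(se_regions))) {
          touched <- FALSE
          for (b in seq_len(nrow(hi))) {
            if (hi$start[b] < se_regions$end[a] && hi$end[b] > se_regions$start[a]) {
              touched <- TRUE
            }
          }
          out <- out + touched
        }
        expect_equal(got$in_degree[got$tf_id == tfi], length(hitters))
        expect_equal(got$out_degree[got$tf_id == tfi], as.integer(out))
      }
      # degree conservation: sum of IN equals the number of directed TF->TF
      # motif relations, recounted independently
      rel <- 0L
      for (tfj in tfs) for (tfi in tfs) {
        hj <- hits[hits$tf_id == tfj, ]
        own <- regions[regions$tf_id == tfi, ]
        any_ov <- FALSE
        for (a in seq_len(nrow(own))) for (b in seq_len(nrow(hj))) {
          if (hj$start[b] < own$end[a] && hj$end[b] > own$start[a]) any_ov <- TRUE
        }
        rel <- rel + any_ov
      }
      expect_equal(sum(got$in_degree), as.integer(rel))
    }
  })
})

test_that("rank_delta sorts by tumor-minus-native total degree with missing-as-zero", {
  tum <- tibble::tibble(tf_id = c("A", "B"), total_degree = c(12L, 4L))
  nat <- tibble::tibble(tf_id = c("A", "C"), total_degree = c(2L, 7L))
  got <- rank_delta(tum, nat)
  expect_equal(got$tf_id, c("A", "B", "C"))
  expect_equal(got$delta, c(10L, 4L, -7L))
  # self-comparison is all-zero
  self <- rank_delta(tum, tum)
  expect_true(all(self$delta == 0))
  # equal deltas ordered by tf_id; top_k respected
  tie <- rank_delta(
    tibble::tibble(tf_id = c("Z", "M"), total_degree = c(5L, 5L)),
    tibble::tibble(tf_id = c("Z", "M"), total_degree = c(1L, 1L))
  )
  expect_equal(tie$tf_id, c("M", "Z"))
  expect_equal(nrow(rank_delta(tum, nat, top_k = 2)), 2)
})

test_that("scan_pwm finds consensus hits on both strands with log2-odds scoring", {
  pwm <- matrix(0, nrow = 4, ncol = 4, dimnames = list(c("A", "C", "G", "T"), NULL))
  pwm["A", 1] <- 1; pwm["C", 2] <- 1; pwm["G", 3] <- 1; pwm["T", 4] <- 1
  # hit at 0-based offset 2; ACGT is palindromic, so the reverse strand
  # scores identically at the same offset; max score = 4 * log2(4) = 8
  hit <- scan_pwm("AAACGTAA", pwm, threshold_fraction = 1)
  expect_equal(hit$offset, c(2L, 2L))
  expect_equal(hit$strand, c("+", "-"))
  expect_equal(hit$score, c(8, 8))
  # reverse complement of ACGT is ACGT itself; use an asymmetric motif
  pwm2 <- matrix(0, nrow = 4, ncol = 3, dimnames = list(c("A", "C", "G", "T"), NULL))
  pwm2["A", 1] <- 1; pwm2["A", 2] <- 1; pwm2["C", 3] <- 1
  # AAC reverse complement GTT embedded at offset 3
  hits2 <- scan_pwm("CCCGTTCC", pwm2, threshold_fraction = 1)
  expect_equal(hits2$strand, "-")
  expect_equal(hits2$offset, 3L)
  # all-N sequence scores 0 -> no hits at positive threshold
  expect_equal(nrow(scan_pwm("NNNNNNNN", pwm, 0.5)), 0)
  # sequence shorter than the motif -> empty
  expect_equal(nrow(scan_pwm("AC", pwm, 0.5)), 0)
  expect_error(scan_pwm("AAAA", pwm * 2, 0.5), "sum to 1")
})
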