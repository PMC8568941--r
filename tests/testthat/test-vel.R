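test_that("call_pair_vels applies the strict fold-change rule", {
  # two loci; counts chosen so locus RPMs are count * 0.01 at lib 1e6 * 200/1000bp
  loci <- iv("chr1", c(0, 5000, 10000), c(1000, 6000, 11000))
  # patient 1: locus1 fc = 2.1 -> gain; locus2 fc exactly 2 -> no call;
  # locus3 both zero -> fc 1 with pseudocount -> no call
  counts_t <- matrix(c(42, 40, 0), ncol = 1)
  counts_n <- matrix(c(20, 20, 0), ncol = 1)
  cohort <- toy_cohort(loci, counts_t, counts_n)
  calls <- call_pair_vels(cohort, far_tss(), pseudocount = 0)
  expect_equal(nrow(calls), 1)
  expect_equal(calls$direction, "gain")
  expect_equal(calls$start, 0L)
  expect_equal(calls$fc, 2.1)

  # lost side mirror with pseudocount
  calls2 <- call_pair_vels(
    toy_cohort(loci, matrix(c(20, 0, 0), ncol = 1), matrix(c(45, 0, 0), ncol = 1)),
    far_tss(), pseudocount = 0.5
  )
  expect_equal(calls2$direction, "lost")

  # TSS-proximal loci never become VELs
  tss_on_locus <- tibble::tibble(gene_id = "G", chrom = "chr1", start = 500L,
                                 end = 501L, strand = "+")
  calls3 <- call_pair_vels(cohort, tss_on_locus, pseudocount = 0)
  expect_false(any(calls3$start == 0))
})

test_that("qc_filter_patients uses strict less-than boundaries and names the rule", {
  loci <- iv("chr1", seq(0, 29000, 1000) * 10, seq(0, 29000, 1000) * 10 + 500)
  mk <- function(n_peaks_t, n_peaks_n) {
    dplyr::bind_rows(
      toy_track("PT", "P", "tumor", loci[seq_len(n_peaks_t), ], rep(1, n_peaks_t)),
      toy_track("PN", "P", "native", loci[seq_len(n_peaks_n), ], rep(1, n_peaks_n))
    )
  }
  calls <- tibble::tibble(patient_id = rep("P", 12))
  qc1 <- qc_filter_patients(mk(25, 25), calls, min_peaks = 25, min_vels = 10)
  expect_false(qc1$excluded)
  qc2 <- qc_filter_patients(mk(25, 24), calls, min_peaks = 25, min_vels = 10)
  expect_true(qc2$excluded)
  expect_match(qc2$reason, "peak count")
  qc3 <- qc_filter_patients(mk(25, 25), calls[1:9, ], min_peaks = 25, min_vels = 10)
  expect_true(qc3$excluded)
  expect_match(qc3$reason, "VEL count")
  qc4 <- qc_filter_patients(mk(25, 25), calls[1:10, ], min_peaks = 25, min_vels = 10)
  expect_false(qc4$excluded)
  # unpaired patient errors
  unpaired <- mk(25, 25)[1, ]
  expect_error(qc_filter_patients(unpaired, calls), "lacks a native")
})

test_that("merge_and_count counts distinct patients per direction", {
  calls <- tibble::tibble(
    patient_id = c("P1", "P3", "P7", "P2", "P5", "P1"),
    chrom = "chr1",
    start = c(100L, 150L, 120L, 110L, 140L, 130L),
    end = c(300L, 350L, 320L, 310L, 340L, 330L),
    direction = c("gain", "gain", "gain", "lost", "lost", "gain")
  )
  got <- merge_and_count(calls)
  gain <- got[got$direction == "gain", ]
  lost <- got[got$direction == "lost", ]
  expect_equal(nrow(gain), 1)
  expect_equal(gain$recurrence, 3)  # P1 counted once despite two calls
  expect_setequal(gain$patients[[1]], c("P1", "P3", "P7"))
  expect_equal(lost$recurrence, 2)
})

test_that("paired_t_test matches the closed form, stats::t.test and conventions", {
  # d = [1,2,3,4]
  res <- paired_t_test(c(2, 4, 6, 8), c(1, 2, 3, 4))
  expect_equal(res$t_stat, 3.87298, tolerance = 1e-5)
  expect_equal(res$p_value, 0.03047, tolerance = 1e-3)
  ref <- t.test(c(2, 4, 6, 8), c(1, 2, 3, 4), paired = TRUE)
  expect_equal(res$t_stat, unname(ref$statistic))
  expect_equal(res$p_value, ref$p.value)
  # sign flip
  res_neg <- paired_t_test(c(1, 2, 3, 4), c(2, 4, 6, 8))
  expect_equal(res_neg$t_stat, -res$t_stat)
  expect_equal(res_neg$p_value, res$p_value)
  # degenerate conventions
  expect_equal(paired_t_test(c(1, 1, 1), c(1, 1, 1))$p_value, 1)
  expect_equal(paired_t_test(c(2, 2, 2), c(1, 1, 1))$p_value, 0)
})

test_that("bh_adjust equals stats::p.adjust and a brute-force step-up", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  withr::with_seed(11, {
    for (rep in 1:50) {
      p <- runif(sample(1:40, 1))
      expect_equal(bh_adjust(p), brute_bh(p))
    }
    # permutation equivariance
    p <- runif(20)
    perm <- sample(20)
    expect_equal(bh_adjust(p)[perm], bh_adjust(p[perm]))
  })
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("select_recurrence_threshold finds the smallest r reaching the target", {
  mk_records <- function(rec, sig) {
    tibble::tibble(direction = "gain", recurrence = rec,
                   p_adj = ifelse(sig, 0.01, 0.5))
  }
  # all significant -> r* = 1
  all_sig <- mk_records(c(1, 2, 5), c(TRUE, TRUE, TRUE))
  expect_equal(select_recurrence_threshold(all_sig)$thresholds$r_star, 1L)
  # r=1 set 40% significant, r>=2 sets >= 96% -> r* = 2
  toy <- mk_records(
    c(rep(1, 60), rep(2, 24), rep(3, 24)),
    c(rep(TRUE, 12), rep(FALSE, 48), rep(TRUE, 23), FALSE, rep(TRUE, 24))
  )
  thr <- select_recurrence_threshold(toy, alpha = 0.05, target_fraction = 0.95)
  tab <- thr$table
  expect_lt(tab$frac_significant[tab$recurrence == 1], 0.95)
  expect_gte(tab$frac_significant[tab$recurrence == 2], 0.95)
  expect_equal(thr$thresholds$r_star, 2L)
  # unreachable target -> sentinel
  not_reached <- mk_records(c(1, 4), c(TRUE, FALSE))
  nr <- select_recurrence_threshold(not_reached, target_fraction = 1)
  expect_true(is.na(nr$thresholds$r_star))
  expect_false(nr$thresholds$reached)
})

test_that("threshold r* is non-increasing as alpha increases", {
  withr::with_seed(3, {
    records <- tibble::tibble(
      direction = "gain",
      recurrence = sample(1:20, 300, replace = TRUE),
      p_adj = runif(300)^2
    )
    rs <- vapply(c(0.01, 0.05, 0.2, 0.5), function(a) {
      r <- select_recurrence_threshold(records, alpha = a, target_fraction = 0.8)
      if (is.na(r$thresholds$r_star)) 1e9 else as.numeric(r$thresholds$r_star)
    }, 0)
    expect_true(all(diff(rs) <= 0))
  })
})

test_that("subgroup_specific_vels agrees with exhaustive comparison", {
  loci <- iv("chr1", c(0, 5000, 10000), c(1000, 6000, 11000))
  # 8 patients, 2 per subgroup; counts give locus1 CMS2-specific
  cms <- rep(c("CMS1", "CMS2", "CMS3", "CMS4"), each = 2)
  counts_t <- rbind(
    c(39, 39, 60, 60, 35, 35, 20, 20),   # CMS2 mean 6.0 vs 3.9/3.5/2.0 (x10)
    c(60, 60, 41, 41, 30, 30, 20, 20),   # 6.0 <= 1.5*4.1 -> none
    rep(30, 8)                           # all equal -> none
  ) * 10
  counts_n <- matrix(10, nrow = 3, ncol = 8)
  cohort <- toy_cohort(loci, counts_t, counts_n, cms = cms)
  sig <- build_signal_matrix(cohort, loci)
  got <- subgroup_specific_vels(sig, ratio = 1.5)
  expect_equal(got$subgroup, c("CMS2", NA, NA))
  # exhaustive oracle over all loci and subgroups
  tum <- sig[sig$tissue == "tumor", ]
  for (li in 1:3) {
    means <- tapply(tum$rpm[tum$locus_id == li], tum$cms[tum$locus_id == li], mean)
    oracle <- NA_character_
    for (g in names(means)) {
      if (all(means[g] > 1.5 * means[setdiff(names(means), g)])) oracle <- g
    }
    expect_equal(got$subgroup[got$locus_id == li], oracle)
  }
  expect_error(
    subgroup_specific_vels(sig[sig$cms %in% c("CMS1", "CMS2", "CMS3") | sig$tissue == "native", ]),
    "no tumor samples|at least two"
  )
})

test_that("test_vel_records scores loci with paired t and per-direction BH", {
  loci <- iv("chr1", c(0, 5000), c(1000, 6000))
  withr::with_seed(5, {
    counts_t <- rbind(rpois(6, 90), rpois(6, 30))
    counts_n <- rbind(rpois(6, 30), rpois(6, 30))
  })
  cohort <- toy_cohort(loci, counts_t, counts_n)
  records <- tibble::tibble(
    chrom = "chr1", start = c(0L, 5000L), end = c(1000L, 6000L),
    direction = "gain", recurrence = c(6L, 1L), patients = list("x", "y")
  )
  scored <- test_vel_records(records, cohort)
  sig <- build_signal_matrix(cohort, loci)
  for (li in 1:2) {
    sub <- sig[sig$locus_id == li, ]
    tum <- sub$rpm[sub$tissue == "tumor"][order(sub$patient_id[sub$tissue == "tumor"])]
    nat <- sub$rpm[sub$tissue == "native"][order(sub$patient_id[sub$tissue == "native"])]
    ref <- paired_t_test(tum, nat)
    expect_equal(scored$t_stat[li], ref$t_stat)
    expect_equal(scored$p_raw[li], ref$p_value)
  }
  expect_equal(scored$p_adj, bh_adjust(scored$p_raw))
  expect_true(all(scored$p_adj >= scored$p_raw))
})
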