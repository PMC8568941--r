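test_that("stitch_enhancers fuses peaks within 12.5 kb after TSS exclusion", {
  tss <- tibble::tibble(gene_id = "G", chrom = "chr1", start = 100000L,
                        end = 100001L, strand = "+")
  # gap 8,000 -> one region; gap 13,000 -> separate
  peaks <- iv("chr1", c(1000, 10000, 40000, 54000), c(2000, 11000, 41000, 55000))
  st <- stitch_enhancers(peaks, tss)
  expect_equal(nrow(st), 3)
  expect_equal(st$n_constituents, c(2L, 1L, 1L))
  expect_equal(st$start[1], 1000L)
  expect_equal(st$end[1], 11000L)
  # a peak inside the TSS flank is dropped before stitching
  with_prox <- dplyr::bind_rows(peaks, iv("chr1", 99000, 99500))
  expect_equal(nrow(stitch_enhancers(with_prox, tss)), 3)
  # stitch_distance 0 reduces to plain merge of distal peaks
  st0 <- stitch_enhancers(peaks, tss, stitch_distance = 0)
  expect_equal(
    st0[c("chrom", "start", "end")],
    merge_intervals(peaks, gap = 0)
  )
})

test_that("tangent_cutoff finds the slope-1 crossing of a quadratic curve", {
  signals <- (0:100)^2
  tc <- tangent_cutoff(signals)
  # analytic tangent of y = x^2 with slope 1 touches at x = 0.5, y = 0.25
  expect_equal(tc$cutoff, 2500)
  expect_equal(sum(tc$is_super), 50)
  expect_true(all(signals[tc$is_super] > 2500))
  # discrete-slope oracle: first sorted index whose forward slope exceeds 1
  y <- signals / max(signals)
  x <- (0:100) / 100
  slopes <- diff(y) / diff(x)
  first <- min(which(slopes > 1))
  expect_equal(tc$cutoff, signals[first])
})

test_that("tangent_cutoff handles degenerate shapes", {
  # strictly linear: slope == 1 everywhere, never strictly above -> none
  lin <- tangent_cutoff(seq(10, 1000, length.out = 50))
  expect_equal(sum(lin$is_super), 0)
  # one extreme outlier among equals: exactly the outlier
  out <- tangent_cutoff(c(rep(5, 30), 500))
  expect_equal(sum(out$is_super), 1)
  expect_true(out$is_super[31])
  # all equal: warning, none
  expect_warning(eq <- tangent_cutoff(rep(3, 10)), "identical")
  expect_equal(sum(eq$is_super), 0)
  expect_error(tangent_cutoff(c(1, 2)))
})

test_that("tangent_cutoff is invariant to affine rescaling and monotone at the top", {
  withr::with_seed(13, {
    base <- sort(rexp(80, rate = 0.01)) + 1:80 * 0.5
    ref <- tangent_cutoff(base)
    for (k in 1:20) {
      a <- runif(1, 0.1, 50)
      b <- runif(1, -20, 100)
      tr <- tangent_cutoff(a * base + b)
      expect_equal(tr$is_super, ref$is_super)
    }
    # raising the top signal never demotes it
    boosted <- base
    boosted[which.max(base)] <- max(base) * 10
    tb <- tangent_cutoff(boosted)
    if (ref$is_super[which.max(base)]) expect_true(tb$is_super[which.max(base)])
  })
})

test_that("call_sample_super_enhancers recovers a planted high-signal cluster", {
  tss <- far_tss()
  # background: 12 isolated doublets; planted: 3-peak cluster with 10x signal
  bg_start <- seq(0, 11) * 40000L
  peaks <- dplyr::bind_rows(
    iv("chr1", bg_start, bg_start + 1000L),
    iv("chr1", bg_start + 4000L, bg_start + 5000L),
    iv("chr1", 600000L + c(0L, 4000L, 8000L), 600000L + c(1000L, 5000L, 9000L))
  )
  frags <- dplyr::bind_rows(
    frags_at("chr1", rep(bg_start + 100L, each = 20)),
    frags_at("chr1", rep(bg_start + 4100L, each = 20)),
    frags_at("chr1", rep(600000L + c(100L, 4100L, 8100L), each = 200))
  )
  se <- call_sample_super_enhancers(peaks, frags, 1e6, tss)
  expect_s3_class(se, "se_ranking")
  sup <- se[se$is_super, ]
  expect_equal(nrow(sup), 1)
  expect_equal(sup$start, 600000L)
  expect_equal(sup$n_constituents, 3L)
  # ranks are a permutation following the signal sort
  expect_equal(sort(se$rank), seq_len(nrow(se)))
  expect_equal(se$rank[order(se$signal)], seq_len(nrow(se)))
  # no fragments -> all-zero signals -> all-identical warning, no supers
  expect_warning(se0 <- call_sample_super_enhancers(
    peaks, frags_at(character(), integer()), 1e6, tss
  ), "identical")
  expect_equal(sum(se0$is_super), 0)
  expect_error(call_sample_super_enhancers(peaks[1, ], frags, 1e6, tss), "fewer than 3")
})

test_that("VSEL pipeline on identical tumor/native inputs yields nothing significant", {
  tss <- far_tss()
  bg_start <- seq(0, 11) * 40000L
  loci <- dplyr::bind_rows(
    iv("chr1", bg_start, bg_start + 1000L),
    iv("chr1", bg_start + 4000L, bg_start + 5000L),
    iv("chr1", 600000L + c(0L, 4000L, 8000L), 600000L + c(1000L, 5000L, 9000L))
  )
  counts <- matrix(rep(c(rep(20, 24), rep(200, 3)), 4), ncol = 4)
  cohort <- toy_cohort(loci, counts, counts)  # tumor == native
  res <- call_vsels(cohort, tss, min_vsels = 0)
  expect_equal(sum(tidy(res)$significant), 0)
})

test_that("call_vsels excludes patients below the VSEL floor (strict less-than)", {
  # QC logic exercised directly through the per-patient call counts
  tss <- far_tss()
  bg_start <- seq(0, 11) * 40000L
  loci <- dplyr::bind_rows(
    iv("chr1", bg_start, bg_start + 1000L),
    iv("chr1", bg_start + 4000L, bg_start + 5000L),
    iv("chr1", 600000L + c(0L, 4000L, 8000L), 600000L + c(1000L, 5000L, 9000L))
  )
  base <- c(rep(20, 24), rep(200, 3))
  # patient 1: tumor gains the cluster 3x -> 1 VSEL call; patient 2: balanced
  t1 <- base; t1[25:27] <- 600
  counts_t <- cbind(t1, base)
  counts_n <- cbind(base, base)
  cohort <- toy_cohort(loci, counts_t, counts_n)
  res1 <- call_vsels(cohort, tss, min_vsels = 1)
  expect_equal(sum(!res1$qc$excluded), 1)
  expect_match(res1$qc$reason[res1$qc$excluded][1], "VSEL count")
  qc_at_floor <- call_vsels(cohort, tss, min_vsels = 0)$qc
  expect_true(all(!qc_at_floor$excluded))
})

test_that("se_gene_recurrence ranks genes by tumor-minus-native recurrence", {
  tss <- tibble::tibble(
    gene_id = c("TFA", "TFB"), chrom = "chr1",
    start = c(10000L, 200000L), end = c(10001L, 200001L), strand = "+"
  )
  mk_set <- function(sid, tissue, which_genes) {
    coords <- list(TFA = iv("chr1", 20000, 30000), TFB = iv("chr1", 180000, 190000))
    dplyr::bind_rows(coords[which_genes]) %>%
      dplyr::mutate(sample_id = sid, tissue = tissue)
  }
  se_sets <- dplyr::bind_rows(
    mk_set("t1", "tumor", c("TFA", "TFB")),
    mk_set("t2", "tumor", "TFA"),
    mk_set("t3", "tumor", "TFA"),
    mk_set("n1", "native", "TFB"),
    mk_set("n2", "native", "TFB")
  )
  got <- se_gene_recurrence(se_sets, tss)
  expect_equal(got$gene_id, c("TFA", "TFB"))
  expect_equal(got$variant_recurrence, c(3L, -1L))
  # brute-force recount
  for (g in got$gene_id) {
    for (ti in c("tumor", "native")) {
      manual <- length(unique(se_sets$sample_id[
        se_sets$tissue == ti &
          abs((se_sets$start + se_sets$end) / 2 - tss$start[tss$gene_id == g]) <= 5e4
      ]))
      col <- paste0("recurrence_", ti)
      expect_equal(got[[col]][got$gene_id == g], manual)
    }
  }
})
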