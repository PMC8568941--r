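# Variant enhancer loci (VELs): per-pair fold-change calls, patient QC,
# merged-locus recurrence, paired-t/BH significance and recurrence-threshold
# selection.

#' Per-patient variant enhancer calls
#'
#' For each patient, unions the tumor and native samples' TSS-distal
#' H3K27ac peaks (gap 0) into that patient's enhancer loci, computes the
#' tumor and native RPM at each locus and calls a gain VEL where
#' `fc = (rpm_tumor + pseudocount) / (rpm_native + pseudocount)` strictly
#' exceeds `fc_threshold`, a lost VEL where `fc < 1 / fc_threshold`.
#'
#' @param cohort Cohort tibble; only `mark == "H3K27ac"` rows are used and
#'   every patient must have both tissues.
#' @param tss TSS tibble (see [read_tss()]).
#' @param fc_threshold Fold-change call threshold (> 1, default 2: the call
#'   is strict, a ratio of exactly 2 is not a VEL).
#' @param pseudocount RPM pseudocount guarding against zero native signal
#'   (default 0.5).
#' @param window TSS flank half-width for enhancer classification (bp).
#' @param extension Fragment extension (bp).
#' @return A tibble of calls: `patient_id`, `chrom`, `start`, `end`,
#'   `rpm_tumor`, `rpm_native`, `fc`, `direction` (`gain`/`lost`).
#' @export
call_pair_vels <- function(cohort, tss, fc_threshold = 2, pseudocount = 0.5,
                           window = 2500, extension = 200) {
  stopifnot(fc_threshold > 1, pseudocount >= 0)
  h27 <- h3k27ac_pairs(cohort)
  calls <- purrr::map(split(seq_len(nrow(h27)), h27$patient_id), function(rows) {
    sub <- h27[rows, ]
    tum <- sub[sub$tissue == "tumor", ]
    nat <- sub[sub$tissue == "native", ]
    enh <- bind_rows(
      sample_enhancers(tum$peaks[[1]], tss, window),
      sample_enhancers(nat$peaks[[1]], tss, window)
    )
    loci <- merge_intervals(enh, gap = 0)
    if (nrow(loci) == 0) return(NULL)
    rpm_t <- compute_rpm(loci, tum$fragments[[1]], tum$library_size[1], extension)
    rpm_n <- compute_rpm(loci, nat$fragments[[1]], nat$library_size[1], extension)
    fc <- (rpm_t + pseudocount) / (rpm_n + pseudocount)
    loci %>%
      mutate(
        patient_id = sub$patient_id[1], rpm_tumor = rpm_t, rpm_native = rpm_n, fc = fc,
        direction = dplyr::case_when(
          fc > fc_threshold ~ "gain",
          fc < 1 / fc_threshold ~ "lost",
          TRUE ~ NA_character_
        )
      ) %>%
      filter(!is.na(.data$direction))
  })
  out <- bind_rows(calls)
  if (nrow(out) == 0) {
    return(tibble(
      patient_id = character(), chrom = character(), start = integer(),
      end = integer(), rpm_tumor = numeric(), rpm_native = numeric(),
      fc = numeric(), direction = character()
    ))
  }
  out %>% select(all_of(c(
    "patient_id", "chrom", "start", "end", "rpm_tumor", "rpm_native", "fc", "direction"
  )))
}

# H3K27ac rows; error on unpaired patients (internal)
h3k27ac_pairs <- function(cohort) {
  validate_cohort(cohort)
  h27 <- cohort %>% filter(.data$mark == "H3K27ac")
  tallies <- h27 %>%
    group_by(.data$patient_id) %>%
    summarise(
      has_tumor = any(.data$tissue == "tumor"),
      has_native = any(.data$tissue == "native")
    )
  bad <- tallies %>% filter(!.data$has_tumor | !.data$has_native)
  if (nrow(bad) > 0) {
    abort(paste0("patient ", bad$patient_id[1], " lacks a ",
                 if (bad$has_tumor[1]) "native" else "tumor", " H3K27ac sample"))
  }
  h27
}

#' Patient quality-control filter
#'
#' A patient is excluded when either H3K27ac sample has fewer than
#' `min_peaks` peaks (strict less-than) or when the patient's total VEL
#' count (gain + lost) is below `min_vels` (strict less-than); patients at
#' exactly the threshold are retained. Low counts at genome scale indicate
#' sampling problems (too few tumor cells in the dissected piece).
#'
#' @param cohort Cohort tibble (H3K27ac pairs).
#' @param pair_calls Per-patient calls from [call_pair_vels()].
#' @param min_peaks Minimum per-sample peak count (default 2500).
#' @param min_vels Minimum per-patient VEL count (default 500).
#' @return A QC tibble: `patient_id`, `n_peaks_tumor`, `n_peaks_native`,
#'   `n_vels`, `excluded`, `reason`.
#' @export
qc_filter_patients <- function(cohort, pair_calls, min_peaks = 2500, min_vels = 500) {
  h27 <- h3k27ac_pairs(cohort)
  counts <- h27 %>%
    mutate(n_peaks = vapply(.data$peaks, nrow, 0L)) %>%
    select(all_of(c("patient_id", "tissue", "n_peaks"))) %>%
    tidyr::pivot_wider(
      names_from = "tissue", values_from = "n_peaks", names_prefix = "n_peaks_"
    )
  vels <- pair_calls %>% count(.data$patient_id, name = "n_vels")
  counts %>%
    left_join(vels, by = "patient_id") %>%
    mutate(
      n_vels = dplyr::coalesce(.data$n_vels, 0L),
      low_peaks = pmin(.data$n_peaks_tumor, .data$n_peaks_native) < min_peaks,
      low_vels = .data$n_vels < min_vels,
      excluded = .data$low_peaks | .data$low_vels,
      reason = dplyr::case_when(
        low_peaks & low_vels ~ "peak count below minimum; VEL count below minimum",
        low_peaks ~ "peak count below minimum",
        low_vels ~ "VEL count below minimum",
        TRUE ~ ""
      )
    ) %>%
    select(all_of(c(
      "patient_id", "n_peaks_tumor", "n_peaks_native", "n_vels", "excluded", "reason"
    ))) %>%
    arrange(.data$patient_id)
}

#' Merge per-patient calls into recurrent variant loci
#'
#' Gain and lost calls are merged separately (gap 0) into one coordinate
#' set per direction; the recurrence of a merged locus is the number of
#' distinct patients with an overlapping same-direction call.
#'
#' @param calls Tibble from [call_pair_vels()] (QC-retained patients).
#' @return A tibble: `chrom`, `start`, `end`, `direction`, `recurrence`,
#'   `patients` (list column of supporting patient ids).
#' @export
merge_and_count <- function(calls) {
  if (nrow(calls) == 0) {
    return(tibble(
      chrom = character(), start = integer(), end = integer(),
      direction = character(), recurrence = integer(), patients = list()
    ))
  }
  per_dir <- purrr::map(split(calls, calls$direction), function(sub) {
    merged <- merge_intervals(sub, gap = 0)
    hits <- find_ov(as_gr(merged), as_gr(sub))
    who <- tibble(
      locus = S4Vectors::queryHits(hits),
      patient_id = sub$patient_id[S4Vectors::subjectHits(hits)]
    ) %>%
      distinct() %>%
      group_by(.data$locus) %>%
      summarise(
        recurrence = dplyr::n(),
        patients = list(sort(.data$patient_id))
      )
    merged %>%
      mutate(locus = row_number(), direction = sub$direction[1]) %>%
      left_join(who, by = "locus") %>%
      mutate(recurrence = dplyr::coalesce(.data$recurrence, 0L)) %>%
      select(-"locus")
  })
  bind_rows(per_dir) %>%
    arrange(.data$direction, .data$chrom, .data$start)
}

#' Paired two-sided t-test with degenerate-case conventions
#'
#' Computes `t = mean(d) / (sd(d) / sqrt(n))` on `d = tumor - native`
#' (sample sd, n - 1 denominator) and a two-sided p-value from Student's t
#' with n - 1 degrees of freedom. When all differences are identical the t
#' statistic is undefined: `p = 1` when the common difference is zero (no
#' signal), `p = 0` otherwise (constant shift).
#'
#' @param tumor,native Equal-length numeric vectors (n >= 2), one entry per
#'   patient pair.
#' @return A list with `t_stat` and `p_value`.
#' @export
paired_t_test <- function(tumor, native) {
  stopifnot(length(tumor) == length(native), length(tumor) >= 2)
  d <- tumor - native
  n <- length(d)
  m <- mean(d)
  s <- stats::sd(d)
  if (s == 0) {
    if (m == 0) return(list(t_stat = NA_real_, p_value = 1))
    return(list(t_stat = sign(m) * Inf, p_value = 0))
  }
  t_stat <- m / (s / sqrt(n))
  list(t_stat = t_stat, p_value = 2 * stats::pt(-abs(t_stat), df = n - 1))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment (via [stats::p.adjust()]) with
#' input validation; output order matches input order.
#'
#' @param p Numeric vector of p-values in [0, 1].
#' @return Adjusted p-values, capped at 1.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) abort("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Score merged variant loci by paired t-test and BH correction
#'
#' At each merged locus the region-mean RPM of every retained pair (carrier
#' or not) enters a two-sided paired t-test; p-values are BH-adjusted
#' separately within the gain and the lost record sets.
#'
#' @param records Merged loci from [merge_and_count()].
#' @param cohort QC-retained H3K27ac cohort tibble.
#' @param extension Fragment extension (bp).
#' @return `records` with `t_stat`, `p_raw`, `p_adj` columns.
#' @export
test_vel_records <- function(records, cohort, extension = 200) {
  if (nrow(records) == 0) {
    return(records %>% mutate(t_stat = numeric(), p_raw = numeric(), p_adj = numeric()))
  }
  h27 <- h3k27ac_pairs(cohort)
  loci <- records %>% select(all_of(c("chrom", "start", "end")))
  sig <- build_signal_matrix(h27, loci, extension)
  wide <- sig %>%
    select(all_of(c("locus_id", "patient_id", "tissue", "rpm"))) %>%
    tidyr::pivot_wider(names_from = "tissue", values_from = "rpm")
  stats_tbl <- wide %>%
    mutate(d = .data$tumor - .data$native) %>%
    group_by(.data$locus_id) %>%
    summarise(n = dplyr::n(), m = mean(.data$d), s = stats::sd(.data$d))
  # n = 1 pair: the paired test is undefined; report p = 1 (no evidence)
  t_stat <- with(stats_tbl, ifelse(
    n < 2 | is.na(s), NA_real_,
    ifelse(s == 0, ifelse(m == 0, NA_real_, sign(m) * Inf), m / (s / sqrt(n)))
  ))
  p_raw <- with(stats_tbl, ifelse(
    n < 2 | is.na(s), 1,
    ifelse(s == 0, ifelse(m == 0, 1, 0),
           2 * stats::pt(-abs(m / (s / sqrt(pmax(n, 2)))), df = pmax(n - 1, 1)))
  ))
  idx <- match(seq_len(nrow(records)), stats_tbl$locus_id)
  out <- records
  out$t_stat <- t_stat[idx]
  out$p_raw <- p_raw[idx]
  out %>%
    group_by(.data$direction) %>%
    mutate(p_adj = bh_adjust(.data$p_raw)) %>%
    ungroup()
}

#' Select the recurrence threshold for significance
#'
#' For each candidate recurrence r (1 .. max observed), computes the
#' fraction of records in the cumulative set `recurrence >= r` with
#' `p_adj < alpha`; the selected threshold is the smallest r whose fraction
#' reaches `target_fraction`. Computed separately per direction. When no r
#' reaches the target the threshold is `NA` ("not reached") and no record
#' can be significant in that direction.
#'
#' @param records Scored records from [test_vel_records()].
#' @param alpha Adjusted-p significance level (default 0.05).
#' @param target_fraction Required significant share (default 0.95).
#' @return A `recurrence_threshold` object: list with `thresholds`
#'   (per-direction tibble of `r_star`, `reached`) and `table`
#'   (per-direction fraction curve for plotting).
#' @export
select_recurrence_threshold <- function(records, alpha = 0.05, target_fraction = 0.95) {
  stopifnot(target_fraction > 0, target_fraction <= 1)
  if (nrow(records) == 0) {
    return(structure(
      list(
        thresholds = tibble(direction = character(), r_star = integer(),
                            reached = logical()),
        table = tibble(direction = character(), recurrence = integer(),
                       n_records = integer(), frac_significant = numeric()),
        alpha = alpha, target_fraction = target_fraction
      ),
      class = "recurrence_threshold"
    ))
  }
  dirs <- sort(unique(records$direction))
  tabs <- purrr::map(dirs, function(dd) {
    sub <- records %>% filter(.data$direction == dd)
    rmax <- max(sub$recurrence)
    purrr::map_dfr(seq_len(rmax), function(r) {
      cum <- sub %>% filter(.data$recurrence >= r)
      tibble(
        direction = dd, recurrence = r, n_records = nrow(cum),
        frac_significant = mean(cum$p_adj < alpha)
      )
    })
  }) %>% bind_rows()
  thresholds <- tabs %>%
    group_by(.data$direction) %>%
    summarise(
      r_star = if (any(.data$frac_significant >= target_fraction)) {
        min(.data$recurrence[.data$frac_significant >= target_fraction])
      } else {
        NA_integer_
      },
      reached = any(.data$frac_significant >= target_fraction)
    )
  structure(
    list(
      thresholds = thresholds, table = tabs,
      alpha = alpha, target_fraction = target_fraction
    ),
    class = "recurrence_threshold"
  )
}

#' @export
print.recurrence_threshold <- function(x, ...) {
  cat("Recurrence threshold selection (alpha =", x$alpha,
      ", target fraction =", x$target_fraction, ")\n")
  print(x$thresholds)
  invisible(x)
}

#' Full variant-enhancer-locus pipeline
#'
#' Runs the complete analysis on a paired H3K27ac cohort: per-patient
#' fold-change calls ([call_pair_vels()]), patient QC
#' ([qc_filter_patients()]), per-direction merge and recurrence counting
#' ([merge_and_count()]), paired-t/BH scoring ([test_vel_records()]) and
#' recurrence-threshold selection ([select_recurrence_threshold()]). A
#' record is significant iff `p_adj < alpha` and its recurrence reaches the
#' selected threshold of its direction.
#'
#' @inheritParams call_pair_vels
#' @inheritParams qc_filter_patients
#' @inheritParams select_recurrence_threshold
#' @return A `vel_result` object: list with `records` (scored VEL tibble
#'   with `significant` flag), `calls`, `qc`, `threshold`, and the
#'   parameters used. `tidy()` returns the records, `glance()` a one-row
#'   summary, `autoplot()` the recurrence-threshold curve.
#' @export
call_vels <- function(cohort, tss, fc_threshold = 2, pseudocount = 0.5,
                      alpha = 0.05, target_fraction = 0.95,
                      min_peaks = 2500, min_vels = 500,
                      window = 2500, extension = 200) {
  calls <- call_pair_vels(cohort, tss, fc_threshold, pseudocount, window, extension)
  qc <- qc_filter_patients(cohort, calls, min_peaks, min_vels)
  retained <- qc$patient_id[!qc$excluded]
  h27 <- h3k27ac_pairs(cohort) %>% filter(.data$patient_id %in% retained)
  calls_kept <- calls %>% filter(.data$patient_id %in% retained)
  if (length(retained) == 0) abort("all patients excluded by QC")
  records <- merge_and_count(calls_kept)
  records <- test_vel_records(records, h27, extension)
  thr <- select_recurrence_threshold(records, alpha, target_fraction)
  records <- records %>%
    left_join(thr$thresholds, by = "direction") %>%
    mutate(significant = !is.na(.data$r_star) & .data$p_adj < alpha &
             .data$recurrence >= .data$r_star) %>%
    select(-"r_star", -"reached")
  structure(
    list(
      records = records, calls = calls_kept, qc = qc, threshold = thr,
      params = list(
        fc_threshold = fc_threshold, pseudocount = pseudocount, alpha = alpha,
        target_fraction = target_fraction, min_peaks = min_peaks,
        min_vels = min_vels, window = window, extension = extension
      ),
      type = "vel"
    ),
    class = "vel_result"
  )
}

#' @export
print.vel_result <- function(x, ...) {
  n_pat <- sum(!x$qc$excluded)
  label <- if (identical(x$type, "vsel")) "VSEL" else "VEL"
  cat(label, "analysis over", n_pat, "retained patient pairs\n")
  tab <- x$records %>%
    group_by(.data$direction) %>%
    summarise(n = dplyr::n(), n_significant = sum(.data$significant))
  print(left_join(tab, x$threshold$thresholds, by = "direction"))
  invisible(x)
}

#' Subgroup-specific gain VELs
#'
#' A locus is specific to subgroup S iff the mean tumor-sample RPM of S
#' strictly exceeds `ratio` times the mean of every other subgroup; at most
#' one subgroup can satisfy this.
#'
#' @param signal Long signal tibble from [build_signal_matrix()] carrying a
#'   `cms` subgroup label per sample (evaluate it on the gain-VEL loci).
#' @param ratio Specificity ratio (> 1, default 1.5).
#' @return One row per locus: coordinates, per-subgroup mean-RPM columns
#'   (`mean_<subgroup>`), and `subgroup` (`NA` when specific to none).
#' @export
subgroup_specific_vels <- function(signal, ratio = 1.5) {
  stopifnot(ratio > 1)
  if (!"cms" %in% names(signal)) abort("signal must carry a cms column")
  groups <- sort(unique(signal$cms[!is.na(signal$cms)]))
  if (length(groups) < 2) abort("need at least two subgroups")
  tum <- signal %>% filter(.data$tissue == "tumor", !is.na(.data$cms))
  missing_grp <- setdiff(groups, unique(tum$cms))
  if (length(missing_grp) > 0) {
    abort(paste0("subgroup ", missing_grp[1], " has no tumor samples"))
  }
  means <- tum %>%
    group_by(.data$locus_id, .data$chrom, .data$start, .data$end, .data$cms) %>%
    summarise(mean_rpm = mean(.data$rpm), .groups = "drop")
  wide <- means %>%
    tidyr::pivot_wider(
      names_from = "cms", values_from = "mean_rpm", names_prefix = "mean_"
    )
  mat <- as.matrix(wide[paste0("mean_", groups)])
  if (any(is.na(mat))) abort("a subgroup has no tumor samples")
  specific <- apply(mat, 1, function(v) {
    top <- which.max(v)
    if (all(v[top] > ratio * v[-top])) groups[top] else NA_character_
  })
  wide %>% mutate(subgroup = specific) %>% arrange(.data$locus_id)
}
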