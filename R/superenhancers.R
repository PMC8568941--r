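# ROSE-style super-enhancers: stitching, slope-1 tangent cutoff, variant
# super-enhancer loci (VSELs) and SE-associated gene recurrence.

#' Stitch TSS-distal peaks into candidate super-enhancer regions
#'
#' Removes peaks overlapping the TSS exclusion flank, merges the remainder
#' with a gap of `stitch_distance` bp, and records how many input peaks
#' constitute each stitched region. With `stitch_distance = 0` this reduces
#' to the plain merge of TSS-distal peaks.
#'
#' @param peaks Interval tibble of one sample's H3K27ac peaks.
#' @param tss TSS tibble.
#' @param stitch_distance Maximum gap fused during stitching (bp, default
#'   12500).
#' @param tss_exclusion TSS flank half-width excluded before stitching (bp,
#'   default 2500).
#' @return Stitched regions with an `n_constituents` column.
#' @export
stitch_enhancers <- function(peaks, tss, stitch_distance = 12500, tss_exclusion = 2500) {
  distal <- sample_enhancers(peaks, tss, tss_exclusion)
  stitched <- merge_intervals(distal, gap = stitch_distance)
  if (nrow(stitched) == 0) return(stitched %>% mutate(n_constituents = integer()))
  hits <- find_ov(as_gr(stitched), as_gr(distal))
  n_con <- integer(nrow(stitched))
  tab <- table(S4Vectors::queryHits(hits))
  n_con[as.integer(names(tab))] <- as.integer(tab)
  stitched %>% mutate(n_constituents = n_con)
}

#' Slope-1 tangent cutoff on the ranked signal curve
#'
#' Sorts signals ascending, rescales rank and signal to [0, 1] (the
#' hockey-stick curve), and finds the first rank at which the discrete
#' slope of the rescaled curve exceeds 1 — the point where a slope-1
#' tangent touches the curve. The cutoff is the signal at the left end of
#' that first crossing segment; regions with signal strictly above the
#' cutoff are super-enhancers. The cutoff index is invariant to affine
#' rescaling of the signal vector. All-equal signals yield zero
#' super-enhancers with a warning.
#'
#' @param signals Numeric vector of stitched-region signals (length >= 3).
#' @return A list with `cutoff` (signal units), `is_super` (logical, input
#'   order) and `table` (sorted curve: `rank`, `signal`, `x`, `y`,
#'   `slope`, `is_super`).
#' @export
tangent_cutoff <- function(signals) {
  stopifnot(length(signals) >= 3, !any(is.na(signals)))
  n <- length(signals)
  ord <- order(signals)
  s <- signals[ord]
  if (max(s) == min(s)) {
    warn("all signals identical; no super-enhancers")
    tab <- tibble(
      rank = seq_len(n), signal = s, x = (seq_len(n) - 1) / (n - 1),
      y = 0, slope = c(NA, rep(0, n - 1)), is_super = FALSE
    )
    return(list(cutoff = max(s), is_super = rep(FALSE, n), table = tab))
  }
  x <- (seq_len(n) - 1) / (n - 1)
  y <- (s - min(s)) / (max(s) - min(s))
  slope <- c(NA, diff(y) / diff(x))
  # strict crossing, with a tolerance so exactly-slope-1 geometry (where no
  # tangent point exists) is not broken by floating-point noise
  crossing <- which(slope > 1 + 1e-9)
  cutoff <- if (length(crossing) == 0) max(s) else s[min(crossing) - 1L]
  is_super_sorted <- s > cutoff
  is_super <- logical(n)
  is_super[ord] <- is_super_sorted
  list(
    cutoff = cutoff, is_super = is_super,
    table = tibble(rank = seq_len(n), signal = s, x = x, y = y,
                   slope = slope, is_super = is_super_sorted)
  )
}

#' Call super-enhancers in one sample
#'
#' Stitches the sample's TSS-distal H3K27ac peaks
#' ([stitch_enhancers()]), scores each stitched region by region-summed RPM
#' (per-bp density times length, so long high-signal clusters rank top) and
#' applies the slope-1 tangent cutoff. By default only regions of two or
#' more constituent peaks enter the super-enhancer candidate set; singleton
#' regions are retained in the ranking but never flagged super.
#'
#' @param peaks,fragments,library_size One sample's peak set, fragment
#'   tibble and total mapped reads.
#' @param tss TSS tibble.
#' @param stitch_distance,tss_exclusion See [stitch_enhancers()].
#' @param extension Fragment extension (bp).
#' @param require_multiple Restrict super-enhancer candidates to stitched
#'   regions of >= 2 peaks (default TRUE).
#' @return An `se_ranking` tibble: stitched regions with `n_constituents`,
#'   `signal`, `rank` (ascending by signal) and `is_super`.
#' @export
call_sample_super_enhancers <- function(peaks, fragments, library_size, tss,
                                        stitch_distance = 12500, tss_exclusion = 2500,
                                        extension = 200, require_multiple = TRUE) {
  stitched <- stitch_enhancers(peaks, tss, stitch_distance, tss_exclusion)
  if (nrow(stitched) < 3) abort("fewer than 3 stitched regions; cannot rank")
  stitched$signal <- compute_rpm_sum(stitched, fragments, library_size, extension)
  stitched$rank <- rank(stitched$signal, ties.method = "first")
  candidate <- if (require_multiple) stitched$n_constituents >= 2 else rep(TRUE, nrow(stitched))
  stitched$is_super <- FALSE
  if (sum(candidate) >= 3) {
    tc <- tangent_cutoff(stitched$signal[candidate])
    stitched$is_super[candidate] <- tc$is_super
  }
  out <- stitched %>% arrange(.data$rank)
  class(out) <- c("se_ranking", class(out))
  out
}

#' Variant super-enhancer loci (VSELs)
#'
#' The VEL pipeline applied to super-enhancer loci: per sample, super-
#' enhancers are called ([call_sample_super_enhancers()]); per patient the
#' tumor and native SE intervals are merged (gap 0) into that patient's SE
#' loci and fold-change calls made on region-mean RPM; patients with fewer
#' than `min_vsels` calls are excluded (strict less-than); calls are merged
#' per direction, recurrence counted, paired-t/BH scored, and the
#' recurrence threshold selected at a significant-fraction target of 0.9.
#'
#' @inheritParams call_vels
#' @param min_vsels Minimum per-patient VSEL count (default 10).
#' @param target_fraction Significant-fraction target (default 0.9 for
#'   VSELs).
#' @param require_multiple See [call_sample_super_enhancers()].
#' @return A `vel_result` object (type `"vsel"`) whose `se_calls` element
#'   holds the per-sample super-enhancer rankings.
#' @export
call_vsels <- function(cohort, tss, fc_threshold = 2, pseudocount = 0.5,
                       alpha = 0.05, target_fraction = 0.9, min_vsels = 10,
                       stitch_distance = 12500, tss_exclusion = 2500,
                       extension = 200, require_multiple = TRUE) {
  h27 <- h3k27ac_pairs(cohort)
  se_sets <- purrr::pmap(
    list(h27$peaks, h27$fragments, h27$library_size),
    function(p, f, l) {
      se <- call_sample_super_enhancers(
        p, f, l, tss, stitch_distance, tss_exclusion, extension, require_multiple
      )
      se %>% filter(.data$is_super)
    }
  )
  names(se_sets) <- h27$sample_id
  calls <- purrr::map(split(seq_len(nrow(h27)), h27$patient_id), function(rows) {
    sub <- h27[rows, ]
    tum <- sub[sub$tissue == "tumor", ]
    nat <- sub[sub$tissue == "native", ]
    ses <- bind_rows(
      se_sets[[tum$sample_id[1]]][c("chrom", "start", "end")],
      se_sets[[nat$sample_id[1]]][c("chrom", "start", "end")]
    )
    if (nrow(ses) == 0) return(NULL)
    loci <- merge_intervals(ses, gap = 0)
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
  }) %>% bind_rows()
  qc <- calls %>%
    count(.data$patient_id, name = "n_vsels") %>%
    tidyr::complete(patient_id = unique(h27$patient_id), fill = list(n_vsels = 0L)) %>%
    mutate(
      excluded = .data$n_vsels < min_vsels,
      reason = if_else(.data$excluded, "VSEL count below minimum", "")
    )
  retained <- qc$patient_id[!qc$excluded]
  if (length(retained) == 0) abort("all patients excluded by VSEL QC")
  calls_kept <- calls %>% filter(.data$patient_id %in% retained)
  h27_kept <- h27 %>% filter(.data$patient_id %in% retained)
  records <- merge_and_count(calls_kept)
  records <- test_vel_records(records, h27_kept, extension)
  thr <- select_recurrence_threshold(records, alpha, target_fraction)
  records <- records %>%
    left_join(thr$thresholds, by = "direction") %>%
    mutate(significant = !is.na(.data$r_star) & .data$p_adj < alpha &
             .data$recurrence >= .data$r_star) %>%
    select(-"r_star", -"reached")
  structure(
    list(
      records = records, calls = calls_kept, qc = qc, threshold = thr,
      se_calls = se_sets,
      params = list(
        fc_threshold = fc_threshold, pseudocount = pseudocount, alpha = alpha,
        target_fraction = target_fraction, min_vsels = min_vsels,
        stitch_distance = stitch_distance, tss_exclusion = tss_exclusion,
        extension = extension
      ),
      type = "vsel"
    ),
    class = "vel_result"
  )
}

#' Super-enhancer gene recurrence (tumor minus native)
#'
#' Assigns each sample's super-enhancers to genes (nearest TSS within
#' `max_distance`, see [assign_genes()]) and, per gene, counts the number
#' of tumor and native samples whose SE set hits it; the variant recurrence
#' is tumor minus native. Genes never SE-associated are absent.
#'
#' @param se_sets Long interval tibble of per-sample super-enhancers with
#'   `sample_id` and `tissue` columns.
#' @param tss TSS tibble.
#' @param max_distance Maximum SE-midpoint-to-TSS distance (bp, default
#'   5e4).
#' @return A tibble sorted by descending `variant_recurrence`: `gene_id`,
#'   `recurrence_tumor`, `recurrence_native`, `variant_recurrence`.
#' @export
se_gene_recurrence <- function(se_sets, tss, max_distance = 5e4) {
  validate_intervals(se_sets, "se_sets")
  if (!all(c("sample_id", "tissue") %in% names(se_sets))) {
    abort("se_sets needs sample_id and tissue columns")
  }
  if (nrow(se_sets) == 0) {
    return(tibble(
      gene_id = character(), recurrence_tumor = integer(),
      recurrence_native = integer(), variant_recurrence = integer()
    ))
  }
  genes <- assign_genes(se_sets, tss, max_distance)
  hits <- genes %>%
    mutate(
      sample_id = se_sets$sample_id[.data$locus_id],
      tissue = se_sets$tissue[.data$locus_id]
    ) %>%
    distinct(.data$gene_id, .data$sample_id, .data$tissue)
  hits %>%
    count(.data$gene_id, .data$tissue) %>%
    tidyr::pivot_wider(
      names_from = "tissue", values_from = "n", values_fill = 0L,
      names_prefix = "recurrence_"
    ) %>%
    mutate(
      recurrence_tumor = if ("recurrence_tumor" %in% names(.)) .data$recurrence_tumor else 0L,
      recurrence_native = if ("recurrence_native" %in% names(.)) .data$recurrence_native else 0L,
      variant_recurrence = .data$recurrence_tumor - .data$recurrence_native
    ) %>%
    select(all_of(c(
      "gene_id", "recurrence_tumor", "recurrence_native", "variant_recurrence"
    ))) %>%
    arrange(desc(.data$variant_recurrence), .data$gene_id)
}
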