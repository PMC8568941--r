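# Promoter/enhancer classification relative to TSS, cohort-level significant
# elements, saturation curves and locus-to-gene assignment.

tss_windows <- function(tss, window) {
  tibble(
    chrom = tss$chrom,
    start = pmax(tss$start - window, 0L),
    end = tss$start + window
  )
}

#' Classify peaks as promoters or enhancers by TSS proximity
#'
#' A peak is TSS-proximal iff it overlaps any `[tss - window, tss + window)`
#' flank (any-overlap, half-open). H3K4me3 proximal peaks are promoters;
#' H3K27ac peaks with no overlap of any flank are enhancers; everything else
#' is discarded.
#'
#' @param peaks Interval tibble of one sample's peaks.
#' @param mark `"H3K27ac"` or `"H3K4me3"`.
#' @param tss TSS tibble from [read_tss()] (or any width-1 interval tibble
#'   with `gene_id`).
#' @param window Flank half-width in bp (default 2500).
#' @return `peaks` with a `role` column in `promoter`, `enhancer`,
#'   `discarded`.
#' @export
classify_peaks <- function(peaks, mark, tss, window = 2500) {
  validate_intervals(peaks, "peaks")
  stopifnot(window > 0)
  if (is.null(tss) || nrow(tss) == 0) abort("classification needs a non-empty TSS list")
  mark <- match.arg(mark, c("H3K27ac", "H3K4me3"))
  proximal <- rep(FALSE, nrow(peaks))
  if (nrow(peaks) > 0) {
    hits <- find_ov(as_gr(peaks), as_gr(tss_windows(tss, window)))
    proximal[unique(S4Vectors::queryHits(hits))] <- TRUE
  }
  role <- rep("discarded", nrow(peaks))
  if (mark == "H3K4me3") role[proximal] <- "promoter"
  if (mark == "H3K27ac") role[!proximal] <- "enhancer"
  out <- as_tibble(peaks)
  out$role <- role  # overwrite any pre-existing role column
  out
}

# enhancers of one cohort row (internal)
sample_enhancers <- function(peaks, tss, window = 2500) {
  cl <- classify_peaks(peaks, "H3K27ac", tss, window)
  cl %>% filter(.data$role == "enhancer") %>% select(all_of(c("chrom", "start", "end")))
}

#' Cohort-level significant elements
#'
#' Merges all samples' element intervals (gap 0) and keeps each merged locus
#' iff peaks from at least `min_samples` distinct samples overlap it —
#' elements seen in fewer samples are treated as irreproducible and dropped.
#'
#' @param elements Long interval tibble with a `sample_id` column (e.g. all
#'   samples' enhancers from [classify_peaks()]).
#' @param min_samples Minimum number of distinct supporting samples
#'   (default 2).
#' @return Merged loci tibble with a `support` column.
#' @export
significant_elements <- function(elements, min_samples = 2) {
  validate_intervals(elements, "elements")
  if (!"sample_id" %in% names(elements)) abort("`elements` needs a sample_id column")
  merged <- merge_intervals(elements, gap = 0)
  if (nrow(merged) == 0) return(merged %>% mutate(support = integer()))
  supp <- overlap_support(merged, elements, "sample_id")
  merged %>%
    mutate(locus = row_number()) %>%
    left_join(supp, by = "locus") %>%
    mutate(support = dplyr::coalesce(.data$support, 0L)) %>%
    filter(.data$support >= min_samples) %>%
    select(-"locus")
}

#' Enhancer discovery saturation curve
#'
#' For random permutations of the sample order, computes for each prefix of
#' k samples the fraction of reference loci overlapped by the cumulative
#' union of the first k samples' enhancer sets, and averages over
#' permutations. Each per-permutation curve is non-decreasing and, when the
#' reference was built from the same samples, ends at 1.
#'
#' @param elements Long interval tibble with `sample_id` (per-sample
#'   enhancer sets).
#' @param reference Interval tibble of the cohort-level significant set.
#' @param n_permutations Number of random sample orders (default 100).
#' @param seed Integer seed for the permutations.
#' @return A `saturation_curve` tibble with `n_samples` and `frac_discovered`
#'   (mean over permutations, in [0, 1]).
#' @export
saturation_curve <- function(elements, reference, n_permutations = 100, seed = 1) {
  validate_intervals(elements, "elements")
  validate_intervals(reference, "reference")
  stopifnot(n_permutations >= 1)
  if (nrow(reference) == 0) abort("reference set is empty")
  if (!"sample_id" %in% names(elements)) abort("`elements` needs a sample_id column")
  samples <- unique(elements$sample_id)
  n <- length(samples)
  n_ref <- nrow(reference)
  # per sample: which reference loci it touches
  hits <- find_ov(as_gr(reference), as_gr(elements))
  touch <- split(
    S4Vectors::queryHits(hits),
    factor(elements$sample_id[S4Vectors::subjectHits(hits)], levels = samples)
  )
  acc <- matrix(0, nrow = n_permutations, ncol = n)
  withr::with_seed(seed, {
    for (p in seq_len(n_permutations)) {
      ord <- sample(samples)
      seen <- logical(n_ref)
      for (k in seq_len(n)) {
        seen[touch[[ord[k]]]] <- TRUE
        acc[p, k] <- sum(seen) / n_ref
      }
    }
  })
  out <- tibble(n_samples = seq_len(n), frac_discovered = colMeans(acc))
  class(out) <- c("saturation_curve", class(out))
  out
}

#' Assign loci to genes by nearest TSS
#'
#' Each locus is assigned to the gene(s) whose TSS is nearest to the locus
#' midpoint, provided that distance is at most `max_distance`; equidistant
#' TSS all report, sorted by `gene_id`. Loci with no TSS in range are absent
#' from the output.
#'
#' @param loci Interval tibble; row order defines `locus_id`.
#' @param tss TSS tibble (see [read_tss()]).
#' @param max_distance Maximum midpoint-to-TSS distance in bp (default 1e5).
#' @return A tibble with `locus_id`, `gene_id`, `distance`.
#' @export
assign_genes <- function(loci, tss, max_distance = 1e5) {
  validate_intervals(loci, "loci")
  stopifnot(max_distance > 0)
  if (nrow(loci) == 0 || nrow(tss) == 0) {
    return(tibble(locus_id = integer(), gene_id = character(), distance = numeric()))
  }
  mid <- floor((loci$start + loci$end) / 2)
  # candidate pairs on the same chromosome within range, then keep nearest
  cand <- tibble(locus_id = seq_len(nrow(loci)), chrom = loci$chrom, mid = mid) %>%
    inner_join(
      tibble(gene_id = tss$gene_id, chrom = tss$chrom, pos = tss$start),
      by = "chrom", relationship = "many-to-many"
    ) %>%
    mutate(distance = abs(.data$mid - .data$pos)) %>%
    filter(.data$distance <= max_distance)
  cand %>%
    group_by(.data$locus_id) %>%
    filter(.data$distance == min(.data$distance)) %>%
    ungroup() %>%
    arrange(.data$locus_id, .data$gene_id) %>%
    select(all_of(c("locus_id", "gene_id", "distance")))
}
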