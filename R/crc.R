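# Core regulatory circuitry: IN/OUT/total degrees of SE-associated TFs from
# motif hits, tumor-minus-native delta ranking, and a small PWM scanner so
# tests need no external motif software.

#' IN/OUT/total degrees of SE-associated transcription factors
#'
#' For TFi, the IN degree is the number of TFs (self included) with at
#' least one motif hit overlapping any region of TFi (its proximal
#' super-enhancer and promoter); the OUT degree is the number of
#' TF-associated super-enhancer regions containing at least one hit of
#' TFi. Duplicate identical hits do not change degrees (set semantics).
#'
#' @param tf_regions Tibble mapping TFs to their regions: `tf_id`, `chrom`,
#'   `start`, `end` and optional `region_type` (`"se"` or `"promoter"`;
#'   absent means `"se"`). Only `"se"` rows count toward OUT degrees.
#' @param hits Motif-hit tibble: `tf_id` (the TF whose motif matched),
#'   `chrom`, `start`, `end`. Hits of TFs absent from `tf_regions` are
#'   dropped with a warning.
#' @return One row per TF: `tf_id`, `in_degree`, `out_degree`,
#'   `total_degree`.
#' @export
compute_degrees <- function(tf_regions, hits) {
  validate_intervals(tf_regions, "tf_regions")
  validate_intervals(hits, "hits")
  if (!"tf_id" %in% names(tf_regions)) abort("tf_regions needs a tf_id column")
  if (!"tf_id" %in% names(hits)) abort("hits needs a tf_id column")
  tfs <- sort(unique(tf_regions$tf_id))
  unknown <- setdiff(unique(hits$tf_id), tfs)
  if (length(unknown) > 0) {
    warn(paste0("dropping hits of unknown TF(s): ", paste(unknown, collapse = ", ")))
    hits <- hits %>% filter(.data$tf_id %in% tfs)
  }
  region_type <- if ("region_type" %in% names(tf_regions)) {
    tf_regions$region_type
  } else {
    rep("se", nrow(tf_regions))
  }
  ov <- find_ov(as_gr(tf_regions), as_gr(hits))
  edges <- tibble(
    region = S4Vectors::queryHits(ov),
    owner = tf_regions$tf_id[S4Vectors::queryHits(ov)],
    region_is_se = region_type[S4Vectors::queryHits(ov)] == "se",
    hitter = hits$tf_id[S4Vectors::subjectHits(ov)]
  ) %>% distinct()
  in_deg <- edges %>%
    distinct(.data$owner, .data$hitter) %>%
    count(.data$owner, name = "in_degree")
  out_deg <- edges %>%
    filter(.data$region_is_se) %>%
    distinct(.data$hitter, .data$region) %>%
    count(.data$hitter, name = "out_degree")
  tibble(tf_id = tfs) %>%
    left_join(in_deg, by = c(tf_id = "owner")) %>%
    left_join(out_deg, by = c(tf_id = "hitter")) %>%
    mutate(
      in_degree = dplyr::coalesce(.data$in_degree, 0L),
      out_degree = dplyr::coalesce(.data$out_degree, 0L),
      total_degree = .data$in_degree + .data$out_degree
    )
}

#' Directed TF-TF edge list from motif hits
#'
#' Edges `tf_source -> tf_target` where `tf_source` has at least one motif
#' hit within a region of `tf_target`; useful for exporting the circuitry
#' to network tools.
#'
#' @inheritParams compute_degrees
#' @return A tibble with `tf_source`, `tf_target`.
#' @export
crc_edges <- function(tf_regions, hits) {
  validate_intervals(tf_regions, "tf_regions")
  validate_intervals(hits, "hits")
  ov <- find_ov(as_gr(tf_regions), as_gr(hits))
  tibble(
    tf_source = hits$tf_id[S4Vectors::subjectHits(ov)],
    tf_target = tf_regions$tf_id[S4Vectors::queryHits(ov)]
  ) %>%
    distinct() %>%
    arrange(.data$tf_source, .data$tf_target)
}

#' Rank TFs by tumor-minus-native total degree
#'
#' Joins the tumor and native degree tables (TFs missing in one group score
#' 0) and sorts by `delta = total_tumor - total_native`, descending, ties
#' broken by `tf_id`.
#'
#' @param nodes_tumor,nodes_native Degree tibbles from [compute_degrees()].
#' @param top_k Optionally keep only the `top_k` largest deltas.
#' @return A tibble with `tf_id`, `total_tumor`, `total_native`, `delta`.
#' @export
rank_delta <- function(nodes_tumor, nodes_native, top_k = NULL) {
  out <- full_join(
    nodes_tumor %>% select(all_of(c("tf_id", "total_degree"))) %>%
      rename(total_tumor = "total_degree"),
    nodes_native %>% select(all_of(c("tf_id", "total_degree"))) %>%
      rename(total_native = "total_degree"),
    by = "tf_id"
  ) %>%
    mutate(
      total_tumor = dplyr::coalesce(.data$total_tumor, 0L),
      total_native = dplyr::coalesce(.data$total_native, 0L),
      delta = .data$total_tumor - .data$total_native
    ) %>%
    arrange(desc(.data$delta), .data$tf_id)
  if (!is.null(top_k)) out <- out %>% slice(seq_len(min(top_k, dplyr::n())))
  out
}

#' Scan a sequence with a position probability matrix
#'
#' Log2-odds scoring against a uniform background on both strands: at each
#' offset the forward score is `sum(log2(p[base_i, i] / 0.25))` and the
#' reverse score is the same on the reverse complement; `N` positions
#' contribute 0. A hit requires a score of at least `threshold_fraction`
#' times the maximum achievable score.
#'
#' @param sequence A single string over `A`, `C`, `G`, `T`, `N`.
#' @param pwm 4 x L numeric matrix of position probabilities, rows named
#'   `A`, `C`, `G`, `T`, columns summing to 1 (tolerance 1e-6).
#' @param threshold_fraction Fraction of the maximal score required for a
#'   hit (in (0, 1]).
#' @return A tibble of hits with 0-based `offset` (position of the motif
#'   window on the forward sequence), `strand` and `score`; empty when the
#'   sequence is shorter than the motif.
#' @export
scan_pwm <- function(sequence, pwm, threshold_fraction = 0.8) {
  stopifnot(is.character(sequence), length(sequence) == 1)
  stopifnot(is.matrix(pwm), nrow(pwm) == 4)
  if (is.null(rownames(pwm))) rownames(pwm) <- c("A", "C", "G", "T")
  pwm <- pwm[c("A", "C", "G", "T"), , drop = FALSE]
  if (any(abs(colSums(pwm) - 1) > 1e-6)) abort("pwm columns must sum to 1")
  stopifnot(threshold_fraction > 0, threshold_fraction <= 1)
  L <- ncol(pwm)
  chars <- strsplit(toupper(sequence), "")[[1]]
  if (!all(chars %in% c("A", "C", "G", "T", "N"))) {
    abort("sequence must be over A, C, G, T, N")
  }
  empty <- tibble(offset = integer(), strand = character(), score = numeric())
  if (length(chars) < L) return(empty)
  lo <- log2(pwm / 0.25)  # -Inf where the column excludes a base
  max_score <- sum(apply(lo, 2, max))
  threshold <- threshold_fraction * max_score
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  n_off <- length(chars) - L + 1L
  score_at <- function(window, mat) {
    sum(vapply(seq_len(L), function(i) {
      if (window[i] == "N") 0 else mat[window[i], i]
    }, 0))
  }
  out <- purrr::map_dfr(seq_len(n_off) - 1L, function(off) {
    window <- chars[(off + 1):(off + L)]
    fwd <- score_at(window, lo)
    rev_window <- rev(unname(comp[window]))
    rvs <- score_at(rev_window, lo)
    res <- empty
    if (fwd >= threshold) res <- bind_rows(res, tibble(offset = off, strand = "+", score = fwd))
    if (rvs >= threshold) res <- bind_rows(res, tibble(offset = off, strand = "-", score = rvs))
    res
  })
  out %>% arrange(.data$offset, .data$strand)
}
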