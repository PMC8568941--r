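# H3K27ac signal quantification: fragment extension and RPM.

#' Extend fragments 3'-ward into fixed footprints
#'
#' Each aligned fragment is replaced by its extended footprint: `extension`
#' bp running 3'-ward from the fragment's 5' start (`+` or unknown strand:
#' `[start, start + extension)`; `-` strand: `[end - extension, end)`,
#' clipped at 0). With `extension = 0` the fragment interval is kept as is.
#'
#' @param fragments Interval tibble of fragments, optionally with `strand`.
#' @param extension Extension length in bp (default 200).
#' @return An interval tibble of footprints, same row order.
#' @export
extend_fragments <- function(fragments, extension = 200) {
  validate_intervals(fragments, "fragments")
  stopifnot(extension >= 0)
  if (extension == 0 || nrow(fragments) == 0) {
    return(as_tibble(fragments)[c("chrom", "start", "end")])
  }
  strand <- if ("strand" %in% names(fragments)) as.character(fragments$strand) else "+"
  minus <- !is.na(strand) & strand == "-"
  start <- ifelse(minus, pmax(fragments$end - extension, 0L), fragments$start)
  end <- ifelse(minus, fragments$end, fragments$start + extension)
  tibble(chrom = fragments$chrom, start = as.integer(start), end = as.integer(end))
}

# total extended-footprint coverage (bp) of each locus (internal)
overlap_bp <- function(loci, footprints) {
  gl <- as_gr(loci)
  gf <- as_gr(footprints)
  hits <- find_ov(gl, gf)
  if (length(hits) == 0) return(numeric(nrow(loci)))
  w <- GenomicRanges::width(IRanges::pintersect(
    IRanges::ranges(gl)[S4Vectors::queryHits(hits)],
    IRanges::ranges(gf)[S4Vectors::subjectHits(hits)]
  ))
  out <- numeric(nrow(loci))
  agg <- tapply(w, S4Vectors::queryHits(hits), sum)
  out[as.integer(names(agg))] <- as.numeric(agg)
  out
}

#' Region H3K27ac signal in RPM
#'
#' Mean per-bp extended-fragment coverage of each region, normalised per
#' million mapped reads: fragments are extended 3'-ward by `extension` bp
#' (see [extend_fragments()]), base overlaps with the region are summed,
#' divided by region length to give a mean per-bp read density, and scaled
#' by `1e6 / library_size`. The per-bp mean (not the region sum) makes
#' values comparable across loci of different lengths.
#'
#' @param loci Interval tibble of query regions.
#' @param fragments Interval tibble of aligned fragments (with `strand`).
#' @param library_size Total mapped reads of the sample (> 0).
#' @param extension Fragment extension in bp (default 200).
#' @return Numeric vector of RPM values, one per row of `loci`.
#' @export
compute_rpm <- function(loci, fragments, library_size, extension = 200) {
  validate_intervals(loci, "loci")
  if (nrow(loci) > 0 && any(loci$end - loci$start <= 0)) abort("zero-length region")
  stopifnot(length(library_size) == 1, library_size > 0)
  if (nrow(loci) == 0) return(numeric(0))
  if (nrow(fragments) == 0) return(numeric(nrow(loci)))
  fp <- extend_fragments(fragments, extension)
  bp <- overlap_bp(loci, fp)
  bp / (loci$end - loci$start) * 1e6 / library_size
}

# region-summed RPM: total extended coverage (bp) per million mapped reads;
# ranks long high-signal clusters above short ones (ROSE convention)
compute_rpm_sum <- function(loci, fragments, library_size, extension = 200) {
  rpm <- compute_rpm(loci, fragments, library_size, extension)
  rpm * (loci$end - loci$start)
}

# ---- cohort tables ----------------------------------------------------------
# A cohort is a tibble with one row per ChIP-seq sample:
#   sample_id, patient_id, tissue ("tumor"/"native"), mark, cms, library_size,
#   peaks (list of interval tibbles), fragments (list of interval tibbles).

validate_cohort <- function(cohort) {
  need <- c("sample_id", "patient_id", "tissue", "mark", "library_size", "peaks", "fragments")
  missing_cols <- setdiff(need, names(cohort))
  if (length(missing_cols) > 0) {
    abort(paste0("cohort lacks column(s): ", paste(missing_cols, collapse = ", ")))
  }
  if (!all(cohort$tissue %in% c("tumor", "native"))) {
    abort("cohort$tissue must be 'tumor' or 'native'")
  }
  if (any(cohort$library_size <= 0)) abort("library_size must be positive")
  dup <- cohort %>%
    count(.data$patient_id, .data$tissue, .data$mark) %>%
    filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort(paste0(
      "ambiguous pairing: patient ", dup$patient_id[1], " has ", dup$n[1],
      " ", dup$tissue[1], " samples of mark ", dup$mark[1]
    ))
  }
  invisible(cohort)
}

#' Read a sample sheet
#'
#' Tab-separated, headered, with columns `sample_id`, `patient_id`, `tissue`
#' (`tumor`/`native`), `mark`, `path_peaks`, `path_fragments` and optional
#' `library_size` (defaults to the fragment count of the tagAlign file) and
#' `cms` subgroup label.
#'
#' @param path Path to the TSV.
#' @return A tibble, one row per sample.
#' @export
read_sample_sheet <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("sample_id", "patient_id", "tissue", "mark", "path_peaks", "path_fragments")
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols) > 0) {
    abort(paste0("sample sheet lacks column(s): ", paste(missing_cols, collapse = ", ")))
  }
  x
}

#' Load a cohort from a sample sheet
#'
#' Reads each sample's peak and fragment files (relative paths resolved
#' against the sheet's directory) into a cohort tibble with `peaks` and
#' `fragments` list-columns.
#'
#' @param sheet Path to a sample-sheet TSV, or the tibble from
#'   [read_sample_sheet()] (then `dir` locates the files).
#' @param dir Directory against which relative paths are resolved.
#' @return A cohort tibble.
#' @export
load_cohort <- function(sheet, dir = NULL) {
  if (is.character(sheet)) {
    if (is.null(dir)) dir <- dirname(sheet)
    sheet <- read_sample_sheet(sheet)
  }
  if (is.null(dir)) dir <- "."
  resolve <- function(p) ifelse(grepl("^/", p), p, file.path(dir, p))
  peaks <- purrr::map(resolve(sheet$path_peaks), read_bed)
  frags <- purrr::map(resolve(sheet$path_fragments), read_tagalign)
  lib <- if ("library_size" %in% names(sheet)) {
    as.numeric(sheet$library_size)
  } else {
    vapply(frags, nrow, 0L)
  }
  cohort <- tibble(
    sample_id = as.character(sheet$sample_id),
    patient_id = as.character(sheet$patient_id),
    tissue = as.character(sheet$tissue),
    mark = as.character(sheet$mark),
    cms = if ("cms" %in% names(sheet)) as.character(sheet$cms) else NA_character_,
    library_size = lib,
    peaks = peaks,
    fragments = frags
  )
  validate_cohort(cohort)
  cohort
}

#' Build a loci-by-samples signal matrix in long form
#'
#' Computes [compute_rpm()] for every locus in every sample of the cohort and
#' returns a long tibble (one row per locus-sample combination) carrying the
#' pairing metadata. Errors if a patient has two tumor or two native samples
#' of the same mark.
#'
#' @param cohort Cohort tibble (see [load_cohort()] or [simulate_cohort()]).
#' @param loci Interval tibble; row order defines `locus_id`.
#' @param extension Fragment extension in bp.
#' @return A tibble with `locus_id`, `chrom`, `start`, `end`, `sample_id`,
#'   `patient_id`, `tissue`, `cms`, `rpm`.
#' @export
build_signal_matrix <- function(cohort, loci, extension = 200) {
  validate_cohort(cohort)
  validate_intervals(loci, "loci")
  if (nrow(loci) == 0) abort("loci must be non-empty")
  if (length(unique(cohort$mark)) > 1) {
    abort("all tracks in a signal matrix must share the mark")
  }
  loci <- as_tibble(loci)[c("chrom", "start", "end")] %>%
    mutate(locus_id = row_number(), .before = 1)
  per_sample <- purrr::pmap(
    list(cohort$sample_id, cohort$fragments, cohort$library_size),
    function(sid, frags, lib) {
      tibble(
        locus_id = loci$locus_id, sample_id = sid,
        rpm = compute_rpm(loci, frags, lib, extension)
      )
    }
  )
  meta <- cohort %>% select(all_of(c("sample_id", "patient_id", "tissue")), any_of_cms(cohort))
  bind_rows(per_sample) %>%
    left_join(loci, by = "locus_id") %>%
    left_join(meta, by = "sample_id") %>%
    select(all_of(c("locus_id", "chrom", "start", "end", "sample_id",
                    "patient_id", "tissue")), everything())
}

any_of_cms <- function(cohort) {
  if ("cms" %in% names(cohort)) "cms" else character()
}
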