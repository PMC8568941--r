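#' @importFrom dplyr %>% arrange bind_rows count distinct filter group_by left_join
#'   mutate n n_distinct pull rename row_number select slice summarise ungroup
#'   across all_of everything inner_join anti_join full_join first desc if_else
#' @importFrom rlang .data abort warn .env
#' @importFrom tibble tibble as_tibble is_tibble
NULL

# ---- interval tibbles -------------------------------------------------------
# All loci in the package are rows of a tibble with columns chrom / start / end
# in 0-based half-open coordinates (BED convention), optionally strand.

#' Validate an interval tibble
#'
#' Checks that `x` has `chrom`, `start`, `end` columns with 0-based half-open
#' coordinates satisfying `start >= 0`, `end > start` and non-empty `chrom`.
#'
#' @param x A data frame of intervals.
#' @param arg Name used in error messages.
#' @return `x` invisibly, as a tibble.
#' @export
validate_intervals <- function(x, arg = "x") {
  if (!is.data.frame(x)) abort(paste0("`", arg, "` must be a data frame of intervals"))
  missing_cols <- setdiff(c("chrom", "start", "end"), names(x))
  if (length(missing_cols) > 0) {
    abort(paste0("`", arg, "` lacks interval column(s): ", paste(missing_cols, collapse = ", ")))
  }
  x <- as_tibble(x)
  if (nrow(x) == 0) return(invisible(x))
  if (any(is.na(x$chrom) | !nzchar(as.character(x$chrom)))) {
    abort(paste0("`", arg, "` has empty chromosome names"))
  }
  if (any(x$start < 0)) abort(paste0("`", arg, "` has negative start coordinates"))
  if (any(x$end <= x$start)) abort(paste0("`", arg, "` has end <= start (degenerate interval)"))
  invisible(x)
}

# interval tibble -> GRanges (internal). 0-based half-open -> 1-based closed.
as_gr <- function(x) {
  strand <- if ("strand" %in% names(x)) {
    s <- as.character(x$strand)
    s[is.na(s) | !(s %in% c("+", "-"))] <- "*"
    s
  } else "*"
  if (nrow(x) == 0) return(GenomicRanges::GRanges())
  chrom <- as.character(x$chrom)
  GenomicRanges::GRanges(
    seqnames = factor(chrom, levels = sort(unique(chrom))),
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end),
    strand = strand
  )
}

# GRanges -> interval tibble
gr_tbl <- function(gr) {
  tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr)
  )
}

# ---- readers ----------------------------------------------------------------

bed_skip <- function(lines) {
  grepl("^(track|browser|#)", lines) | !nzchar(trimws(lines))
}

#' Read a BED-style file of genomic intervals
#'
#' Reads BED3/BED6 (and wider) files into an interval tibble. Coordinates are
#' kept 0-based half-open as in the file. `track`, `browser`, comment and
#' blank lines are skipped. Columns beyond the sixth are ignored.
#'
#' @param path Path to the file.
#' @param min_columns Minimum number of tab-separated fields each data line
#'   must have (default 3).
#' @return A tibble with `chrom`, `start`, `end` and, when present, `name`,
#'   `score`, `strand`, in file order.
#' @export
read_bed <- function(path, min_columns = 3) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  keep <- !bed_skip(lines)
  idx <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < min_columns)) {
    bad <- idx[which(nf < min_columns)[1]]
    abort(paste0("line ", bad, " of ", path, " has fewer than ", min_columns, " fields"))
  }
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3L)))
  bad <- which(is.na(start) | is.na(end) | end <= start | start < 0)
  if (length(bad) > 0) {
    abort(paste0(
      "line ", idx[bad[1]], " of ", path,
      " is malformed (non-integer coordinates or end <= start)"
    ))
  }
  out <- tibble(chrom = vapply(fields, `[[`, "", 1L), start = start, end = end)
  if (all(nf >= 4)) out$name <- vapply(fields, `[[`, "", 4L)
  if (all(nf >= 5)) out$score <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 5L)))
  if (all(nf >= 6)) out$strand <- vapply(fields, `[[`, "", 6L)
  out
}

#' Read a narrowPeak file
#'
#' narrowPeak is BED6+4; the first six columns are parsed as by [read_bed()]
#' and column 7 (signalValue) is retained as `peak_score`.
#'
#' @inheritParams read_bed
#' @return An interval tibble with `peak_score` when column 7 is present.
#' @export
read_narrowpeak <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!bed_skip(lines)]
  out <- read_bed(path, min_columns = 3)
  if (nrow(out) > 0 && length(lines) > 0) {
    fields <- strsplit(lines, "\t", fixed = TRUE)
    if (all(lengths(fields) >= 7)) {
      out$peak_score <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 7L)))
    }
  }
  out
}

#' Read a tagAlign file of aligned fragments
#'
#' tagAlign is BED6 with one row per aligned read/fragment; `strand` is
#' required downstream for 3'-ward extension and defaults to `+` when absent.
#'
#' @inheritParams read_bed
#' @return An interval tibble with a `strand` column.
#' @export
read_tagalign <- function(path) {
  x <- read_bed(path, min_columns = 3)
  if (!"strand" %in% names(x)) x$strand <- "+"
  x
}

#' Read TSS annotation
#'
#' Accepts BED6 (name column = gene id) or a two-column TSV of
#' `gene_id <tab> position` plus optional `chrom` handling; for the TSV form
#' the columns must be `gene_id`, `chrom`, `pos` with a header. Each TSS is a
#' width-1 interval at the transcription start.
#'
#' @param path Path to a BED6 file or a headered TSV.
#' @return A tibble with `gene_id`, `chrom`, `start`, `end` (width 1) and
#'   `strand`.
#' @export
read_tss <- function(path) {
  first <- readLines(path, n = 1, warn = FALSE)
  if (grepl("gene_id", first)) {
    x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
    if (!all(c("gene_id", "chrom", "pos") %in% names(x))) {
      abort("TSS TSV must have columns gene_id, chrom, pos")
    }
    out <- tibble(
      gene_id = as.character(x$gene_id), chrom = as.character(x$chrom),
      start = as.integer(x$pos), end = as.integer(x$pos) + 1L,
      strand = if ("strand" %in% names(x)) x$strand else "+"
    )
  } else {
    x <- read_bed(path, min_columns = 4)
    out <- tibble(
      gene_id = x$name, chrom = x$chrom, start = x$start, end = x$end,
      strand = if ("strand" %in% names(x)) x$strand else "+"
    )
  }
  if (any(out$end - out$start != 1L)) abort("TSS records must have width exactly 1")
  validate_intervals(out, "tss")
  out
}

#' Write intervals as BED
#'
#' Writes `chrom`, `start`, `end` and, when present, `name`, `score`,
#' `strand` as tab-separated BED. Coordinates are written 0-based half-open,
#' so [read_bed()] round-trips exactly.
#'
#' @param x Interval tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  validate_intervals(x)
  cols <- intersect(c("chrom", "start", "end", "name", "score", "strand"), names(x))
  # BED columns are positional: stop at the first absent one
  keep <- character()
  for (col in c("chrom", "start", "end", "name", "score", "strand")) {
    if (!col %in% cols) break
    keep <- c(keep, col)
  }
  utils::write.table(
    as.data.frame(x[keep]), path,
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  invisible(path)
}

# ---- merge ------------------------------------------------------------------

#' Merge genomic intervals
#'
#' Unions intervals on the same chromosome whose separation is at most `gap`
#' base pairs. With `gap = 0` this is the plain union of overlapping or
#' abutting intervals.
#'
#' @param x Interval tibble (may be unsorted).
#' @param gap Maximum separation (bp, >= 0) for two intervals to be fused.
#' @return A tibble of merged intervals sorted by (`chrom`, `start`).
#' @export
merge_intervals <- function(x, gap = 0) {
  validate_intervals(x)
  stopifnot(gap >= 0)
  if (nrow(x) == 0) return(tibble(chrom = character(), start = integer(), end = integer()))
  gr <- GenomicRanges::reduce(as_gr(x), min.gapwidth = gap + 1L, ignore.strand = TRUE)
  gr <- GenomicRanges::sort(gr, ignore.strand = TRUE)
  gr_tbl(gr)
}

# findOverlaps without the disjoint-seqlevel warning (internal)
find_ov <- function(a, b) {
  suppressWarnings(GenomicRanges::findOverlaps(a, b, ignore.strand = TRUE))
}

# count, per interval of `loci`, how many distinct values of `by` among
# overlapping rows of `x` (internal)
overlap_support <- function(loci, x, by) {
  hits <- find_ov(as_gr(loci), as_gr(x))
  tibble(
    locus = S4Vectors::queryHits(hits),
    who = x[[by]][S4Vectors::subjectHits(hits)]
  ) %>%
    distinct() %>%
    count(.data$locus, name = "support")
}
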