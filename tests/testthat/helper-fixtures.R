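# shared fixture builders and independent brute-force oracles

iv <- function(chrom, start, end) {
  tibble::tibble(chrom = chrom, start = as.integer(start), end = as.integer(end))
}

frags_at <- function(chrom, starts, len = 50, strand = "+") {
  tibble::tibble(
    chrom = chrom, start = as.integer(starts), end = as.integer(starts) + len,
    strand = strand
  )
}

# brute-force gap-closed union by enumerating base positions
brute_merge <- function(x, gap = 0) {
  out <- list()
  for (ch in sort(unique(x$chrom))) {
    sub <- x[x$chrom == ch, ]
    covered <- sort(unique(unlist(Map(function(s, e) s:(e - 1), sub$start, sub$end))))
    runs <- split(covered, cumsum(c(1, diff(covered) > gap + 1)))
    for (r in runs) out[[length(out) + 1]] <- iv(ch, min(r), max(r) + 1)
  }
  dplyr::arrange(dplyr::bind_rows(out), chrom, start)
}

# brute-force BH step-up
brute_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  sorted <- p[ord]
  adj <- numeric(m)
  running <- Inf
  for (i in m:1) {
    running <- min(running, sorted[i] * m / i)
    adj[i] <- min(running, 1)
  }
  out <- numeric(m)
  out[ord] <- adj
  out
}

# hand-built 1-sample track: one peak per locus, count fragments fully inside
toy_track <- function(sample_id, patient_id, tissue, loci, counts,
                      lib = 1e6, mark = "H3K27ac", cms = NA_character_) {
  frag_list <- purrr::pmap(
    list(loci$chrom, loci$start, counts),
    function(ch, st, n) {
      if (n == 0) return(frags_at(character(), integer()))
      frags_at(ch, rep(st + 10L, n))
    }
  )
  tibble::tibble(
    sample_id = sample_id, patient_id = patient_id, tissue = tissue, mark = mark,
    cms = cms, library_size = lib,
    peaks = list(loci[rep(TRUE, nrow(loci)), c("chrom", "start", "end")][counts > 0, ]),
    fragments = list(dplyr::bind_rows(frag_list))
  )
}

# paired toy cohort: counts matrices loci x patients for tumor and native
toy_cohort <- function(loci, counts_tumor, counts_native, lib = 1e6,
                       cms = NULL) {
  n_pat <- ncol(counts_tumor)
  patients <- sprintf("P%02d", seq_len(n_pat))
  rows <- purrr::map(seq_len(n_pat), function(j) {
    dplyr::bind_rows(
      toy_track(paste0(patients[j], "T"), patients[j], "tumor", loci,
                counts_tumor[, j], lib,
                cms = if (is.null(cms)) NA_character_ else cms[j]),
      toy_track(paste0(patients[j], "N"), patients[j], "native", loci,
                counts_native[, j], lib,
                cms = if (is.null(cms)) NA_character_ else cms[j])
    )
  })
  dplyr::bind_rows(rows)
}

# TSS far away from everything on a spare chromosome
far_tss <- function() {
  tibble::tibble(gene_id = "FAR", chrom = "chrZ", start = 1000L, end = 1001L,
                 strand = "+")
}
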