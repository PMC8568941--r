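# Synthetic paired tumor/native H3K27ac cohort generator with planted
# variant enhancer loci, super-enhancer clusters and subgroup structure;
# the ground truth is returned alongside so every pipeline stage can be
# validated without external data.

#' Simulation configuration
#'
#' Defaults describe a paired cohort of 40 patients over a 4 x 30 Mb toy
#' genome with 2,000 enhancers, 200 planted gain and 50 planted lost VELs
#' at a 3x tumor:native signal ratio carried by 75% of patients, and 10
#' planted super-enhancer clusters (3 peaks within a 10 kb span at 10x
#' base signal) of which 6 gain 3x in carrier tumors. Counts are
#' negative-binomial with gamma-mixture dispersion `nb_dispersion`
#' (variance `mu + nb_dispersion * mu^2`) to emulate inter-patient
#' biological variability.
#'
#' @param seed Integer seed; all output is reproducible from (seed,
#'   config).
#' @param n_patients Number of tumor/native pairs.
#' @param genome Tibble with `chrom`, `length` (bp).
#' @param n_enhancers Number of ordinary enhancer loci.
#' @param n_tss Number of annotated TSS (genes) beyond the per-cluster
#'   super-enhancer genes.
#' @param enhancer_width Width of each enhancer locus (bp).
#' @param doublet_fraction Fraction of ordinary enhancer loci placed as
#'   2-peak clusters under 12.5 kb apart (clustered enhancers, so stitched
#'   multi-peak regions exist outside the planted clusters).
#' @param planted_gain,planted_lost Numbers of planted gain / lost VELs.
#' @param effect_ratio Tumor:native signal ratio at planted gain loci
#'   (lost loci use its reciprocal); 1 disables the planted effect.
#' @param recurrence_fraction Share of patients carrying each planted VEL;
#'   carriers are drawn exactly (`ceiling(fraction * n_patients)` per
#'   locus), not binomially.
#' @param n_planted_ses Number of planted super-enhancer clusters.
#' @param n_se_gain How many clusters gain `effect_ratio`-fold in carrier
#'   tumors (default 6, capped at `n_planted_ses`).
#' @param se_peaks Constituent peaks per cluster.
#' @param se_span Span containing the cluster's peaks (bp, <= 12.5 kb).
#' @param se_signal_multiplier Signal multiple of base rate at cluster
#'   peaks.
#' @param subgroups Named numeric vector of subgroup shares summing to 1
#'   (patient labels, e.g. CMS1-4).
#' @param n_subgroup_specific Loci per subgroup elevated by
#'   [plant_subgroup_signal()].
#' @param subgroup_effect Mean multiple applied to those loci in the
#'   target subgroup's tumors (>= 2 recommended).
#' @param nb_dispersion Negative-binomial dispersion (0 gives Poisson).
#' @param base_rate Expected fragments per ordinary enhancer per sample.
#' @param detection_floor Minimum fragment count for a locus to be emitted
#'   in a sample's peak set (peak-caller sensitivity stand-in).
#' @param read_length Nominal read length (bp) of emitted fragments.
#' @param library_size Total mapped reads per sample (default 2e5): each
#'   sample is topped up to this depth with uniform genome-wide background
#'   fragments, so library sizes are equal across samples (sequencing to
#'   fixed depth) and RPM normalisation does not import composition bias
#'   from the planted signal. `NA` bookkeeps the emitted count instead.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1,
                       n_patients = 40,
                       genome = tibble(chrom = paste0("chr", 1:4), length = 3e7),
                       n_enhancers = 2000,
                       n_tss = 400,
                       enhancer_width = 1000,
                       doublet_fraction = 0.3,
                       planted_gain = 200,
                       planted_lost = 50,
                       effect_ratio = 3,
                       recurrence_fraction = 0.75,
                       n_planted_ses = 10,
                       n_se_gain = NULL,
                       se_peaks = 3,
                       se_span = 10000,
                       se_signal_multiplier = 10,
                       subgroups = c(CMS1 = 0.25, CMS2 = 0.25, CMS3 = 0.25, CMS4 = 0.25),
                       n_subgroup_specific = 2,
                       subgroup_effect = 2.5,
                       nb_dispersion = 0.05,
                       base_rate = 50,
                       detection_floor = 5,
                       read_length = 50,
                       library_size = 2e5) {
  if (is.null(n_se_gain)) n_se_gain <- min(6L, n_planted_ses)
  cfg <- list(
    seed = seed, n_patients = n_patients, genome = as_tibble(genome),
    n_enhancers = n_enhancers, n_tss = n_tss, enhancer_width = enhancer_width,
    doublet_fraction = doublet_fraction, planted_gain = planted_gain,
    planted_lost = planted_lost, effect_ratio = effect_ratio,
    recurrence_fraction = recurrence_fraction, n_planted_ses = n_planted_ses,
    n_se_gain = n_se_gain, se_peaks = se_peaks, se_span = se_span,
    se_signal_multiplier = se_signal_multiplier, subgroups = subgroups,
    n_subgroup_specific = n_subgroup_specific, subgroup_effect = subgroup_effect,
    nb_dispersion = nb_dispersion, base_rate = base_rate,
    detection_floor = detection_floor, read_length = read_length,
    library_size = library_size
  )
  stopifnot(
    n_patients >= 1, n_enhancers >= 0, planted_gain >= 0, planted_lost >= 0,
    planted_gain + planted_lost <= n_enhancers,
    effect_ratio >= 1, recurrence_fraction > 0, recurrence_fraction <= 1,
    n_se_gain <= n_planted_ses, se_span <= 12500, nb_dispersion >= 0,
    base_rate > 0, doublet_fraction >= 0, doublet_fraction <= 1
  )
  if (!is.null(subgroups) && abs(sum(subgroups) - 1) > 1e-8) {
    abort("subgroup shares must sum to 1")
  }
  structure(cfg, class = "sim_config")
}

# anchor stride of the placement grid; ordinary loci on distinct anchors can
# never merge (gap 0) or stitch (12.5 kb) with each other
.sim_stride <- 20000L

#' Simulate a paired tumor/native H3K27ac cohort
#'
#' Places TSS and enhancer loci on a slotted grid (uniformly shuffled
#' anchors, all loci outside TSS +/- 2.5 kb and mutually non-overlapping),
#' draws per-locus per-sample fragment counts from a negative binomial
#' whose mean is `base_rate` times the locus effect (planted gains:
#' `effect_ratio` in carrier tumors; planted losses: its reciprocal;
#' super-enhancer peaks: `se_signal_multiplier`, gaining clusters
#' additionally `effect_ratio` in carrier tumors), scatters that many
#' extended-read 5' positions uniformly within each locus +/- 100 bp, and
#' emits a sample's peak call for every locus whose count reaches the
#' detection floor. Deterministic given the config seed; the caller's RNG
#' state is left untouched.
#'
#' @param config A [sim_config()] object.
#' @return A `sim_cohort` list: `cohort` (cohort tibble), `tss` (TSS
#'   tibble), `truth` (planted loci with carriers, SE clusters, subgroup
#'   assignments, patient table) and `config`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, simulate_cohort_impl(config))
}

simulate_cohort_impl <- function(cfg) {
  stride <- .sim_stride
  anchors <- purrr::pmap_dfr(cfg$genome, function(chrom, length) {
    pos <- seq(50000L, length - 60000L, by = stride)
    tibble(chrom = chrom, pos = as.integer(pos))
  })
  anchors <- anchors[sample(nrow(anchors)), ]

  # planted SE clusters first: anchors mutually >= 3 strides apart, each
  # reserving its own anchor plus flanking strides so the cluster stitches
  # alone and its gene TSS stays clear of other loci
  n_se <- cfg$n_planted_ses
  se_rows <- integer()
  if (n_se > 0) {
    for (k in seq_len(nrow(anchors))) {
      if (length(se_rows) == n_se) break
      ok <- TRUE
      for (r in se_rows) {
        if (anchors$chrom[k] == anchors$chrom[r] &&
            abs(anchors$pos[k] - anchors$pos[r]) < 3L * stride) {
          ok <- FALSE
          break
        }
      }
      if (ok) se_rows <- c(se_rows, k)
    }
    if (length(se_rows) < n_se) abort("genome too small to place loci without overlap")
  }
  se_anchor <- anchors[se_rows, , drop = FALSE]
  if (n_se > 0) {
    blocked <- purrr::map2(se_anchor$chrom, se_anchor$pos, function(ch, p) {
      tibble(chrom = ch, pos = as.integer(p + c(-stride, 0L, stride)))
    }) %>% bind_rows()
    anchors <- anti_join(anchors, blocked, by = c("chrom", "pos"))
  }

  n_doublet_loci <- 2L * floor(cfg$doublet_fraction * cfg$n_enhancers / 2)
  n_pairs <- n_doublet_loci / 2L
  n_single <- cfg$n_enhancers - n_doublet_loci
  n_needed <- cfg$n_tss + n_single + n_pairs
  if (nrow(anchors) < n_needed) {
    abort("genome too small to place loci without overlap")
  }
  tss_anchor <- anchors[seq_len(cfg$n_tss), , drop = FALSE]
  enh_anchor <- anchors[cfg$n_tss + seq_len(n_single + n_pairs), , drop = FALSE]

  w <- cfg$enhancer_width
  single <- enh_anchor[seq_len(n_single), , drop = FALSE]
  pairs <- enh_anchor[n_single + seq_len(n_pairs), , drop = FALSE]
  enh <- bind_rows(
    tibble(chrom = single$chrom, start = single$pos, end = single$pos + w),
    tibble(chrom = pairs$chrom, start = pairs$pos, end = pairs$pos + w),
    tibble(chrom = pairs$chrom, start = pairs$pos + w + 3000L,
           end = pairs$pos + 2L * w + 3000L)
  )

  # cluster peaks spread evenly across the span
  se_loci <- NULL
  if (n_se > 0) {
    offsets <- as.integer(round(seq(0, cfg$se_span - w, length.out = cfg$se_peaks)))
    se_loci <- purrr::map_dfr(seq_len(n_se), function(i) {
      tibble(
        chrom = se_anchor$chrom[i],
        start = se_anchor$pos[i] + offsets,
        end = se_anchor$pos[i] + offsets + w,
        se_cluster = i
      )
    })
  }

  planted_idx <- sample(nrow(enh), cfg$planted_gain + cfg$planted_lost)
  role <- rep("background", nrow(enh))
  role[planted_idx[seq_len(cfg$planted_gain)]] <- "gain"
  if (cfg$planted_lost > 0) {
    role[planted_idx[cfg$planted_gain + seq_len(cfg$planted_lost)]] <- "lost"
  }

  loci <- bind_rows(
    enh %>% mutate(role = role, se_cluster = NA_integer_),
    if (!is.null(se_loci)) se_loci %>% mutate(role = "se_constituent", .before = "se_cluster")
  ) %>%
    mutate(locus_id = row_number(), .before = 1)

  patients <- sprintf("P%02d", seq_len(cfg$n_patients))
  n_carrier <- ceiling(cfg$recurrence_fraction * cfg$n_patients)
  carriers <- vector("list", nrow(loci))
  for (i in which(loci$role %in% c("gain", "lost"))) {
    carriers[[i]] <- sort(sample(patients)[seq_len(n_carrier)])
  }
  gaining_clusters <- sort(sample(n_se)[seq_len(min(cfg$n_se_gain, n_se))])
  se_carriers <- purrr::map(seq_len(n_se), function(i) {
    if (i %in% gaining_clusters) sort(sample(patients)[seq_len(n_carrier)]) else character()
  })
  for (i in which(loci$role == "se_constituent")) {
    carriers[[i]] <- se_carriers[[loci$se_cluster[i]]]
  }
  loci$carriers <- carriers

  # subgroup labels per patient
  cms <- NULL
  if (!is.null(cfg$subgroups)) {
    counts <- floor(cfg$subgroups * cfg$n_patients)
    rest <- cfg$n_patients - sum(counts)
    if (rest > 0) counts[seq_len(rest)] <- counts[seq_len(rest)] + 1
    cms <- sample(rep(names(cfg$subgroups), counts))
  }
  patient_tbl <- tibble(
    patient_id = patients,
    cms = if (is.null(cms)) NA_character_ else cms
  )

  # per-locus per-sample count means
  samples <- tibble(
    sample_id = c(paste0(patients, "T"), paste0(patients, "N")),
    patient_id = rep(patients, 2),
    tissue = rep(c("tumor", "native"), each = cfg$n_patients)
  ) %>% arrange(.data$patient_id, desc(.data$tissue))
  mult <- matrix(1, nrow = nrow(loci), ncol = nrow(samples))
  is_se <- loci$role == "se_constituent"
  mult[is_se, ] <- cfg$se_signal_multiplier
  tumor_cols <- which(samples$tissue == "tumor")
  pat_of_col <- samples$patient_id
  for (i in seq_len(nrow(loci))) {
    if (loci$role[i] == "background" || length(carriers[[i]]) == 0) next
    cols <- tumor_cols[pat_of_col[tumor_cols] %in% carriers[[i]]]
    fac <- switch(loci$role[i],
      gain = cfg$effect_ratio,
      lost = 1 / cfg$effect_ratio,
      se_constituent = cfg$effect_ratio
    )
    mult[i, cols] <- mult[i, cols] * fac
  }
  mu <- cfg$base_rate * mult
  counts <- if (cfg$nb_dispersion > 0) {
    matrix(
      stats::rnbinom(length(mu), mu = mu, size = 1 / cfg$nb_dispersion),
      nrow = nrow(mu)
    )
  } else {
    matrix(stats::rpois(length(mu), mu), nrow = nrow(mu))
  }

  genome_len <- stats::setNames(cfg$genome$length, cfg$genome$chrom)
  tracks <- purrr::map(seq_len(nrow(samples)), function(j) {
    cnt <- counts[, j]
    idx <- rep.int(seq_len(nrow(loci)), cnt)
    lo <- loci$start[idx] - 100L
    hi <- loci$end[idx] + 100L - cfg$read_length
    fr_start <- as.integer(lo + floor(stats::runif(length(idx)) * (hi - lo + 1)))
    frags <- tibble(
      chrom = loci$chrom[idx],
      start = pmax(fr_start, 0L),
      end = pmax(fr_start, 0L) + cfg$read_length,
      strand = sample(c("+", "-"), length(idx), replace = TRUE)
    )
    if (!is.na(cfg$library_size) && cfg$library_size > nrow(frags)) {
      n_bg <- cfg$library_size - nrow(frags)
      bg_chrom <- sample(cfg$genome$chrom, n_bg, replace = TRUE,
                         prob = cfg$genome$length / sum(cfg$genome$length))
      bg_start <- as.integer(floor(stats::runif(n_bg) *
                                     (genome_len[bg_chrom] - cfg$read_length)))
      frags <- bind_rows(frags, tibble(
        chrom = bg_chrom, start = bg_start, end = bg_start + cfg$read_length,
        strand = sample(c("+", "-"), n_bg, replace = TRUE)
      ))
    }
    peaks <- loci[cnt >= cfg$detection_floor, c("chrom", "start", "end")]
    list(peaks = as_tibble(peaks), fragments = frags)
  })

  cohort <- samples %>%
    left_join(patient_tbl, by = "patient_id") %>%
    mutate(
      mark = "H3K27ac",
      library_size = vapply(tracks, function(t) nrow(t$fragments), 0L),
      peaks = purrr::map(tracks, "peaks"),
      fragments = purrr::map(tracks, "fragments")
    ) %>%
    select(all_of(c("sample_id", "patient_id", "tissue", "mark", "cms",
                    "library_size", "peaks", "fragments")))

  tss <- bind_rows(
    tibble(
      gene_id = sprintf("G%04d", seq_len(cfg$n_tss)),
      chrom = tss_anchor$chrom, start = tss_anchor$pos,
      end = tss_anchor$pos + 1L, strand = "+"
    ),
    if (n_se > 0) tibble(
      gene_id = sprintf("SEG%02d", seq_len(n_se)),
      chrom = se_anchor$chrom, start = se_anchor$pos + cfg$se_span + 15000L,
      end = se_anchor$pos + cfg$se_span + 15001L, strand = "+"
    )
  ) %>% arrange(.data$chrom, .data$start)

  se_clusters <- if (n_se > 0) {
    tibble(
      cluster_id = seq_len(n_se),
      chrom = se_anchor$chrom,
      start = se_anchor$pos,
      end = se_anchor$pos + as.integer(cfg$se_span),
      gene_id = sprintf("SEG%02d", seq_len(n_se)),
      gaining = seq_len(n_se) %in% gaining_clusters,
      carriers = se_carriers
    )
  } else {
    tibble(
      cluster_id = integer(), chrom = character(), start = integer(),
      end = integer(), gene_id = character(), gaining = logical(),
      carriers = list()
    )
  }

  structure(
    list(
      cohort = validate_cohort(cohort),
      tss = tss,
      truth = list(
        loci = loci, se_clusters = se_clusters,
        subgroup_specific = tibble(
          locus_id = integer(), chrom = character(), start = integer(),
          end = integer(), subgroup = character()
        ),
        patients = patient_tbl
      ),
      config = cfg
    ),
    class = "sim_cohort"
  )
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat(
    "Simulated paired cohort:", x$config$n_patients, "patients,",
    nrow(x$truth$loci), "loci (",
    sum(x$truth$loci$role == "gain"), "gain,",
    sum(x$truth$loci$role == "lost"), "lost,",
    nrow(x$truth$se_clusters), "SE clusters )\n"
  )
  invisible(x)
}

#' Plant subgroup-specific tumor signal
#'
#' Elevates a set of background loci in the tumor samples of one subgroup
#' each, by appending extra negative-binomial fragments so the target
#' subgroup's mean is about `subgroup_effect` times the others'. Records
#' the assignments in `truth$subgroup_specific`. A no-op when the config
#' has no subgroups; errors if any subgroup has fewer than 2 patients.
#'
#' @param sim A `sim_cohort` from [simulate_cohort()].
#' @return The modified `sim_cohort`.
#' @export
plant_subgroup_signal <- function(sim) {
  stopifnot(inherits(sim, "sim_cohort"))
  cfg <- sim$config
  if (is.null(cfg$subgroups) || cfg$n_subgroup_specific == 0) return(sim)
  tally <- sim$truth$patients %>% count(.data$cms)
  if (any(tally$n < 2)) abort("each subgroup needs at least 2 patients")
  withr::with_seed(cfg$seed + 10000L, {
    bg <- which(sim$truth$loci$role == "background")
    groups <- names(cfg$subgroups)
    chosen <- sample(bg, cfg$n_subgroup_specific * length(groups))
    assign_tbl <- tibble(
      locus_id = chosen,
      subgroup = rep(groups, each = cfg$n_subgroup_specific)
    )
    extra_mu <- cfg$base_rate * (cfg$subgroup_effect - 1)
    for (k in seq_len(nrow(assign_tbl))) {
      li <- assign_tbl$locus_id[k]
      locus <- sim$truth$loci[li, ]
      pats <- sim$truth$patients$patient_id[
        sim$truth$patients$cms == assign_tbl$subgroup[k]
      ]
      rows <- which(sim$cohort$tissue == "tumor" & sim$cohort$patient_id %in% pats)
      for (r in rows) {
        n_extra <- if (cfg$nb_dispersion > 0) {
          stats::rnbinom(1, mu = extra_mu, size = 1 / cfg$nb_dispersion)
        } else {
          stats::rpois(1, extra_mu)
        }
        if (n_extra == 0) next
        lo <- locus$start - 100L
        hi <- locus$end + 100L - cfg$read_length
        fr_start <- as.integer(lo + floor(stats::runif(n_extra) * (hi - lo + 1)))
        add <- tibble(
          chrom = locus$chrom, start = pmax(fr_start, 0L),
          end = pmax(fr_start, 0L) + cfg$read_length,
          strand = sample(c("+", "-"), n_extra, replace = TRUE)
        )
        sim$cohort$fragments[[r]] <- bind_rows(sim$cohort$fragments[[r]], add)
        sim$cohort$library_size[r] <- sim$cohort$library_size[r] + n_extra
      }
    }
    sim$truth$subgroup_specific <- assign_tbl %>%
      left_join(
        sim$truth$loci %>% select(all_of(c("locus_id", "chrom", "start", "end"))),
        by = "locus_id"
      ) %>%
      select(all_of(c("locus_id", "chrom", "start", "end", "subgroup")))
  })
  sim
}

#' Write a simulated cohort as plain-text fixture files
#'
#' Emits, under `out_dir`: per-sample peak BEDs and tagAlign fragment
#' files, a `samples.tsv` sheet (with library sizes and subgroup labels),
#' `tss.bed`, and ground-truth TSVs (`truth_loci.tsv`,
#' `truth_se_clusters.tsv`, `truth_subgroup.tsv`). Everything round-trips
#' through [load_cohort()] and [read_tss()].
#'
#' @param sim A `sim_cohort`.
#' @param out_dir Output directory (created if missing).
#' @return `out_dir`, invisibly.
#' @export
write_fixture <- function(sim, out_dir) {
  stopifnot(inherits(sim, "sim_cohort"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  co <- sim$cohort
  peak_files <- paste0(co$sample_id, ".peaks.bed")
  frag_files <- paste0(co$sample_id, ".tagAlign")
  for (i in seq_len(nrow(co))) {
    write_bed(co$peaks[[i]], file.path(out_dir, peak_files[i]))
    frg <- co$fragments[[i]] %>%
      mutate(name = ".", score = 0L) %>%
      select(all_of(c("chrom", "start", "end", "name", "score", "strand")))
    write_bed(frg, file.path(out_dir, frag_files[i]))
  }
  sheet <- co %>%
    select(all_of(c("sample_id", "patient_id", "tissue", "mark", "cms", "library_size"))) %>%
    mutate(path_peaks = peak_files, path_fragments = frag_files)
  readr::write_tsv(sheet, file.path(out_dir, "samples.tsv"), progress = FALSE)
  tss_bed <- sim$tss %>%
    mutate(name = .data$gene_id, score = 0L) %>%
    select(all_of(c("chrom", "start", "end", "name", "score", "strand")))
  write_bed(tss_bed, file.path(out_dir, "tss.bed"))
  loci_out <- sim$truth$loci %>%
    mutate(carriers = vapply(.data$carriers, function(x) {
      paste(x, collapse = ",")
    }, ""))
  readr::write_tsv(loci_out, file.path(out_dir, "truth_loci.tsv"), progress = FALSE)
  se_out <- sim$truth$se_clusters %>%
    mutate(carriers = vapply(.data$carriers, function(x) {
      paste(x, collapse = ",")
    }, ""))
  readr::write_tsv(se_out, file.path(out_dir, "truth_se_clusters.tsv"), progress = FALSE)
  readr::write_tsv(sim$truth$subgroup_specific, file.path(out_dir, "truth_subgroup.tsv"),
                   progress = FALSE)
  invisible(out_dir)
}
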