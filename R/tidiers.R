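# broom-style accessors and ggplot2 autoplot methods for fitted results.

#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_hline
#'   geom_vline labs scale_y_continuous facet_wrap
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

#' Tidy a VEL/VSEL result
#'
#' @param x A `vel_result` from [call_vels()] or [call_vsels()].
#' @param ... Unused.
#' @return The scored record tibble (one row per merged variant locus).
#' @method tidy vel_result
#' @export
tidy.vel_result <- function(x, ...) {
  x$records
}

#' One-row summary of a VEL/VSEL result
#'
#' @inheritParams tidy.vel_result
#' @return A tibble with record and significance counts per direction, the
#'   selected recurrence thresholds and the number of retained patients.
#' @method glance vel_result
#' @export
glance.vel_result <- function(x, ...) {
  per_dir <- function(dd, what) {
    sub <- x$records %>% filter(.data$direction == dd)
    if (what == "n") nrow(sub) else sum(sub$significant)
  }
  thr <- function(dd) {
    row <- x$threshold$thresholds %>% filter(.data$direction == dd)
    if (nrow(row) == 0) NA_integer_ else row$r_star
  }
  tibble(
    type = x$type,
    n_patients_retained = sum(!x$qc$excluded),
    n_gain = per_dir("gain", "n"),
    n_lost = per_dir("lost", "n"),
    n_sig_gain = per_dir("gain", "sig"),
    n_sig_lost = per_dir("lost", "sig"),
    r_star_gain = thr("gain"),
    r_star_lost = thr("lost"),
    alpha = x$params$alpha,
    target_fraction = x$params$target_fraction
  )
}

#' Tidy a recurrence-threshold selection
#'
#' @param x A `recurrence_threshold` from [select_recurrence_threshold()].
#' @param ... Unused.
#' @return The per-direction fraction table.
#' @method tidy recurrence_threshold
#' @export
tidy.recurrence_threshold <- function(x, ...) {
  x$table
}

#' Recurrence-threshold curve (significant fraction vs recurrence)
#'
#' One curve per direction: the fraction of records with recurrence at
#' least r that are BH-significant, with the target fraction and the
#' selected thresholds marked.
#'
#' @param object A `recurrence_threshold` or `vel_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot recurrence_threshold
#' @export
autoplot.recurrence_threshold <- function(object, ...) {
  thr <- object$thresholds %>% filter(!is.na(.data$r_star))
  p <- ggplot(object$table, aes(x = .data$recurrence, y = .data$frac_significant,
                                colour = .data$direction)) +
    geom_line() +
    geom_point(size = 0.8) +
    geom_hline(yintercept = object$target_fraction, linetype = "dashed") +
    scale_y_continuous(labels = function(v) paste0(100 * v, "%")) +
    labs(
      x = "recurrence threshold r (records with recurrence ≥ r)",
      y = "significant fraction (p.adj < alpha)",
      colour = NULL
    )
  if (nrow(thr) > 0) {
    p <- p + geom_vline(
      data = thr, aes(xintercept = .data$r_star, colour = .data$direction),
      linetype = "dotted"
    )
  }
  p
}

#' @rdname autoplot.recurrence_threshold
#' @method autoplot vel_result
#' @export
autoplot.vel_result <- function(object, ...) {
  autoplot(object$threshold, ...)
}

#' Super-enhancer hockey-stick plot
#'
#' Ranked region-summed signal with super-enhancers highlighted and the
#' tangent cutoff visible as the colour switch.
#'
#' @param object An `se_ranking` from [call_sample_super_enhancers()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot se_ranking
#' @export
autoplot.se_ranking <- function(object, ...) {
  ggplot(object, aes(x = .data$rank, y = .data$signal, colour = .data$is_super)) +
    geom_point(size = 0.8) +
    labs(x = "enhancer rank (ascending signal)", y = "region-summed RPM",
         colour = "super-enhancer")
}

#' Saturation curve plot
#'
#' @param object A `saturation_curve` from [saturation_curve()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot saturation_curve
#' @export
autoplot.saturation_curve <- function(object, ...) {
  ggplot(object, aes(x = .data$n_samples, y = .data$frac_discovered)) +
    geom_line() +
    geom_point() +
    scale_y_continuous(labels = function(v) paste0(100 * v, "%"), limits = c(0, 1)) +
    labs(x = "number of samples", y = "share of significant enhancers discovered")
}
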