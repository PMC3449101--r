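# ggplot2 figures: chromosome overview, karyogram, track and heatmap plots.
# Colour language follows the report convention: green = gain, red = loss,
# yellow = high-level gain, cyan = high-level loss, purple = CRI flanks.

swat_cols <- c(gain = "#2e8b57", loss = "#c0392b",
               high_gain = "#e6c400", high_loss = "#00b3b3",
               cri = "#7d3c98")

#' Three-panel chromosome overview plot
#'
#' Top: per-probe median log2 ratio across samples with a 95% band (2.5th
#' to 97.5th percentile of the per-probe sample values). Middle: probe
#' window scores (gains above, losses below the axis) at the reporting
#' window size, the chosen adaptive thresholds as dashed lines and the
#' gated CRIs as thick serially indexed bars. Bottom: per-probe frequency
#' of high-level CNA, the axis maximally scaled to 25% of the sample set
#' (larger frequencies are clipped to the axis).
#'
#' @param probes A `swat_probes`.
#' @param tracks A `swat_pws` tibble.
#' @param regions A `swat_regions` object.
#' @param calls The matching `swat_calls` table.
#' @param chromosome Chromosome label to draw.
#' @param config A [swat_config()] (`report_window`).
#' @return A patchwork of three ggplots.
#' @export
plot_chromosome_overview <- function(probes, tracks, regions, calls,
                                     chromosome, config = swat_config()) {
  assert_probes(probes)
  w <- config$report_window
  idx <- which(probes$chrom == chromosome)
  pos <- (probes$start[idx] + probes$end[idx]) / 2 / 1e6
  m <- sample_matrix(probes)[idx, , drop = FALSE]
  prof <- tibble::tibble(
    pos = pos,
    med = apply(m, 1, stats::median, na.rm = TRUE),
    lo = apply(m, 1, stats::quantile, probs = 0.025, na.rm = TRUE),
    hi = apply(m, 1, stats::quantile, probs = 0.975, na.rm = TRUE))
  p_top <- ggplot2::ggplot(prof, ggplot2::aes(x = .data$pos)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                         fill = swat_cols[["cri"]], alpha = 0.25) +
    ggplot2::geom_line(ggplot2::aes(y = .data$med), linewidth = 0.3) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dotted") +
    ggplot2::labs(y = "median log2", x = NULL,
                  title = sprintf("Chromosome %s", chromosome)) +
    ggplot2::theme_minimal(base_size = 9)

  tr <- tracks[tracks$chrom == chromosome & tracks$w == w, ]
  tr$signed <- ifelse(tr$direction == "gain", tr$score, -tr$score)
  tr$pos <- pos[tr$start]
  ths <- regions$thresholds
  ths <- ths[ths$chrom == chromosome & ths$w == w & !is.na(ths$chosen_at), ]
  cri <- regions$cri
  cri <- cri[cri$chrom == chromosome & cri$w == w, , drop = FALSE]
  p_mid <- ggplot2::ggplot(tr, ggplot2::aes(x = .data$pos, y = .data$signed,
                                            fill = .data$direction)) +
    ggplot2::geom_col(width = min(diff(sort(unique(pos))), na.rm = TRUE)) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::scale_fill_manual(values = c(gain = swat_cols[["gain"]],
                                          loss = swat_cols[["loss"]]),
                               guide = "none") +
    ggplot2::scale_y_continuous(limits = c(-115, 115),
                                breaks = c(-100, -50, 0, 50, 100)) +
    ggplot2::labs(y = sprintf("%d-probe PWS (%%)", w), x = NULL) +
    ggplot2::theme_minimal(base_size = 9)
  if (nrow(ths)) {
    p_mid <- p_mid + ggplot2::geom_hline(
      data = tibble::tibble(y = ifelse(ths$direction == "gain",
                                       ths$chosen_at, -ths$chosen_at)),
      ggplot2::aes(yintercept = .data$y), linetype = "dashed",
      colour = "grey30")
  }
  if (nrow(cri)) {
    cri_df <- tibble::tibble(
      xmin = cri$start / 1e6, xmax = cri$end / 1e6,
      y = ifelse(cri$direction == "gain", 108, -108),
      label = cri$cri)
    p_mid <- p_mid +
      ggplot2::geom_segment(data = cri_df,
                            ggplot2::aes(x = .data$xmin, xend = .data$xmax,
                                         y = .data$y, yend = .data$y),
                            linewidth = 2.2, colour = swat_cols[["cri"]],
                            inherit.aes = FALSE) +
      ggplot2::geom_text(data = cri_df,
                         ggplot2::aes(x = (.data$xmin + .data$xmax) / 2,
                                      y = .data$y * 1.05,
                                      label = .data$label),
                         size = 2.4, inherit.aes = FALSE)
  }

  cm <- as.matrix(as.data.frame(calls)[idx, sample_ids(calls), drop = FALSE])
  n_pos <- length(pos)
  hl <- tibble::tibble(
    pos = rep(pos, 2),
    freq = c(pmin(100 * rowMeans(cm == 2L), 25),
             -pmin(100 * rowMeans(cm == -2L), 25)),
    direction = rep(c("high_gain", "high_loss"), each = n_pos))
  p_bot <- ggplot2::ggplot(hl, ggplot2::aes(x = .data$pos, y = .data$freq,
                                            fill = .data$direction)) +
    ggplot2::geom_col(width = min(diff(sort(unique(pos))), na.rm = TRUE)) +
    ggplot2::scale_fill_manual(values = c(high_gain = swat_cols[["high_gain"]],
                                          high_loss = swat_cols[["high_loss"]]),
                               guide = "none") +
    ggplot2::scale_y_continuous(limits = c(-25, 25)) +
    ggplot2::labs(y = "high-level CNA (%)", x = "position (Mb)") +
    ggplot2::theme_minimal(base_size = 9)

  patchwork::wrap_plots(p_top, p_mid, p_bot, ncol = 1, heights = c(1, 1.4, 0.8))
}

#' Genome karyogram of detected regions
#'
#' One horizontal bar per chromosome; regions of gain are drawn green above
#' the bar and losses red below, high-level events (any sample at +/-2)
#' yellow/cyan, CRIs as purple flanking bars, and amplitude-significant
#' MRIs (P below the configured cutoff) marked with arrowheads.
#'
#' @param regions A `swat_regions` object.
#' @param probes A `swat_probes` (chromosome extents).
#' @param calls Optional `swat_calls` for the high-level bands.
#' @param priority Optional `swat_priority` table for significance arrows.
#' @param config A [swat_config()].
#' @return A ggplot.
#' @export
plot_karyogram <- function(regions, probes, calls = NULL, priority = NULL,
                           config = swat_config()) {
  assert_probes(probes)
  w <- config$report_window
  chroms <- unique(probes$chrom)
  extent <- probes |>
    tibble::as_tibble() |>
    dplyr::group_by(.data$chrom) |>
    dplyr::summarise(len = max(.data$end) / 1e6, .groups = "drop")
  extent$chrom <- factor(extent$chrom, levels = chroms)
  p <- ggplot2::ggplot(extent) +
    ggplot2::geom_rect(ggplot2::aes(xmin = 0, xmax = .data$len,
                                    ymin = -0.12, ymax = 0.12),
                       fill = "grey85", colour = "grey55", linewidth = 0.2) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$chrom), switch = "y") +
    ggplot2::labs(x = "position (Mb)", y = NULL) +
    ggplot2::theme_minimal(base_size = 9) +
    ggplot2::theme(axis.text.y = ggplot2::element_blank(),
                   panel.grid = ggplot2::element_blank(),
                   strip.text.y.left = ggplot2::element_text(angle = 0))
  cri <- regions$cri
  if (nrow(cri)) {
    cri <- cri[cri$w == w, ]
    cri$chrom <- factor(cri$chrom, levels = chroms)
    band <- dplyr::mutate(
      cri,
      xmin = .data$start / 1e6, xmax = .data$end / 1e6,
      ymin = ifelse(.data$direction == "gain", 0.15, -0.3),
      ymax = ifelse(.data$direction == "gain", 0.3, -0.15))
    p <- p +
      ggplot2::geom_rect(data = band,
                         ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax,
                                      ymin = .data$ymin, ymax = .data$ymax,
                                      fill = .data$direction),
                         inherit.aes = FALSE) +
      ggplot2::scale_fill_manual(values = c(gain = swat_cols[["gain"]],
                                            loss = swat_cols[["loss"]]),
                                 guide = "none") +
      ggplot2::geom_rect(data = band,
                         ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax,
                                      ymin = -0.45, ymax = -0.38),
                         fill = swat_cols[["cri"]], inherit.aes = FALSE)
  }
  if (!is.null(calls)) {
    hi <- tibble::as_tibble(calls) |>
      dplyr::mutate(pos = (.data$start + .data$end) / 2 / 1e6)
    samples <- sample_ids(calls)
    cm <- as.matrix(as.data.frame(calls)[, samples, drop = FALSE])
    hi$any_high_gain <- rowSums(cm == 2L) > 0
    hi$any_high_loss <- rowSums(cm == -2L) > 0
    hg <- hi[hi$any_high_gain, ]; hl <- hi[hi$any_high_loss, ]
    hg$chrom <- factor(hg$chrom, levels = chroms)
    hl$chrom <- factor(hl$chrom, levels = chroms)
    if (nrow(hg)) p <- p + ggplot2::geom_point(
      data = hg, ggplot2::aes(x = .data$pos, y = 0.38), shape = 15,
      size = 0.8, colour = swat_cols[["high_gain"]], inherit.aes = FALSE)
    if (nrow(hl)) p <- p + ggplot2::geom_point(
      data = hl, ggplot2::aes(x = .data$pos, y = -0.55), shape = 15,
      size = 0.8, colour = swat_cols[["high_loss"]], inherit.aes = FALSE)
  }
  if (!is.null(priority) && nrow(priority)) {
    sig <- priority[priority$p_value < config$p_cutoff, ]
    if (nrow(sig)) {
      sig$chrom <- factor(sig$chrom, levels = chroms)
      sig$pos <- (sig$start + sig$end) / 2 / 1e6
      sig$y <- ifelse(sig$direction == "gain", 0.5, -0.68)
      p <- p + ggplot2::geom_point(
        data = sig, ggplot2::aes(x = .data$pos, y = .data$y),
        shape = 25, fill = "black", size = 1.6, inherit.aes = FALSE)
    }
  }
  p + ggplot2::coord_cartesian(ylim = c(-0.8, 0.6))
}

#' Plot probe window score tracks
#'
#' PWS against window start, faceted by window size and chromosome, gains
#' and losses in opposite colours.
#'
#' @param object A `swat_pws` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot swat_pws
#' @export
autoplot.swat_pws <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$start,
                               y = ifelse(.data$direction == "gain",
                                          .data$score, -.data$score),
                               fill = .data$direction)) +
    ggplot2::geom_col() +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$w),
                        cols = ggplot2::vars(.data$chrom)) +
    ggplot2::scale_fill_manual(values = c(gain = swat_cols[["gain"]],
                                          loss = swat_cols[["loss"]])) +
    ggplot2::labs(x = "window start (probe index)", y = "PWS (%)") +
    ggplot2::theme_minimal(base_size = 9)
}

#' Heatmap of per-region CNA fractions
#'
#' Samples in columns, regions in rows; shading is the fraction of region
#' probes gained (orange) minus lost (blue) per sample.
#'
#' @param heatmap Long tibble from [region_heatmap_matrix()].
#' @param groups Optional named group vector (from [cluster_samples()]) used
#'   to order the sample columns.
#' @return A ggplot.
#' @export
plot_region_heatmap <- function(heatmap, groups = NULL) {
  heatmap$label <- sprintf("%s:%.1f-%.1fMb", heatmap$chrom,
                           heatmap$start / 1e6, heatmap$end / 1e6)
  if (!is.null(groups)) {
    ord <- names(sort(groups))
    heatmap$sample <- factor(heatmap$sample, levels = ord)
  }
  ggplot2::ggplot(heatmap, ggplot2::aes(x = .data$sample, y = .data$label,
                                        fill = .data$value)) +
    ggplot2::geom_tile(colour = "white", linewidth = 0.2) +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "grey95",
                                  high = "#e08214", limits = c(-1, 1),
                                  name = "gain - loss\nfraction") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal(base_size = 9) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}
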