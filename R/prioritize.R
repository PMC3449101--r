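# Prioritisation of detected MRIs: (a) permutation-based amplitude
# significance against a Gaussian null of random window mean intensities,
# (b) gene-density weighting (ARI/RIC/AFI/GDW scores).

#' Null distribution of window mean intensities
#'
#' Draws `n_perm` random probe windows of length `w` genome-wide, the number
#' drawn from each chromosome proportional to its probe count (chromosomes
#' shorter than `w` contribute no draws). The statistic of each draw is the
#' mean log2 ratio over the window's probes across all samples; the null is
#' summarised by the sample mean and (n-1) standard deviation of the
#' `n_perm` statistics.
#'
#' @param probes A `swat_probes` object.
#' @param w Window length in probes.
#' @param n_perm Number of random windows (>= 100).
#' @param seed Integer seed; draws are fully reproducible.
#' @return List with `mu`, `sigma`, `w`, `n_perm`.
#' @export
null_distribution <- function(probes, w, n_perm = 10000, seed = 1) {
  assert_probes(probes)
  if (n_perm < 100) rlang::abort("`n_perm` must be >= 100.")
  counts <- table(probes$chrom)
  chroms <- names(counts)[counts >= w]
  if (!length(chroms)) {
    rlang::abort(sprintf("No chromosome has >= %d probes.", w))
  }
  weights <- as.numeric(counts[chroms])
  m <- sample_matrix(probes)
  chrom_rows <- lapply(chroms, function(ch) which(probes$chrom == ch))
  names(chrom_rows) <- chroms
  set.seed(seed)
  pick_ch <- sample(seq_along(chroms), n_perm, replace = TRUE,
                    prob = weights / sum(weights))
  stats <- vapply(pick_ch, function(ci) {
    rows <- chrom_rows[[ci]]
    s <- sample.int(length(rows) - w + 1L, 1L)
    mean(m[rows[s:(s + w - 1L)], ], na.rm = TRUE)
  }, numeric(1))
  list(mu = mean(stats), sigma = stats::sd(stats), w = as.integer(w),
       n_perm = as.integer(n_perm))
}

#' One-tailed amplitude significance
#'
#' Gaussian tail probability of an MRI's mean log2 intensity under the
#' permutation null, taken in the CNA's direction: for gains
#' `P = 1 - Phi((x - mu) / sigma)`, for losses `P = Phi((x - mu) / sigma)`.
#' With a degenerate null (`sigma = 0`), P is 0 when x lies beyond mu in
#' the tested direction and 1 otherwise.
#'
#' @param x Mean log2 intensity (vectorised).
#' @param direction `"gain"` or `"loss"` (recycled).
#' @param mu,sigma Null parameters from [null_distribution()].
#' @return P values in \[0, 1\].
#' @export
amplitude_p <- function(x, direction, mu, sigma) {
  stopifnot(sigma >= 0)
  sign_dir <- ifelse(direction == "gain", 1, -1)
  if (sigma == 0) {
    return(ifelse(sign_dir * (x - mu) > 0, 0, 1))
  }
  z <- (x - mu) / sigma
  ifelse(sign_dir > 0, stats::pnorm(z, lower.tail = FALSE), stats::pnorm(z))
}

#' Amplitude-based filtering and ranking of MRIs
#'
#' Computes each MRI's one-tailed permutation-Gaussian P value (the null is
#' computed once per window size present in `mris`) and keeps regions with
#' `P < p_cutoff` (default 0.1). Kept MRIs are ranked within direction by
#' ascending P, ties broken by descending absolute mean intensity.
#'
#' @param mris MRI tibble (from [swat_regions()]`$mri`) with columns
#'   `chrom`, `w`, `direction`, `start`, `end`, `probe_first`,
#'   `probe_last`, `n_probes`, `recurrence`, `mean_intensity`.
#' @param probes A `swat_probes` object.
#' @param config A [swat_config()] (`p_cutoff`, `n_permutations`,
#'   `rng_seed`).
#' @param keep_all Keep non-significant MRIs too (flagged by `significant`).
#' @return The MRI tibble with `p_value`, `significant` and
#'   `amplitude_rank` columns, filtered to `P < p_cutoff` unless
#'   `keep_all = TRUE`.
#' @export
amplitude_filter <- function(mris, probes, config = swat_config(),
                             keep_all = FALSE) {
  if (nrow(mris) == 0) {
    mris$p_value <- numeric(0); mris$significant <- logical(0)
    mris$amplitude_rank <- integer(0)
    return(mris)
  }
  mris$p_value <- NA_real_
  for (w in unique(mris$w)) {
    null <- null_distribution(probes, w, config$n_permutations,
                              seed = config$rng_seed + w)
    rows <- which(mris$w == w)
    mris$p_value[rows] <- amplitude_p(mris$mean_intensity[rows],
                                      mris$direction[rows],
                                      null$mu, null$sigma)
  }
  mris$significant <- mris$p_value < config$p_cutoff
  if (!keep_all) mris <- mris[mris$significant, ]
  mris <- mris |>
    dplyr::group_by(.data$direction) |>
    dplyr::arrange(.data$p_value, dplyr::desc(abs(.data$mean_intensity)),
                   .by_group = TRUE) |>
    dplyr::mutate(amplitude_rank = ifelse(.data$significant,
                                          cumsum(.data$significant),
                                          NA_integer_)) |>
    dplyr::ungroup()
  mris
}

#' Aberration recurrence index (ARI)
#'
#' Absolute mean log2 intensity of an MRI multiplied by its recurrence
#' (peak PWS as a fraction of samples). The absolute value puts gains and
#' losses on comparable positive scales; ranking is done per direction.
#'
#' @param mean_intensity Mean log2 ratio over the MRI (vectorised).
#' @param recurrence Fraction in (0, 1].
#' @return Non-negative score.
#' @export
ari <- function(mean_intensity, recurrence) {
  if (any(recurrence <= 0 | recurrence > 1)) {
    rlang::abort("`recurrence` must be a fraction in (0, 1].")
  }
  abs(mean_intensity) * recurrence
}

#' Regional information content (RIC)
#'
#' Number of genes overlapping the MRI divided by the number of probes
#' comprising it. A region overlapping no annotated gene scores 0 and
#' cannot rank under gene-density weighting.
#'
#' @param gene_count,probe_count Non-negative integers (`probe_count >= 1`).
#' @return `gene_count / probe_count`.
#' @export
ric <- function(gene_count, probe_count) {
  if (any(probe_count < 1)) rlang::abort("`probe_count` must be >= 1.")
  gene_count / probe_count
}

#' Gene density weighting (GDW)
#'
#' The aberration focality index is computed literally as
#' `AFI = (RIC x ARI) / ARI`, which algebraically reduces to RIC (with the
#' convention AFI = RIC when ARI = 0), and `GDW = AFI x ARI`.
#'
#' @param ari_score,ric_score Non-negative scores (vectorised).
#' @return List with `afi` and `gdw` vectors.
#' @export
gdw <- function(ari_score, ric_score) {
  if (any(ari_score < 0) || any(ric_score < 0)) {
    rlang::abort("Scores must be non-negative.")
  }
  afi <- ifelse(ari_score == 0, ric_score, (ric_score * ari_score) / ari_score)
  list(afi = afi, gdw = afi * ari_score)
}

#' Count genes overlapping each region
#'
#' Distinct gene names whose span overlaps the region's genomic span by at
#' least one base pair; multiple transcripts of one gene count once.
#'
#' @param regions Tibble with `chrom`, `start`, `end` (0-based half-open).
#' @param genes A `swat_genes` annotation (possibly empty).
#' @return Integer vector of gene counts, one per region row.
#' @export
count_genes <- function(regions, genes) {
  if (nrow(regions) == 0) return(integer(0))
  if (is.null(genes) || nrow(genes) == 0) return(rep(0L, nrow(regions)))
  rgr <- GenomicRanges::GRanges(
    regions$chrom, IRanges::IRanges(regions$start + 1L, regions$end))
  ggr <- GenomicRanges::GRanges(
    genes$chrom, IRanges::IRanges(genes$start + 1L, genes$end),
    name = genes$name)
  hits <- GenomicRanges::findOverlaps(rgr, ggr)
  counts <- rep(0L, nrow(regions))
  if (length(hits)) {
    byr <- split(ggr$name[S4Vectors::subjectHits(hits)],
                 S4Vectors::queryHits(hits))
    counts[as.integer(names(byr))] <- vapply(byr, dplyr::n_distinct, integer(1))
  }
  counts
}

#' Rank MRIs by gene density weighting
#'
#' Orders a prioritised MRI table within each direction by descending GDW,
#' ties broken by descending ARI, then by genome position.
#'
#' @param pmris Tibble with `gdw`, `ari`, `chrom`, `start`, `direction`.
#' @return The table with a `gdw_rank` column, reordered.
#' @export
gdw_rank <- function(pmris) {
  pmris |>
    dplyr::group_by(.data$direction) |>
    dplyr::arrange(dplyr::desc(.data$gdw), dplyr::desc(.data$ari),
                   chrom_factor(.data$chrom), .data$start, .by_group = TRUE) |>
    dplyr::mutate(gdw_rank = dplyr::row_number()) |>
    dplyr::ungroup()
}

#' Full prioritisation of detected MRIs
#'
#' Applies the amplitude permutation filter, then annotates the surviving
#' MRIs with gene counts and the ARI/RIC/AFI/GDW scores and both rankings.
#'
#' @param regions A `swat_regions` object (or its `$mri` tibble).
#' @param probes The cohort's `swat_probes`.
#' @param genes A `swat_genes` annotation, or `NULL` (all gene counts 0).
#' @param config A [swat_config()]; `report_window` selects the window size
#'   whose detections are prioritised, and `consistent` MRIs only are used.
#' @param keep_all Keep amplitude-non-significant MRIs (flagged).
#' @return A `swat_priority` tibble: one row per MRI with `p_value`,
#'   `gene_count`, `ari`, `ric`, `afi`, `gdw`, `amplitude_rank`,
#'   `gdw_rank`.
#' @export
swat_prioritize <- function(regions, probes, genes = NULL,
                            config = swat_config(), keep_all = FALSE) {
  mris <- if (inherits(regions, "swat_regions")) regions$mri else regions
  if (nrow(mris) > 0 && "w" %in% names(mris)) {
    mris <- mris[mris$w == config$report_window, ]
  }
  if (nrow(mris) > 0 && "consistent" %in% names(mris)) {
    mris <- mris[mris$consistent, ]
  }
  out <- amplitude_filter(mris, probes, config, keep_all = keep_all)
  out$gene_count <- count_genes(out, genes)
  out$probe_count <- out$n_probes
  out$ari <- if (nrow(out)) ari(out$mean_intensity, out$recurrence) else numeric(0)
  out$ric <- if (nrow(out)) ric(out$gene_count, out$probe_count) else numeric(0)
  g <- gdw(out$ari, out$ric)
  out$afi <- g$afi
  out$gdw <- g$gdw
  out <- gdw_rank(out)
  new_swat_tbl(out, "swat_priority")
}
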