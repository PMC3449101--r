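# Adaptive thresholds and CRI/MRI extraction.
#
# Per chromosome and per direction, a descending ladder of adaptive
# thresholds (AT) is scanned from the most stringent value down; the first
# AT gating at least the target fraction of the chromosome's probes
# (default 5% per direction, hence ~10% overall) is chosen. Chromosomes
# where even the least stringent AT gates nothing are deemed without CNA.

track_n_probes <- function(track) {
  if (nrow(track) == 0) return(0L)
  max(track$start) + track$w[1] - 1L
}

covered_probes <- function(gated_starts, w, n_probes) {
  cov <- logical(n_probes)
  for (s in gated_starts) cov[s:(s + w - 1L)] <- TRUE
  cov
}

#' Gate windows at a threshold
#'
#' A window is gated when its PWS is greater than or equal to the adaptive
#' threshold (the boundary is inclusive: a region gated at AT = 80 is
#' aberrant in >= 80% of the cohort).
#'
#' @param track A single `swat_pws` track (one chromosome, size, direction).
#' @param at Threshold percentage, or `NA` ("none": nothing is gated).
#' @return Logical vector over the track's windows.
#' @export
gate_windows <- function(track, at) {
  if (is.na(at)) return(rep(FALSE, nrow(track)))
  if (at <= 0 || at > 100) rlang::abort("`at` must be in (0, 100].")
  track$score >= at
}

#' Select the adaptive threshold for one track
#'
#' Evaluates probe coverage (fraction of the chromosome's probes inside
#' gated windows) at each ladder value from the most to the least stringent
#' and returns the first (highest) AT whose coverage reaches
#' `target_coverage`. If no ladder value reaches the target, the lowest AT
#' is returned provided it gates anything at all; when even the lowest AT
#' yields zero coverage the chromosome is deemed without CNA in that
#' direction (`chosen_at = NA`).
#'
#' @param track A single `swat_pws` track.
#' @param ladder Strictly decreasing percentage ladder (default 80..20 by 10).
#' @param target_coverage Target fraction of chromosome probes per direction.
#' @return One-row tibble: `chosen_at` (percentage or `NA`) and `coverage`
#'   (fraction in \[0, 1\], 0 when `chosen_at` is `NA`).
#' @export
select_adaptive_threshold <- function(track, ladder = seq(80, 20, by = -10),
                                      target_coverage = 0.05) {
  if (length(ladder) > 1 && any(diff(ladder) >= 0)) {
    rlang::abort("`ladder` must be strictly decreasing.")
  }
  n <- track_n_probes(track)
  if (n == 0L) {
    return(tibble::tibble(chosen_at = NA_real_, coverage = 0))
  }
  w <- track$w[1]
  cov_at <- function(at) {
    g <- track$start[gate_windows(track, at)]
    if (!length(g)) return(0)
    mean(covered_probes(g, w, n))
  }
  covs <- vapply(ladder, cov_at, numeric(1))
  hit <- which(covs >= target_coverage)
  if (length(hit)) {
    i <- hit[1]
    return(tibble::tibble(chosen_at = ladder[i], coverage = covs[i]))
  }
  last <- length(ladder)
  if (covs[last] > 0) {
    return(tibble::tibble(chosen_at = ladder[last], coverage = covs[last]))
  }
  tibble::tibble(chosen_at = NA_real_, coverage = 0)
}

#' Extract contiguous regions of interest (CRIs)
#'
#' A CRI is a maximal probe span covered by consecutive gated windows:
#' gated-window probe unions that overlap or are adjacent merge into one
#' region. CRIs are serially indexed in genome order within their
#' chromosome and direction.
#'
#' @param gated Logical vector from [gate_windows()].
#' @param track The corresponding `swat_pws` track.
#' @return Tibble with one row per CRI: `cri` (serial index), `probe_first`,
#'   `probe_last` (1-based probe indices within the chromosome),
#'   `n_probes`, `peak_pws` (maximum PWS among member windows).
#' @export
extract_cris <- function(gated, track) {
  n <- track_n_probes(track)
  empty <- tibble::tibble(cri = integer(), probe_first = integer(),
                          probe_last = integer(), n_probes = integer(),
                          peak_pws = numeric())
  if (n == 0L || !any(gated)) return(empty)
  w <- track$w[1]
  cov <- covered_probes(track$start[gated], w, n)
  runs <- logical_runs(cov)
  runs$cri <- seq_len(nrow(runs))
  runs$n_probes <- runs$last - runs$first + 1L
  runs$peak_pws <- vapply(seq_len(nrow(runs)), function(i) {
    member <- gated & track$start >= runs$first[i] &
      (track$start + w - 1L) <= runs$last[i]
    max(track$score[member])
  }, numeric(1))
  tibble::tibble(cri = runs$cri, probe_first = runs$first,
                 probe_last = runs$last, n_probes = runs$n_probes,
                 peak_pws = runs$peak_pws)
}

#' Extract minimum regions of interest (MRIs) within a CRI
#'
#' The MRI is the smallest probe span showing the CRI's most frequent
#' concordant CNA: with m the maximum PWS among the CRI's member gated
#' windows, MRIs are the maximal contiguous probe runs covered by windows
#' achieving m (overlapping or adjacent top-scoring windows chain into one
#' MRI; separated maxima yield several MRIs). When PWS is flat across the
#' CRI the MRI equals the CRI.
#'
#' @param cri One row of the tibble from [extract_cris()].
#' @param gated Logical gating vector for `track`.
#' @param track The corresponding `swat_pws` track.
#' @return Tibble with one row per MRI: `mri` (serial within the CRI),
#'   `probe_first`, `probe_last`, `n_probes`, `recurrence` (peak PWS as a
#'   fraction of samples).
#' @export
extract_mris <- function(cri, gated, track) {
  w <- track$w[1]
  member <- gated & track$start >= cri$probe_first &
    (track$start + w - 1L) <= cri$probe_last
  m <- max(track$score[member])
  top_starts <- track$start[member & track$score == m]
  cov <- logical(cri$probe_last)
  for (s in top_starts) cov[s:(s + w - 1L)] <- TRUE
  runs <- logical_runs(cov)
  tibble::tibble(
    mri = seq_len(nrow(runs)),
    probe_first = runs$first, probe_last = runs$last,
    n_probes = runs$last - runs$first + 1L,
    recurrence = m / 100
  )
}

#' Mean log2 intensity over a region
#'
#' Arithmetic mean of all non-missing log2 values over the region's probes
#' across all samples.
#'
#' @param probes A `swat_probes` object.
#' @param chromosome Chromosome label.
#' @param probe_first,probe_last 1-based probe index span within the
#'   chromosome.
#' @return Mean log2 value; an error if every value in the block is missing.
#' @export
mri_mean_intensity <- function(probes, chromosome, probe_first, probe_last) {
  assert_probes(probes)
  idx <- which(probes$chrom == chromosome)[probe_first:probe_last]
  vals <- as.matrix(as.data.frame(probes)[idx, sample_ids(probes), drop = FALSE])
  if (all(is.na(vals))) {
    rlang::abort("All log2 values in the region are missing.")
  }
  mean(vals, na.rm = TRUE)
}

#' Adaptive thresholding and region extraction for all tracks
#'
#' Runs the full region-detection stage: for every (chromosome, window
#' size, direction) track, selects the adaptive threshold, gates windows,
#' extracts CRIs and their MRIs, attaches genomic spans and mean log2
#' intensities, and flags every MRI's cross-window-size consistency
#' (see [consistency_filter()]).
#'
#' @param tracks A `swat_pws` tibble from [compute_all_tracks()].
#' @param probes The cohort's `swat_probes` object.
#' @param config A [swat_config()].
#' @return A `swat_regions` list of three tibbles: `$thresholds` (one row
#'   per track: `chrom`, `w`, `direction`, `chosen_at`, `coverage`), `$cri`
#'   and `$mri` (regions with probe and genomic spans; MRIs carry
#'   `recurrence`, `mean_intensity` and `consistent`).
#' @export
swat_regions <- function(tracks, probes, config = swat_config()) {
  assert_probes(probes)
  key <- unique(tracks[, c("chrom", "w", "direction")])
  thresholds <- list(); cris <- list(); mris <- list()
  for (i in seq_len(nrow(key))) {
    ch <- key$chrom[i]; w <- key$w[i]; dir <- key$direction[i]
    tr <- tracks[tracks$chrom == ch & tracks$w == w & tracks$direction == dir, ]
    sel <- select_adaptive_threshold(tr, config$at_ladder, config$target_coverage)
    thresholds[[i]] <- dplyr::bind_cols(
      tibble::tibble(chrom = ch, w = w, direction = dir), sel)
    if (is.na(sel$chosen_at)) next
    gated <- gate_windows(tr, sel$chosen_at)
    cri_tbl <- extract_cris(gated, tr)
    if (nrow(cri_tbl) == 0) next
    pidx <- which(probes$chrom == ch)
    cri_tbl <- dplyr::mutate(
      cri_tbl,
      chrom = ch, w = w, direction = dir, at = sel$chosen_at,
      start = probes$start[pidx[.data$probe_first]],
      end = probes$end[pidx[.data$probe_last]],
      .before = 1)
    mri_i <- purrr::map(seq_len(nrow(cri_tbl)), function(k) {
      mm <- extract_mris(cri_tbl[k, ], gated, tr)
      mm$cri <- cri_tbl$cri[k]
      mm
    })
    mri_tbl <- dplyr::bind_rows(mri_i)
    mri_tbl <- dplyr::mutate(
      mri_tbl,
      chrom = ch, w = w, direction = dir, at = sel$chosen_at,
      start = probes$start[pidx[.data$probe_first]],
      end = probes$end[pidx[.data$probe_last]],
      .before = 1)
    mri_tbl$mean_intensity <- vapply(seq_len(nrow(mri_tbl)), function(k) {
      mri_mean_intensity(probes, ch, mri_tbl$probe_first[k], mri_tbl$probe_last[k])
    }, numeric(1))
    cris[[length(cris) + 1]] <- cri_tbl
    mris[[length(mris) + 1]] <- mri_tbl
  }
  cri <- dplyr::bind_rows(cris)
  mri <- dplyr::bind_rows(mris)
  if (nrow(mri)) {
    mri$peak_pws <- mri$recurrence * 100
    mri$consistent <- vapply(seq_len(nrow(mri)), function(k) {
      consistency_filter(mri$probe_first[k], mri$probe_last[k],
                         mri$peak_pws[k], mri$chrom[k], mri$direction[k],
                         mri$w[k], tracks, config$window_sizes)
    }, logical(1))
  }
  structure(list(thresholds = dplyr::bind_rows(thresholds),
                 cri = cri, mri = mri),
            class = "swat_regions", config = config)
}

#' @export
print.swat_regions <- function(x, ...) {
  cat(sprintf("<swat_regions> %d CRI(s), %d MRI(s) across %d track(s)\n",
              nrow(x$cri), nrow(x$mri), nrow(x$thresholds)))
  invisible(x)
}

#' Region tables as TSV (1-based printed positions)
#'
#' @param regions A `swat_regions` object.
#' @param dir Output directory (created if needed).
#' @return Paths of the written files, invisibly.
#' @export
write_region_tables <- function(regions, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(thresholds = file.path(dir, "adaptive_thresholds.tsv"),
             cri = file.path(dir, "cri.tsv"),
             mri = file.path(dir, "mri.tsv"))
  readr::write_tsv(regions$thresholds, paths["thresholds"], progress = FALSE)
  for (nm in c("cri", "mri")) {
    tab <- regions[[nm]]
    if (nrow(tab)) {
      tab <- tab[order(chrom_factor(tab$chrom), tab$start), ]
      tab$start <- tab$start + 1L
    }
    readr::write_tsv(tab, paths[nm], progress = FALSE)
  }
  invisible(paths)
}
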