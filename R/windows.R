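# Sliding probe-window scoring. The probe window score (PWS) of a w-probe
# window is the percentage of samples in which ALL w probes share the
# window's CNA direction. Windows advance by one probe; no partial windows
# at chromosome ends, so a track has n_probes - w + 1 scores.

# Window "all match" counts for a logical probe x sample matrix, via
# column-wise cumulative sums: a window matches in a sample iff its w
# indicator values sum to w.
window_all_count <- function(match_mat, w) {
  n <- nrow(match_mat)
  if (n < w) return(integer(0))
  cs <- apply(match_mat, 2, function(col) cumsum(as.integer(col)))
  cs <- rbind(0L, matrix(cs, nrow = n))
  win <- cs[(w + 1):(n + 1), , drop = FALSE] - cs[1:(n - w + 1), , drop = FALSE]
  as.integer(rowSums(win == w))
}

#' Probe window scores for one chromosome and window size
#'
#' @param direction A `swat_direction` table (see [collapse_direction()]).
#' @param chromosome Chromosome label to score.
#' @param w Window size in probes (>= 2).
#' @param direction_label `"gain"` or `"loss"`: the CNA direction scored. A
#'   sample counts for a window only if every probe in the window carries
#'   this direction; samples mixing directions inside the window count for
#'   neither.
#' @return A `swat_pws` tibble with one row per window start (1-based probe
#'   index within the chromosome): columns `chrom`, `w`, `direction`,
#'   `start`, `score` (percentage, a multiple of 100 / n_samples) and
#'   `n_samples`. A chromosome with fewer than `w` probes yields an empty
#'   track with a warning.
#' @examples
#' fx <- figure1_fixture()
#' dirs <- collapse_direction(fx$calls)
#' compute_pws(dirs, "1", 3)[1:2, ]  # scores 0 and 50 on the toy cohort
#' @export
compute_pws <- function(direction, chromosome, w, direction_label = c("gain", "loss")) {
  direction_label <- match.arg(direction_label)
  if (w < 2) rlang::abort("Window size `w` must be >= 2.")
  idx <- which(direction$chrom == chromosome)
  samples <- sample_ids(direction)
  n_s <- length(samples)
  d <- as.matrix(as.data.frame(direction)[idx, samples, drop = FALSE])
  target <- if (direction_label == "gain") 1L else -1L
  if (length(idx) < w) {
    rlang::warn(sprintf("Chromosome %s has %d probes (< w = %d); empty track.",
                        chromosome, length(idx), w))
    return(new_swat_tbl(tibble::tibble(
      chrom = character(), w = integer(), direction = character(),
      start = integer(), score = numeric(), n_samples = integer()
    ), "swat_pws"))
  }
  mm <- !is.na(d) & d == target
  counts <- window_all_count(mm, w)
  new_swat_tbl(tibble::tibble(
    chrom = chromosome, w = as.integer(w), direction = direction_label,
    start = seq_along(counts),
    score = 100 * counts / n_s,
    n_samples = n_s
  ), "swat_pws")
}

#' All window-score tracks for a cohort
#'
#' One track per (chromosome, window size, direction) combination.
#'
#' @param direction A `swat_direction` table.
#' @param config A [swat_config()]; `window_sizes` (default 3--20) selects
#'   the sizes computed.
#' @return A `swat_pws` tibble stacking every track.
#' @export
compute_all_tracks <- function(direction, config = swat_config()) {
  chroms <- unique(direction$chrom)
  grid <- expand.grid(chrom = chroms, w = config$window_sizes,
                      dir = c("gain", "loss"), stringsAsFactors = FALSE)
  tracks <- purrr::pmap(grid, function(chrom, w, dir) {
    suppressWarnings(compute_pws(direction, chrom, w, dir))
  })
  new_swat_tbl(dplyr::bind_rows(tracks), "swat_pws")
}

#' Cross-window-size consistency of a detected region
#'
#' Scores from larger windows are considered the more robust detections, but
#' a region found at size w is retained only if it is also present in the
#' internal smaller windows at equal or higher recurrence: for every
#' configured size w' < w, every probe of the region's MRI must be covered
#' by at least one w'-window whose PWS is >= the region's peak PWS at size
#' w. A region detected at the smallest configured size is trivially
#' retained.
#'
#' @param mri_first,mri_last 1-based probe index span of the region's MRI
#'   within its chromosome.
#' @param peak_pws The region's peak PWS (percentage) at its detection size.
#' @param chromosome,direction_label,w Identity of the detection track.
#' @param tracks A `swat_pws` tibble holding tracks for all configured sizes.
#' @param window_sizes The configured window sizes.
#' @return `TRUE` if the region is retained, `FALSE` if discarded.
#' @export
consistency_filter <- function(mri_first, mri_last, peak_pws, chromosome,
                               direction_label, w, tracks,
                               window_sizes) {
  smaller <- window_sizes[window_sizes < w]
  if (!length(smaller)) return(TRUE)
  for (wp in smaller) {
    tr <- tracks[tracks$chrom == chromosome & tracks$w == wp &
                   tracks$direction == direction_label, ]
    if (nrow(tr) == 0) return(FALSE)
    ok_starts <- tr$start[tr$score >= peak_pws]
    for (p in mri_first:mri_last) {
      # windows of size wp covering probe p start in [p - wp + 1, p]
      if (!any(ok_starts >= p - wp + 1 & ok_starts <= p)) return(FALSE)
    }
  }
  TRUE
}
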