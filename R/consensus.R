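# Cross-method consensus and sample clustering.

#' Consolidate MRIs across segmentation methods
#'
#' Same-direction MRIs from different methods whose genomic spans overlap
#' by at least one base pair are pooled transitively; pools supported by at
#' least `min_methods` distinct methods become consensus regions whose span
#' is the union of the member spans.
#'
#' @param mri_lists Named list of MRI tibbles (one per method; names are
#'   the method labels), each with `chrom`, `start`, `end`, `direction`.
#'   Alternatively a single tibble carrying a `method` column.
#' @param min_methods Minimum number of distinct supporting methods
#'   (default 2).
#' @return A `swat_consensus` tibble: `chrom`, `direction`, `start`, `end`,
#'   `n_methods`, `methods` (comma-joined labels), `n_members`.
#' @export
consensus_merge <- function(mri_lists, min_methods = 2) {
  if (is.data.frame(mri_lists)) {
    if (!"method" %in% names(mri_lists)) {
      rlang::abort("A single tibble input must carry a `method` column.")
    }
    all_mri <- tibble::as_tibble(mri_lists)
  } else {
    if (length(mri_lists) < 2) {
      rlang::abort("At least 2 method lists are required for consensus.")
    }
    if (is.null(names(mri_lists)) || any(!nzchar(names(mri_lists)))) {
      rlang::abort("`mri_lists` must be a named list (names = method labels).")
    }
    all_mri <- dplyr::bind_rows(
      purrr::imap(mri_lists, function(tb, nm) dplyr::mutate(tb, method = nm)))
  }
  if (dplyr::n_distinct(all_mri$method) < 2) {
    rlang::abort("At least 2 distinct methods are required for consensus.")
  }
  out <- list()
  for (dir in unique(all_mri$direction)) {
    d <- all_mri[all_mri$direction == dir, ]
    gr <- GenomicRanges::GRanges(
      d$chrom, IRanges::IRanges(d$start + 1L, d$end))
    pools <- GenomicRanges::reduce(gr, min.gapwidth = 0L)
    hit <- GenomicRanges::findOverlaps(gr, pools)
    pool_of <- S4Vectors::subjectHits(hit)[order(S4Vectors::queryHits(hit))]
    d$pool <- pool_of
    agg <- d |>
      dplyr::group_by(.data$pool) |>
      dplyr::summarise(
        chrom = .data$chrom[1],
        direction = dir,
        start = min(.data$start),
        end = max(.data$end),
        n_methods = dplyr::n_distinct(.data$method),
        methods = paste(sort(unique(.data$method)), collapse = ","),
        n_members = dplyr::n(), .groups = "drop") |>
      dplyr::select(-"pool")
    out[[dir]] <- agg[agg$n_methods >= min_methods, ]
  }
  res <- dplyr::bind_rows(out)
  res <- res[order(chrom_factor(res$chrom), res$start), ]
  new_swat_tbl(res, "swat_consensus")
}

#' Intersect the two prioritisation schemes
#'
#' Keeps consensus regions flagged by both the amplitude-based and the
#' gene-density-weighted prioritisations: regions of the two lists that
#' overlap (>= 1 bp, same direction) are pooled transitively; pools with
#' members from both lists survive, with the pooled span.
#'
#' @param amplitude_list,gdw_list `swat_consensus` tibbles.
#' @return A `swat_consensus` tibble with logical columns
#'   `in_amplitude_list` and `in_gdw_list` (both `TRUE` on kept rows).
#' @export
intersect_prioritizations <- function(amplitude_list, gdw_list) {
  empty <- new_swat_tbl(tibble::tibble(
    chrom = character(), direction = character(), start = integer(),
    end = integer(), n_methods = integer(), methods = character(),
    in_amplitude_list = logical(), in_gdw_list = logical()
  ), "swat_consensus")
  if (nrow(amplitude_list) == 0 || nrow(gdw_list) == 0) return(empty)
  both <- dplyr::bind_rows(
    dplyr::mutate(amplitude_list, .source = "amplitude"),
    dplyr::mutate(gdw_list, .source = "gdw"))
  out <- list()
  for (dir in unique(both$direction)) {
    d <- both[both$direction == dir, ]
    gr <- GenomicRanges::GRanges(d$chrom, IRanges::IRanges(d$start + 1L, d$end))
    pools <- GenomicRanges::reduce(gr, min.gapwidth = 0L)
    hit <- GenomicRanges::findOverlaps(gr, pools)
    d$pool <- S4Vectors::subjectHits(hit)[order(S4Vectors::queryHits(hit))]
    agg <- d |>
      dplyr::group_by(.data$pool) |>
      dplyr::summarise(
        chrom = .data$chrom[1],
        direction = dir,
        start = min(.data$start),
        end = max(.data$end),
        n_methods = max(.data$n_methods),
        methods = paste(sort(unique(unlist(strsplit(.data$methods, ",")))),
                        collapse = ","),
        in_amplitude_list = any(.data$.source == "amplitude"),
        in_gdw_list = any(.data$.source == "gdw"),
        .groups = "drop") |>
      dplyr::select(-"pool")
    out[[dir]] <- agg[agg$in_amplitude_list & agg$in_gdw_list, ]
  }
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0) return(empty)
  res <- res[order(chrom_factor(res$chrom), res$start), ]
  new_swat_tbl(res, "swat_consensus")
}

#' Unsupervised hierarchical clustering of samples on gated CRIs
#'
#' Builds the feature matrix from the classification calls at probes inside
#' CRIs whose chosen adaptive threshold is at least `min_at` (so only
#' regions recurrent in a sufficient fraction of the cohort drive the
#' clustering), then clusters the sample columns agglomeratively.
#'
#' @param calls A `swat_calls` table.
#' @param cris CRI tibble (from [swat_regions()]`$cri`) with `chrom`,
#'   `probe_first`, `probe_last`, `at`; typically restricted to one window
#'   size beforehand.
#' @param min_at Minimum adaptive threshold (percentage, default 40).
#' @param n_groups Number of groups to cut the tree into (default 3).
#' @param distance,linkage Distance measure for [stats::dist()] and
#'   agglomeration method for [stats::hclust()] (defaults: Euclidean
#'   distance on the integer call vectors, Ward linkage).
#' @return A `swat_clusters` list: `tree` (an `hclust`), `groups` (named
#'   integer vector, one group per sample), `feature_probes` (tibble of the
#'   probes used), `n_groups`.
#' @export
cluster_samples <- function(calls, cris, min_at = 40, n_groups = 3,
                            distance = "euclidean", linkage = "ward.D2") {
  assert_calls(calls)
  samples <- sample_ids(calls)
  if (length(samples) < 2) rlang::abort("Clustering needs at least 2 samples.")
  keep_cri <- cris[!is.na(cris$at) & cris$at >= min_at, ]
  if (nrow(keep_cri) == 0) {
    rlang::abort(sprintf(
      "No CRI passes the minimum adaptive threshold of %s%%; nothing to cluster on.",
      format(min_at)))
  }
  sel <- logical(nrow(calls))
  for (i in seq_len(nrow(keep_cri))) {
    idx <- which(calls$chrom == keep_cri$chrom[i])
    sel[idx[keep_cri$probe_first[i]:keep_cri$probe_last[i]]] <- TRUE
  }
  feat <- as.matrix(as.data.frame(calls)[sel, samples, drop = FALSE])
  tree <- stats::hclust(stats::dist(t(feat), method = distance),
                        method = linkage)
  groups <- stats::cutree(tree, k = min(n_groups, length(samples)))
  structure(list(tree = tree, groups = groups,
                 feature_probes = calls[sel, meta_cols],
                 n_groups = as.integer(n_groups)),
            class = "swat_clusters")
}

#' @export
print.swat_clusters <- function(x, ...) {
  cat(sprintf("<swat_clusters> %d samples, %d feature probes, %d groups\n",
              length(x$groups), nrow(x$feature_probes), x$n_groups))
  invisible(x)
}

#' Export the sample tree as Newick
#'
#' @param clusters A `swat_clusters` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cluster_newick <- function(clusters, path) {
  if (!requireNamespace("ape", quietly = TRUE)) {
    rlang::abort("Package 'ape' is required for Newick export.")
  }
  ape::write.tree(ape::as.phylo(clusters$tree), file = path)
  invisible(path)
}

#' Per-region, per-sample CNA fraction matrix
#'
#' For each region and sample, the fraction of the region's probes called
#' gained minus the fraction called lost, in \[-1, 1\] (the region-level
#' summary underlying the consensus heatmap).
#'
#' @param calls A `swat_calls` table.
#' @param regions Tibble with `chrom`, `start`, `end` (0-based half-open)
#'   and optionally `direction`.
#' @return Long tibble: `region`, `chrom`, `start`, `end`, `sample`,
#'   `value`.
#' @export
region_heatmap_matrix <- function(calls, regions) {
  assert_calls(calls)
  if (nrow(regions) == 0) {
    rlang::abort("`regions` must be non-empty.")
  }
  samples <- sample_ids(calls)
  m <- as.matrix(as.data.frame(calls)[, samples, drop = FALSE])
  rows <- purrr::map(seq_len(nrow(regions)), function(i) {
    idx <- which(calls$chrom == regions$chrom[i] &
                   calls$start < regions$end[i] &
                   calls$end > regions$start[i])
    frac_gain <- colMeans(m[idx, , drop = FALSE] > 0)
    frac_loss <- colMeans(m[idx, , drop = FALSE] < 0)
    tibble::tibble(region = i, chrom = regions$chrom[i],
                   start = regions$start[i], end = regions$end[i],
                   sample = samples, value = unname(frac_gain - frac_loss))
  })
  dplyr::bind_rows(rows)
}
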