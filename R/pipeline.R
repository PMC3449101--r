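#' Run the full recurrence analysis
#'
#' End-to-end driver: for each segmentation method, classifies probes,
#' collapses calls to direction, computes all sliding-window score tracks,
#' applies adaptive thresholds and extracts CRIs/MRIs, and prioritises MRIs
#' by amplitude significance and gene-density weighting. With two or more
#' methods, per-method MRI lists are consolidated into consensus regions
#' (amplitude list and gene-weighted list — the latter restricted to
#' gene-containing regions, i.e. GDW > 0 — then intersected). Samples are
#' clustered on the calls inside strongly recurrent CRIs (adaptive
#' threshold at least `cluster_min_at`).
#'
#' @param probes A `swat_probes` object (missing values are imputed).
#' @param segments A `swat_segments` tibble (one or more methods), or a
#'   list of them.
#' @param genes Optional `swat_genes` annotation for gene-density scores.
#' @param config A [swat_config()].
#' @param cluster_method Method whose calls drive the sample clustering
#'   (default: the first method).
#' @param out_dir If non-`NULL`, a web-style report is written there.
#' @return A `swat_result` list: `probes`, `config`, `methods` (per-method
#'   list of `calls`, `direction`, `tracks`, `regions`, `priority`),
#'   `consensus` (`amplitude`, `gdw`, `final`, or `NULL` with one method),
#'   `clusters` (or `NULL`), `heatmap` (long tibble, or `NULL`).
#' @export
swat_run <- function(probes, segments, genes = NULL, config = swat_config(),
                     cluster_method = NULL, out_dir = NULL) {
  assert_probes(probes)
  if (is.list(segments) && !is.data.frame(segments)) {
    segments <- bind_segments(segments)
  }
  if (anyNA(as.data.frame(probes)[, sample_ids(probes)])) {
    probes <- impute_log2(probes)
  }
  methods <- unique(segments$method)
  per_method <- list()
  t0 <- proc.time()[["elapsed"]]
  for (mth in methods) {
    message(sprintf("[swatcna] %-12s classify + windows + regions ...", mth))
    calls <- classify_segments(segments[segments$method == mth, ], probes, config)
    dirs <- collapse_direction(calls)
    tracks <- compute_all_tracks(dirs, config)
    regions <- swat_regions(tracks, probes, config)
    priority <- swat_prioritize(regions, probes, genes, config)
    per_method[[mth]] <- list(calls = calls, direction = dirs,
                              tracks = tracks, regions = regions,
                              priority = priority)
  }
  consensus <- NULL
  if (length(methods) >= 2) {
    amp_lists <- purrr::map(per_method, "priority")
    gdw_lists <- purrr::map(amp_lists, function(p) p[p$gdw > 0, ])
    nonempty <- function(ls) sum(vapply(ls, nrow, integer(1)) > 0) >= 2
    amp_cons <- if (nonempty(amp_lists)) {
      consensus_merge(amp_lists, config$consensus_min_methods)
    } else NULL
    gdw_cons <- if (nonempty(gdw_lists)) {
      consensus_merge(gdw_lists, config$consensus_min_methods)
    } else NULL
    final <- if (!is.null(amp_cons) && !is.null(gdw_cons)) {
      intersect_prioritizations(amp_cons, gdw_cons)
    } else NULL
    consensus <- list(amplitude = amp_cons, gdw = gdw_cons, final = final)
  }
  cluster_method <- cluster_method %||% methods[1]
  cm <- per_method[[cluster_method]]
  cri_w <- cm$regions$cri
  if (nrow(cri_w)) cri_w <- cri_w[cri_w$w == config$report_window, ]
  clusters <- tryCatch(
    cluster_samples(cm$calls, cri_w, min_at = config$cluster_min_at,
                    n_groups = config$n_groups,
                    distance = config$cluster_distance,
                    linkage = config$cluster_linkage),
    error = function(e) {
      rlang::inform(paste("Clustering skipped:", conditionMessage(e)))
      NULL
    })
  heat_regions <- if (!is.null(consensus) && !is.null(consensus$final) &&
                      nrow(consensus$final) > 0) {
    consensus$final
  } else if (nrow(cri_w) > 0) {
    cri_w
  } else NULL
  heatmap <- if (!is.null(heat_regions)) {
    region_heatmap_matrix(cm$calls, heat_regions)
  } else NULL
  message(sprintf("[swatcna] analysis finished in %.1f s",
                  proc.time()[["elapsed"]] - t0))
  res <- structure(list(probes = probes, config = config,
                        methods = per_method, consensus = consensus,
                        clusters = clusters, heatmap = heatmap,
                        cluster_method = cluster_method),
                   class = "swat_result")
  if (!is.null(out_dir)) swat_report(res, out_dir)
  res
}

#' @export
print.swat_result <- function(x, ...) {
  cat(sprintf("<swat_result> %d sample(s), %d probe(s), method(s): %s\n",
              length(sample_ids(x$probes)), nrow(x$probes),
              paste(names(x$methods), collapse = ", ")))
  for (mth in names(x$methods)) {
    r <- x$methods[[mth]]$regions
    p <- x$methods[[mth]]$priority
    cat(sprintf("  %-12s %4d CRI(s), %4d MRI(s), %3d significant at w=%d\n",
                mth, nrow(r$cri), nrow(r$mri), nrow(p),
                x$config$report_window))
  }
  if (!is.null(x$consensus) && !is.null(x$consensus$final)) {
    cat(sprintf("  consensus    %d region(s) in both prioritisation lists\n",
                nrow(x$consensus$final)))
  }
  invisible(x)
}
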