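# broom-style tidiers for the fitted/derived objects.

#' Tidy region-detection results
#'
#' @param x A `swat_regions` object.
#' @param type Which table to return: `"mri"` (default), `"cri"` or
#'   `"thresholds"`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy swat_regions
#' @export
tidy.swat_regions <- function(x, type = c("mri", "cri", "thresholds"), ...) {
  type <- match.arg(type)
  tibble::as_tibble(x[[type]])
}

#' @describeIn tidy.swat_regions One-row summary: region counts and the
#'   probe coverage attained by the adaptive thresholds.
#' @method glance swat_regions
#' @export
glance.swat_regions <- function(x, ...) {
  th <- x$thresholds
  tibble::tibble(
    n_tracks = nrow(th),
    n_tracks_with_cna = sum(!is.na(th$chosen_at)),
    n_cri = nrow(x$cri),
    n_mri = nrow(x$mri),
    mean_coverage = mean(th$coverage))
}

#' Tidy sample clustering
#'
#' @param x A `swat_clusters` object.
#' @param ... Unused.
#' @return Tibble with one row per sample: `sample`, `group`.
#' @method tidy swat_clusters
#' @export
tidy.swat_clusters <- function(x, ...) {
  tibble::tibble(sample = names(x$groups), group = unname(x$groups))
}

#' @describeIn tidy.swat_clusters One-row summary of the clustering.
#' @method glance swat_clusters
#' @export
glance.swat_clusters <- function(x, ...) {
  tibble::tibble(n_samples = length(x$groups),
                 n_groups = length(unique(x$groups)),
                 n_feature_probes = nrow(x$feature_probes))
}

#' Tidy a full analysis result
#'
#' @param x A `swat_result` from [swat_run()].
#' @param what `"consensus"` (default; the final intersected consensus
#'   regions, falling back to the first method's prioritised MRIs when only
#'   one method was run) or `"priority"`, `"cri"`, `"mri"` for the chosen
#'   method's tables.
#' @param method Method name for the per-method tables.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy swat_result
#' @export
tidy.swat_result <- function(x, what = c("consensus", "priority", "cri", "mri"),
                             method = NULL, ...) {
  what <- match.arg(what)
  method <- method %||% names(x$methods)[1]
  if (what == "consensus") {
    if (!is.null(x$consensus) && !is.null(x$consensus$final)) {
      return(tibble::as_tibble(x$consensus$final))
    }
    return(tibble::as_tibble(x$methods[[method]]$priority))
  }
  switch(what,
         priority = tibble::as_tibble(x$methods[[method]]$priority),
         cri = tibble::as_tibble(x$methods[[method]]$regions$cri),
         mri = tibble::as_tibble(x$methods[[method]]$regions$mri))
}

#' @describeIn tidy.swat_result One row per method: region and
#'   significance counts.
#' @method glance swat_result
#' @export
glance.swat_result <- function(x, ...) {
  dplyr::bind_rows(purrr::imap(x$methods, function(m, nm) {
    tibble::tibble(method = nm,
                   n_cri = nrow(m$regions$cri),
                   n_mri = nrow(m$regions$mri),
                   n_significant = nrow(m$priority),
                   mean_coverage = mean(m$regions$thresholds$coverage))
  }))
}
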