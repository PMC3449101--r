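#' Per-sample abnormality threshold from the middle fifty of the distributions
#'
#' A segment of a sample is declared copy-number abnormal when its absolute
#' mean log2 ratio exceeds a per-sample threshold T. T is the absolute
#' difference between the inter-quartile range of the sample's observed
#' probe log2 ratios and the IQR of the segmentation-predicted values (each
#' probe's segment mean), scaled by the `factor_change` fraction:
#' `T = |IQR(observed) - IQR(predicted)| * factor_change`. Quartiles use the
#' default linear-interpolation (type 7) estimator.
#'
#' @param observed Numeric vector of a sample's observed probe log2 ratios.
#' @param predicted Numeric vector of the same length: each probe's segment
#'   mean under the segmentation being classified.
#' @param factor_change Scaling fraction; the default analysis uses 0.75.
#' @return A single non-negative threshold in log2 units. When both IQRs are
#'   zero (all-constant input) the threshold is 0 with a warning, so every
#'   non-zero segment mean is called abnormal.
#' @examples
#' # IQR(observed) = 0.40, IQR(predicted) = 0.10 -> T = 0.3 * 0.75 = 0.225
#' @export
nud_threshold <- function(observed, predicted, factor_change = 0.75) {
  if (sum(!is.na(observed)) < 4 || sum(!is.na(predicted)) < 4) {
    rlang::abort("Need at least 4 non-missing observations per sample.")
  }
  iqr_obs <- stats::IQR(observed, na.rm = TRUE, type = 7)
  iqr_pred <- stats::IQR(predicted, na.rm = TRUE, type = 7)
  if (iqr_obs == 0 && iqr_pred == 0) {
    rlang::warn("Both observed and predicted IQRs are zero; threshold is 0.")
  }
  abs(iqr_obs - iqr_pred) * factor_change
}

#' Five-point classification of segmented probes
#'
#' Converts one segmentation method's segment calls into the probe x sample
#' classification table over `{-2, -1, 0, 1, 2}` (high-level loss, loss,
#' normal, gain, high-level gain/amplification). Per sample, a segment is
#' abnormal when `|segment mean| > T` with T from [nud_threshold()];
#' abnormal segments spanning at most `highlevel_max_width` probes are
#' called high-level (call +/-2), wider abnormal segments single-copy
#' (call +/-1), the sign taken from the segment mean. All probes of a
#' segment carry the segment's call.
#'
#' @param segments A `swat_segments` tibble holding exactly one method.
#' @param probes A `swat_probes` object; every probe of every sample must be
#'   covered by a segment (impute/fill gaps upstream).
#' @param config A [swat_config()] list (`factor_change`,
#'   `highlevel_max_width`, and the optional `highlevel_amplitude_check`
#'   which additionally requires `|segment mean| > 2 T` for high-level calls).
#' @return A `swat_calls` tibble: probe metadata columns plus one integer
#'   call column per sample. The per-sample thresholds are stored in the
#'   `"thresholds"` attribute.
#' @export
classify_segments <- function(segments, probes, config = swat_config()) {
  assert_probes(probes)
  methods <- unique(segments$method)
  if (length(methods) != 1) {
    rlang::abort(sprintf("`classify_segments()` takes a single method; got: %s",
                         paste(methods, collapse = ", ")))
  }
  m <- sample_matrix(probes)
  samples <- colnames(m)
  miss <- setdiff(samples, unique(segments$sample))
  if (length(miss)) {
    rlang::abort(sprintf("No segments for sample(s): %s",
                         paste(miss, collapse = ", ")))
  }
  calls <- matrix(0L, nrow = nrow(probes), ncol = length(samples),
                  dimnames = list(NULL, samples))
  thresholds <- setNames(numeric(length(samples)), samples)
  for (s in samples) {
    seg_s <- segments[segments$sample == s, ]
    predicted <- rep(NA_real_, nrow(probes))
    seg_of_probe <- rep(NA_integer_, nrow(probes))
    for (ch in unique(probes$chrom)) {
      pidx <- which(probes$chrom == ch)
      sc <- seg_s[seg_s$chrom == ch, ]
      if (nrow(sc) == 0) {
        rlang::abort(sprintf(
          "Probe(s) on chromosome %s of sample '%s' not covered by any segment.",
          ch, s))
      }
      hit <- findInterval(probes$start[pidx], sc$start)
      inside <- hit >= 1 & probes$start[pidx] < sc$end[pmax(hit, 1L)]
      if (!all(inside)) {
        rlang::abort(sprintf(
          "Probe '%s' (sample '%s') is not covered by any segment.",
          probes$probe_id[pidx[which(!inside)[1]]], s))
      }
      predicted[pidx] <- sc$seg_mean[hit]
      seg_of_probe[pidx] <- match(ch, unique(probes$chrom)) * 1e6L + hit
    }
    th <- nud_threshold(m[, s], predicted, config$factor_change)
    thresholds[[s]] <- th
    # per-segment call, applied to all of its probes
    grp <- split(seq_len(nrow(probes)), seg_of_probe)
    for (g in grp) {
      mu <- predicted[g[1]]
      width <- length(g)
      call <- 0L
      if (abs(mu) > th) {
        high <- width <= config$highlevel_max_width
        if (high && config$highlevel_amplitude_check) {
          high <- abs(mu) > 2 * th
        }
        call <- as.integer(sign(mu)) * (if (high) 2L else 1L)
      }
      calls[g, s] <- call
    }
  }
  out <- dplyr::bind_cols(probes[, meta_cols], tibble::as_tibble(calls))
  out <- new_swat_tbl(out, "swat_calls")
  attr(out, "thresholds") <- thresholds
  attr(out, "method") <- methods
  out
}

#' Collapse calls to CNA direction
#'
#' Combines gain with amplification and loss with deletion: calls in
#' `{1, 2}` map to 1, `{-1, -2}` to -1, normal stays 0. Window scoring and
#' region detection operate on this direction table.
#'
#' @param calls A `swat_calls` object.
#' @return A `swat_calls`-shaped tibble with values in `{-1, 0, 1}` and
#'   class `swat_direction`.
#' @export
collapse_direction <- function(calls) {
  assert_calls(calls)
  out <- calls
  for (s in sample_ids(calls)) {
    out[[s]] <- as.integer(sign(calls[[s]]))
  }
  class(out) <- c("swat_direction", class(tibble::tibble()))
  attr(out, "method") <- attr(calls, "method")
  out
}

#' Write a classification table as TSV
#'
#' Probe rows, sample columns, integer calls in `{-2,...,2}`; positions are
#' printed 1-based.
#'
#' @param calls A `swat_calls` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_calls_tsv <- function(calls, path) {
  out <- tibble::as_tibble(calls)
  out$start <- out$start + 1L
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
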