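#' Construct a probe matrix
#'
#' Low-level constructor for the canonical probe-level container: a tibble
#' with metadata columns `probe_id`, `chrom`, `start`, `end` (0-based
#' half-open genomic coordinates) followed by one numeric log2-ratio column
#' per sample. Rows are sorted by genome position. Most users will call
#' [read_probe_matrix()] or [simulate_cohort()] instead.
#'
#' @param meta Tibble/data frame with columns `probe_id`, `chrom`, `start`,
#'   `end` (0-based half-open).
#' @param log2 Numeric matrix, probes x samples; column names are sample ids.
#' @return A `swat_probes` tibble.
#' @export
swat_probes <- function(meta, log2) {
  meta <- tibble::as_tibble(meta)
  stopifnot(all(meta_cols %in% names(meta)))
  log2 <- as.matrix(log2)
  if (nrow(log2) != nrow(meta)) {
    rlang::abort("`log2` must have one row per probe.")
  }
  if (is.null(colnames(log2)) || anyDuplicated(colnames(log2))) {
    rlang::abort("`log2` must have unique sample column names.")
  }
  if (anyDuplicated(meta$probe_id)) {
    rlang::abort("Duplicate probe_id values are not allowed.")
  }
  if (any(meta$start > meta$end)) {
    rlang::abort("Probe start must be <= end.")
  }
  x <- dplyr::bind_cols(
    meta[, meta_cols],
    tibble::as_tibble(log2)
  )
  x <- x[order(chrom_factor(x$chrom), x$start), ]
  new_swat_tbl(x, "swat_probes")
}

#' Read a probe-level log2-ratio matrix
#'
#' Reads a tab-delimited table whose header row is `probe_id`, `chromosome`
#' (or `chrom`), `start`, `end`, followed by one column per sample.
#' Coordinates in the file are 1-based inclusive (the convention of array
#' manifest files) and are converted to the package-internal 0-based
#' half-open representation. Non-numeric log2 cells become missing values.
#' Probes on chromosomes outside the declared autosome set are dropped with
#' a message; rows are sorted by genome position regardless of input order.
#'
#' @param path Path to the TSV file.
#' @param autosomes Character vector of chromosome labels to keep (after
#'   stripping any `chr` prefix). Defaults to the human autosomes 1--22.
#' @return A `swat_probes` tibble (see [swat_probes()]).
#' @export
read_probe_matrix <- function(path, autosomes = as.character(1:22)) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  names(raw)[1:4] <- tolower(names(raw)[1:4])
  names(raw)[names(raw) %in% c("chromosome", "chr")] <- "chrom"
  need <- c("probe_id", "chrom", "start", "end")
  if (!all(need %in% names(raw)[1:4])) {
    rlang::abort("Header must start with: probe_id, chromosome, start, end.")
  }
  samples <- setdiff(names(raw), need)
  if (length(samples) < 2) {
    rlang::abort("A probe matrix needs at least 2 sample columns.")
  }
  if (anyDuplicated(raw$probe_id)) {
    dup <- raw$probe_id[duplicated(raw$probe_id)][1]
    rlang::abort(sprintf("Duplicate probe_id '%s' in %s.", dup, path))
  }
  meta <- tibble::tibble(
    probe_id = raw$probe_id,
    chrom = norm_chrom(raw$chrom),
    start = as.integer(raw$start) - 1L,
    end = as.integer(raw$end)
  )
  log2 <- vapply(raw[samples], function(col) suppressWarnings(as.numeric(col)),
                 numeric(nrow(raw)))
  log2 <- matrix(log2, nrow = nrow(raw), dimnames = list(NULL, samples))
  keep <- meta$chrom %in% autosomes
  if (!all(keep)) {
    rlang::inform(sprintf("Dropped %d probe(s) outside the autosome set.", sum(!keep)))
  }
  swat_probes(meta[keep, ], log2[keep, , drop = FALSE])
}

#' Write a probe matrix back to TSV
#'
#' Inverse of [read_probe_matrix()]: coordinates are printed 1-based
#' inclusive, so a write/read round trip reproduces the in-memory object.
#'
#' @param probes A `swat_probes` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_probe_matrix <- function(probes, path) {
  assert_probes(probes)
  out <- tibble::as_tibble(probes)
  out$start <- out$start + 1L
  names(out)[names(out) == "chrom"] <- "chromosome"
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Impute missing log2 ratios
#'
#' Replaces each missing probe value, per sample and per chromosome, by the
#' mean of the nearest non-missing flanking probes (one value at chromosome
#' ends). The number of imputed cells is reported and stored in the
#' `"n_imputed"` attribute.
#'
#' @param probes A `swat_probes` object.
#' @return The probe matrix with no missing values (samples that are missing
#'   on an entire chromosome are left missing there and trigger a warning).
#' @export
impute_log2 <- function(probes) {
  assert_probes(probes)
  m <- sample_matrix(probes)
  n_imp <- 0L
  for (ch in unique(probes$chrom)) {
    idx <- which(probes$chrom == ch)
    for (j in seq_len(ncol(m))) {
      v <- m[idx, j]
      na <- which(is.na(v))
      if (!length(na)) next
      ok <- which(!is.na(v))
      if (!length(ok)) {
        rlang::warn(sprintf(
          "Sample '%s' has no values on chromosome %s; cannot impute.",
          colnames(m)[j], ch))
        next
      }
      for (i in na) {
        lo <- ok[ok < i]
        hi <- ok[ok > i]
        flank <- c(if (length(lo)) v[max(lo)], if (length(hi)) v[min(hi)])
        v[i] <- mean(flank)
      }
      n_imp <- n_imp + length(na)
      m[idx, j] <- v
    }
  }
  if (n_imp > 0) rlang::inform(sprintf("Imputed %d missing log2 value(s).", n_imp))
  out <- swat_probes(probes[, meta_cols], m)
  attr(out, "n_imputed") <- n_imp
  out
}
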