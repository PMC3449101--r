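#' Read per-sample segment calls (SEG dialect)
#'
#' Reads a SEG-style table of constant-copy-number segments produced by an
#' external segmentation algorithm (DNAcopy, GLAD, HMM variants, ...).
#' Expected columns, in order: sample, chromosome, start, end, and either
#' `seg_mean` or `num_probes, seg_mean`. A header row is optional; fields may
#' be tab- or whitespace-delimited. Chromosome labels are normalised by
#' stripping any `chr` prefix; input coordinates are 1-based inclusive and
#' converted to 0-based half-open.
#'
#' Within each sample and chromosome, segments must tile the chromosome:
#' overlapping segments are always an error; gaps between consecutive
#' segments are an error unless `fill_gaps = TRUE`, in which case the gap is
#' closed by extending the nearest flanking segment (split at the midpoint).
#'
#' @param path Path to the SEG file.
#' @param method Label of the segmentation method that produced the file.
#' @param sample_map Optional named character vector mapping file sample
#'   names to cohort sample ids (`c(file_name = "cohort_name")`).
#' @param fill_gaps Close inter-segment gaps by nearest-segment extension.
#' @return A `swat_segments` tibble with columns `method`, `sample`,
#'   `chrom`, `start`, `end`, `n_probes`, `seg_mean`.
#' @export
read_segments <- function(path, method, sample_map = NULL, fill_gaps = FALSE) {
  first <- readLines(path, n = 1L, warn = FALSE)
  fields1 <- strsplit(trimws(first), "[\t ]+")[[1]]
  has_header <- length(fields1) >= 3 &&
    is.na(suppressWarnings(as.numeric(fields1[3])))
  raw <- utils::read.table(path, header = has_header, sep = "",
                           stringsAsFactors = FALSE)
  if (ncol(raw) == 5) {
    names(raw) <- c("sample", "chrom", "start", "end", "seg_mean")
    raw$n_probes <- NA_integer_
  } else if (ncol(raw) >= 6) {
    raw <- raw[, 1:6]
    names(raw) <- c("sample", "chrom", "start", "end", "n_probes", "seg_mean")
  } else {
    rlang::abort("SEG file must have 5 or 6 columns (sample, chrom, start, end, [num_probes,] seg_mean).")
  }
  seg <- tibble::tibble(
    method = method,
    sample = as.character(raw$sample),
    chrom = norm_chrom(raw$chrom),
    start = as.integer(raw$start) - 1L,
    end = as.integer(raw$end),
    n_probes = as.integer(raw$n_probes),
    seg_mean = as.numeric(raw$seg_mean)
  )
  if (!is.null(sample_map)) {
    hit <- seg$sample %in% names(sample_map)
    seg$sample[hit] <- unname(sample_map[seg$sample[hit]])
  }
  seg <- seg[order(seg$sample, chrom_factor(seg$chrom), seg$start), ]
  seg <- validate_segments(seg, fill_gaps = fill_gaps)
  new_swat_tbl(seg, "swat_segments")
}

validate_segments <- function(seg, fill_gaps = FALSE) {
  pieces <- split(seg, list(seg$sample, seg$chrom), drop = TRUE)
  fixed <- lapply(pieces, function(p) {
    if (nrow(p) < 2) return(p)
    for (i in 2:nrow(p)) {
      if (p$start[i] < p$end[i - 1]) {
        rlang::abort(sprintf(
          "Overlapping segments for sample '%s' chromosome %s near position %d.",
          p$sample[1], p$chrom[1], p$start[i] + 1L))
      }
      if (p$start[i] > p$end[i - 1]) {
        if (!fill_gaps) {
          rlang::abort(sprintf(
            "Gap between segments for sample '%s' chromosome %s at %d-%d; set fill_gaps = TRUE to close gaps by nearest-segment extension.",
            p$sample[1], p$chrom[1], p$end[i - 1] + 1L, p$start[i]))
        }
        mid <- (p$end[i - 1] + p$start[i]) %/% 2L
        p$end[i - 1] <- mid
        p$start[i] <- mid
      }
    }
    p
  })
  out <- dplyr::bind_rows(fixed)
  out[order(out$sample, chrom_factor(out$chrom), out$start), ]
}

#' Combine segment sets from several methods
#'
#' @param ... `swat_segments` objects (or a single list of them).
#' @return One `swat_segments` tibble keyed by `(method, sample)`.
#' @export
bind_segments <- function(...) {
  dots <- list(...)
  if (length(dots) == 1 && is.list(dots[[1]]) && !is.data.frame(dots[[1]])) {
    dots <- dots[[1]]
  }
  new_swat_tbl(dplyr::bind_rows(dots), "swat_segments")
}
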