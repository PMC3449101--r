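#' Export regions of interest as BED
#'
#' Writes CRI (or MRI) records as a BED file: 0-based half-open coordinates,
#' name `<direction>_CRI_<serial index>` (e.g. `gain_CRI_3`), score = peak
#' PWS x 10 (so a 100% window scores the BED maximum of 1000). Rows are in
#' genome order. An empty region list produces a file holding only the track
#' header.
#'
#' @param regions Tibble of regions with columns `chrom`, `start`, `end`,
#'   `direction`, `cri` (serial index) and `peak_pws` (see [swat_regions()]).
#' @param path Output path.
#' @param track_name Name used in the BED track header line.
#' @return `path`, invisibly.
#' @seealso [read_regions_bed()] for the round-trip reader.
#' @export
write_regions_bed <- function(regions, path, track_name = "swatcna_regions") {
  header <- sprintf("track name=%s description=\"CNA regions of interest\"",
                    track_name)
  if (is.null(regions) || nrow(regions) == 0) {
    writeLines(header, path)
    return(invisible(path))
  }
  regions <- regions[order(chrom_factor(regions$chrom), regions$start), ]
  lines <- sprintf("%s\t%d\t%d\t%s_CRI_%d\t%d",
                   regions$chrom, regions$start, regions$end,
                   regions$direction, regions$cri,
                   as.integer(round(regions$peak_pws * 10)))
  writeLines(c(header, lines), path)
  invisible(path)
}

#' Read back a regions BED file
#'
#' Inverse of [write_regions_bed()]: reconstructs `chrom`, `start`, `end`,
#' `direction`, `cri` and `peak_pws` from the BED fields.
#'
#' @param path Path to a BED file written by [write_regions_bed()].
#' @return A tibble in genome order.
#' @export
read_regions_bed <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !grepl("^(track|browser|#)", lines)]
  if (!length(lines)) {
    return(tibble::tibble(chrom = character(), start = integer(),
                          end = integer(), direction = character(),
                          cri = integer(), peak_pws = numeric()))
  }
  f <- do.call(rbind, strsplit(lines, "\t", fixed = TRUE))
  name <- f[, 4]
  m <- regmatches(name, regexec("^(gain|loss)_CRI_([0-9]+)$", name))
  bad <- which(lengths(m) != 3)
  if (length(bad)) {
    rlang::abort(sprintf("Unrecognised region name '%s' in %s.", name[bad[1]], path))
  }
  tibble::tibble(
    chrom = f[, 1],
    start = as.integer(f[, 2]),
    end = as.integer(f[, 3]),
    direction = vapply(m, `[`, "", 2),
    cri = as.integer(vapply(m, `[`, "", 3)),
    peak_pws = as.numeric(f[, 5]) / 10
  )
}
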