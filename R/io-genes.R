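#' Read gene annotation from BED or GFF3
#'
#' Gene records are used for gene-density weighting (RIC/GDW). The dialect
#' is auto-detected from the file extension (`.bed` vs `.gff`/`.gff3`) and
#' can be overridden. BED input is 0-based half-open, GFF3 1-based closed;
#' both are normalised to the internal 0-based half-open convention. Strand
#' is read but never used downstream. Duplicate names (e.g. one row per
#' transcript) are allowed; gene overlap counting collapses them by name.
#'
#' @param path Path to a BED or GFF3 file.
#' @param format `"auto"` (default), `"bed"` or `"gff"`.
#' @return A `swat_genes` tibble with columns `name`, `chrom`, `start`,
#'   `end` (0-based half-open), `strand`. An empty file yields an empty
#'   annotation (zero genes for every region downstream).
#' @export
read_genes <- function(path, format = c("auto", "bed", "gff")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("gff", "gff3", "gtf")) "gff" else "bed"
  }
  lines <- readLines(path, warn = FALSE)
  body <- which(nzchar(trimws(lines)) & !grepl("^(#|track|browser)", lines))
  empty <- new_swat_tbl(tibble::tibble(
    name = character(), chrom = character(),
    start = integer(), end = integer(), strand = character()
  ), "swat_genes")
  if (!length(body)) return(empty)

  if (format == "bed") {
    for (i in body) {
      f <- strsplit(lines[[i]], "[\t ]+")[[1]]
      if (length(f) < 3 || anyNA(suppressWarnings(as.integer(f[2:3])))) {
        rlang::abort(sprintf("Unparseable BED line %d in %s: '%s'", i, path, lines[[i]]))
      }
    }
    gr <- rtracklayer::import(path, format = "bed")
    nm <- if (!is.null(gr$name)) as.character(gr$name) else
      paste0("gene_", seq_along(gr))
  } else {
    gr <- tryCatch(
      rtracklayer::import(path, format = "gff3"),
      error = function(e) {
        rlang::abort(sprintf("Unparseable GFF in %s: %s", path, conditionMessage(e)))
      })
    md <- S4Vectors::mcols(gr)
    nm <- rep(NA_character_, length(gr))
    for (key in c("Name", "gene_name", "gene_id", "ID")) {
      if (key %in% names(md)) {
        val <- as.character(md[[key]])
        nm <- dplyr::coalesce(nm, val)
      }
    }
    nm[is.na(nm)] <- paste0("gene_", which(is.na(nm)))
  }
  out <- tibble::tibble(
    name = nm,
    chrom = norm_chrom(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,  # GRanges is 1-based closed
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr))
  )
  if (any(out$start < 0 | out$end < out$start)) {
    rlang::abort(sprintf("Invalid gene coordinates in %s.", path))
  }
  out <- out[order(chrom_factor(out$chrom), out$start), ]
  new_swat_tbl(out, "swat_genes")
}
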