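# Shared internal helpers: chromosome label handling, run extraction,
# lightweight assertions.

norm_chrom <- function(x) {
  sub("^(?i)chr", "", as.character(x), perl = TRUE)
}

# Order chromosome labels numerically where possible ("2" before "10"),
# lexically otherwise.
chrom_order <- function(x) {
  x <- as.character(x)
  num <- suppressWarnings(as.numeric(x))
  order(is.na(num), num, x)
}

chrom_factor <- function(x) {
  lev <- unique(as.character(x))
  lev <- lev[chrom_order(lev)]
  factor(as.character(x), levels = lev)
}

# Maximal runs of TRUE in a logical vector -> tibble(first, last), 1-based.
logical_runs <- function(flag) {
  flag[is.na(flag)] <- FALSE
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  tibble::tibble(first = starts[keep], last = ends[keep])
}

meta_cols <- c("probe_id", "chrom", "start", "end")

assert_probes <- function(x, arg = "probes") {
  if (!inherits(x, "swat_probes")) {
    rlang::abort(sprintf("`%s` must be a `swat_probes` object (see `read_probe_matrix()`).", arg))
  }
  invisible(x)
}

assert_calls <- function(x, arg = "calls") {
  if (!inherits(x, "swat_calls")) {
    rlang::abort(sprintf("`%s` must be a `swat_calls` object (see `classify_segments()`).", arg))
  }
  invisible(x)
}

#' Sample identifiers of a probe matrix or call table
#'
#' @param x A `swat_probes` or `swat_calls` object.
#' @return Character vector of sample column names, in column order.
#' @export
sample_ids <- function(x) {
  setdiff(names(x), meta_cols)
}

# Numeric matrix of the sample columns (probes x samples).
sample_matrix <- function(x) {
  m <- as.matrix(as.data.frame(x)[, sample_ids(x), drop = FALSE])
  rownames(m) <- x$probe_id
  m
}

new_swat_tbl <- function(x, class) {
  class(x) <- c(class, class(tibble::tibble()))
  x
}
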