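# Builders and independent oracles shared across the suite. All fixtures
# are generated in code; nothing is read from disk unless a test writes it
# first.

probe_meta <- function(n, chrom = "1", spacing = 10000L) {
  start <- (seq_len(n) - 1L) * spacing
  tibble::tibble(probe_id = sprintf("P%s_%03d", chrom, seq_len(n)),
                 chrom = chrom, start = start, end = start + 60L)
}

# A swat_calls table from an integer matrix (probes x samples).
calls_table <- function(mat, chrom = "1") {
  n <- nrow(mat)
  if (is.null(colnames(mat))) colnames(mat) <- sprintf("S%02d", seq_len(ncol(mat)))
  meta <- if (length(chrom) == 1) probe_meta(n, chrom) else {
    dplyr::bind_rows(lapply(unique(chrom), function(ch) {
      probe_meta(sum(chrom == ch), ch)
    }))
  }
  out <- dplyr::bind_cols(meta, tibble::as_tibble(mat))
  class(out) <- c("swat_calls", class(tibble::tibble()))
  attr(out, "method") <- "test"
  out
}

dir_table <- function(mat, chrom = "1") {
  out <- calls_table(sign(mat), chrom)
  class(out) <- c("swat_direction", class(tibble::tibble()))
  out
}

# Independent brute-force PWS oracle: per window, per sample loop.
pws_brute <- function(mat, w, target) {
  n <- nrow(mat)
  vapply(seq_len(n - w + 1), function(i) {
    hits <- 0L
    for (s in seq_len(ncol(mat))) {
      ok <- TRUE
      for (p in i:(i + w - 1)) {
        if (is.na(mat[p, s]) || mat[p, s] != target) { ok <- FALSE; break }
      }
      if (ok) hits <- hits + 1L
    }
    100 * hits / ncol(mat)
  }, numeric(1))
}

random_dir_matrix <- function(n_probes, n_samples) {
  matrix(sample(c(-1L, 0L, 1L), n_probes * n_samples, replace = TRUE,
                prob = c(0.25, 0.5, 0.25)),
         nrow = n_probes)
}

# Hand-built swat_pws track for direct unit tests of gating/extraction.
manual_track <- function(scores, w = 3L, chrom = "1", direction = "gain",
                         n_samples = 10L) {
  out <- tibble::tibble(chrom = chrom, w = as.integer(w),
                        direction = direction,
                        start = seq_along(scores),
                        score = as.numeric(scores), n_samples = n_samples)
  class(out) <- c("swat_pws", class(tibble::tibble()))
  out
}

# Adjusted Rand index between two labelled partitions.
adj_rand <- function(a, b) {
  if (requireNamespace("mclust", quietly = TRUE)) {
    return(mclust::adjustedRandIndex(a, b))
  }
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sij <- sum(comb2(tab)); si <- sum(comb2(rowSums(tab)))
  sj <- sum(comb2(colSums(tab))); n <- comb2(sum(tab))
  (sij - si * sj / n) / ((si + sj) / 2 - si * sj / n)
}

probes_from_matrix <- function(mat, chrom = "1") {
  if (is.null(colnames(mat))) colnames(mat) <- sprintf("S%02d", seq_len(ncol(mat)))
  meta <- if (length(chrom) == 1) probe_meta(nrow(mat), chrom) else {
    dplyr::bind_rows(lapply(unique(chrom), function(ch) {
      probe_meta(sum(chrom == ch), ch)
    }))
  }
  swat_probes(meta, mat)
}
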