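#' Toy six-sample, twenty-probe worked example
#'
#' A deterministic miniature aCGH cohort used throughout the documentation
#' and tests: 6 samples (A--F) hybridised to a 20-probe platform carrying
#' regions of copy number gain only. The layout is chosen so that the
#' 3-probe sliding-window scores exhibit the canonical behaviour of the
#' method:
#'
#' * no sample is gained across all of probes 1--3, so the first 3-probe
#'   window scores 0%;
#' * exactly samples A, D and E are gained across probes 2--4, so the
#'   second window scores 50%;
#' * the windows with non-zero score cover exactly probes 2--10 and
#'   12--19, yielding two CRIs at any gating threshold up to 50%;
#' * the first CRI has a single interior PWS maximum (window 4--6, 4/6
#'   samples), so its MRI is strictly inside it, while the second CRI has
#'   flat PWS and its MRI equals the CRI.
#'
#' Gain spans per sample (1-based probes): A 2--10, B 4--10, C 12--19,
#' D 2--6 and 12--19, E 2--10, F 12--19. Gained probes have log2 ratio
#' +0.58 (log2 of 3/2, a single-copy gain), others 0.
#'
#' @return List with `probes` (a `swat_probes`, chromosome "1") and
#'   `calls` (the matching `swat_calls` table, 1 = gain, 0 = normal).
#' @examples
#' fx <- figure1_fixture()
#' dim(fx$probes)
#' @export
figure1_fixture <- function() {
  n <- 20L
  samples <- LETTERS[1:6]
  spans <- list(
    A = list(c(2L, 10L)),
    B = list(c(4L, 10L)),
    C = list(c(12L, 19L)),
    D = list(c(2L, 6L), c(12L, 19L)),
    E = list(c(2L, 10L)),
    F = list(c(12L, 19L))
  )
  calls <- matrix(0L, nrow = n, ncol = length(samples),
                  dimnames = list(NULL, samples))
  for (s in samples) {
    for (sp in spans[[s]]) calls[sp[1]:sp[2], s] <- 1L
  }
  start <- (seq_len(n) - 1L) * 10000L
  meta <- tibble::tibble(probe_id = sprintf("P%02d", seq_len(n)),
                         chrom = "1", start = start, end = start + 60L)
  probes <- swat_probes(meta, calls * 0.58)
  call_tbl <- dplyr::bind_cols(meta, tibble::as_tibble(calls))
  call_tbl <- new_swat_tbl(call_tbl, "swat_calls")
  attr(call_tbl, "method") <- "fixture"
  list(probes = probes, calls = call_tbl)
}
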