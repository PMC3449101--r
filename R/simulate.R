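# Synthetic cohorts: planted-CNA generators and a naive reference
# segmenter, so the whole pipeline runs end-to-end with no external
# segmentation tool. Probes are laid on a uniform 10 kb grid (60 bp
# features), a coarse stand-in for a 44K-style oligonucleotide array.

PROBE_SPACING <- 10000L
PROBE_WIDTH <- 60L

#' Specification of a simulated cohort
#'
#' @param n_samples Number of samples.
#' @param n_chrom Number of chromosomes (labelled "1", "2", ...).
#' @param probes_per_chrom Probes per chromosome (recycled to `n_chrom`).
#' @param events Tibble of planted CNA events with columns `chrom`
#'   (label), `probe_first`, `probe_last` (1-based probe indices within the
#'   chromosome), `direction` (`"gain"`/`"loss"`), `amplitude` (positive
#'   log2 magnitude; defaults 0.58 for gains — log2(3/2), a single-copy
#'   gain in a diploid genome — and 1.0 for losses), `prevalence` (fraction
#'   in (0, 1]), `high_level` (logical, narrow/strong events).
#' @param noise_sd Standard deviation of the iid Gaussian probe noise
#'   (log2 units).
#' @param seed Mandatory integer seed; all draws are reproducible.
#' @return A `sim_spec` list.
#' @export
sim_spec <- function(n_samples, n_chrom = 2, probes_per_chrom = 500,
                     events = sim_events(), noise_sd = 0.05, seed) {
  if (missing(seed)) rlang::abort("`seed` is mandatory for reproducibility.")
  events <- tibble::as_tibble(events)
  probes_per_chrom <- rep_len(probes_per_chrom, n_chrom)
  if (nrow(events)) {
    if (any(events$prevalence <= 0 | events$prevalence > 1)) {
      rlang::abort("Event prevalence must be in (0, 1].")
    }
    npc <- probes_per_chrom[match(events$chrom, as.character(seq_len(n_chrom)))]
    if (anyNA(npc) || any(events$probe_first < 1) ||
        any(events$probe_last > npc) ||
        any(events$probe_first > events$probe_last)) {
      rlang::abort("Event spans must lie within their chromosome.")
    }
  }
  structure(list(n_samples = as.integer(n_samples),
                 n_chrom = as.integer(n_chrom),
                 probes_per_chrom = as.integer(probes_per_chrom),
                 events = events, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "sim_spec")
}

#' Helper to build a planted-event table
#'
#' @param chrom,probe_first,probe_last,direction,amplitude,prevalence,high_level
#'   Vectors (recycled) describing the events; see [sim_spec()].
#' @return Event tibble.
#' @export
sim_events <- function(chrom = character(), probe_first = integer(),
                       probe_last = integer(), direction = character(),
                       amplitude = NULL, prevalence = numeric(),
                       high_level = FALSE) {
  n <- length(chrom)
  if (n == 0) {
    return(tibble::tibble(chrom = character(), probe_first = integer(),
                          probe_last = integer(), direction = character(),
                          amplitude = numeric(), prevalence = numeric(),
                          high_level = logical()))
  }
  if (is.null(amplitude)) {
    amplitude <- ifelse(direction == "gain", 0.58, 1.0)
  }
  tibble::tibble(chrom = as.character(chrom),
                 probe_first = as.integer(probe_first),
                 probe_last = as.integer(probe_last),
                 direction = rep_len(direction, n),
                 amplitude = rep_len(amplitude, n),
                 prevalence = rep_len(prevalence, n),
                 high_level = rep_len(high_level, n))
}

#' Simulate a planted-CNA cohort
#'
#' Log2 ratios are iid Gaussian noise plus, for each planted event, a
#' constant signed amplitude over the event span in carrier samples.
#' Carriers are drawn per event by seeded Bernoulli sampling at the stated
#' prevalence (carrier counts are binomial; the draw is exactly
#' reproducible for a given seed). Where two same-direction events overlap
#' in one sample their amplitudes sum; such events are flagged in the truth
#' table.
#'
#' @param spec A [sim_spec()].
#' @return List of `probes` (a `swat_probes`) and `truth` (the event table
#'   with added `carriers` — comma-joined sample ids — `n_carriers`,
#'   genomic `start`/`end`, and an `overlaps` flag).
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  set.seed(spec$seed)
  samples <- sprintf("S%02d", seq_len(spec$n_samples))
  chroms <- as.character(seq_len(spec$n_chrom))
  meta <- dplyr::bind_rows(purrr::map2(chroms, spec$probes_per_chrom, function(ch, np) {
    start <- (seq_len(np) - 1L) * PROBE_SPACING
    tibble::tibble(probe_id = sprintf("P%s_%04d", ch, seq_len(np)),
                   chrom = ch, start = start, end = start + PROBE_WIDTH)
  }))
  n <- nrow(meta)
  m <- matrix(stats::rnorm(n * spec$n_samples, 0, spec$noise_sd),
              nrow = n, dimnames = list(NULL, samples))
  events <- spec$events
  truth <- events
  truth$carriers <- character(nrow(events))
  truth$n_carriers <- integer(nrow(events))
  carrier_mask <- matrix(FALSE, nrow = n, ncol = spec$n_samples)
  overlaps <- rep(FALSE, nrow(events))
  if (nrow(events)) {
    for (i in seq_len(nrow(events))) {
      is_carrier <- stats::runif(spec$n_samples) < events$prevalence[i]
      rows <- which(meta$chrom == events$chrom[i])
      rows <- rows[events$probe_first[i]:events$probe_last[i]]
      amp <- events$amplitude[i] * (if (events$direction[i] == "gain") 1 else -1)
      for (j in which(is_carrier)) {
        if (any(carrier_mask[rows, j])) overlaps[i] <- TRUE
        m[rows, j] <- m[rows, j] + amp
        carrier_mask[rows, j] <- TRUE
      }
      truth$carriers[i] <- paste(samples[is_carrier], collapse = ",")
      truth$n_carriers[i] <- sum(is_carrier)
    }
    truth$overlaps <- overlaps
    truth$start <- meta$start[vapply(seq_len(nrow(events)), function(i) {
      which(meta$chrom == events$chrom[i])[events$probe_first[i]]
    }, integer(1))]
    truth$end <- meta$end[vapply(seq_len(nrow(events)), function(i) {
      which(meta$chrom == events$chrom[i])[events$probe_last[i]]
    }, integer(1))]
  }
  list(probes = swat_probes(meta, m), truth = truth)
}

# Maximal two-sample t statistic over all binary splits of x that leave at
# least min_seg points on each side. Returns c(t, split_index) with the
# left part being 1..split_index; c(NA, NA) when no split is admissible or
# the series is constant.
max_split_t <- function(x, min_seg) {
  n <- length(x)
  if (n < 2 * min_seg) return(c(NA_real_, NA_real_))
  cs <- cumsum(x)
  cs2 <- cumsum(x^2)
  i <- min_seg:(n - min_seg)
  n1 <- i; n2 <- n - i
  m1 <- cs[i] / n1
  m2 <- (cs[n] - cs[i]) / n2
  ss1 <- cs2[i] - n1 * m1^2
  ss2 <- (cs2[n] - cs2[i]) - n2 * m2^2
  sp2 <- pmax((ss1 + ss2) / (n - 2), 0)  # guard tiny negative rounding
  tt <- abs(m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  tt[!is.finite(tt)] <- NA_real_
  if (all(is.na(tt))) return(c(NA_real_, NA_real_))
  k <- which.max(tt)
  c(tt[k], i[k])
}

#' Naive reference segmenter
#'
#' A deliberately simple change-point segmenter used only for synthetic
#' end-to-end runs: per sample and chromosome, the probe series is split
#' recursively at the position maximising the two-sample t statistic, the
#' split being accepted while its permutation p-value (the fraction of
#' value-shuffled series whose maximal t statistic is at least as large) is
#' below `alpha` and both parts keep at least `min_seg` probes. Segment
#' means are attached. This is not a re-implementation of any published
#' segmentation algorithm.
#'
#' @param probes A `swat_probes` object (no missing values).
#' @param min_seg Minimum segment length in probes (>= 2).
#' @param alpha Significance level for accepting a split.
#' @param n_perm Permutations per split test (must allow p below `alpha`:
#'   the smallest attainable p is 1 / (n_perm + 1)).
#' @param seed Integer seed for the permutation draws.
#' @return A `swat_segments` tibble with `method = "naive"`.
#' @export
naive_segment <- function(probes, min_seg = 10, alpha = 0.01,
                          n_perm = 199, seed = 1) {
  assert_probes(probes)
  if (min_seg < 2) rlang::abort("`min_seg` must be >= 2.")
  set.seed(seed)
  samples <- sample_ids(probes)
  m <- sample_matrix(probes)
  out <- list()
  for (ch in unique(probes$chrom)) {
    rows <- which(probes$chrom == ch)
    for (s in samples) {
      x <- m[rows, s]
      bounds <- segment_recursive(x, min_seg, alpha, n_perm)
      st <- probes$start[rows[bounds$first]]
      # abutting segments tile the chromosome (no bp gaps)
      en <- c(st[-1], probes$end[rows[length(rows)]])
      seg <- tibble::tibble(
        method = "naive", sample = s, chrom = ch,
        start = st, end = en,
        n_probes = bounds$last - bounds$first + 1L,
        seg_mean = vapply(seq_len(nrow(bounds)), function(i) {
          mean(x[bounds$first[i]:bounds$last[i]])
        }, numeric(1)))
      out[[length(out) + 1]] <- seg
    }
  }
  new_swat_tbl(dplyr::bind_rows(out), "swat_segments")
}

segment_recursive <- function(x, min_seg, alpha, n_perm) {
  n <- length(x)
  one <- tibble::tibble(first = 1L, last = n)
  obs <- max_split_t(x, min_seg)
  if (is.na(obs[1])) return(one)
  perm <- vapply(seq_len(n_perm), function(b) {
    max_split_t(sample(x), min_seg)[1]
  }, numeric(1))
  p <- (1 + sum(perm >= obs[1], na.rm = TRUE)) / (n_perm + 1)
  if (p > alpha) return(one)
  k <- as.integer(obs[2])
  left <- segment_recursive(x[1:k], min_seg, alpha, n_perm)
  right <- segment_recursive(x[(k + 1):n], min_seg, alpha, n_perm)
  dplyr::bind_rows(left, dplyr::mutate(right, first = .data$first + k,
                                       last = .data$last + k))
}

#' Perturb segment breakpoints
#'
#' Fabricates additional pseudo segmentation "methods" for consensus tests
#' by jittering each internal breakpoint by a seeded uniform integer offset
#' in `[-jitter, jitter]` probes and recomputing segment means from the
#' probe data. Breakpoints that collide after jittering drop the squeezed
#' segment with a warning (its probes are absorbed by the neighbours), so
#' the perturbed set still tiles each chromosome.
#'
#' @param segments A `swat_segments` tibble (single method).
#' @param probes The `swat_probes` the segments were fitted on.
#' @param jitter Maximum absolute breakpoint shift in probes (>= 0).
#' @param seed Integer seed.
#' @param method Label for the perturbed copy.
#' @return A `swat_segments` tibble.
#' @export
perturb_segments <- function(segments, probes, jitter, seed,
                             method = "perturbed") {
  assert_probes(probes)
  if (jitter < 0) rlang::abort("`jitter` must be >= 0.")
  set.seed(seed)
  dropped <- 0L
  out <- list()
  for (s in unique(segments$sample)) {
    for (ch in unique(segments$chrom[segments$sample == s])) {
      seg <- segments[segments$sample == s & segments$chrom == ch, ]
      seg <- seg[order(seg$start), ]
      rows <- which(probes$chrom == ch)
      n <- length(rows)
      # probe-index breakpoints: positions after which a new segment begins
      last_idx <- vapply(seq_len(nrow(seg)), function(i) {
        max(which(probes$start[rows] < seg$end[i]))
      }, integer(1))
      internal <- last_idx[-length(last_idx)]
      if (length(internal) && jitter > 0) {
        internal <- internal + sample(seq(-jitter, jitter), length(internal),
                                      replace = TRUE)
        internal <- pmin(pmax(internal, 1L), n - 1L)
        # a breakpoint jittered past its successor squeezes that segment to
        # nothing: drop it (probes are absorbed by the neighbours)
        kept <- integer(0)
        for (b in internal) {
          if (length(kept) && b <= kept[length(kept)]) {
            dropped <- dropped + 1L
          } else {
            kept <- c(kept, b)
          }
        }
        internal <- kept
      }
      bounds <- tibble::tibble(first = c(1L, internal + 1L),
                               last = c(internal, n))
      seg_means <- vapply(seq_len(nrow(bounds)), function(i) {
        v <- as.data.frame(probes)[rows[bounds$first[i]:bounds$last[i]], s]
        mean(v, na.rm = TRUE)
      }, numeric(1))
      st <- probes$start[rows[bounds$first]]
      en <- c(st[-1], probes$end[rows[n]])
      out[[length(out) + 1]] <- tibble::tibble(
        method = method, sample = s, chrom = ch,
        start = st, end = en,
        n_probes = bounds$last - bounds$first + 1L,
        seg_mean = seg_means)
    }
  }
  if (dropped > 0) {
    rlang::warn(sprintf("%d segment(s) became degenerate under jitter and were dropped.",
                        dropped))
  }
  new_swat_tbl(dplyr::bind_rows(out), "swat_segments")
}
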