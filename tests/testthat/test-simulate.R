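# Synthetic-data generators and the naive reference segmenter.

test_that("toy fixture satisfies every documented constraint, deterministically", {
  fx <- figure1_fixture()
  expect_equal(dim(fx$probes), c(20L, 4L + 6L))
  expect_equal(sample_ids(fx$probes), LETTERS[1:6])
  m <- as.matrix(as.data.frame(fx$calls)[, LETTERS[1:6]])
  # no sample gains all of probes 1-3; exactly A, D, E gain probes 2-4
  expect_false(any(colSums(m[1:3, ]) == 3))
  expect_equal(colnames(m)[colSums(m[2:4, ]) == 3], c("A", "D", "E"))
  # non-zero 3-probe windows cover exactly probes 2-10 and 12-19
  dirs <- collapse_direction(fx$calls)
  tr <- compute_pws(dirs, "1", 3)
  nz <- tr$start[tr$score > 0]
  covered <- sort(unique(unlist(lapply(nz, function(s) s:(s + 2)))))
  expect_equal(covered, c(2:10, 12:19))
  # log2 values are consistent with the calls
  expect_equal(sample_matrix(fx$probes), m * 0.58, ignore_attr = TRUE)
  expect_identical(figure1_fixture(), figure1_fixture())
})

test_that("cohort simulation is seed-deterministic with binomial carriers", {
  spec <- sim_spec(n_samples = 38, n_chrom = 2, probes_per_chrom = 120,
                   events = sim_events("1", 30, 60, "gain",
                                       prevalence = 0.5),
                   noise_sd = 0.05, seed = 77)
  s1 <- simulate_cohort(spec)
  s2 <- simulate_cohort(spec)
  expect_identical(s1, s2)
  # carrier count is the seeded binomial draw; plausible under Binomial(38, .5)
  expect_true(s1$truth$n_carriers >= 9 && s1$truth$n_carriers <= 29)
  carriers <- strsplit(s1$truth$carriers, ",")[[1]]
  expect_length(carriers, s1$truth$n_carriers)
  # planted amplitude appears only in carriers over the span
  mat <- sample_matrix(s1$probes)
  in_span <- which(s1$probes$chrom == "1")[30:60]
  for (s in sample_ids(s1$probes)) {
    shift <- mean(mat[in_span, s])
    if (s %in% carriers) expect_gt(shift, 0.4) else expect_lt(abs(shift), 0.1)
  }

  null_spec <- sim_spec(n_samples = 4, n_chrom = 1, probes_per_chrom = 50,
                        events = sim_events(), noise_sd = 0.05, seed = 1)
  ns <- simulate_cohort(null_spec)
  expect_equal(nrow(ns$truth), 0)
  expect_lt(max(abs(sample_matrix(ns$probes))), 0.3)

  expect_error(sim_spec(4, events = sim_events("1", 10, 2000, "gain",
                                               prevalence = 0.5), seed = 1),
               "within their chromosome")
  expect_error(sim_spec(4, seed = 1, events = sim_events("1", 1, 5, "gain",
                                                         prevalence = 2)),
               "prevalence")
})

test_that("naive segmenter recovers a planted step and resists over-splitting", {
  set.seed(61)
  x <- stats::rnorm(150, 0, 0.05)
  x[50:80] <- x[50:80] + 0.8
  probes <- probes_from_matrix(cbind(A = x, B = x))
  seg <- naive_segment(probes, min_seg = 5, alpha = 0.01, seed = 3)
  sa <- seg[seg$sample == "A", ]
  expect_equal(nrow(sa), 3)
  # breakpoints within 2 probes of the planted change points
  bp <- sa$start[-1] / 10000 + 1   # probe index of each segment start
  expect_true(abs(bp[1] - 50) <= 2)
  expect_true(abs(bp[2] - 81) <= 2)
  expect_equal(sum(sa$n_probes), 150L)
  expect_gt(sa$seg_mean[2], 0.6)

  flat <- probes_from_matrix(matrix(0.2, 60, 2))
  expect_equal(nrow(naive_segment(flat, seed = 1)), 2)  # 1 per sample

  # alpha below the permutation floor -> no split is ever accepted
  noisy <- probes_from_matrix(matrix(stats::rnorm(200, 0, 1), 100, 2))
  seg0 <- naive_segment(noisy, alpha = 1e-6, n_perm = 99, seed = 1)
  expect_equal(nrow(seg0), 2)
})

test_that("breakpoint jitter: identity at zero, degeneracy warned, tiling kept", {
  set.seed(62)
  x <- c(rep(0, 40), rep(0.8, 10), rep(0, 40)) + stats::rnorm(90, 0, 0.03)
  probes <- probes_from_matrix(cbind(A = x, B = x))
  # three hand-built abutting segments per sample (breaks after probes 40, 50)
  seg <- dplyr::bind_rows(lapply(c("A", "B"), function(s) tibble::tibble(
    method = "manual", sample = s, chrom = "1",
    start = probes$start[c(1, 41, 51)],
    end = c(probes$start[c(41, 51)], max(probes$end)),
    n_probes = c(40L, 10L, 40L),
    seg_mean = c(mean(x[1:40]), mean(x[41:50]), mean(x[51:90])))))
  id <- perturb_segments(seg, probes, jitter = 0, seed = 9, method = "manual")
  expect_equal(as.data.frame(id), as.data.frame(seg))

  j2 <- perturb_segments(seg, probes, jitter = 2, seed = 9)
  expect_equal(unique(j2$method), "perturbed")
  by_s <- split(j2, j2$sample)
  for (p in by_s) {   # still tiles the chromosome
    p <- p[order(p$start), ]
    expect_equal(p$start[-1], p$end[-nrow(p)])
    expect_equal(sum(p$n_probes), 90L)
  }
  # jitter far beyond the middle segment's width collapses it
  expect_warning(j3 <- perturb_segments(seg, probes, jitter = 50, seed = 10),
                 "degenerate")
  expect_lt(nrow(j3), nrow(seg))
  for (p in split(j3, j3$sample)) {
    p <- p[order(p$start), ]
    expect_equal(sum(p$n_probes), 90L)
  }
})

test_that("jittered pseudo-methods still reach cross-method consensus", {
  spec <- sim_spec(n_samples = 10, n_chrom = 1, probes_per_chrom = 200,
                   events = sim_events("1", 80, 130, "gain",
                                       amplitude = 0.8, prevalence = 0.8),
                   noise_sd = 0.05, seed = 13)
  sim <- simulate_cohort(spec)
  base <- naive_segment(sim$probes, seed = 2)
  cfg <- swat_config(window_sizes = c(3, 5), n_permutations = 300)
  lists <- lapply(1:3, function(k) {
    segs <- if (k == 1) base else
      perturb_segments(base, sim$probes, jitter = 2, seed = 20 + k,
                       method = paste0("m", k))
    segs$method <- paste0("m", k)
    calls <- classify_segments(segs, sim$probes, cfg)
    reg <- swat_regions(compute_all_tracks(collapse_direction(calls), cfg),
                        sim$probes, cfg)
    mri <- reg$mri
    mri[mri$w == 3, ]
  })
  names(lists) <- paste0("m", 1:3)
  cons <- consensus_merge(lists, min_methods = 2)
  expect_gte(nrow(cons), 1)
  hit <- cons[cons$direction == "gain", ]
  expect_true(any(hit$start <= sim$truth$start & hit$end >= sim$truth$end))
})
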