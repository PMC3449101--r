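# Amplitude permutation filter and gene-density weighting.

test_that("null distribution behaves: constant, CLT, determinism, weighting", {
  const <- probes_from_matrix(matrix(0.3, 40, 4))
  nd <- null_distribution(const, 3, n_perm = 200, seed = 5)
  expect_equal(nd$mu, 0.3)
  expect_equal(nd$sigma, 0)

  set.seed(6)
  noisy <- probes_from_matrix(matrix(stats::rnorm(2000 * 10, 0, 0.2), 2000, 10))
  nd2 <- null_distribution(noisy, 3, n_perm = 2000, seed = 7)
  expect_lt(abs(nd2$mu), 4 * nd2$sigma / sqrt(2000))

  expect_equal(null_distribution(noisy, 3, 500, seed = 11),
               null_distribution(noisy, 3, 500, seed = 11))

  # chromosomes shorter than w contribute no draws; all short is an error
  short <- probes_from_matrix(matrix(0.1, 4, 2))
  expect_error(null_distribution(short, 10, 200, 1), "No chromosome")
  expect_error(null_distribution(noisy, 3, n_perm = 50, 1), ">= 100")
})

test_that("one-tailed amplitude P values match Gaussian quantiles", {
  expect_equal(amplitude_p(0.5, "gain", 0.5, 0.1), 0.5)
  expect_equal(amplitude_p(0.5, "loss", 0.5, 0.1), 0.5)
  expect_equal(amplitude_p(0.5 + 1.2816 * 0.1, "gain", 0.5, 0.1), 0.1,
               tolerance = 1e-3)
  expect_equal(amplitude_p(0.2, "loss", 0, 0.1), stats::pnorm(2), tolerance = 1e-9)
  # degenerate null
  expect_equal(amplitude_p(1, "gain", 0, 0), 0)
  expect_equal(amplitude_p(-1, "gain", 0, 0), 1)
  expect_equal(amplitude_p(-1, "loss", 0, 0), 0)
})

planted_regions <- function() {
  set.seed(41)
  m <- matrix(stats::rnorm(300 * 10, 0, 0.1), 300, 10)
  m[100:110, ] <- m[100:110, ] + 1.2   # strong focal gain, all samples
  probes <- probes_from_matrix(m)
  mris <- tibble::tibble(
    chrom = "1", w = 3L, direction = c("gain", "gain"),
    probe_first = c(100L, 200L), probe_last = c(110L, 210L),
    n_probes = 11L, recurrence = c(1, 0.5),
    at = 50, cri = 1:2, mri = 1L,
    start = probes$start[c(100, 200)], end = probes$end[c(110, 210)],
    mean_intensity = c(mri_mean_intensity(probes, "1", 100, 110),
                       mri_mean_intensity(probes, "1", 200, 210)))
  list(probes = probes, mris = mris)
}

test_that("amplitude filter keeps planted events and drops null-mean regions", {
  pr <- planted_regions()
  cfg <- swat_config(n_permutations = 1000, rng_seed = 3)
  kept <- amplitude_filter(pr$mris, pr$probes, cfg)
  expect_equal(kept$probe_first, 100L)        # focal gain survives
  expect_lt(kept$p_value, 0.001)
  all_rows <- amplitude_filter(pr$mris, pr$probes, cfg, keep_all = TRUE)
  expect_gt(all_rows$p_value[2], 0.1)         # null-mean region filtered
  expect_false(all_rows$significant[2])
  expect_equal(all_rows$amplitude_rank[1], 1L)
  # bit-reproducible under a fixed seed
  expect_equal(amplitude_filter(pr$mris, pr$probes, cfg),
               amplitude_filter(pr$mris, pr$probes, cfg))
  # cutoff 1 keeps everything with p < 1
  loose <- amplitude_filter(pr$mris, pr$probes,
                            swat_config(n_permutations = 1000, rng_seed = 3,
                                        p_cutoff = 1))
  expect_equal(nrow(loose), 2)
})

test_that("ARI, RIC and GDW arithmetic", {
  expect_equal(ari(0.8, 0.89), 0.712)
  expect_equal(ari(-0.8, 0.89), 0.712)   # losses score on the same scale
  expect_equal(ari(0.3, 1), 0.3)
  expect_equal(ari(0, 0.5), 0)
  expect_error(ari(0.5, 0), "\\(0, 1\\]")

  expect_equal(ric(2, 4), 0.5)
  expect_equal(ric(0, 7), 0)
  expect_equal(ric(3, 1), 3)
  expect_error(ric(1, 0), ">= 1")

  g <- gdw(0.712, 0.5)
  expect_equal(g$afi, 0.5)               # AFI reduces to RIC as printed
  expect_equal(g$gdw, 0.356)
  expect_equal(gdw(0, 0.5)$gdw, 0)
  expect_equal(gdw(0.4, 0)$gdw, 0)
})

test_that("gene-density ranking prefers gene-dense regions and breaks ties by position", {
  tb <- tibble::tibble(
    chrom = c("2", "1"), start = c(100L, 500L), end = c(200L, 600L),
    direction = "gain", ari = c(0.4, 0.4), ric = c(0.1, 1.0))
  tb$gdw <- gdw(tb$ari, tb$ric)$gdw
  ranked <- gdw_rank(tb)
  expect_equal(ranked$ric[ranked$gdw_rank == 1], 1.0)

  flat <- tibble::tibble(
    chrom = c("2", "1"), start = c(0L, 0L), end = c(10L, 10L),
    direction = "gain", ari = c(0, 0), gdw = c(0, 0))
  rf <- gdw_rank(flat)
  expect_equal(rf$chrom[order(rf$gdw_rank)], c("1", "2"))  # genome order

  single <- gdw_rank(tb[1, ])
  expect_equal(single$gdw_rank, 1L)
})

test_that("gdw ordering is invariant to positive rescaling of log2 ratios", {
  set.seed(42)
  tb <- tibble::tibble(
    chrom = "1", start = seq(0L, 900L, 100L), end = seq(50L, 950L, 100L),
    direction = rep(c("gain", "loss"), 5),
    mean_intensity = stats::rnorm(10, 0, 0.5),
    recurrence = stats::runif(10, 0.2, 1),
    ric = stats::runif(10, 0, 2))
  score <- function(scale) {
    t2 <- tb
    t2$ari <- ari(t2$mean_intensity * scale, t2$recurrence)
    t2$gdw <- gdw(t2$ari, t2$ric)$gdw
    r <- gdw_rank(t2)
    r[order(r$direction, r$start), ]$gdw_rank
  }
  expect_equal(score(1), score(3.7))
})

test_that("gene counting collapses transcripts and needs >= 1 bp overlap", {
  genes <- tibble::tibble(
    name = c("G1", "G1", "G2", "G3"), chrom = c("1", "1", "1", "2"),
    start = c(100L, 120L, 500L, 0L), end = c(200L, 260L, 600L, 50L),
    strand = "+")
  class(genes) <- c("swat_genes", class(tibble::tibble()))
  regions <- tibble::tibble(chrom = c("1", "1", "2"),
                            start = c(150L, 300L, 10L),
                            end = c(520L, 400L, 20L))
  expect_equal(count_genes(regions, genes), c(2L, 0L, 1L))
})

test_that("full prioritisation wires scores and both rankings together", {
  pr <- planted_regions()
  genes <- tibble::tibble(name = "G1", chrom = "1",
                          start = pr$mris$start[1], end = pr$mris$end[1],
                          strand = "+")
  class(genes) <- c("swat_genes", class(tibble::tibble()))
  cfg <- swat_config(n_permutations = 500, rng_seed = 3, report_window = 3)
  out <- swat_prioritize(pr$mris, pr$probes, genes, cfg)
  expect_s3_class(out, "swat_priority")
  expect_equal(nrow(out), 1)
  expect_equal(out$gene_count, 1L)
  expect_equal(out$ric, 1 / 11)
  expect_equal(out$gdw, out$ari * out$ric)
  expect_equal(out$amplitude_rank, 1L)
  expect_equal(out$gdw_rank, 1L)
})
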