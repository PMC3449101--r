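# Adaptive thresholds (descending ladder, ~5% per direction) and CRI/MRI
# extraction.

test_that("high-prevalence chromosomes select the stringent 80% threshold", {
  # 100-probe chromosome; windows 10..20 score 80 -> 13/100 probes >= 5%
  scores <- rep(0, 98); scores[10:20] <- 80
  sel <- select_adaptive_threshold(manual_track(scores), seq(80, 20, -10), 0.05)
  expect_equal(sel$chosen_at, 80)
  expect_equal(sel$coverage, 0.13)
})

test_that("a 32%-max-prevalence chromosome needs the 20% threshold", {
  # one 32% window (3 probes = 1.5% coverage), plus 25% windows that only
  # bring coverage to 5% once the 20% rung is reached
  scores <- rep(0, 198); scores[50] <- 32; scores[60:70] <- 25
  sel <- select_adaptive_threshold(manual_track(scores), seq(80, 20, -10), 0.05)
  expect_equal(sel$chosen_at, 20)
  expect_equal(sel$coverage, 16 / 200)
})

test_that("chromosomes with no recurrent CNA are deemed without CNA", {
  expect_true(is.na(select_adaptive_threshold(manual_track(rep(0, 50)),
                                              seq(80, 20, -10), 0.05)$chosen_at))
  empty <- manual_track(numeric(0))
  expect_true(is.na(select_adaptive_threshold(empty)$chosen_at))
  # below target at every rung but non-zero at the lowest -> lowest accepted
  scores <- rep(0, 998); scores[100] <- 25
  sel <- select_adaptive_threshold(manual_track(scores), seq(80, 20, -10), 0.05)
  expect_equal(sel$chosen_at, 20)
  expect_true(sel$coverage > 0)
})

test_that("gating boundary is inclusive", {
  tr <- manual_track(c(80, 79.9, 50))
  expect_equal(gate_windows(tr, 80), c(TRUE, FALSE, FALSE))
  expect_equal(gate_windows(tr, NA), rep(FALSE, 3))
  expect_error(gate_windows(tr, 0), "in \\(0, 100\\]")
})

test_that("coverage never decreases when the threshold is lowered", {
  set.seed(31)
  for (rep in 1:10) {
    scores <- sample(c(0, 0, 20, 40, 60, 80), 60, replace = TRUE)
    tr <- manual_track(scores)
    n <- 62L
    covs <- vapply(seq(80, 20, -10), function(at) {
      g <- tr$start[gate_windows(tr, at)]
      if (!length(g)) return(0)
      mean(swatcna:::covered_probes(g, 3L, n))
    }, numeric(1))
    expect_true(all(diff(covs) >= 0))
  }
})

test_that("toy cohort yields the two expected CRIs", {
  fx <- figure1_fixture()
  dirs <- collapse_direction(fx$calls)
  tr <- compute_pws(dirs, "1", 3, "gain")
  cris <- extract_cris(gate_windows(tr, 50), tr)
  expect_equal(nrow(cris), 2)
  expect_equal(cris$probe_first, c(2L, 12L))
  expect_equal(cris$probe_last, c(10L, 19L))
  expect_equal(cris$cri, 1:2)
  expect_equal(cris$peak_pws, c(200 / 3, 50))

  expect_equal(nrow(extract_cris(gate_windows(tr, NA), tr)), 0)
  one <- manual_track(c(0, 60, 0))
  cris1 <- extract_cris(gate_windows(one, 50), one)
  expect_equal(cris1$n_probes, 3L)
})

test_that("MRI extraction: flat CRIs, separated maxima, focal narrowing", {
  # flat PWS -> MRI equals CRI
  tr <- manual_track(c(0, 50, 50, 50, 0))
  g <- gate_windows(tr, 40)
  cri <- extract_cris(g, tr)
  mri <- extract_mris(cri[1, ], g, tr)
  expect_equal(nrow(mri), 1)
  expect_equal(c(mri$probe_first, mri$probe_last),
               c(cri$probe_first, cri$probe_last))
  expect_equal(mri$recurrence, 0.5)

  # two separated maxima -> two MRIs
  tr2 <- manual_track(c(70, 50, 50, 50, 70))
  g2 <- gate_windows(tr2, 40)
  cri2 <- extract_cris(g2, tr2)
  expect_equal(nrow(cri2), 1)
  mri2 <- extract_mris(cri2[1, ], g2, tr2)
  expect_equal(nrow(mri2), 2)
  expect_equal(mri2$probe_first, c(1L, 5L))
  expect_equal(mri2$probe_last, c(3L, 7L))

  # planted focal deletion inside a broader loss: MRI strictly inside CRI
  mat <- matrix(0L, 60, 10)
  mat[10:40, 1:5] <- -1L    # broad loss, 50% of samples
  mat[20:26, 6:9] <- -1L    # focal deletion lifts recurrence to 90%
  dirs <- dir_table(mat)
  trf <- compute_pws(dirs, "1", 3, "loss")
  gf <- gate_windows(trf, 50)
  crif <- extract_cris(gf, trf)
  expect_equal(nrow(crif), 1)
  mrif <- extract_mris(crif[1, ], gf, trf)
  expect_true(mrif$probe_first > crif$probe_first)
  expect_true(mrif$probe_last < crif$probe_last)
  expect_equal(mrif$recurrence, 0.9)
})

test_that("every probe inside a CRI is covered by a gated window, none outside", {
  set.seed(32)
  mat <- random_dir_matrix(50, 8)
  dirs <- dir_table(mat)
  tr <- compute_pws(dirs, "1", 3, "gain")
  for (at in c(25, 50)) {
    g <- gate_windows(tr, at)
    if (!any(g)) next
    cov <- swatcna:::covered_probes(tr$start[g], 3L, 50L)
    cris <- extract_cris(g, tr)
    inside <- logical(50)
    for (i in seq_len(nrow(cris))) {
      inside[cris$probe_first[i]:cris$probe_last[i]] <- TRUE
    }
    expect_equal(inside, cov)
  }
})

test_that("gain and loss thresholds are selected independently per chromosome", {
  mat <- matrix(0L, 100, 10)
  mat[10:25, 1:8] <- 1L   # gains in 80% of samples
  mat[60:70, 1:3] <- -1L  # losses in 30%
  dirs <- dir_table(mat)
  cfg <- swat_config(window_sizes = 3)
  reg <- swat_regions(compute_all_tracks(dirs, cfg), probes_from_matrix(mat * 0.5), cfg)
  th <- reg$thresholds
  expect_equal(th$chosen_at[th$direction == "gain"], 80)
  expect_equal(th$chosen_at[th$direction == "loss"], 30)
})

test_that("mean region intensity averages all non-missing values", {
  m <- matrix(c(1, 1, 0, 0), ncol = 2)
  pm <- probes_from_matrix(m)
  expect_equal(mri_mean_intensity(pm, "1", 1, 2), 0.5)
  one <- probes_from_matrix(matrix(c(0.7, 0.7, 0, 0), ncol = 2))
  expect_equal(mri_mean_intensity(one, "1", 1, 1), 0.35)
  nap <- probes_from_matrix(matrix(NA_real_, 2, 2))
  expect_error(mri_mean_intensity(nap, "1", 1, 2), "missing")

  # expectation under the generator: amplitude 0.8 at 50% prevalence
  spec <- sim_spec(n_samples = 40, n_chrom = 1, probes_per_chrom = 100,
                   events = sim_events("1", 20, 60, "gain",
                                       amplitude = 0.8, prevalence = 0.5),
                   noise_sd = 0.05, seed = 99)
  sim <- simulate_cohort(spec)
  mu <- mri_mean_intensity(sim$probes, "1", 20, 60)
  k <- sim$truth$n_carriers
  se <- sqrt(0.8^2 * 0.25 / 40 + 0.05^2 / (41 * 40))
  expect_lt(abs(mu - 0.8 * k / 40), 3 * 0.05 / sqrt(41 * 40) + 1e-9)
  expect_lt(abs(mu - 0.4), 3 * se + 0.05)
})
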