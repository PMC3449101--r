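# Cross-method consensus, list intersection, clustering and the region
# heatmap summary.

mri_stub <- function(chrom, start, end, direction = "gain") {
  tibble::tibble(chrom = chrom, start = as.integer(start),
                 end = as.integer(end), direction = direction)
}

test_that("overlapping same-direction regions from two methods merge", {
  cons <- consensus_merge(list(A = mri_stub("1", 100, 200),
                               B = mri_stub("1", 150, 250)))
  expect_equal(nrow(cons), 1)
  expect_equal(cons$start, 100L)
  expect_equal(cons$end, 250L)
  expect_equal(cons$n_methods, 2L)
  expect_equal(cons$methods, "A,B")
})

test_that("single-method regions are dropped; directions never pool", {
  cons <- consensus_merge(list(A = mri_stub("1", 100, 200),
                               B = mri_stub("1", 500, 600)))
  expect_equal(nrow(cons), 0)

  mixed <- consensus_merge(list(A = mri_stub("1", 100, 200, "gain"),
                                B = mri_stub("1", 150, 250, "loss")))
  expect_equal(nrow(mixed), 0)

  expect_error(consensus_merge(list(A = mri_stub("1", 1, 2))), "At least 2")
})

test_that("consensus is order-independent in methods and rows", {
  a <- dplyr::bind_rows(mri_stub("1", 100, 200), mri_stub("2", 10, 90),
                        mri_stub("1", 400, 450, "loss"))
  b <- dplyr::bind_rows(mri_stub("1", 180, 300), mri_stub("2", 50, 120),
                        mri_stub("1", 420, 480, "loss"))
  c1 <- consensus_merge(list(A = a, B = b))
  c2 <- consensus_merge(list(B = b[sample(nrow(b)), ], A = a[sample(nrow(a)), ]))
  expect_equal(as.data.frame(c1), as.data.frame(c2))
})

test_that("intersection keeps only regions present in both prioritisations", {
  amp <- consensus_merge(list(A = dplyr::bind_rows(mri_stub("1", 100, 200),
                                                   mri_stub("3", 10, 50)),
                              B = dplyr::bind_rows(mri_stub("1", 150, 250),
                                                   mri_stub("3", 20, 60))))
  gw <- consensus_merge(list(A = mri_stub("1", 180, 300),
                             B = mri_stub("1", 190, 320)))
  fin <- intersect_prioritizations(amp, gw)
  expect_equal(nrow(fin), 1)
  expect_equal(fin$chrom, "1")
  expect_true(all(fin$in_amplitude_list & fin$in_gdw_list))
  # the chr3 amplitude-only region (a non-gene-coding locus, say) is gone
  expect_false("3" %in% fin$chrom)

  empty <- gw[0, ]
  expect_equal(nrow(intersect_prioritizations(amp, empty)), 0)
})

planted_groups <- function(noise = 0) {
  # 12 samples in 3 groups of 4; each group gains a distinct probe block
  set.seed(51)
  m <- matrix(0L, 90, 12)
  m[1:20, 1:4] <- 1L
  m[31:50, 5:8] <- 1L
  m[61:80, 9:12] <- 1L
  if (noise > 0) {
    flips <- which(stats::runif(length(m)) < noise)
    m[flips] <- 1L - m[flips]
  }
  calls_table(m)
}

test_that("clustering recovers planted sample subgroups exactly at zero noise", {
  calls <- planted_groups()
  cris <- tibble::tibble(chrom = "1", probe_first = c(1L, 31L, 61L),
                         probe_last = c(20L, 50L, 80L), at = c(80, 80, 80))
  cl <- cluster_samples(calls, cris, min_at = 40, n_groups = 3)
  truth <- rep(1:3, each = 4)
  expect_equal(adj_rand(cl$groups, truth), 1)
  expect_equal(sort(unique(cl$groups)), 1:3)
  expect_equal(nrow(cl$feature_probes), 60)
})

test_that("clustering is invariant under sample permutation up to labels", {
  calls <- planted_groups()
  cris <- tibble::tibble(chrom = "1", probe_first = 1L, probe_last = 90L, at = 80)
  cl1 <- cluster_samples(calls, cris, n_groups = 3)
  perm <- sample(sample_ids(calls))
  shuffled <- calls_table(as.matrix(as.data.frame(calls)[, perm]))
  names(shuffled)[-(1:4)] <- perm
  cl2 <- cluster_samples(shuffled, cris, n_groups = 3)
  expect_equal(adj_rand(cl1$groups[names(cl2$groups)], cl2$groups), 1)
})

test_that("identical samples give a zero-height tree; weak CRIs are excluded", {
  m <- matrix(rep(c(1L, 0L), each = 10), nrow = 20, ncol = 6)
  calls <- calls_table(m)
  cris <- tibble::tibble(chrom = "1", probe_first = 1L, probe_last = 10L, at = 80)
  cl <- cluster_samples(calls, cris, n_groups = 1)
  expect_true(all(cl$tree$height == 0))
  expect_equal(unname(cl$groups), rep(1L, 6))

  weak <- tibble::tibble(chrom = "1", probe_first = c(1L, 11L),
                         probe_last = c(10L, 20L), at = c(20, 80))
  cl2 <- cluster_samples(calls, weak, min_at = 40, n_groups = 1)
  expect_equal(nrow(cl2$feature_probes), 10)   # the AT=20 CRI is dropped
  only_weak <- weak[1, ]
  expect_error(cluster_samples(calls, only_weak, min_at = 40), "No CRI passes")
})

test_that("heatmap values are gain minus loss probe fractions", {
  m <- cbind(A = rep(1L, 10),
             B = c(rep(1L, 5), rep(0L, 5)),
             C = c(rep(1L, 3), rep(-1L, 2), rep(0L, 5)))
  calls <- calls_table(m)
  regions <- tibble::tibble(chrom = "1", start = 0L, end = max(calls$end))
  hm <- region_heatmap_matrix(calls, regions)
  expect_equal(hm$value[hm$sample == "A"], 1)
  expect_equal(hm$value[hm$sample == "B"], 0.5)
  expect_equal(hm$value[hm$sample == "C"], 0.1)
  expect_error(region_heatmap_matrix(calls, regions[0, ]), "non-empty")
})

test_that("newick export writes one tree with every sample as a tip", {
  skip_if_not_installed("ape")
  calls <- planted_groups()
  cris <- tibble::tibble(chrom = "1", probe_first = 1L, probe_last = 90L, at = 80)
  cl <- cluster_samples(calls, cris)
  f <- withr::local_tempfile(fileext = ".nwk")
  write_cluster_newick(cl, f)
  tree <- ape::read.tree(f)
  expect_setequal(tree$tip.label, sample_ids(calls))
})
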