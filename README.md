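# swatcna

Sliding-window, adaptive-threshold detection of recurrent copy number
aberrations (CNAs) from array comparative genomic hybridisation (aCGH)
cohorts.

## Who this is for

Cancer-genomics analysts with a cohort of per-sample aCGH profiles
(probe-level log2 ratios) that have already been segmented by one or more
external algorithms (DNAcopy, GLAD, HMM variants, …), who want a single,
reproducible answer to: *which genomic regions are recurrently gained or
lost across this sample set, and in what order should I look at them?*
Segmentation itself is consumed as input (SEG tables); it is not
re-implemented here.

## The method in brief

1. **Five-point classification.** Per sample, a segment is copy-number
   abnormal when |segment mean| exceeds
   `T = |IQR(observed) − IQR(predicted)| × f` (factor change `f` = 0.75 by
   default); abnormal segments of at most 10 probes are high-level calls
   (±2), wider ones single-copy (±1), others 0.
2. **Probe window scores (PWS).** For window sizes *w* = 3…20, the PWS of
   a *w*-probe sliding window is the percentage of samples in which all
   its probes share the same CNA direction.
3. **Adaptive thresholds (AT).** Per chromosome and direction, a ladder of
   thresholds 80%, 70%, …, 20% is scanned from the top; the first rung
   whose gated windows cover ≥ 5% of the chromosome's probes is chosen
   (≈ 10% of each chromosome flagged overall), so chromosomes with modest
   prevalence still surface their most recurrent regions.
4. **CRIs and MRIs.** Runs of gated windows merge into contiguous regions
   of interest (CRIs); within each, the minimum region of interest (MRI)
   is the smallest probe span at the CRI's peak recurrence.
5. **Prioritisation.** MRIs are filtered by a one-tailed permutation-
   Gaussian test on mean log2 intensity (*P* < 0.1) and ranked two ways:
   by amplitude, and by gene density weighting
   `GDW = RIC × ARI` with `ARI = |mean log2| × recurrence` and
   `RIC = genes per MRI / probes per MRI`.
6. **Consensus, clustering, report.** Regions flagged by ≥ 2 segmentation
   methods and present in both prioritisation lists form the consensus
   set; samples are hierarchically clustered on calls inside strongly
   recurrent CRIs (AT ≥ 40%); everything is written as a browsable static
   HTML report with per-chromosome overview plots, karyograms and
   per-region classification grids.

## Worked example

The package ships a deterministic 6-sample × 20-probe toy cohort. Scoring
3-probe windows for gain:

```r
library(swatcna)
fx <- figure1_fixture()
dirs <- collapse_direction(fx$calls)
compute_pws(dirs, "1", 3)[1:4, ]
#> # A tibble: 4 × 6
#>   chrom     w direction start score n_samples
#>   <chr> <int> <chr>     <int> <dbl>     <int>
#> 1 1         3 gain          1   0           6
#> 2 1         3 gain          2  50           6
#> 3 1         3 gain          3  50           6
#> 4 1         3 gain          4  66.7        6
```

The first window (probes 1–3) scores 0% — no sample is gained across all
three probes; the second (probes 2–4) scores 50% — samples A, D and E
agree. Gating at 50% yields two CRIs (probes 2–10 and 12–19).

A full run on a simulated cohort (two planted events, two pseudo-methods
from the packaged naive segmenter):

```r
cfg <- swat_config(window_sizes = c(3, 5), n_permutations = 500)
spec <- sim_spec(n_samples = 12, n_chrom = 2, probes_per_chrom = 400,
  events = sim_events(chrom = c("1", "2"),
                      probe_first = c(100L, 150L), probe_last = c(160L, 230L),
                      direction = c("gain", "loss"),
                      amplitude = c(0.8, 1.0), prevalence = c(0.6, 0.75)),
  noise_sd = 0.05, seed = 2026)
sim <- simulate_cohort(spec)
writeLines(c("chr1\t1200000\t1300000\tGENE_A",
             "chr2\t1800000\t1900000\tGENE_B"), "genes.bed")
genes <- read_genes("genes.bed")
segs  <- naive_segment(sim$probes, seed = 1)
segs2 <- perturb_segments(segs, sim$probes, jitter = 2, seed = 2,
                          method = "jittered")
res <- swat_run(sim$probes, list(segs, segs2), genes = genes, config = cfg)
tidy(res, "priority")[, c("chrom", "direction", "recurrence",
                          "mean_intensity", "p_value", "gdw_rank")]
#>   chrom direction recurrence mean_intensity p_value gdw_rank
#> 1     1      gain      0.833          0.667 0.0124         1
#> 2     2      loss      0.833         -0.834 0.0056         1
res$consensus$final[, c("chrom", "direction", "start", "end", "n_methods")]
#>   chrom direction   start     end n_methods
#> 1     1      gain  990000 1590060         2
#> 2     2      loss 1490000 2290060         2
```

Both planted events are recovered (recurrence ≈ the planted prevalence,
mean intensity ≈ carrier fraction × amplitude, significant at *P* < 0.1)
and confirmed by both pseudo-methods. `swat_report(res, "out/")` renders
the HTML report; `tidy(res$clusters)` gives the sample grouping.

A thin command-line wrapper is provided at `inst/cli/swatcna.R` with
`run`, `simulate` and `report` subcommands.

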