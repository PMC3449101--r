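---
title: "Detecting recurrent copy number aberrations with sliding windows and adaptive thresholds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting recurrent copy number aberrations with sliding windows and adaptive thresholds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(swatcna)
library(dplyr)
```

## The problem

Array comparative genomic hybridisation (aCGH) measures DNA copy number as
per-probe log2 test/reference fluorescence ratios. Given a cohort of tumour
samples, the analytical task is to find the genomic regions whose copy
number aberrations (CNAs) recur across samples — integrating three signals
that individually mislead: probe amplitude (noisy), aberration width
(platform-dependent), and recurrence (dominated by a few gross events if
thresholds are global). swatcna implements a heuristic that addresses each
in turn: probe classification smoothed over segments, sliding probe-window
recurrence scores, per-chromosome adaptive thresholds, and a two-track
prioritisation of the detected regions.

Segmentation itself is an *input*: any external change-point algorithm's
per-sample segment means (a SEG table) are accepted, and results from
several segmenters can be consolidated. The package deliberately does not
re-implement any published segmentation algorithm; a naive reference
segmenter ships with the synthetic-data module only so the pipeline can be
exercised end-to-end without external tools.

## The procedure

### 1. Five-point classification

Each sample's segments are classified into
$\{-2,-1,0,1,2\}$ = {high-level loss, loss, normal, gain, high-level
gain/amplification}. A segment is *abnormal* when its absolute mean log2
ratio exceeds a per-sample threshold

$$T = \lvert \mathrm{IQR}(\text{observed}) - \mathrm{IQR}(\text{predicted})
\rvert \times f,$$

where "observed" are the sample's probe log2 ratios, "predicted" the
segment means expanded per probe, and $f$ the *factor change* (default
0.75). We read "the middle fifty of the distributions" as the
inter-quartile range because it is the only interpretation that yields a
per-sample scalar threshold from the two distributions involved; quartiles
use the default type-7 linear interpolation. Abnormal segments spanning at
most `highlevel_max_width` probes (default 10, roughly 700 kb on a 44K
array) are called high-level ($\pm 2$); wider abnormal segments are
single-copy calls ($\pm 1$). The width rule is deliberately width-only, as
specified for the classification scheme we follow; an optional
`highlevel_amplitude_check` additionally requires
$\lvert\text{mean}\rvert > 2T$ for high-level calls, off by default. For
recurrence scoring, calls collapse to direction: gain with amplification,
loss with deletion.

### 2. Probe window scores (PWS)

For each chromosome, window size $w \in \{3,\dots,20\}$ and direction, the
PWS of the window starting at probe $i$ is the percentage of samples in
which *all* probes $i..i{+}w{-}1$ carry that direction. Windows slide by
one probe; no partial windows are scored at chromosome ends because a
score over fewer probes would not be comparable. Two consequences are
useful checks: every score is a multiple of $100/n_{\text{samples}}$, and
PWS is anti-monotone in $w$ (a superset of probes must agree). The
implementation is cross-checked in the test suite against a brute-force
per-window, per-sample counter.

```{r}
fx <- figure1_fixture()
dirs <- collapse_direction(fx$calls)
compute_pws(dirs, "1", 3)[1:4, ]
```

On the packaged 6-sample, 20-probe toy cohort the first 3-probe window
scores 0% (no sample gained across probes 1–3) and the second 50%
(samples A, D, E agree across probes 2–4).

### 3. Adaptive thresholds, CRIs and MRIs

Per chromosome and per direction, a descending ladder of adaptive
thresholds (AT; default 80%, 70%, …, 20%) is scanned from the most
stringent value. The chosen AT is the first whose gated windows cover at
least `target_coverage` of the chromosome's probes (default 5% per
direction, hence roughly 10% of each chromosome overall). If no rung
reaches the target, the least stringent rung is accepted provided it gates
anything; otherwise the chromosome is deemed without CNA in that
direction. The printed rule text we implement is internally inconsistent
as stated ("if an AT results in 0% CNA, the next higher threshold is
accepted" — coverage cannot increase with a higher threshold), so we adopt
the scan-from-high reading, which reproduces both canonical behaviours: a
chromosome with ~90% prevalent gains selects AT = 80, while a chromosome
whose gains peak at 32% prevalence needs AT = 20 to reach 5% coverage.
The PWS $\ge$ AT boundary is inclusive (a region gated at 80 is aberrant
in at least 80% of samples). Coverage is measured in probes, not base
pairs: on a uniform array the two agree, and probe counting is
platform-independent.

Runs of consecutive gated windows merge (where their probe unions overlap
or touch) into **contiguous regions of interest (CRIs)**, serially indexed
in genome order. Within a CRI, the **minimum region of interest (MRI)** is
the smallest probe span achieving the CRI's maximum PWS $m$: maximal
contiguous probe runs covered by windows scoring exactly $m$. Overlapping
or adjacent top-scoring windows chain into one MRI; separated maxima yield
several; a flat-PWS CRI is its own MRI. The MRI's *recurrence* is $m$ as a
fraction of samples.

Regions detected at larger window sizes are additionally checked against
the internal smaller windows: each MRI probe must be covered by a smaller
window at equal or higher PWS than the region's *peak* score (we compare
against the peak, not the CRI average, because the MRI is defined by peak
recurrence). By the anti-monotonicity property this check always passes on
tracks computed from a real direction table — it is kept as an explicit
guard (and exercised directly in tests) because it becomes informative
when tracks from different preprocessing runs are mixed.

### 4. Prioritisation

**Amplitude.** A null distribution of window mean intensities is estimated
by drawing `n_permutations` (default 10,000) random probe windows
genome-wide, each chromosome contributing proportionally to its probe
count; the statistic is the mean log2 ratio over the window's probes
across all samples, and the null is summarised by the sample mean $\mu$
and $(n{-}1)$ standard deviation $\sigma$. Each MRI's P value is the
one-tailed Gaussian tail probability of its mean intensity in the CNA's
direction (one-tailed because a "gain" with strongly negative mean should
not pass); MRIs with $P < 0.1$ are retained and ranked by ascending P
within direction, ties broken by absolute mean intensity. Under a null
cohort these P values are approximately Uniform(0,1), which the test suite
checks with a Kolmogorov–Smirnov test. No multiple-testing correction is
applied: the procedure is a screening filter at a deliberately permissive
raw cutoff, not an inferential claim.

**Gene density.** For the gene-centred ranking,

$$\mathrm{ARI} = \lvert \overline{\log_2} \rvert \times \text{recurrence},
\qquad \mathrm{RIC} = \frac{\#\text{genes in MRI}}{\#\text{probes in MRI}},
\qquad \mathrm{AFI} = \frac{\mathrm{RIC}\times\mathrm{ARI}}{\mathrm{ARI}},
\qquad \mathrm{GDW} = \mathrm{AFI}\times\mathrm{ARI}.$$

AFI is implemented literally as printed in the formulation we follow; it
algebraically reduces to RIC (we guard ARI = 0 by setting AFI = RIC), so
GDW = RIC × ARI. Whether a non-degenerate focality index was intended
cannot be determined from the text; the literal form is used and
documented. Genes count once per distinct name regardless of transcript
rows, with any ≥ 1 bp overlap. MRIs are ranked by descending GDW within
direction, ties by ARI then genome position. A region overlapping no gene
has GDW 0 and cannot rank — the known, intended blind spot of
gene-weighted prioritisation.

### 5. Consensus and clustering

With two or more segmentation methods, same-direction MRIs overlapping by
at least 1 bp pool transitively across methods; pools supported by at
least `consensus_min_methods` (default 2) distinct methods become
consensus regions. Two consensus lists are built — one from the
amplitude-filtered MRIs, one from their gene-weighted reordering
restricted to gene-containing regions (GDW > 0, which is what makes the
two lists differ in membership rather than order alone) — and regions
present in both survive. Any-overlap pooling is the simplest deterministic
matching rule; no overlap-fraction criterion is specified by the method we
follow, so none is imposed.

Samples are clustered on the classification calls at probes inside CRIs
whose chosen AT is at least `cluster_min_at` (default 40%), so only
strongly recurrent regions drive the grouping. Defaults are Euclidean
distance on the integer call vectors with Ward linkage ("agglomerative
hierarchical clustering" is all the source method specifies); the full
tree is always returned so any cut is recoverable, with `n_groups = 3` as
the default cut.

## Parameters at a glance

| parameter | default | units | role |
|---|---|---|---|
| `window_sizes` | 3–20 | probes | sliding-window lengths scored |
| `at_ladder` | 80…20 by −10 | % samples | adaptive-threshold rungs |
| `target_coverage` | 0.05 | fraction of probes | per-direction gating target |
| `highlevel_max_width` | 10 | probes | width bound for ±2 calls |
| `factor_change` | 0.75 | fraction | scales the IQR-difference threshold |
| `p_cutoff` | 0.1 | probability | amplitude significance cutoff |
| `n_permutations` | 10,000 | draws | null-distribution size |
| `consensus_min_methods` | 2 | methods | cross-method support |
| `cluster_min_at` | 40 | % samples | CRI stringency for clustering |
| `report_window` | 3 | probes | window size for tables/plots |

## The synthetic-data module

`simulate_cohort()` generates planted-CNA cohorts: iid Gaussian probe
noise plus constant signed amplitudes over event spans in carrier samples,
carriers drawn per event by seeded Bernoulli sampling at the stated
prevalence. Default amplitudes are +0.58 for gains (log2 of 3/2, a
single-copy gain in a diploid genome) and −1.0 for losses. Probes sit on a
uniform 10 kb grid, a coarse stand-in for a 44K-style array.
`naive_segment()` is a deliberately simple recursive binary splitter on
the maximal two-sample t statistic; each split is accepted only if its
permutation p value (value-shuffled series, 199 permutations by default)
is below `alpha`, which keeps it honest on null data — a plain
t-distribution p on a maximised statistic over-splits pure noise.
`perturb_segments()` jitters breakpoints to fabricate disagreeing
pseudo-methods for consensus tests. `figure1_fixture()` freezes the
20-probe toy cohort described above.

What the generator does *not* emulate — and hence what passing tests do
not establish about real data: GC/wave artifacts, germline copy number
variants, probe-specific response, segmentation-method idiosyncrasies,
heavy-tailed noise, and sex-chromosome dosage (the analysis is restricted
to autosomes throughout; X/Y probes are dropped on input). Recovery
results on planted events therefore validate the region logic, not any
claim about a particular array platform.

## Numerical and design choices

* Genomic coordinates are 0-based half-open internally; all user-facing
  tables print 1-based positions. Probe indices are 1-based within each
  chromosome, matching R's vector semantics (an explicit choice over
  0-based indices to avoid off-by-one bookkeeping in R code).
* Quartiles: type 7 (linear interpolation), the documented R default.
* Gating boundary inclusive; adaptive-threshold scan from stringent to
  permissive as motivated above.
* Permutation nulls and the naive segmenter draw through R's RNG from a
  mandatory seed; `amplitude_filter()` derives one seed per window size so
  results are bit-reproducible.
* Degenerate inputs: both-IQRs-zero thresholds warn and classify every
  non-zero segment abnormal; a zero-σ null gives P ∈ {0, 1} by direction;
  chromosomes shorter than a window size produce empty tracks with a
  warning and contribute no null draws.
* The test suite runs its heavier property checks at 12 samples × 1,000
  probes (recovery, calibration) and 200 random tables of ≤ 30 probes × 8
  samples (oracle equivalence) — sizes chosen so the full suite exercises
  every stage in well under a minute each while keeping binomial carrier
  draws away from degenerate corners.

## Known limitations

* The width-only high-level rule can mislabel narrow single-copy events
  as amplifications; the optional amplitude check mitigates but deviates
  from the canonical classification.
* GDW inherits annotation quality: unannotated or poorly mapped regions
  cannot rank, which is precisely the failure mode the amplitude track is
  kept to cover.
* Ladder quantisation means the attained coverage can overshoot the 5%
  target at the chosen rung; the first rung meeting the target is
  accepted by design.
* Cluster group counts are user choices; no statistical significance is
  attached to the grouping.
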