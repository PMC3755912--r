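---
title: "Estimating cell size at birth from binned asynchronous size distributions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating cell size at birth from binned asynchronous size distributions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(birthsize)
```

## The problem and the model

Budding yeast divides asymmetrically: a newborn daughter is smaller than
the mother it separates from, and in an asynchronously proliferating
culture at least half of all cells are newborn daughters. A Coulter-type
channelyzer summarises such a culture as a histogram of cell volumes over
discrete channels of *non-uniform* width. `birthsize` extracts, for each
strain's histogram $f(x)$, five parameters:

* $x_0$ — the start of the cell-size support, placed so that spurious
  low-channel debris counts are excluded;
* $x_d$ — the mode of $f$ on $[x_0, x_y]$, read as the maximum daughter
  size: because daughters are smaller than mothers, the left-of-mode
  region $[x_0, x_d]$ is attributed to daughters;
* $x_b(q)$ — the **birth size**: the channel at which the running sum of
  counts from $x_0$ first reaches a fraction $q$ (default 20%) of the
  daughter-interval total, $\sum_{x_0}^{x_b} f \ge q \sum_{x_0}^{x_d} f$,
  with inclusive sums and no interpolation inside channels;
* $x_m$ — the frequency-weighted mean size over the support;
* $x_y$ — the last occupied channel.

Every parameter sits on a channel and is only known to within that
channel's width; the package reports the interval to the next channel,
$x_p \pm (x_{p+1} - x_p)$, as the error bound (the last channel uses the
preceding interval). Nothing downstream assumes uniform channel widths.

Strains are then categorised as small/normal/large at birth under two
schemes, and birth size is associated with published phenotypes (mean
size, competitive fitness rank, %G1 DNA content) by Spearman rank
correlation within each category and by group-mean comparisons.

## Automating the support curation

The original style of analysis located $x_0$ by eye. The package replaces
visual curation with a deterministic rule: $x_0$ is the smallest channel
whose count reaches a fraction $\alpha$ (default 0.01) of the raw modal
count, sustained over $k$ consecutive channels (default 3). The
persistence requirement stops an isolated debris spike in a low channel
from opening the support; $\alpha$ expresses "distinguishable from noise"
relative to the histogram's own scale. Two escape hatches reproduce
manual decisions as configuration: a per-strain `(x0, xy)` override table
and an exclusion list (strains flagged `manual_excluded`, retained in the
bookkeeping but given no parameters).

Abnormality is defined by testable conditions rather than by eye: a
profile is `abnormal_no_daughter_range` when no channel satisfies the
$x_0$ rule, when the support collapses, or when the mode falls at the
support start so that no daughter interval exists (as in a monotone
decreasing profile). These conditions are a stated proxy for the
published visual notion of an abnormal profile, not a reconstruction of
it.

Two further conventions matter and are deliberate:

* **Threshold comparison is `>=`**, exactly as the cumulative rule above
  states; the method accepts channel-granularity error instead of
  interpolating inside channels.
* **Mode ties break to the smallest channel**, and optional odd-width
  moving-average smoothing (default off) can stabilise the argmax on
  ragged histograms; the reported mode always lies on the original grid.
* **$x_m$ is computed over $[x_0, x_y]$ only**, so debris outside the
  support cannot pull the mean; computing it over all channels is
  available (`mean_over_support = FALSE`) as a sensitivity analysis.

## Categorisation schemes

The **wild-type-SD scheme** computes the sample mean and SD (n−1) of
$x_b$ over wild-type replicate cultures and labels a strain small if
$x_b < \mu_{WT} - 2\,SD$, large if $x_b > \mu_{WT} + 2\,SD$. The
inequalities are strict, so boundary equality maps to normal; the
strain's channel-valued $x_b$ is compared against the continuous
thresholds. Which panel columns are wild type is configuration — file
formats do not record it.

The **quantile scheme** labels the channels holding the smallest and
largest 5% of mutant birth sizes. Because $x_b$ is channel-valued, whole
boundary channels are included, so tails can slightly exceed the nominal
fraction. Boundaries are order statistics without interpolation: with $n$
pool strains and $k = \lfloor n \cdot tail \rfloor$, the lower boundary is
the $k$-th smallest $x_b$. Wild-type replicates are excluded from the
quantile pool by default (the tails are defined over mutants) but still
receive labels against the mutant-derived boundaries, so every QC-pass
strain is assigned under both schemes.

## Association analyses

Spearman's rank correlation (midranks for ties) is computed per category
and overall; pairs with a missing phenotype are dropped per analysis
cell, not listwise. The p-value uses the large-sample t approximation,
with the exact permutation distribution for $n \le 10$ without ties.
Fitness is an ordinal rank (1 = most fit … 21 = least fit) and is used
only in rank-based analyses.

Group means are compared with Welch's two-sample t test — the question
the analysis asks is about differences of means — with the Mann–Whitney
U test reported alongside as a robustness check against the skew typical
of size-derived quantities; both are two-sided, and no multiple-testing
correction is applied by default (a Holm option exists). Boxplot
summaries report quartiles, 1.5·IQR whiskers and both mean and median;
the figures draw the band inside the box at the *mean*, which is the
convention the %G1 comparison uses, while the median stays available in
the summary table.

The birth-to-budding increase, $100 (x_{bud} - x_b)/x_b$ with budding
taken at 35 fl, is reported unrounded and rounded to the nearest percent.

## What the synthetic generator emulates

`generate_panel()` draws, for each strain, a two-component size mixture
on a shared channelyzer-style grid:

* **Daughters** (mixture weight 0.55) are born lognormal around the
  strain's true birth size $B$ (within-strain CV 0.12) and grow
  multiplicatively toward budding by a log-uniform factor up to the
  budding/birth ratio (35/23.7). This spreads daughter sizes from birth
  toward budding without simulating time dynamics — enough to create the
  left-of-mode daughter mass the extraction assumes.
* **Mothers** are lognormal with median `mother_daughter_ratio`·B (1.6)
  and a tighter CV (0.10). Keeping mothers tighter than the daughter
  spread puts the mixture's mode at the daughter/mother boundary, so the
  left-of-mode region holds all daughters plus the mothers' lower tail —
  the structure the partition heuristic requires. Every generated strain
  carries at least half its support mass left of the mode.
* **The grid** is deterministic: channel widths grow linearly from
  0.385662112 fl to 1.203735813 fl across an 8–110 fl window, mirroring
  how Coulter volume channels widen with size and making the
  grid-integrity readback exact.
* **Debris** is Poisson noise confined to channels below the daughter
  component's 0.1 percentile, mimicking pre-support noise counts.
* **Variation** has three layers: within-strain (the mixture), between
  strains (true $B$ varies with CV 0.06 across unplanted mutants —
  deletion strains vary continuously in size, and rank-based recovery is
  only meaningful against a continuous ground truth), and between
  cultures (every panel column gets a replicate-level CV of 0.04, the
  scale implied by wild-type replicate birth sizes of roughly
  23.7 ± 1 fl). Planted mutants multiply $B$ (defaults ×0.75 and ×1.3).
* **Phenotypes** are generated only with planted links: %G1 rises with
  the birth-size deficit of planted small strains (default 1.5 points
  per fl, Gaussian noise SD 5 around a baseline of 40%), outliers pay a
  fitness penalty (6 ranks, clipped to 1–21), and the published mean
  size is the analytic mixture mean plus 1 fl of measurement noise.
  Unplanted strains carry no links, so null panels probe type-I
  behaviour.

Note a deliberate semantic point: `wt_birth_mean` is the *median true
birth size*. The extracted $x_b$ estimates the *maximum* birth size (the
top of the newborn pool within the daughter interval) and therefore sits
somewhat above $B$ by construction. All recovery statements are
rank- or label-based and unaffected by this offset.

What passing tests on this generator do **not** show: real channelyzer
data contain abnormal profiles (aggregates, debris inside the support,
multi-modal mutants) that the two-component mixture never produces, the
real mother-age structure is richer than one lognormal component, and
real phenotype datasets come from different strain backgrounds and
ploidies than the size data. Results on synthetic panels validate the
machinery, not those biological complications.

## Numerical choices and edge cases

* All randomness flows from a single integer seed per generated object;
  identical spec + seed is bit-identical, and the pipeline derives stage
  seeds from the run seed.
* TSV/CSV output of count matrices uses 17-significant-digit decimal
  representations and a correctly-rounding parser, so read/write round
  trips are value-exact.
* Degenerate inputs: all-zero strain columns are flagged, not dropped;
  identical wild-type replicates (SD = 0) warn that every deviating
  mutant becomes an outlier; a quantile tail of 0.5 empties the normal
  category with a warning; zero-variance group pairs report the
  Mann–Whitney test with the t test undefined.
* Stability under refinement: splitting every channel into two
  equal-count halves moves $x_0$, $x_d$, $x_m$, $x_y$ by at most one
  original channel interval. $x_b$ has one extra, predictable
  sensitivity: only half the mode channel's counts remain inside the
  refined daughter interval, lowering the cumulative threshold by
  $q \cdot c_{mode}/2$, and on sparse histograms the crossing can move
  further than one interval. The test suite pins the exact sharpened
  bound (one interval around the original-grid crossing of the shifted
  threshold) rather than pretending the naive bound holds.

## Problem sizes

The packaged analyses and checks run at: 500 mutants + 10 wild-type
replicates, 20 000 cells per strain for panel-level work; one strain at
10^6 cells for the closed-form single-strain comparison; 1000 randomized
histograms for the oracle-equivalence properties; and 1000 phenotype
replicates over a fixed null panel for the type-I calibration of the
%G1 group comparison (the phenotype layer is generated independently of
the histograms under the null, so redrawing phenotypes over one panel
samples the same null distribution as regenerating panels, at a fraction
of the cost). These sizes are the package's own choices and give stable
statistics: rank recovery of true birth size is ≈0.99, and the null
rejection rate sits within binomial noise of 5%.

## A worked run

```{r example, eval = FALSE}
spec <- synthetic_panel_spec(n_mutants = 500, n_wildtype = 10,
                             planted = planted_outliers(25, 25),
                             seed = 20130901)
gen <- generate_panel(spec)
params <- extract_panel_parameters(gen$panel)
wt_reference(params, 0.20)
assignments <- assign_categories(params)
phen <- phenotype_link(gen$truth, seed = 20130902)
per_category_association(params, assignments, phen, "pct_g1",
                         scheme = "quantile")
```

The numbered scripts under `analysis/` run the same stages against files
under `results/`, and `run_pipeline()` drives everything from one config.

## Known limitations

* The QC conditions are a programmatic proxy for visual curation; on
  real data some profiles a human would reject will pass, and the
  exclusion list exists precisely to encode such decisions.
* $x_b$ is a population-level estimate; strains with highly variable
  birth sizes will have their apparent birth size pulled above the
  typical newborn size.
* The quantile scheme's tails are channel-resolved and can exceed the
  nominal fraction when many strains share a boundary channel.
* Whether the support-restricted or all-channel mean matches a given
  external dataset is not decidable from the histogram alone; both are
  provided.
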