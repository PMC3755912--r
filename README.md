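# birthsize

Cell size at birth from binned asynchronous size distributions of
budding yeast.

## The problem

*Saccharomyces cerevisiae* divides asymmetrically: newborn daughters are
smaller than their mothers, and in an asynchronous culture at least half
of all cells are newborn daughters. In a channelyzer histogram of such a
culture, daughters occupy the region left of the mode. `birthsize`
exploits that structure to estimate each strain's size at birth from a
plain binned size distribution — no synchronisation or single-cell
imaging required — and to ask, across a deletion-strain panel, whether
being born small or large predicts a strain's mean size, its fitness,
and how it progresses through G1.

For a strain's histogram f(x) on channels of non-uniform width (fl), the
package extracts:

* **x0, xy** — the cell-size support, with low-channel debris excluded by
  an α-fraction-of-mode rule sustained over k consecutive channels
  (defaults α = 0.01, k = 3), plus per-strain overrides and an exclusion
  list for manual curation;
* **xd** — the mode, partitioning daughters `[x0, xd]` from mothers
  `[xd, xy]`;
* **xb(q)** — the birth size: the channel where cumulative counts from x0
  first reach a fraction q (default 20%; also 10/15/25%) of the
  daughter-interval counts, Σ<sub>x0..xb</sub> f ≥ q·Σ<sub>x0..xd</sub> f;
* **xm** — the support-restricted mean size;

each with the channel-granularity error bound x<sub>p</sub> ±
(x<sub>p+1</sub> − x<sub>p</sub>). Strains are then labelled
small/normal/large by two schemes (±2 wild-type SDs of replicate xb; the
empirical 5% tails of mutant xb with whole boundary channels included),
and birth size is associated with phenotypes by Spearman rank correlation
per category and by Welch/Mann–Whitney group-mean comparisons. A
synthetic panel generator with known ground truth (lognormal
daughter/mother mixture, non-uniform grid, planted small/large mutants
with linked %G1 and fitness effects) makes every stage testable.

## Worked example

```r
library(birthsize)

spec <- synthetic_panel_spec(n_mutants = 500, n_wildtype = 10,
                             planted = planted_outliers(25, 25),
                             seed = 20130901)
gen    <- generate_panel(spec)
params <- extract_panel_parameters(gen$panel)
wt_reference(params, 0.20)
#> <wt_reference> mu 25.22 fl, sd 0.8976 fl, n = 10 (xb at 20%)

phen        <- phenotype_link(gen$truth, seed = 20130902)
assignments <- assign_categories(params)
gc <- group_mean_comparison(params, assignments, phen, "pct_g1",
                            scheme = "quantile")
subset(gc$comparisons, group_a == "small" & group_b == "normal")
#> # A tibble: 1 x 9
#>   phenotype scheme   group_a group_b   n_a   n_b mean_diff    welch_t_p mann_whitney_p
#>   <chr>     <chr>    <chr>   <chr>   <int> <int>     <dbl>        <dbl>          <dbl>
#> 1 pct_g1    quantile small   normal     25   450      10.0 0.0000000240       5.15e-11
```

The wild-type reference says the ten replicate cultures have a mean
birth size of 25.2 fl with 0.90 fl of replicate scatter; the group
comparison says strains in the small-birth tail carry ~10 percentage
points more G1-phase cells than normal strains (Welch p ≈ 2×10⁻⁸) — the
planted small-birth/slow-G1 link, recovered end to end from binned
histograms. The same run shows no %G1 shift for large-birth strains
(p ≈ 0.2), the published asymmetry this analysis is designed to expose.
The numbered scripts in `analysis/` (01_simulate … 05_figures) run these
stages against `results/`, printing what each stage found; scatter and
boxplot figures land in `results/figures/`.

To analyse real data instead, feed `read_distribution_matrix()` a
TSV/CSV/XLSX with channels in rows (first column `bin_fl`, one column
per strain), `read_phenotype_table()` a per-strain phenotype table, and
drive everything with `run_pipeline()` from a single YAML config.

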