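#!/usr/bin/env Rscript

# Stage 2: extract the five distribution parameters per strain.
#
# For every strain: support [x0, xy] (debris-filtered), mode xd (the
# daughter/mother partition), birth size xb at the 10/15/20/25% daughter
# cutoffs, and the support-restricted mean xm, each with its channel-width
# error bound and a QC status.

library(birthsize)

panel <- read_distribution_matrix(
  "results/panel/distributions.tsv",
  wildtype_ids = readLines("results/panel/wildtype_ids.txt"))

params <- extract_panel_parameters(panel, support_config())
readr::write_tsv(params, "results/params.tsv")

cat("QC:", sum(params$qc == "pass"), "pass,",
    sum(params$qc == "abnormal_no_daughter_range"), "abnormal,",
    sum(params$qc == "manual_excluded"), "excluded\n")

ref <- wt_reference(params, 0.20)
cat(sprintf("Wild-type birth size (20%% cutoff): %.2f +/- %.2f fl (n=%d)\n",
            ref$mu_wt, ref$sd_wt, ref$n_wt))

for (q in c(10, 15, 20, 25)) {
  col <- sprintf("xb_%d", q)
  cat(sprintf("  mutant xb at %2d%%: median %.2f fl (IQR %.2f-%.2f)\n", q,
              median(params[[col]], na.rm = TRUE),
              quantile(params[[col]], 0.25, na.rm = TRUE),
              quantile(params[[col]], 0.75, na.rm = TRUE)))
}

# growth implied between birth and budding, taking budding at 35 fl
inc <- birth_to_budding_increase(
  c(mean(params$xb_10[params$role == "wild_type"]),
    mean(params$xb_25[params$role == "wild_type"])), 35)
cat(sprintf("Birth-to-budding increase: %d%% (10%% cutoff), %d%% (25%% cutoff)\n",
            inc$increase_pct_rounded[1], inc$increase_pct_rounded[2]))
cat("Wrote results/params.tsv\n")
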