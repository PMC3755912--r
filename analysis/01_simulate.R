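#!/usr/bin/env Rscript

# Stage 1: build the study panel.
#
# A synthetic deletion-collection size screen: 500 mutant cultures and 10
# wild-type replicate cultures measured on a channelyzer-style grid, with
# 5% of mutants planted small at birth (x0.75) and 5% planted large
# (x1.3), plus a linked phenotype layer (%G1 rises with birth-size
# deficit in the planted small group; outliers pay a fitness penalty).

library(birthsize)

seed <- 20130901
out <- "results/panel"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

spec <- synthetic_panel_spec(n_mutants = 500, n_wildtype = 10,
                             planted = planted_outliers(25, 25),
                             seed = seed)
gen <- generate_panel(spec)
phen <- phenotype_link(gen$truth, seed = seed + 1L,
                       wt_birth_mean = spec$wt_birth_mean)

write_distribution_matrix(gen$panel, file.path(out, "distributions.tsv"))
readr::write_tsv(gen$truth, file.path(out, "truth.tsv"))
readr::write_tsv(phen, file.path(out, "phenotypes.tsv"))
writeLines(gen$panel$strains$orf[gen$panel$strains$role == "wild_type"],
           file.path(out, "wildtype_ids.txt"))

grid <- validate_bin_grid(gen$panel)
cat(sprintf(
  "Simulated %d strains (%d wild type) on %d channels (%.6g-%.6g fl),\n",
  n_strains(gen$panel), spec$n_wildtype, grid$n_bins,
  grid$range_lo_fl, grid$range_hi_fl))
cat(sprintf("channel widths %.9g-%.9g fl; %d cells per strain.\n",
            grid$min_interval_fl, grid$max_interval_fl,
            spec$cells_per_strain))
cat(sprintf("Planted: %d small (x%.2f), %d large (x%.2f).\n",
            sum(spec$planted$birth_effect < 1), 0.75,
            sum(spec$planted$birth_effect > 1), 1.3))
cat("Wrote", out, "\n")
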