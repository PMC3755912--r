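#!/usr/bin/env Rscript

# Stage 5: figures.
#
# Scatter panels of birth size against mean size and fitness (category
# colours, per-category rho annotations) and %G1 category boxplots with
# the band at the group mean, under both categorisation schemes.

library(birthsize)

params <- readr::read_tsv("results/params.tsv", show_col_types = FALSE)
assignments <- readr::read_tsv("results/categories.tsv",
                               show_col_types = FALSE)
phen <- readr::read_tsv("results/panel/phenotypes.tsv",
                        show_col_types = FALSE)

dir.create("results/figures", showWarnings = FALSE, recursive = TRUE)
save_fig <- function(p, name) {
  path <- file.path("results/figures", name)
  ggplot2::ggsave(path, p, width = 5, height = 4)
  cat("wrote", path, "\n")
}

for (sc in c("wt_sd", "quantile")) {
  save_fig(plot_birth_vs_phenotype(params, assignments, phen, "mean_size",
                                   scheme = sc),
           sprintf("birth_vs_mean_size_%s.pdf", sc))
  save_fig(plot_birth_vs_phenotype(params, assignments, phen, "fitness",
                                   scheme = sc),
           sprintf("birth_vs_fitness_%s.pdf", sc))
  save_fig(plot_category_box(params, assignments, phen, "pct_g1",
                             scheme = sc),
           sprintf("g1_by_category_%s.pdf", sc))
}
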