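#!/usr/bin/env Rscript

# Stage 3: assign small/normal/large birth-size categories.
#
# Two schemes over xb at the 20% cutoff: outliers beyond two wild-type
# SDs of the replicate mean, and the empirical 5% tails of the mutant
# birth-size distribution (whole boundary channels included).

library(birthsize)

params <- readr::read_tsv("results/params.tsv", show_col_types = FALSE)
assignments <- assign_categories(params, cutoff = 0.20, tail = 0.05)
readr::write_tsv(assignments, "results/categories.tsv")

for (sc in c("wt_sd", "quantile")) {
  tab <- table(assignments$label[assignments$scheme == sc])
  cat(sprintf("%-9s scheme: %d small / %d normal / %d large\n", sc,
              tab[["small"]], tab[["normal"]], tab[["large"]]))
}

overlap <- compare_schemes(
  assignments[assignments$scheme == "wt_sd", ],
  assignments[assignments$scheme == "quantile", ])
cat("Scheme overlap (rows wt_sd, cols quantile):\n")
print(overlap)
cat(sprintf("Outlier agreement: %d of %d quantile smalls and %d of %d\n",
            overlap["small", "small"], sum(overlap[, "small"]),
            overlap["large", "large"], sum(overlap[, "large"])),
    "quantile larges are also wild-type-SD outliers.\n")

truth <- readr::read_tsv("results/panel/truth.tsv", show_col_types = FALSE)
q <- merge(assignments[assignments$scheme == "quantile", ],
           truth[c("orf", "true_label")], by = "orf")
planted <- q[q$true_label != "normal", ]
cat(sprintf("Planted-label recovery (quantile scheme): %.0f%% of %d\n",
            100 * mean(planted$label == planted$true_label), nrow(planted)))
cat("Wrote results/categories.tsv\n")
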