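#' Spearman rank correlation with missing-data handling
#'
#' Midrank (average-rank) Spearman correlation with a two-sided p-value.
#' Pairs with a missing value in either variable are dropped. The p-value
#' comes from the large-sample t approximation; for small samples without
#' ties (`n <= exact_max`) the exact permutation distribution is used
#' instead.
#'
#' @param x,y Numeric vectors of equal length.
#' @param exact_max Largest `n` at which the exact p-value is attempted
#'   (default 10; ties force the approximation).
#' @return List: `rho`, `p_value`, `n` (pairs used), `method`. `rho` is `NA`
#'   with `method = "undefined"` when fewer than 3 complete pairs remain or
#'   either variable is constant.
#' @export
spearman_assoc <- function(x, y, exact_max = 10) {
  stopifnot(length(x) == length(y))
  keep <- stats::complete.cases(x, y)
  x <- x[keep]
  y <- y[keep]
  n <- length(x)
  if (n < 3 || length(unique(x)) < 2 || length(unique(y)) < 2) {
    return(list(rho = NA_real_, p_value = NA_real_, n = n,
                method = "undefined"))
  }
  ties <- anyDuplicated(x) > 0 || anyDuplicated(y) > 0
  exact <- n <= exact_max && !ties
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = exact)
  )
  list(rho = unname(ct$estimate), p_value = ct$p.value, n = n,
       method = if (exact) "exact" else "t-approximation")
}

category_table <- function(params, assignments, phenotypes, scheme,
                           mutants_only = TRUE) {
  ok <- params[params$qc == "pass", ]
  if (mutants_only) ok <- ok[ok$role == "mutant", ]
  asg <- assignments[assignments$scheme == scheme, c("orf", "label")]
  tab <- dplyr::inner_join(ok, asg, by = "orf")
  dplyr::left_join(tab, phenotypes, by = "orf")
}

#' Birth-size associations per category
#'
#' Spearman correlation between birth size (or mean size) and one phenotype,
#' within each birth-size category and overall. "Overall" is all qc-pass
#' mutants; category cells use the given scheme's assignment. Pairs with a
#' missing phenotype are dropped per cell (pairwise deletion); a cell with
#' fewer than 3 complete pairs is reported with `rho = NA`.
#'
#' @param params Parameter tibble from [extract_panel_parameters()].
#' @param assignments Assignment tibble from [assign_categories()] (or a
#'   single scheme's categoriser).
#' @param phenotypes Phenotype tibble (`orf`, `mean_size`, `fitness_rank`,
#'   `pct_g1`).
#' @param phenotype One of `"mean_size"`, `"fitness"`, `"pct_g1"`.
#' @param cutoff Daughter-interval cutoff whose `xb` is correlated
#'   (default 0.20).
#' @param scheme Which scheme's categories to stratify by (default
#'   `"wt_sd"`).
#' @param x_var `"xb"` (default) correlates birth size; `"xm"` correlates
#'   the extracted mean size instead (e.g. mean size vs %G1).
#' @return Tibble: `phenotype`, `scheme`, `cutoff_q`, `category`, `n`,
#'   `rho`, `p_value`.
#' @export
per_category_association <- function(params, assignments, phenotypes,
                                     phenotype = c("mean_size", "fitness",
                                                   "pct_g1"),
                                     cutoff = 0.20, scheme = "wt_sd",
                                     x_var = c("xb", "xm")) {
  phenotype <- match.arg(phenotype)
  x_var <- match.arg(x_var)
  ycol <- switch(phenotype, mean_size = "mean_size",
                 fitness = "fitness_rank", pct_g1 = "pct_g1")
  xcol <- if (x_var == "xb") xb_column(cutoff) else "xm"
  tab <- category_table(params, assignments, phenotypes, scheme)
  cells <- list(small = tab[tab$label == "small", ],
                normal = tab[tab$label == "normal", ],
                large = tab[tab$label == "large", ],
                overall = tab)
  rows <- lapply(names(cells), function(cat) {
    cell <- cells[[cat]]
    sp <- spearman_assoc(cell[[xcol]], cell[[ycol]])
    tibble::tibble(phenotype = phenotype, scheme = scheme,
                   cutoff_q = cutoff, category = cat,
                   n = sp$n, rho = sp$rho, p_value = sp$p_value)
  })
  dplyr::bind_rows(rows)
}

#' Five-number boxplot summary with Tukey whiskers
#'
#' Quartiles (type-7), whiskers at the most extreme data within 1.5 IQR of
#' the quartiles, and both mean and median (the figure convention here
#' draws the band at the mean).
#'
#' @param x Numeric vector (missing values dropped).
#' @return Tibble: `n`, `mean`, `sd`, `median`, `q1`, `q3`, `whisker_lo`,
#'   `whisker_hi`, `n_outliers`.
#' @export
boxplot_summary <- function(x) {
  x <- x[!is.na(x)]
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
  iqr <- q[3] - q[1]
  lo <- min(x[x >= q[1] - 1.5 * iqr])
  hi <- max(x[x <= q[3] + 1.5 * iqr])
  tibble::tibble(n = length(x), mean = mean(x), sd = stats::sd(x),
                 median = q[2], q1 = q[1], q3 = q[3],
                 whisker_lo = lo, whisker_hi = hi,
                 n_outliers = sum(x < lo | x > hi))
}

#' Compare phenotype means between birth-size categories
#'
#' For every pair of categories, and for each category against the rest of
#' the panel, tests the difference in phenotype means with Welch's
#' two-sample t test (primary: the question is about means) and the
#' Mann-Whitney U test (robustness to skew), both two-sided. When both
#' groups have zero variance the t test is undefined and reported `NA`;
#' Mann-Whitney is still computed.
#'
#' @inheritParams per_category_association
#' @param holm If `TRUE`, append Holm-adjusted p-value columns.
#' @return List with `comparisons` (one row per pair: `phenotype`, `scheme`,
#'   `group_a`, `group_b`, `n_a`, `n_b`, `mean_diff`, `welch_t_p`,
#'   `mann_whitney_p`) and `groups` (per-category [boxplot_summary()] rows).
#' @export
group_mean_comparison <- function(params, assignments, phenotypes,
                                  phenotype = c("mean_size", "fitness",
                                                "pct_g1"),
                                  cutoff = 0.20, scheme = "wt_sd",
                                  holm = FALSE) {
  phenotype <- match.arg(phenotype)
  ycol <- switch(phenotype, mean_size = "mean_size",
                 fitness = "fitness_rank", pct_g1 = "pct_g1")
  tab <- category_table(params, assignments, phenotypes, scheme)
  tab <- tab[!is.na(tab[[ycol]]), ]
  lv <- c("small", "normal", "large")
  groups <- lapply(lv, function(g) tab[[ycol]][tab$label == g])
  names(groups) <- lv
  pairs <- list(c("small", "normal"), c("small", "large"),
                c("normal", "large"),
                c("small", "rest"), c("normal", "rest"), c("large", "rest"))
  one <- function(a, b) {
    va <- groups[[a]]
    vb <- if (b == "rest") tab[[ycol]][tab$label != a] else groups[[b]]
    if (length(va) < 2 || length(vb) < 2) {
      return(tibble::tibble(phenotype = phenotype, scheme = scheme,
                            group_a = a, group_b = b,
                            n_a = length(va), n_b = length(vb),
                            mean_diff = NA_real_, welch_t_p = NA_real_,
                            mann_whitney_p = NA_real_))
    }
    tp <- if (stats::sd(va) == 0 && stats::sd(vb) == 0) {
      NA_real_
    } else {
      stats::t.test(va, vb)$p.value
    }
    wp <- suppressWarnings(stats::wilcox.test(va, vb)$p.value)
    tibble::tibble(phenotype = phenotype, scheme = scheme,
                   group_a = a, group_b = b,
                   n_a = length(va), n_b = length(vb),
                   mean_diff = mean(va) - mean(vb),
                   welch_t_p = tp, mann_whitney_p = wp)
  }
  comparisons <- dplyr::bind_rows(lapply(pairs, function(p) one(p[1], p[2])))
  if (holm) {
    comparisons$welch_t_p_holm <- stats::p.adjust(comparisons$welch_t_p,
                                                  "holm")
    comparisons$mann_whitney_p_holm <-
      stats::p.adjust(comparisons$mann_whitney_p, "holm")
  }
  summaries <- dplyr::bind_rows(lapply(c(lv, "overall"), function(g) {
    v <- if (g == "overall") tab[[ycol]] else groups[[g]]
    if (length(v) == 0) return(NULL)
    dplyr::bind_cols(tibble::tibble(phenotype = phenotype, scheme = scheme,
                                    category = g),
                     boxplot_summary(v))
  }))
  list(comparisons = comparisons, groups = summaries)
}

#' Percent size increase from birth to budding
#'
#' Given an estimated birth size and the size at which buds first appear,
#' the relative growth during G1: `100 * (budding - xb) / xb`. Reported
#' both unrounded and rounded to the nearest integer percent.
#'
#' @param xb Birth size in fl (positive; vectorised).
#' @param budding_size Budding size in fl (default 35, the size at which
#'   new buds become visible in elutriated early-G1 daughters).
#' @return Tibble: `xb`, `budding_size`, `increase_pct`,
#'   `increase_pct_rounded`. A budding size below `xb` yields a negative
#'   increase and a warning.
#' @export
birth_to_budding_increase <- function(xb, budding_size = 35) {
  stopifnot(all(xb > 0))
  pct <- 100 * (budding_size - xb) / xb
  if (any(pct < 0)) {
    warning("budding size below birth size: negative increase", call. = FALSE)
  }
  tibble::tibble(xb = xb, budding_size = budding_size,
                 increase_pct = pct,
                 increase_pct_rounded = round(pct))
}
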