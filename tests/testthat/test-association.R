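test_that("spearman handles monotone, tied and degenerate inputs", {
  expect_equal(spearman_assoc(1:4, c(10, 20, 30, 40))$rho, 1.0)
  expect_equal(spearman_assoc(1:4, c(40, 30, 20, 10))$rho, -1.0)

  x <- c(1, 2, 2, 4); y <- c(3, 1, 2, 4)
  got <- spearman_assoc(x, y)
  expect_equal(got$rho, brute_spearman(x, y))
  expect_equal(got$method, "t-approximation")  # ties block the exact path

  const <- spearman_assoc(rep(2, 5), 1:5)
  expect_true(is.na(const$rho))
  expect_equal(const$method, "undefined")

  short <- spearman_assoc(c(1, 2, NA), c(NA, 1, 2))
  expect_true(is.na(short$rho))
})

test_that("spearman matches the midrank oracle and drops pairs listwise", {
  set.seed(13)
  for (i in 1:100) {
    n <- sample(5:40, 1)
    x <- sample(1:12, n, replace = TRUE)
    y <- x + rnorm(n, 0, 3)
    x[sample(n, 2)] <- NA
    keep <- complete.cases(x, y)
    if (sum(keep) < 3 || length(unique(x[keep])) < 2) next
    expect_equal(spearman_assoc(x, y)$rho,
                 brute_spearman(x[keep], y[keep]))
  }
})

test_that("spearman is invariant under strictly increasing transforms", {
  set.seed(17)
  for (i in 1:50) {
    x <- rnorm(20); y <- rnorm(20) + x
    r0 <- spearman_assoc(x, y)$rho
    expect_equal(spearman_assoc(exp(x), y)$rho, r0)
    expect_equal(spearman_assoc(x, y^3)$rho, r0)
    expect_equal(spearman_assoc(rank(x), exp(y / 2))$rho, r0)
  }
})

test_that("small tie-free samples use the exact permutation p-value", {
  got <- spearman_assoc(c(1, 3, 2, 5, 4), c(2, 1, 4, 3, 5))
  expect_equal(got$method, "exact")
  expect_equal(got$p_value,
               cor.test(c(1, 3, 2, 5, 4), c(2, 1, 4, 3, 5),
                        method = "spearman", exact = TRUE)$p.value)
})

make_assoc_fixture <- function(n = 120, seed = 3) {
  set.seed(seed)
  xb <- round(rnorm(n, 24, 2), 1)
  params <- tibble::tibble(orf = sprintf("S%04d", 1:n), role = "mutant",
                           x0 = 15, xd = xb + 8, xb_20 = xb, xm = xb + 12,
                           xy = xb + 30, qc = "pass")
  phen <- tibble::tibble(orf = params$orf,
                         mean_size = xb + rnorm(n, 0, 0.5),
                         fitness_rank = pmin(21, pmax(1, round(12 - xb / 3 +
                                                                 rnorm(n)))),
                         pct_g1 = 40 + rnorm(n, 0, 5))
  asg <- categorize_quantile(params, tail = 0.10)
  asg$scheme <- "quantile"
  list(params = params, phen = phen, asg = asg)
}

test_that("per-category association recovers a planted size link", {
  fx <- make_assoc_fixture()
  res <- per_category_association(fx$params, fx$asg, fx$phen, "mean_size",
                                  scheme = "quantile")
  expect_setequal(res$category, c("small", "normal", "large", "overall"))
  overall <- res[res$category == "overall", ]
  expect_gt(overall$rho, 0.9)
  # the overall cell is exactly spearman on the pooled pairs
  direct <- spearman_assoc(fx$params$xb_20, fx$phen$mean_size)
  expect_equal(overall$rho, direct$rho)
  expect_equal(overall$n, direct$n)
  # category cells partition the overall pairs
  expect_equal(sum(res$n[res$category != "overall"]), overall$n)
})

test_that("cells with too few complete pairs report rho as missing", {
  fx <- make_assoc_fixture()
  fx$phen$pct_g1[fx$asg$label == "small"] <- NA
  res <- per_category_association(fx$params, fx$asg, fx$phen, "pct_g1",
                                  scheme = "quantile")
  expect_true(is.na(res$rho[res$category == "small"]))
  expect_false(is.na(res$rho[res$category == "overall"]))
})

test_that("group comparison is null on identical groups and detects shifts", {
  # identically drawn groups with equal means: t statistic 0, p = 1
  params <- tibble::tibble(orf = sprintf("S%d", 1:40), role = "mutant",
                           x0 = 15, xd = 30,
                           xb_20 = rep(c(20, 24), each = 20),
                           xm = 35, xy = 60, qc = "pass")
  asg <- tibble::tibble(orf = params$orf, scheme = "quantile",
                        cutoff_q = 0.2,
                        label = rep(c("small", "normal"), each = 20))
  phen <- tibble::tibble(orf = params$orf, mean_size = NA_real_,
                         fitness_rank = NA_real_,
                         pct_g1 = rep(c(30, 40, 50, 60), 10))
  gc <- group_mean_comparison(params, asg, phen, "pct_g1",
                              scheme = "quantile")
  sn <- gc$comparisons[gc$comparisons$group_a == "small" &
                         gc$comparisons$group_b == "normal", ]
  expect_equal(sn$mean_diff, 0)
  expect_equal(sn$welch_t_p, 1)

  # planted +10 shift at n = 50 per group rejects essentially always
  set.seed(19)
  rej <- replicate(1000, {
    t.test(rnorm(50, 50, 5), rnorm(50, 40, 5))$p.value < 0.01
  })
  expect_gte(mean(rej), 0.99)
})

test_that("degenerate zero-variance groups fall back to Mann-Whitney", {
  params <- tibble::tibble(orf = sprintf("S%d", 1:40), role = "mutant",
                           x0 = 15, xd = 30, xb_20 = rep(c(20, 24), 20),
                           xm = 35, xy = 60, qc = "pass")
  asg <- tibble::tibble(orf = params$orf, scheme = "wt_sd", cutoff_q = 0.2,
                        label = rep(c("small", "normal"), 20))
  phen <- tibble::tibble(orf = params$orf,
                         mean_size = NA_real_, fitness_rank = NA_real_,
                         pct_g1 = rep(c(50, 40), 20))
  gc <- group_mean_comparison(params, asg, phen, "pct_g1")
  sn <- gc$comparisons[gc$comparisons$group_a == "small" &
                         gc$comparisons$group_b == "normal", ]
  expect_true(is.na(sn$welch_t_p))
  expect_lt(sn$mann_whitney_p, 0.001)
})

test_that("boxplot summaries follow Tukey conventions", {
  s <- boxplot_summary(1:9)
  expect_equal(s$median, 5)
  expect_equal(s$q1, 3)
  expect_equal(s$q3, 7)
  expect_equal(s$n_outliers, 0)
  expect_equal(c(s$whisker_lo, s$whisker_hi), c(1, 9))

  s2 <- boxplot_summary(c(1:9, 100))
  expect_equal(s2$n_outliers, 1)
  expect_lt(s2$whisker_hi, 100)
})

test_that("welch and Mann-Whitney mostly agree on 1-SD normal shifts", {
  set.seed(29)
  agree <- replicate(400, {
    a <- rnorm(50); b <- rnorm(50, 1)
    (t.test(a, b)$p.value < 0.05) ==
      (wilcox.test(a, b)$p.value < 0.05)
  })
  expect_gte(mean(agree), 0.9)
})

test_that("holm adjustment is appended on request", {
  fx <- make_assoc_fixture()
  gc <- group_mean_comparison(fx$params, fx$asg, fx$phen, "pct_g1",
                              scheme = "quantile", holm = TRUE)
  expect_true(all(c("welch_t_p_holm", "mann_whitney_p_holm") %in%
                    names(gc$comparisons)))
  expect_true(all(gc$comparisons$welch_t_p_holm >=
                    gc$comparisons$welch_t_p, na.rm = TRUE))
})

test_that("birth-to-budding increase arithmetic", {
  expect_equal(birth_to_budding_increase(35, 35)$increase_pct, 0)
  got <- birth_to_budding_increase(c(21.84, 27.40), 35)
  expect_equal(got$increase_pct, c(60.25641, 27.737226), tolerance = 1e-6)
  expect_equal(got$increase_pct_rounded, c(60, 28))
  expect_warning(neg <- birth_to_budding_increase(40, 35), "negative")
  expect_lt(neg$increase_pct, 0)
})
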