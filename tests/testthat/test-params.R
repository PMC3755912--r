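test_that("support detection keeps the cell interval and drops debris", {
  d1 <- size_distribution(18:26, c(0, 0, 5, 9, 12, 7, 3, 1, 0))
  s1 <- detect_support(d1, support_config(alpha = 0.01, k = 3))
  expect_equal(s1$qc, "pass")
  expect_equal(s1$x0, 20)
  expect_equal(s1$xy, 25)

  # debris spike in the lowest channel, isolated by empty channels: the
  # k-consecutive rule must refuse to open the support there
  d2 <- size_distribution(18:25, c(40, 0, 0, 5, 9, 12, 7, 3))
  s2 <- detect_support(d2, support_config(alpha = 0.01, k = 3))
  expect_equal(s2$x0, 21)
  expect_equal(s2$xy, 25)
  expect_equal(s2$x0, brute_x0(d2$bin_fl, d2$counts, 0.01, 3))
})

test_that("support detection agrees with the exhaustive rule oracle", {
  set.seed(7)
  for (i in 1:200) {
    d <- random_distribution()
    s <- detect_support(d, support_config())
    o <- brute_x0(d$bin_fl, d$counts, 0.01, 3)
    if (s$qc == "pass") {
      expect_identical(s$x0, o)
      expect_identical(s$xy, d$bin_fl[max(which(d$counts > 0))])
    } else {
      expect_true(is.na(o) || o >= d$bin_fl[max(which(d$counts > 0))])
    }
  }
})

test_that("exclusion lists and manual overrides are honoured", {
  d <- size_distribution(18:26, c(0, 0, 5, 9, 12, 7, 3, 1, 0))
  cfg <- support_config(exclusion_list = "YBR001C")
  expect_equal(detect_support(d, cfg, orf = "YBR001C")$qc, "manual_excluded")
  expect_equal(detect_support(d, cfg, orf = "YBR002C")$qc, "pass")

  ov <- support_config(manual_overrides = tibble::tibble(
    orf = "YBR003C", x0 = 19, xy = 24))
  s <- detect_support(d, ov, orf = "YBR003C")
  expect_equal(c(s$x0, s$xy), c(19, 24))
})

test_that("mode location breaks ties leftward and flags empty daughters", {
  d <- size_distribution(c(20, 21, 22, 23), c(5, 9, 12, 7))
  expect_equal(find_mode(d, 20, 23)$xd, 22)

  dt <- size_distribution(c(20, 21, 22, 23), c(5, 12, 12, 7))
  expect_equal(find_mode(dt, 20, 23)$xd, 21)

  dd <- size_distribution(c(20, 21, 22), c(12, 5, 3))
  m <- find_mode(dd, 20, 22)
  expect_equal(m$qc, "abnormal_no_daughter_range")
})

test_that("smoothing can relocate a spiky mode but reports on the grid", {
  d <- size_distribution(20:26, c(2, 6, 20, 5, 18, 19, 3))
  expect_equal(find_mode(d, 20, 26, smoothing_window = 1)$xd, 22)
  sm <- find_mode(d, 20, 26, smoothing_window = 3)$xd
  expect_true(sm %in% d$bin_fl)
  expect_equal(sm, 23)  # window mean (20+5+18)/3 beats the lone spike's
})

test_that("birth size follows the inclusive cumulative-threshold rule", {
  d <- size_distribution(c(20, 21, 22, 23), c(2, 3, 5, 10))
  expect_equal(birth_size(d, 20, 23, 0.20)$xb, 21)  # threshold 4: 2, then 5

  one <- size_distribution(c(28, 30, 32), c(0, 7, 0))
  for (q in c(0.10, 0.15, 0.20, 0.25)) {
    expect_equal(birth_size(one, 28, 32, q)$xb, 30)
  }

  empty <- size_distribution(c(20, 21, 22, 23), c(0, 0, 0, 5))
  expect_equal(birth_size(empty, 20, 22)$qc, "abnormal_no_daughter_range")
})

test_that("birth size matches the brute-force oracle on random data", {
  set.seed(11)
  for (i in 1:1000) {
    d <- random_distribution()
    p <- extract_parameters(d)
    if (p$qc != "pass") next
    for (q in c(0.10, 0.15, 0.20, 0.25)) {
      expect_identical(birth_size(d, p$x0, p$xd, q)$xb,
                       brute_birth_size(d$bin_fl, d$counts, p$x0, p$xd, q))
    }
  }
})

test_that("mean size is the renormalised frequency-weighted average", {
  single <- size_distribution(c(38, 40, 42), c(0, 6, 0))
  expect_equal(mean_size(single, 38, 42), 40)

  sym <- size_distribution(c(20, 30, 40), c(5, 0, 5))
  expect_equal(mean_size(sym, 20, 40), 30)

  wt <- size_distribution(c(20, 22, 24), c(1, 0, 3))
  expect_equal(mean_size(wt, 20, 24), 23)  # (20 + 3*24)/4

  # noise outside the support must not pull the mean
  noisy <- size_distribution(c(10, 20, 22, 24), c(500, 1, 0, 3))
  expect_equal(mean_size(noisy, 20, 24), 23)
})

test_that("error bounds equal the local grid interval", {
  bins <- c(20, 20.5, 21.5, 23)
  expect_equal(bin_error(bins, 20), 0.5)
  expect_equal(bin_error(bins, 20.5), 1.0)
  expect_equal(bin_error(bins, 23), 1.5)    # last channel: preceding interval
  expect_equal(bin_error(bins, 21.0), 1.0)  # between channels: containing one

  d <- size_distribution(c(20, 20.5, 21.5, 23), c(2, 6, 4, 1))
  p <- extract_parameters(d)
  expect_equal(p$qc, "pass")
  expect_equal(unname(p$err[names(p$xb)[3]]),
               bin_error(d$bin_fl, p$xb[[3]]))
})

test_that("full extraction satisfies the parameter ordering invariants", {
  set.seed(23)
  n_pass <- 0
  for (i in 1:300) {
    d <- random_distribution()
    p <- extract_parameters(d)
    if (p$qc != "pass") next
    n_pass <- n_pass + 1
    expect_true(p$x0 <= min(p$xb) && max(p$xb) <= p$xd && p$xd <= p$xy)
    expect_true(p$x0 <= p$xm && p$xm <= p$xy)
    expect_true(all(diff(p$xb) >= 0))  # xb monotone in the cutoff
    expect_true(all(p$err > 0))
  }
  expect_gt(n_pass, 150)
})

test_that("a monotone-decreasing profile is abnormal", {
  d <- size_distribution(20:27, c(40, 30, 20, 12, 6, 3, 1, 0))
  expect_equal(extract_parameters(d)$qc, "abnormal_no_daughter_range")
})

test_that("zero-count channels outside the support change nothing", {
  set.seed(31)
  for (i in 1:100) {
    d <- random_distribution()
    p <- extract_parameters(d)
    if (p$qc != "pass") next
    bins2 <- c(d$bin_fl[1] - c(1.0, 0.5), d$bin_fl,
               d$bin_fl[length(d$bin_fl)] + c(0.5, 1.0))
    d2 <- size_distribution(bins2, c(0, 0, d$counts, 0, 0))
    p2 <- extract_parameters(d2)
    expect_equal(p2$qc, "pass")
    expect_identical(
      c(p2$x0, p2$xb, p2$xd, p2$xm, p2$xy),
      c(p$x0, p$xb, p$xd, p$xm, p$xy))
  }
})

test_that("halving every channel leaves the extraction stable", {
  # Support, mode and mean move by at most one original interval. Birth
  # size has one extra, predictable sensitivity: the refined mode channel
  # keeps only half its counts inside the daughter interval, lowering the
  # cumulative threshold by q * c_mode / 2; xb must track the original-grid
  # crossing of that shifted threshold to within one interval.
  set.seed(37)
  n_checked <- 0
  for (i in 1:60) {
    d <- random_distribution()
    p <- extract_parameters(d)
    if (p$qc != "pass") next
    w <- diff(d$bin_fl)
    w <- c(w[1], w)  # local width attributed to each channel
    fine_bins <- as.numeric(rbind(d$bin_fl - w / 4, d$bin_fl + w / 4))
    fine_counts <- as.numeric(rbind(d$counts / 2, d$counts / 2))
    if (any(diff(fine_bins) <= 0)) next
    # halving the channels doubles how many of them span the same physical
    # persistence window, so k scales with the refinement
    p2 <- extract_parameters(size_distribution(fine_bins, fine_counts),
                             support_config(k = 6))
    if (p2$qc != "pass") next
    n_checked <- n_checked + 1
    for (nm in c("x0", "xd", "xm", "xy")) {
      expect_lte(abs(p2[[nm]] - p[[nm]]),
                 bin_error(d$bin_fl, p[[nm]]) + 1e-9)
    }
    in_d <- d$bin_fl >= p$x0 & d$bin_fl <= p$xd
    total <- sum(d$counts[in_d])
    c_mode <- d$counts[d$bin_fl == p$xd]
    for (qi in seq_along(p$xb)) {
      q <- c(0.10, 0.15, 0.20, 0.25)[qi]
      q_shift <- q * (total - c_mode / 2) / total
      ref <- brute_birth_size(d$bin_fl, d$counts, p$x0, p$xd, q_shift)
      expect_lte(abs(p2$xb[[qi]] - ref), bin_error(d$bin_fl, ref) + 1e-9)
    }
  }
  expect_gt(n_checked, 20)
})

test_that("panel-level extraction mirrors per-strain extraction", {
  qp <- quick_panel()
  pt <- qp$params
  expect_equal(nrow(pt), n_strains(qp$panel))
  orf <- pt$orf[which(pt$qc == "pass")[1]]
  p <- extract_parameters(panel_distribution(qp$panel, orf))
  row <- pt[pt$orf == orf, ]
  expect_equal(row$x0, p$x0)
  expect_equal(row$xb_20, p$xb[["xb_20"]])
  expect_equal(row$xm, p$xm)
  expect_equal(row$err_xm, unname(p$err[["xm"]]))
})

test_that("excluded strains appear in the panel table as manual_excluded", {
  qp <- quick_panel()
  cfg <- support_config(exclusion_list = qp$panel$strains$orf[1:3])
  pt <- extract_panel_parameters(qp$panel, cfg)
  expect_equal(sum(pt$qc == "manual_excluded"), 3)
  expect_true(all(is.na(pt$x0[pt$qc == "manual_excluded"])))
})
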