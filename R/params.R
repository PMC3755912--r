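#' Configuration for support detection and curation
#'
#' The original analysis located the true cell-size interval of each
#' histogram by eye, discarding spurious low-channel debris counts and a
#' handful of profiles too abnormal to partition into daughters and mothers.
#' This package automates that curation with a deterministic rule (an
#' alpha-fraction-of-mode threshold that must hold for `k` consecutive
#' channels) while keeping two escape hatches that reproduce manual
#' decisions as configuration: a per-strain support override table and an
#' exclusion list.
#'
#' @param alpha Noise threshold as a fraction of the raw histogram's modal
#'   count (default 0.01). A channel only counts as the start of the cell
#'   interval if its count reaches `alpha * max(counts)`.
#' @param k Persistence: the threshold must hold for `k` consecutive
#'   channels (default 3), so an isolated debris spike cannot open the
#'   support.
#' @param smoothing_window Odd moving-average window used when locating the
#'   mode (default 1 = no smoothing). Mild smoothing emulates visual mode
#'   placement on ragged histograms; the mode is always reported on the
#'   original grid.
#' @param manual_overrides Optional tibble/data.frame with columns `orf`,
#'   `x0`, `xy` giving hand-curated supports that bypass the automatic rule.
#' @param exclusion_list Character vector of ORFs to drop as abnormal
#'   profiles (`qc = "manual_excluded"`).
#' @param mean_over_support If `TRUE` (default) the mean size is computed
#'   over the detected support only, excluding noise channels; if `FALSE`,
#'   over all channels (sensitivity analysis).
#' @return A list of class `support_config`.
#' @export
support_config <- function(alpha = 0.01, k = 3, smoothing_window = 1,
                           manual_overrides = NULL,
                           exclusion_list = character(),
                           mean_over_support = TRUE) {
  if (alpha < 0 || alpha >= 1) stop("`alpha` must be in [0, 1)", call. = FALSE)
  if (k < 1) stop("`k` must be >= 1", call. = FALSE)
  if (smoothing_window < 1 || smoothing_window %% 2 != 1) {
    stop("`smoothing_window` must be an odd integer >= 1", call. = FALSE)
  }
  if (!is.null(manual_overrides)) {
    manual_overrides <- tibble::as_tibble(manual_overrides)
    stopifnot(all(c("orf", "x0", "xy") %in% names(manual_overrides)))
  }
  structure(list(alpha = alpha, k = as.integer(k),
                 smoothing_window = as.integer(smoothing_window),
                 manual_overrides = manual_overrides,
                 exclusion_list = as.character(exclusion_list),
                 mean_over_support = isTRUE(mean_over_support)),
            class = "support_config")
}

#' Detect the cell-size support of a distribution
#'
#' Finds `[x0, xy]`, the channel interval actually occupied by cells.
#' Channels below `x0` often hold spurious debris counts; `x0` is the
#' smallest channel whose count reaches `alpha` times the raw modal count
#' and does so for `k` consecutive channels, and `xy` is the largest channel
#' with any count. A strain in the exclusion list short-circuits to
#' `qc = "manual_excluded"`; a strain with a manual override returns the
#' override unchanged.
#'
#' @param dist A [size_distribution()].
#' @param cfg A [support_config()].
#' @param orf Optional strain identifier, used only to look up overrides and
#'   exclusions.
#' @return List with `x0`, `xy` (fl, `NA` on failure) and `qc` (`"pass"`,
#'   `"abnormal_no_daughter_range"` or `"manual_excluded"`).
#' @export
detect_support <- function(dist, cfg = support_config(), orf = NULL) {
  stopifnot(inherits(dist, "size_distribution"),
            inherits(cfg, "support_config"))
  if (!is.null(orf) && orf %in% cfg$exclusion_list) {
    return(list(x0 = NA_real_, xy = NA_real_, qc = "manual_excluded"))
  }
  if (!is.null(orf) && !is.null(cfg$manual_overrides) &&
      orf %in% cfg$manual_overrides$orf) {
    ov <- cfg$manual_overrides[cfg$manual_overrides$orf == orf, ][1, ]
    return(list(x0 = ov$x0, xy = ov$xy, qc = "pass"))
  }
  counts <- dist$counts
  n <- length(counts)
  thr <- cfg$alpha * max(counts)
  ok <- counts >= thr & counts > 0
  # run of k consecutive above-threshold channels starting at each position
  run_ok <- rep(FALSE, n)
  if (n >= cfg$k) {
    csum <- cumsum(c(0, as.numeric(ok)))
    run_ok[seq_len(n - cfg$k + 1)] <-
      (csum[(cfg$k + 1):(n + 1)] - csum[seq_len(n - cfg$k + 1)]) == cfg$k
  }
  i0 <- which(run_ok)[1]
  iy <- max(which(counts > 0))
  if (is.na(i0) || i0 >= iy) {
    return(list(x0 = NA_real_, xy = NA_real_,
                qc = "abnormal_no_daughter_range"))
  }
  list(x0 = dist$bin_fl[i0], xy = dist$bin_fl[iy], qc = "pass")
}

moving_average <- function(x, window) {
  if (window <= 1) return(x)
  half <- (window - 1) / 2
  n <- length(x)
  csum <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1)
  hi <- pmin(seq_len(n) + half, n)
  (csum[hi + 1] - csum[lo]) / (hi - lo + 1)
}

#' Locate the mode (maximum daughter size) of a distribution
#'
#' Budding yeast divides asymmetrically, so in an asynchronous population at
#' least half the cells are newborn daughters smaller than their mothers.
#' The histogram mode `xd` therefore separates the daughter interval
#' `[x0, xd]` from the mother interval `[xd, xy]`. Ties break to the
#' smallest channel; optional moving-average smoothing stabilises the
#' argmax on ragged histograms while the reported location stays on the
#' original grid. A mode at the support start leaves no daughter interval
#' and is flagged abnormal.
#'
#' @param dist A [size_distribution()].
#' @param x0,xy Support bounds from [detect_support()], in fl.
#' @param smoothing_window Odd integer >= 1 (default 1, no smoothing).
#' @return List with `xd` (fl, `NA` on failure) and `qc`.
#' @export
find_mode <- function(dist, x0, xy, smoothing_window = 1) {
  stopifnot(inherits(dist, "size_distribution"), x0 < xy)
  idx <- which(dist$bin_fl >= x0 & dist$bin_fl <= xy)
  sm <- moving_average(dist$counts, smoothing_window)[idx]
  xd <- dist$bin_fl[idx[which.max(sm)]]   # which.max: leftmost tie
  if (xd == x0) {
    return(list(xd = xd, qc = "abnormal_no_daughter_range"))
  }
  list(xd = xd, qc = "pass")
}

#' Birth size from the daughter interval
#'
#' The birth size `xb` is the channel at which the running sum of counts
#' from `x0` first reaches a fixed fraction `q` (default 20%) of the total
#' count in the daughter interval `[x0, xd]`; both sums include their
#' endpoint channels and the comparison is `>=`, with no interpolation
#' inside channels — the method accepts channel-granularity error instead.
#'
#' @param dist A [size_distribution()].
#' @param x0,xd Daughter interval bounds in fl.
#' @param cutoff Fraction `q` in (0, 1) of daughter-interval observations
#'   (default 0.20).
#' @return List with `xb` (fl, `NA` when the daughter interval holds no
#'   counts) and `qc`.
#' @export
birth_size <- function(dist, x0, xd, cutoff = 0.20) {
  stopifnot(inherits(dist, "size_distribution"),
            cutoff > 0, cutoff < 1, x0 <= xd)
  idx <- which(dist$bin_fl >= x0 & dist$bin_fl <= xd)
  total <- sum(dist$counts[idx])
  if (total <= 0) {
    return(list(xb = NA_real_, qc = "abnormal_no_daughter_range"))
  }
  cum <- cumsum(dist$counts[idx])
  hit <- which(cum >= cutoff * total)[1]
  list(xb = dist$bin_fl[idx[hit]], qc = "pass")
}

#' Mean cell size over the support
#'
#' The frequency-weighted average channel size, with frequencies
#' renormalised over `[x0, xy]` so that noise counts outside the support do
#' not pull the mean.
#'
#' @param dist A [size_distribution()].
#' @param x0,xy Support bounds in fl. Pass the full grid range to average
#'   over all channels instead.
#' @return Mean size in fl.
#' @export
mean_size <- function(dist, x0, xy) {
  stopifnot(inherits(dist, "size_distribution"), x0 <= xy)
  idx <- which(dist$bin_fl >= x0 & dist$bin_fl <= xy)
  w <- dist$counts[idx]
  stopifnot(sum(w) > 0)
  sum(dist$bin_fl[idx] * w) / sum(w)
}

#' Channel-granularity error bound at a size
#'
#' Every extracted parameter sits on a channel and is only known to within
#' that channel's width: the bound at channel `x_p` is the interval to the
#' next channel, `x_{p+1} - x_p`. The last channel uses the preceding
#' interval. For values between channels (the mean), the containing
#' channel's interval is used.
#'
#' @param bin_fl The channel grid.
#' @param value Size in fl at (or between) channels.
#' @return Interval width in fl.
#' @export
bin_error <- function(bin_fl, value) {
  if (is.na(value)) return(NA_real_)
  n <- length(bin_fl)
  i <- findInterval(value, bin_fl)
  i <- min(max(i, 1L), n)
  if (i < n) bin_fl[i + 1] - bin_fl[i] else bin_fl[n] - bin_fl[n - 1]
}

#' Extract all distribution parameters for one strain
#'
#' Composes [detect_support()], [find_mode()], [birth_size()] (once per
#' cutoff) and [mean_size()] into the five-parameter summary of one
#' strain's size distribution, attaching per-parameter channel-width error
#' bounds and a QC status. A failure at any stage propagates its QC label;
#' parameters from completed stages are retained for diagnostics.
#'
#' @param dist A [size_distribution()].
#' @param cfg A [support_config()].
#' @param cutoffs Numeric vector of daughter-interval fractions (default
#'   `c(0.10, 0.15, 0.20, 0.25)`).
#' @param orf Optional strain identifier (override/exclusion lookup).
#' @return A list of class `distribution_parameters` with fields `x0`, `xd`,
#'   `xb` (named by cutoff percentage), `xm`, `xy`, `err` (named), `qc`.
#' @export
extract_parameters <- function(dist, cfg = support_config(),
                               cutoffs = c(0.10, 0.15, 0.20, 0.25),
                               orf = NULL) {
  stopifnot(all(cutoffs > 0 & cutoffs < 1))
  cutoffs <- sort(cutoffs)
  xb <- stats::setNames(rep(NA_real_, length(cutoffs)),
                        sprintf("xb_%g", 100 * cutoffs))
  out <- list(x0 = NA_real_, xd = NA_real_, xb = xb, xm = NA_real_,
              xy = NA_real_, err = numeric(), qc = "pass")
  class(out) <- "distribution_parameters"

  sup <- detect_support(dist, cfg, orf = orf)
  out$qc <- sup$qc
  if (sup$qc != "pass") return(out)
  out$x0 <- sup$x0
  out$xy <- sup$xy

  md <- find_mode(dist, sup$x0, sup$xy, cfg$smoothing_window)
  out$xd <- md$xd
  if (md$qc != "pass") {
    out$qc <- md$qc
    return(out)
  }

  for (j in seq_along(cutoffs)) {
    bs <- birth_size(dist, sup$x0, md$xd, cutoffs[j])
    if (bs$qc != "pass") {
      out$qc <- bs$qc
      return(out)
    }
    out$xb[j] <- bs$xb
  }

  out$xm <- if (cfg$mean_over_support) {
    mean_size(dist, sup$x0, sup$xy)
  } else {
    mean_size(dist, dist$bin_fl[1], dist$bin_fl[length(dist$bin_fl)])
  }

  vals <- c(x0 = out$x0, xd = out$xd, out$xb, xm = out$xm, xy = out$xy)
  out$err <- vapply(vals, function(v) bin_error(dist$bin_fl, v), numeric(1))
  out
}

#' @export
print.distribution_parameters <- function(x, ...) {
  cat(sprintf("<distribution_parameters> qc=%s x0=%.4g xd=%.4g xm=%.4g xy=%.4g\n",
              x$qc, x$x0, x$xd, x$xm, x$xy))
  if (!all(is.na(x$xb))) {
    cat("  xb:", paste(sprintf("%s=%.4g", names(x$xb), x$xb), collapse = " "),
        "\n")
  }
  invisible(x)
}

#' Extract parameters for every strain in a panel
#'
#' @param panel A [strain_panel()].
#' @param cfg A [support_config()].
#' @param cutoffs Daughter-interval fractions, as in [extract_parameters()].
#' @return Tibble with one row per strain: `orf`, `role`, `x0`, `xd`,
#'   `xb_<pct>` per cutoff, `xm`, `xy`, matching `err_*` columns, `qc`.
#'   All-zero strains are reported with `qc = "abnormal_no_daughter_range"`.
#' @export
extract_panel_parameters <- function(panel, cfg = support_config(),
                                     cutoffs = c(0.10, 0.15, 0.20, 0.25)) {
  stopifnot(inherits(panel, "strain_panel"))
  cutoffs <- sort(cutoffs)
  rows <- lapply(seq_len(n_strains(panel)), function(i) {
    orf <- panel$strains$orf[i]
    if (panel$strains$all_zero[i]) {
      p <- list(x0 = NA_real_, xd = NA_real_,
                xb = stats::setNames(rep(NA_real_, length(cutoffs)),
                                     sprintf("xb_%g", 100 * cutoffs)),
                xm = NA_real_, xy = NA_real_, err = numeric(),
                qc = "abnormal_no_daughter_range")
    } else {
      p <- extract_parameters(panel_distribution(panel, orf), cfg,
                              cutoffs, orf = orf)
    }
    err <- stats::setNames(rep(NA_real_, length(cutoffs) + 4),
                           paste0("err_", c("x0", "xd", names(p$xb),
                                            "xm", "xy")))
    if (length(p$err) > 0) {
      err[paste0("err_", names(p$err))] <- p$err
    }
    tibble::as_tibble(c(
      list(orf = orf, role = panel$strains$role[i],
           x0 = p$x0, xd = p$xd),
      as.list(p$xb),
      list(xm = p$xm, xy = p$xy),
      as.list(err),
      list(qc = p$qc)
    ))
  })
  dplyr::bind_rows(rows)
}
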