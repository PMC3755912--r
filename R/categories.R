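xb_column <- function(cutoff) sprintf("xb_%g", 100 * cutoff)

qc_pass <- function(params) params[params$qc == "pass", ]

#' Wild-type birth-size reference
#'
#' Mean and sample standard deviation (n-1 denominator) of birth size over
#' the wild-type replicate strains, the anchor for the wild-type-SD
#' categorisation scheme.
#'
#' @param params Parameter tibble from [extract_panel_parameters()].
#' @param cutoff Daughter-interval cutoff whose `xb` column to use
#'   (default 0.20).
#' @return List of class `wt_reference`: `mu_wt`, `sd_wt`, `n_wt`,
#'   `cutoff_q`.
#' @export
wt_reference <- function(params, cutoff = 0.20) {
  col <- xb_column(cutoff)
  if (!col %in% names(params)) {
    stop("no column '", col, "' in parameter table", call. = FALSE)
  }
  wt <- qc_pass(params)
  wt <- wt[wt$role == "wild_type", ]
  if (nrow(wt) < 2) {
    stop("need >= 2 qc-pass wild-type strains to form a reference",
         call. = FALSE)
  }
  xb <- wt[[col]]
  sd_wt <- stats::sd(xb)
  if (sd_wt == 0) {
    warning("wild-type xb values are identical (sd = 0): every deviating ",
            "mutant becomes an outlier", call. = FALSE)
  }
  structure(list(mu_wt = mean(xb), sd_wt = sd_wt, n_wt = nrow(wt),
                 cutoff_q = cutoff),
            class = "wt_reference")
}

#' @export
print.wt_reference <- function(x, ...) {
  cat(sprintf("<wt_reference> mu %.4g fl, sd %.4g fl, n = %d (xb at %g%%)\n",
              x$mu_wt, x$sd_wt, x$n_wt, 100 * x$cutoff_q))
  invisible(x)
}

#' Categorise strains by deviation from the wild-type mean
#'
#' A strain is `small` if its birth size lies strictly more than two
#' standard deviations below the wild-type mean, `large` if strictly more
#' than two above, otherwise `normal`. Equality at a threshold is `normal`:
#' the rule is a strict inequality. The strain's channel-valued `xb` is
#' compared against the continuous thresholds.
#'
#' @param params Parameter tibble from [extract_panel_parameters()].
#' @param ref A [wt_reference()].
#' @param n_sd Number of standard deviations defining the outlier bands
#'   (default 2).
#' @return Tibble of assignments: `orf`, `scheme` (`"wt_sd"`), `cutoff_q`,
#'   `label`; one row per qc-pass strain.
#' @export
categorize_wt_sd <- function(params, ref, n_sd = 2) {
  stopifnot(inherits(ref, "wt_reference"))
  ok <- qc_pass(params)
  xb <- ok[[xb_column(ref$cutoff_q)]]
  lo <- ref$mu_wt - n_sd * ref$sd_wt
  hi <- ref$mu_wt + n_sd * ref$sd_wt
  tibble::tibble(
    orf = ok$orf,
    scheme = "wt_sd",
    cutoff_q = ref$cutoff_q,
    label = dplyr::case_when(xb < lo ~ "small",
                             xb > hi ~ "large",
                             TRUE ~ "normal")
  )
}

#' Categorise strains by empirical birth-size quantiles
#'
#' Strains in channels holding the smallest `tail` fraction of mutant birth
#' sizes are `small`, those in channels holding the largest `tail` fraction
#' are `large`, the rest `normal`. Because `xb` is channel-valued, the
#' boundary is a channel: every strain sharing the boundary channel of a
#' tail is included in that tail, so tails can slightly exceed the nominal
#' fraction. Boundaries use the order statistics directly (no
#' interpolation): with `n` strains in the pool and `k = floor(n * tail)`,
#' the lower boundary is the k-th smallest `xb` and the upper the k-th
#' largest.
#'
#' @param params Parameter tibble from [extract_panel_parameters()].
#' @param tail Tail fraction (default 0.05).
#' @param cutoff Daughter-interval cutoff whose `xb` column to use.
#' @param include_wildtype If `FALSE` (default) the quantile pool is mutants
#'   only; wild-type replicates are still labelled against the
#'   mutant-derived boundaries.
#' @return Tibble of assignments: `orf`, `scheme` (`"quantile"`),
#'   `cutoff_q`, `label`.
#' @export
categorize_quantile <- function(params, tail = 0.05, cutoff = 0.20,
                                include_wildtype = FALSE) {
  stopifnot(tail > 0, tail <= 0.5)
  ok <- qc_pass(params)
  col <- xb_column(cutoff)
  pool <- if (include_wildtype) ok else ok[ok$role == "mutant", ]
  n <- nrow(pool)
  if (n < ceiling(1 / tail)) {
    stop("need >= ", ceiling(1 / tail), " qc-pass strains in the quantile ",
         "pool for tail = ", tail, call. = FALSE)
  }
  k <- max(1L, floor(n * tail))
  srt <- sort(pool[[col]])
  lo_bound <- srt[k]
  hi_bound <- srt[n - k + 1]
  xb <- ok[[col]]
  label <- ifelse(xb <= lo_bound, "small",
                  ifelse(xb >= hi_bound, "large", "normal"))
  if (!any(label == "normal")) {
    warning("quantile tails cover every strain; `normal` is empty",
            call. = FALSE)
  }
  tibble::tibble(orf = ok$orf, scheme = "quantile", cutoff_q = cutoff,
                 label = label)
}

#' Assign categories under both schemes
#'
#' Convenience wrapper running [categorize_wt_sd()] and
#' [categorize_quantile()] on the same parameter table.
#'
#' @param params Parameter tibble from [extract_panel_parameters()].
#' @param cutoff Daughter-interval cutoff (default 0.20).
#' @param tail Quantile tail (default 0.05).
#' @param n_sd SD multiple for the wild-type scheme (default 2).
#' @return Long tibble of assignments for both schemes.
#' @export
assign_categories <- function(params, cutoff = 0.20, tail = 0.05, n_sd = 2) {
  ref <- wt_reference(params, cutoff)
  dplyr::bind_rows(
    categorize_wt_sd(params, ref, n_sd = n_sd),
    categorize_quantile(params, tail = tail, cutoff = cutoff)
  )
}

#' Cross-tabulate two categorisation schemes
#'
#' @param a,b Assignment tibbles (e.g. from [categorize_wt_sd()] and
#'   [categorize_quantile()]) over the same strain set.
#' @return 3x3 contingency matrix (rows: labels under `a`; columns: labels
#'   under `b`) in small/normal/large order.
#' @export
compare_schemes <- function(a, b) {
  if (!setequal(a$orf, b$orf) || nrow(a) != nrow(b)) {
    stop("the two assignments must cover the same strain set", call. = FALSE)
  }
  lv <- c("small", "normal", "large")
  m <- dplyr::inner_join(a[c("orf", "label")], b[c("orf", "label")],
                         by = "orf", suffix = c("_a", "_b"))
  table(factor(m$label_a, lv), factor(m$label_b, lv))
}
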