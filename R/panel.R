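#' A single strain's binned cell-size distribution
#'
#' Constructs a validated `size_distribution`: an ordered grid of channel
#' sizes (femtoliters) with one non-negative count per channel. Channel grids
#' from Coulter-type instruments are non-uniform, so no downstream code may
#' assume equal bin widths; each `bin_fl` value is the representative size of
#' its channel and the interval to the next channel is the resolution (and
#' hence the error bound) at that size.
#'
#' @param bin_fl Numeric vector of channel sizes in fl, strictly increasing,
#'   length >= 3.
#' @param counts Numeric vector of non-negative counts, same length as
#'   `bin_fl`, with positive total. Counts need not be integers: channelyzer
#'   exports are sometimes rescaled, and all downstream computation uses
#'   frequencies.
#' @return An object of class `size_distribution` with fields `bin_fl` and
#'   `counts`.
#' @examples
#' d <- size_distribution(c(20, 21, 22), c(1, 2, 1))
#' sum(frequencies(d))
#' @export
size_distribution <- function(bin_fl, counts) {
  bin_fl <- as.numeric(bin_fl)
  counts <- as.numeric(counts)
  if (length(bin_fl) != length(counts)) {
    stop("`bin_fl` and `counts` must have the same length", call. = FALSE)
  }
  if (length(bin_fl) < 3) {
    stop("a size distribution needs at least 3 channels", call. = FALSE)
  }
  if (anyNA(bin_fl) || anyNA(counts)) {
    stop("`bin_fl` and `counts` must not contain missing values", call. = FALSE)
  }
  if (any(diff(bin_fl) <= 0)) {
    stop("`bin_fl` must be strictly increasing", call. = FALSE)
  }
  if (any(counts < 0)) {
    stop("`counts` must be non-negative", call. = FALSE)
  }
  if (sum(counts) <= 0) {
    stop("total count must be positive", call. = FALSE)
  }
  structure(list(bin_fl = bin_fl, counts = counts),
            class = "size_distribution")
}

#' @export
print.size_distribution <- function(x, ...) {
  cat(sprintf("<size_distribution> %d channels, %.6g-%.6g fl, total count %.6g\n",
              length(x$bin_fl), x$bin_fl[1], x$bin_fl[length(x$bin_fl)],
              sum(x$counts)))
  invisible(x)
}

#' Channel frequencies of a size distribution
#'
#' Counts normalised to sum to 1 over the full channel range. This is the
#' empirical frequency function f(x) used throughout the parameter
#' extraction.
#'
#' @param dist A [size_distribution()].
#' @return Numeric vector summing to 1.
#' @export
frequencies <- function(dist) {
  stopifnot(inherits(dist, "size_distribution"))
  dist$counts / sum(dist$counts)
}

#' A panel of strains sharing one channel grid
#'
#' The central container of the package: one shared channel grid, a
#' channels-by-strains count matrix, per-strain metadata (identifier, role,
#' flags) and, once joined, per-strain phenotypes. Columns of `counts` are
#' named by ORF and aligned with rows of `strains`.
#'
#' @param bin_fl Shared channel grid (strictly increasing, fl).
#' @param counts Numeric matrix, `length(bin_fl)` rows, one column per strain,
#'   column names are ORFs.
#' @param strains Tibble with at least `orf` (unique, non-empty) and `role`
#'   (`"mutant"` or `"wild_type"`). An `all_zero` flag column is added if
#'   absent.
#' @param phenotypes Optional tibble of per-strain phenotypes (see
#'   [read_phenotype_table()]), or `NULL` before joining.
#' @return An object of class `strain_panel`.
#' @seealso [read_distribution_matrix()], [join_panel()], [panel_distribution()]
#' @export
strain_panel <- function(bin_fl, counts, strains, phenotypes = NULL) {
  bin_fl <- as.numeric(bin_fl)
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  strains <- tibble::as_tibble(strains)
  if (any(diff(bin_fl) <= 0)) {
    stop("panel channel grid must be strictly increasing", call. = FALSE)
  }
  if (nrow(counts) != length(bin_fl)) {
    stop("`counts` must have one row per channel", call. = FALSE)
  }
  if (!all(c("orf", "role") %in% names(strains))) {
    stop("`strains` must have columns `orf` and `role`", call. = FALSE)
  }
  if (ncol(counts) != nrow(strains)) {
    stop("`counts` must have one column per strain", call. = FALSE)
  }
  if (any(!nzchar(strains$orf)) || anyNA(strains$orf)) {
    stop("strain identifiers must be non-empty", call. = FALSE)
  }
  if (anyDuplicated(strains$orf)) {
    stop("duplicate strain identifier: ",
         paste(unique(strains$orf[duplicated(strains$orf)]), collapse = ", "),
         call. = FALSE)
  }
  if (!all(strains$role %in% c("mutant", "wild_type"))) {
    stop("`role` must be 'mutant' or 'wild_type'", call. = FALSE)
  }
  colnames(counts) <- strains$orf
  if (!"all_zero" %in% names(strains)) {
    strains$all_zero <- unname(colSums(counts) <= 0)
  }
  structure(list(bin_fl = bin_fl, counts = counts, strains = strains,
                 phenotypes = phenotypes),
            class = "strain_panel")
}

#' @export
print.strain_panel <- function(x, ...) {
  cat(sprintf(
    "<strain_panel> %d strains (%d wild-type), %d channels %.6g-%.6g fl%s\n",
    nrow(x$strains), sum(x$strains$role == "wild_type"),
    length(x$bin_fl), x$bin_fl[1], x$bin_fl[length(x$bin_fl)],
    if (is.null(x$phenotypes)) "" else ", phenotypes joined"))
  invisible(x)
}

#' Number of strains in a panel
#' @param panel A [strain_panel()].
#' @return Integer count.
#' @export
n_strains <- function(panel) {
  stopifnot(inherits(panel, "strain_panel"))
  nrow(panel$strains)
}

#' Extract one strain's distribution from a panel
#'
#' @param panel A [strain_panel()].
#' @param orf Strain identifier.
#' @return A [size_distribution()].
#' @export
panel_distribution <- function(panel, orf) {
  stopifnot(inherits(panel, "strain_panel"))
  if (!orf %in% panel$strains$orf) {
    stop("unknown strain: ", orf, call. = FALSE)
  }
  size_distribution(panel$bin_fl, panel$counts[, orf])
}
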