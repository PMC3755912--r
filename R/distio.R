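#' Read a binned size-distribution matrix
#'
#' Reads the canonical on-disk layout for asynchronous cell-size
#' distributions: channels in rows, a numeric `bin_fl` first column holding
#' channel sizes in femtoliters, and one count column per strain named by
#' ORF. TSV, CSV and XLSX (single sheet, same layout, as in a supplementary
#' "asynchronous" sheet) are recognised by file extension. A transposed
#' layout (strains in rows) is accepted via `layout = "bins_in_columns"`.
#'
#' All-zero strain columns are retained but flagged (`all_zero` in the
#' strain table) so they can be audited rather than silently lost.
#'
#' @param source Path to a `.tsv`, `.csv` or `.xlsx` file.
#' @param layout `"bins_in_rows"` (default, canonical) or
#'   `"bins_in_columns"`.
#' @param wildtype_ids Character vector of strain identifiers to mark as
#'   wild-type replicates. Which columns are wild type is configuration, not
#'   something the file format records.
#' @param sheet Sheet name or index for XLSX sources (default first sheet).
#' @param bin_column Name of the channel-size column (default `"bin_fl"`;
#'   for `bins_in_columns` layouts, the name of the identifier column).
#' @return A [strain_panel()] with roles assigned from `wildtype_ids`.
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' writeLines(c("bin_fl\tYAL001C", "20\t1", "21\t2", "22\t1"), f)
#' p <- read_distribution_matrix(f)
#' sum(panel_distribution(p, "YAL001C")$counts)
#' @export
read_distribution_matrix <- function(source,
                                     layout = c("bins_in_rows",
                                                "bins_in_columns"),
                                     wildtype_ids = character(),
                                     sheet = NULL,
                                     bin_column = "bin_fl") {
  layout <- match.arg(layout)
  raw <- read_table_any(source, sheet = sheet)
  if (!bin_column %in% names(raw)) {
    stop("column '", bin_column, "' not found in ", source, call. = FALSE)
  }
  if (layout == "bins_in_columns") {
    ids <- as.character(raw[[bin_column]])
    bins <- suppressWarnings(as.numeric(sub(paste0("^", bin_column, "_?"), "",
                                            setdiff(names(raw), bin_column))))
    if (anyNA(bins)) {
      stop("bins_in_columns layout requires numeric channel-size column names",
           call. = FALSE)
    }
    mat <- t(as.matrix(raw[setdiff(names(raw), bin_column)]))
    colnames(mat) <- ids
    raw <- tibble::as_tibble(as.data.frame(mat))
    raw[[bin_column]] <- bins
    raw <- raw[c(bin_column, ids)]
  }
  bins <- raw[[bin_column]]
  if (!is.numeric(bins) || anyNA(bins)) {
    stop("channel sizes must be numeric and complete", call. = FALSE)
  }
  if (any(diff(bins) <= 0)) {
    stop("channel grid is not strictly increasing (non-monotone bin sizes)",
         call. = FALSE)
  }
  strain_cols <- names(raw)[names(raw) != bin_column]
  if (length(strain_cols) == 0) {
    stop("no strain columns found", call. = FALSE)
  }
  if (anyDuplicated(strain_cols)) {
    stop("duplicate strain identifier: ",
         paste(unique(strain_cols[duplicated(strain_cols)]), collapse = ", "),
         call. = FALSE)
  }
  mat <- matrix(NA_real_, nrow = length(bins), ncol = length(strain_cols),
                dimnames = list(NULL, strain_cols))
  for (s in strain_cols) {
    v <- raw[[s]]
    if (is.character(v)) {
      conv <- suppressWarnings(as.numeric(v))
      if (anyNA(conv) & !anyNA(v)) {
        stop("non-numeric count cell in strain column '", s, "'",
             call. = FALSE)
      }
      v <- conv
    }
    if (!is.numeric(v) || anyNA(v)) {
      stop("non-numeric or missing count cell in strain column '", s, "'",
           call. = FALSE)
    }
    if (any(v < 0)) {
      stop("negative count in strain column '", s, "'", call. = FALSE)
    }
    mat[, s] <- v
  }
  strains <- tibble::tibble(
    orf = strain_cols,
    role = ifelse(strain_cols %in% wildtype_ids, "wild_type", "mutant"),
    all_zero = unname(colSums(mat) <= 0)
  )
  if (any(strains$all_zero)) {
    warning("all-zero strain column(s) flagged: ",
            paste(strains$orf[strains$all_zero], collapse = ", "),
            call. = FALSE)
  }
  strain_panel(bins, mat, strains)
}

#' Write a panel's distribution matrix
#'
#' Writes the canonical channels-in-rows layout. TSV/CSV round trips are
#' value-exact (shortest round-trippable decimal representation).
#'
#' @param panel A [strain_panel()].
#' @param path Output path ending in `.tsv` or `.csv`.
#' @return `path`, invisibly.
#' @export
write_distribution_matrix <- function(panel, path) {
  stopifnot(inherits(panel, "strain_panel"))
  sep <- if (tolower(tools::file_ext(path)) == "csv") "," else "\t"
  # %.17g guarantees a decimal representation that parses back to the same
  # double, so round trips are value-exact
  fmt <- function(x) formatC(x, digits = 17, format = "g")
  body <- cbind(fmt(panel$bin_fl),
                matrix(fmt(panel$counts), nrow = length(panel$bin_fl)))
  lines <- c(paste(c("bin_fl", colnames(panel$counts)), collapse = sep),
             apply(body, 1, paste, collapse = sep))
  writeLines(lines, path)
  invisible(path)
}

read_table_any <- function(source, sheet = NULL) {
  ext <- tolower(tools::file_ext(source))
  if (ext %in% c("xlsx", "xls")) {
    readxl::read_excel(source, sheet = if (is.null(sheet)) 1 else sheet,
                       .name_repair = "minimal")
  } else if (ext == "csv") {
    # base parser: correctly-rounded doubles, so round trips are exact
    tibble::as_tibble(utils::read.csv(source, check.names = FALSE),
                      .name_repair = "minimal")
  } else {
    tibble::as_tibble(utils::read.delim(source, check.names = FALSE),
                      .name_repair = "minimal")
  }
}

#' Read a per-strain phenotype table
#'
#' Reads a delimited table of published phenotypes: mean cell size (fl),
#' competitive fitness rank (1 = most fit ... 21 = least fit) and percent-G1
#' DNA content. Missing values are permitted everywhere except the strain
#' identifier; rows with out-of-range fitness or %G1 are rejected with
#' row-level diagnostics (returned in the `rejected` attribute) rather than
#' silently kept or dropped without trace.
#'
#' @param source Path to a TSV/CSV/XLSX file with a header row.
#' @param column_map Named character vector mapping the canonical names
#'   `orf`, `mean_size`, `fitness_rank`, `pct_g1` to the file's column
#'   names. Unmapped optional phenotypes are filled with `NA`; an
#'   unresolvable mapped column is an error.
#' @param sheet Sheet for XLSX sources.
#' @return Tibble with columns `orf`, `mean_size`, `fitness_rank`, `pct_g1`;
#'   attribute `rejected` holds the diagnostics tibble (row, orf, reason).
#' @export
read_phenotype_table <- function(source,
                                 column_map = c(orf = "orf",
                                                mean_size = "mean_size",
                                                fitness_rank = "fitness_rank",
                                                pct_g1 = "pct_g1"),
                                 sheet = NULL) {
  raw <- read_table_any(source, sheet = sheet)
  if (!"orf" %in% names(column_map)) {
    stop("`column_map` must map 'orf'", call. = FALSE)
  }
  missing_cols <- setdiff(unname(column_map), names(raw))
  if (length(missing_cols) > 0) {
    stop("column(s) not found in ", source, ": ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  pull_num <- function(canon) {
    if (canon %in% names(column_map)) {
      suppressWarnings(as.numeric(raw[[column_map[[canon]]]]))
    } else {
      rep(NA_real_, nrow(raw))
    }
  }
  out <- tibble::tibble(
    orf = as.character(raw[[column_map[["orf"]]]]),
    mean_size = pull_num("mean_size"),
    fitness_rank = pull_num("fitness_rank"),
    pct_g1 = pull_num("pct_g1")
  )
  bad_fit <- !is.na(out$fitness_rank) &
    (out$fitness_rank < 1 | out$fitness_rank > 21 |
       out$fitness_rank != round(out$fitness_rank))
  bad_g1 <- !is.na(out$pct_g1) & (out$pct_g1 < 0 | out$pct_g1 > 100)
  bad_orf <- is.na(out$orf) | !nzchar(out$orf)
  bad <- bad_fit | bad_g1 | bad_orf
  rejected <- tibble::tibble(
    row = which(bad),
    orf = out$orf[bad],
    reason = dplyr::case_when(
      bad_orf[bad] ~ "missing strain identifier",
      bad_fit[bad] ~ "fitness rank outside 1..21",
      TRUE ~ "%G1 outside 0..100"
    )
  )
  if (nrow(rejected) > 0) {
    warning(nrow(rejected), " phenotype row(s) rejected; see attr 'rejected'",
            call. = FALSE)
  }
  out <- out[!bad, ]
  attr(out, "rejected") <- rejected
  out
}

#' Join phenotypes onto a strain panel
#'
#' Left join on ORF: every strain in the panel is kept; phenotypes without a
#' matching strain are reported, not errors. Match/miss counts are attached
#' as the `join_report` attribute of the returned panel.
#'
#' @param panel A [strain_panel()].
#' @param phenotypes Tibble from [read_phenotype_table()] (or any tibble with
#'   `orf`, `mean_size`, `fitness_rank`, `pct_g1`). Duplicate ORFs are a hard
#'   error: the join key must be unique.
#' @return The panel with `$phenotypes` filled (one row per strain, `NA`
#'   where no phenotype matched).
#' @export
join_panel <- function(panel, phenotypes) {
  stopifnot(inherits(panel, "strain_panel"))
  phenotypes <- tibble::as_tibble(phenotypes)
  needed <- c("orf", "mean_size", "fitness_rank", "pct_g1")
  for (col in setdiff(needed, names(phenotypes))) {
    phenotypes[[col]] <- NA_real_
  }
  if (anyDuplicated(phenotypes$orf)) {
    stop("duplicate orf in phenotype table: ",
         paste(unique(phenotypes$orf[duplicated(phenotypes$orf)]),
               collapse = ", "), call. = FALSE)
  }
  joined <- dplyr::left_join(panel$strains["orf"], phenotypes[needed],
                             by = "orf")
  panel$phenotypes <- joined
  attr(panel, "join_report") <- list(
    n_strains = nrow(panel$strains),
    n_matched = sum(joined$orf %in% phenotypes$orf),
    n_unmatched_phenotypes = sum(!phenotypes$orf %in% panel$strains$orf),
    unmatched_phenotypes = setdiff(phenotypes$orf, panel$strains$orf)
  )
  panel
}

#' Summarise a panel's channel grid
#'
#' Data-integrity readback of the shared channel grid: number of channels
#' and the smallest and largest successive-channel interval. Used to check
#' ingested data against an instrument's documented channel-width range.
#'
#' @param panel A [strain_panel()] (or a bare numeric grid).
#' @return Tibble with `n_bins`, `min_interval_fl`, `max_interval_fl`,
#'   `range_lo_fl`, `range_hi_fl`.
#' @export
validate_bin_grid <- function(panel) {
  bins <- if (inherits(panel, "strain_panel")) panel$bin_fl else as.numeric(panel)
  if (any(diff(bins) <= 0)) {
    stop("channel grid is not strictly increasing", call. = FALSE)
  }
  iv <- diff(bins)
  tibble::tibble(
    n_bins = length(bins),
    min_interval_fl = min(iv),
    max_interval_fl = max(iv),
    range_lo_fl = bins[1],
    range_hi_fl = bins[length(bins)]
  )
}
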