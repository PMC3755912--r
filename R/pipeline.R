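#' Run the full birth-size analysis pipeline
#'
#' Orchestrates ingest (or simulate) -> parameter extraction ->
#' categorisation -> association, writing every stage's table plus a run
#' manifest to `out_dir`. The configuration is a named list (or a YAML file
#' holding one) with exactly one of `input` (paths to on-disk data) or
#' `simulate` (arguments for [synthetic_panel_spec()]):
#'
#' * `input`: `distributions` (TSV/CSV/XLSX), optional `phenotypes`,
#'   optional `wildtype_ids` (vector, or path to a one-ID-per-line file).
#' * `simulate`: fields of [synthetic_panel_spec()]; optional `n_small`,
#'   `n_large`, `small_effect`, `large_effect` for planted outliers, and a
#'   `link` sublist passed to [phenotype_link()].
#' * `support`: fields of [support_config()] (optional `exclusion_list`
#'   vector or path).
#' * `cutoffs` (default `c(0.10, 0.15, 0.20, 0.25)`), `cutoff` (the one
#'   used for categories/associations, default 0.20), `tail` (default
#'   0.05), `n_sd` (default 2).
#' * `out_dir`, `seed`.
#'
#' Every source of randomness derives from `seed`. A stage failure writes a
#' `FAILED` marker naming the stage and rethrows; completed stages' outputs
#' are retained.
#'
#' @param config Named list or path to a YAML file.
#' @return The run manifest (list), invisibly written to
#'   `manifest.json`-style YAML in `out_dir`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  has_input <- !is.null(config$input)
  has_sim <- !is.null(config$simulate)
  if (has_input == has_sim) {
    stop("config must contain exactly one of `input` or `simulate`",
         call. = FALSE)
  }
  out_dir <- config$out_dir %||% stop("config needs `out_dir`", call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$seed %||% 1)
  cutoffs <- config$cutoffs %||% c(0.10, 0.15, 0.20, 0.25)
  cutoff <- config$cutoff %||% 0.20
  tail <- config$tail %||% 0.05
  n_sd <- config$n_sd %||% 2
  failed <- function(stage, err) {
    writeLines(paste("FAILED at stage:", stage, "-", conditionMessage(err)),
               file.path(out_dir, "FAILED"))
    stop("[", stage, "] ", conditionMessage(err), call. = FALSE)
  }
  unlink(file.path(out_dir, "FAILED"))

  # --- ingest / simulate -----------------------------------------------
  truth <- NULL
  phenotypes <- NULL
  panel <- tryCatch({
    if (has_sim) {
      sim <- config$simulate
      link <- sim$link %||% list()
      sim$link <- NULL
      planted <- NULL
      if (!is.null(sim$n_small) || !is.null(sim$n_large)) {
        planted <- planted_outliers(
          n_small = sim$n_small %||% 0, n_large = sim$n_large %||% 0,
          small_effect = sim$small_effect %||% 0.75,
          large_effect = sim$large_effect %||% 1.3)
        sim[c("n_small", "n_large", "small_effect", "large_effect")] <- NULL
      }
      spec <- do.call(synthetic_panel_spec,
                      c(sim, list(planted = planted, seed = seed)))
      gen <- generate_panel(spec)
      truth <- gen$truth
      phenotypes <- do.call(
        phenotype_link,
        c(list(truth = gen$truth, seed = seed + 1L,
               wt_birth_mean = spec$wt_birth_mean), link))
      write_distribution_matrix(gen$panel,
                                file.path(out_dir, "distributions.tsv"))
      readr::write_tsv(gen$truth, file.path(out_dir, "truth.tsv"))
      readr::write_tsv(phenotypes, file.path(out_dir, "phenotypes.tsv"))
      join_panel(gen$panel, phenotypes)
    } else {
      inp <- config$input
      wt <- inp$wildtype_ids %||% character()
      if (length(wt) == 1 && file.exists(wt)) wt <- readLines(wt)
      p <- read_distribution_matrix(inp$distributions,
                                    wildtype_ids = wt,
                                    sheet = inp$sheet)
      if (!is.null(inp$phenotypes)) {
        phenotypes <- read_phenotype_table(inp$phenotypes)
        p <- join_panel(p, phenotypes)
      }
      p
    }
  }, error = function(e) failed("ingest", e))
  if (is.null(phenotypes)) phenotypes <- panel$phenotypes

  # --- parameters -------------------------------------------------------
  params <- tryCatch({
    sup <- config$support %||% list()
    excl <- sup$exclusion_list %||% character()
    if (length(excl) == 1 && file.exists(excl)) excl <- readLines(excl)
    cfg <- support_config(
      alpha = sup$alpha %||% 0.01, k = sup$k %||% 3,
      smoothing_window = sup$smoothing_window %||% 1,
      exclusion_list = excl)
    pt <- extract_panel_parameters(panel, cfg, cutoffs)
    readr::write_tsv(pt, file.path(out_dir, "params.tsv"))
    pt
  }, error = function(e) failed("params", e))

  # --- categories -------------------------------------------------------
  categories <- tryCatch({
    ct <- assign_categories(params, cutoff = cutoff, tail = tail,
                            n_sd = n_sd)
    readr::write_tsv(ct, file.path(out_dir, "categories.tsv"))
    ct
  }, error = function(e) failed("categories", e))

  # --- associations -----------------------------------------------------
  assoc <- tryCatch({
    if (is.null(phenotypes)) {
      NULL
    } else {
      combos <- expand.grid(ph = c("mean_size", "fitness", "pct_g1"),
                            sc = c("wt_sd", "quantile"),
                            stringsAsFactors = FALSE)
      at <- dplyr::bind_rows(lapply(seq_len(nrow(combos)), function(i) {
        per_category_association(params, categories, phenotypes,
                                 phenotype = combos$ph[i], cutoff = cutoff,
                                 scheme = combos$sc[i])
      }))
      readr::write_tsv(at, file.path(out_dir, "associations.tsv"))
      gc_all <- lapply(seq_len(nrow(combos)), function(i) {
        group_mean_comparison(params, categories, phenotypes,
                              phenotype = combos$ph[i], cutoff = cutoff,
                              scheme = combos$sc[i])
      })
      readr::write_tsv(dplyr::bind_rows(lapply(gc_all, `[[`, "comparisons")),
                       file.path(out_dir, "group_comparisons.tsv"))
      readr::write_tsv(dplyr::bind_rows(lapply(gc_all, `[[`, "groups")),
                       file.path(out_dir, "group_summaries.tsv"))
      at
    }
  }, error = function(e) failed("association", e))

  manifest <- list(
    seed = seed,
    config_hash = rlang::hash(config[setdiff(names(config), "out_dir")]),
    n_ingested = n_strains(panel),
    n_qc_pass = sum(params$qc == "pass"),
    n_abnormal = sum(params$qc == "abnormal_no_daughter_range"),
    n_manual_excluded = sum(params$qc == "manual_excluded"),
    n_wildtype = sum(panel$strains$role == "wild_type"),
    cutoffs = cutoffs, cutoff = cutoff, tail = tail, n_sd = n_sd,
    outputs = setdiff(sort(list.files(out_dir)),
                      c("manifest.yaml", "FAILED")),
    manifest_hash = NA_character_
  )
  manifest$manifest_hash <- rlang::hash(manifest[names(manifest) !=
                                                   "manifest_hash"])
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
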