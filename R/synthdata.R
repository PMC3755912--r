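#' Channelyzer-style channel grid
#'
#' Builds a deterministic non-uniform channel grid whose successive
#' intervals grow linearly from `width_lo` to `width_hi` across the
#' instrument window. Coulter-type volume channels widen with size, and the
#' default extremes are the documented channel-width range of the
#' instrument the analysis targets, so a grid-integrity readback recovers
#' them exactly.
#'
#' @param grid_min Smallest channel size in fl (default 8).
#' @param grid_max Approximate largest channel size in fl (default 110; the
#'   realised top channel is the closest achievable with the width ramp).
#' @param width_lo,width_hi Smallest and largest channel interval in fl
#'   (defaults 0.385662112 and 1.203735813).
#' @return Strictly increasing numeric grid of channel sizes.
#' @export
channel_grid <- function(grid_min = 8, grid_max = 110,
                         width_lo = 0.385662112, width_hi = 1.203735813) {
  stopifnot(grid_max > grid_min, width_hi >= width_lo, width_lo > 0)
  n_iv <- max(3L, round((grid_max - grid_min) / ((width_lo + width_hi) / 2)))
  widths <- seq(width_lo, width_hi, length.out = n_iv)
  grid_min + cumsum(c(0, widths))
}

#' Specification of a synthetic strain panel
#'
#' Describes the generative model behind a synthetic deletion-collection
#' size screen. Each strain's asynchronous size distribution is a
#' two-component lognormal-type mixture: newborn daughters born at
#' (strain-specific) size `B` growing multiplicatively toward budding, and
#' larger post-budding mothers; at least half of all cells are daughters
#' and they occupy the left-of-mode region, which is exactly the structure
#' the extraction heuristic assumes. Planted mutants perturb `B`
#' multiplicatively and can carry linked %G1 and fitness effects.
#'
#' @param n_mutants Number of mutant strains (default 500).
#' @param n_wildtype Number of wild-type replicate columns (default 10).
#' @param wt_birth_mean Median true birth size of wild type, fl
#'   (default 23.7).
#' @param wt_birth_cv Within-strain coefficient of variation of birth size
#'   (default 0.12).
#' @param between_strain_cv Strain-to-strain CV of true birth size among
#'   unplanted mutants (default 0.06): deletion strains vary continuously
#'   in size, and rank-based recovery is only meaningful against a
#'   continuous ground truth.
#' @param replicate_cv Culture-to-culture CV applied to every strain's
#'   realised birth size (default 0.04): each panel column is one culture
#'   measurement, and wild-type replicate cultures scatter far more than
#'   counting noise alone (a birth-size reference of 23.7 fl with SD close
#'   to 1 fl implies roughly 4% replicate variation).
#' @param mother_daughter_ratio Median mother / median birth size
#'   (default 1.6).
#' @param mother_cv Within-strain CV of mother size (default 0.10). Mothers
#'   are kept tighter than the daughter spread so the mixture's mode sits
#'   at the daughter/mother boundary — the left-of-mode region then holds
#'   the daughters plus the mothers' lower tail, the structure the
#'   partition heuristic assumes.
#' @param daughter_fraction Mixture weight of the daughter component, in
#'   `[0.5, 1)` (default 0.55).
#' @param budding_ratio Budding size / birth size, the multiplicative
#'   growth spanned during G1 (default 35/23.7).
#' @param cells_per_strain Cells sampled per strain (default 20000).
#' @param grid Channel grid (default [channel_grid()]).
#' @param noise_rate Expected spurious low-channel debris counts per strain
#'   (default 30), placed Poisson-wise below the daughter component's 0.1
#'   percentile.
#' @param planted Optional tibble with columns `orf`, `birth_effect`
#'   (multiplier on `B`), `g1_shift` (percentage points), `fitness_shift`
#'   (ranks); see [planted_outliers()].
#' @param seed Integer seed driving every random draw.
#' @return List of class `synthetic_panel_spec`.
#' @export
synthetic_panel_spec <- function(n_mutants = 500, n_wildtype = 10,
                                 wt_birth_mean = 23.7, wt_birth_cv = 0.12,
                                 between_strain_cv = 0.06,
                                 replicate_cv = 0.04,
                                 mother_daughter_ratio = 1.6,
                                 mother_cv = 0.10,
                                 daughter_fraction = 0.55,
                                 budding_ratio = 35 / 23.7,
                                 cells_per_strain = 20000,
                                 grid = channel_grid(),
                                 noise_rate = 30,
                                 planted = NULL,
                                 seed = 1) {
  stopifnot(n_mutants >= 1, n_wildtype >= 0, wt_birth_mean > 0,
            wt_birth_cv > 0, between_strain_cv >= 0, replicate_cv >= 0,
            mother_daughter_ratio > 1,
            daughter_fraction >= 0.5, daughter_fraction < 1,
            budding_ratio > 1, cells_per_strain >= 1, noise_rate >= 0)
  if (any(diff(grid) <= 0)) stop("grid must be strictly increasing",
                                 call. = FALSE)
  if (!is.null(planted)) {
    planted <- tibble::as_tibble(planted)
    stopifnot(all(c("orf", "birth_effect") %in% names(planted)))
    if (!"g1_shift" %in% names(planted)) planted$g1_shift <- 0
    if (!"fitness_shift" %in% names(planted)) planted$fitness_shift <- 0L
  }
  sd_birth <- wt_birth_mean * 2 * wt_birth_cv
  n_res <- sum(grid >= wt_birth_mean - sd_birth &
                 grid <= wt_birth_mean + sd_birth)
  if (n_res < 10) {
    stop("grid too coarse to resolve wt_birth_cv: only ", n_res,
         " channels across +/- 2 SD of wild-type birth size", call. = FALSE)
  }
  structure(list(n_mutants = as.integer(n_mutants),
                 n_wildtype = as.integer(n_wildtype),
                 wt_birth_mean = wt_birth_mean, wt_birth_cv = wt_birth_cv,
                 between_strain_cv = between_strain_cv,
                 replicate_cv = replicate_cv,
                 mother_daughter_ratio = mother_daughter_ratio,
                 mother_cv = mother_cv,
                 daughter_fraction = daughter_fraction,
                 budding_ratio = budding_ratio,
                 cells_per_strain = as.integer(cells_per_strain),
                 grid = grid, noise_rate = noise_rate,
                 planted = planted, seed = as.integer(seed)),
            class = "synthetic_panel_spec")
}

#' Planted birth-size outliers for a synthetic panel
#'
#' Convenience constructor for the `planted` slot of
#' [synthetic_panel_spec()]: the first `n_small` mutant ORFs get a
#' small-birth multiplier and the next `n_large` a large-birth multiplier,
#' with optional linked %G1 and fitness shifts.
#'
#' @param n_small,n_large Numbers of planted small and large mutants.
#' @param small_effect,large_effect Multipliers on true birth size
#'   (defaults 0.75 and 1.3).
#' @param g1_shift_small %G1 shift (percentage points) for planted smalls
#'   (default 0; the birth-size-linked slope in [phenotype_link()] is the
#'   usual mechanism).
#' @param fitness_shift Extra fitness ranks for all planted outliers
#'   (default 0).
#' @return Tibble suitable for `synthetic_panel_spec(planted = ...)`.
#' @export
planted_outliers <- function(n_small, n_large, small_effect = 0.75,
                             large_effect = 1.3, g1_shift_small = 0,
                             fitness_shift = 0L) {
  tibble::tibble(
    orf = sprintf("MUT%04d", seq_len(n_small + n_large)),
    birth_effect = rep(c(small_effect, large_effect), c(n_small, n_large)),
    g1_shift = rep(c(g1_shift_small, 0), c(n_small, n_large)),
    fitness_shift = rep(as.integer(fitness_shift), n_small + n_large)
  )
}

# Per-strain mixture parameters on the log-size scale. The whole mixture
# scales multiplicatively with the true birth size B.
strain_mixture <- function(spec, B) {
  list(
    meanlog_birth = log(B),
    sdlog_birth = sqrt(log(1 + spec$wt_birth_cv^2)),
    log_growth = log(spec$budding_ratio),
    meanlog_mother = log(spec$mother_daughter_ratio * B),
    sdlog_mother = sqrt(log(1 + spec$mother_cv^2)),
    weight_daughter = spec$daughter_fraction
  )
}

sample_strain_sizes <- function(mix, n) {
  is_d <- stats::runif(n) < mix$weight_daughter
  nd <- sum(is_d)
  sizes <- numeric(n)
  # daughters: born lognormal, grown by a log-uniform factor toward budding
  sizes[is_d] <- exp(stats::rnorm(nd, mix$meanlog_birth, mix$sdlog_birth) +
                       stats::runif(nd) * mix$log_growth)
  sizes[!is_d] <- stats::rlnorm(n - nd, mix$meanlog_mother,
                                mix$sdlog_mother)
  sizes
}

bin_sizes_onto_grid <- function(sizes, grid) {
  # channel boundaries are midpoints between representative channel sizes;
  # observations outside the instrument window are discarded
  bounds <- c(grid[1] - (grid[2] - grid[1]) / 2,
              (grid[-length(grid)] + grid[-1]) / 2,
              grid[length(grid)] + (grid[length(grid)] -
                                      grid[length(grid) - 1]) / 2)
  idx <- findInterval(sizes, bounds, rightmost.closed = TRUE)
  as.numeric(tabulate(idx[idx >= 1 & idx <= length(grid)],
                      nbins = length(grid)))
}

#' Generate a synthetic strain panel with ground truth
#'
#' Draws per-strain true birth sizes (wild types at the specified median;
#' unplanted mutants with between-strain variation; planted mutants with
#' their multipliers), samples each strain's daughter/mother size mixture,
#' bins it onto the shared channel grid, and sprinkles Poisson debris
#' counts into the channels below the daughter component. All randomness
#' flows from `spec$seed`, so identical specs give bit-identical panels.
#'
#' @param spec A [synthetic_panel_spec()].
#' @return List with `panel` (a [strain_panel()]) and `truth` (tibble:
#'   `orf`, `role`, `true_birth_fl`, `birth_effect`, `g1_shift`,
#'   `fitness_shift`, `true_label`, `true_mean_fl`, and the per-strain
#'   mixture parameters `meanlog_birth`, `sdlog_birth`, `log_growth`,
#'   `meanlog_mother`, `sdlog_mother`, `weight_daughter`).
#' @export
generate_panel <- function(spec) {
  stopifnot(inherits(spec, "synthetic_panel_spec"))
  set.seed(spec$seed)
  orfs_m <- sprintf("MUT%04d", seq_len(spec$n_mutants))
  orfs_w <- if (spec$n_wildtype > 0) {
    sprintf("WT%02d", seq_len(spec$n_wildtype))
  } else {
    character()
  }
  sd_between <- sqrt(log(1 + spec$between_strain_cv^2))
  sd_rep <- sqrt(log(1 + spec$replicate_cv^2))
  B_m <- spec$wt_birth_mean * exp(stats::rnorm(spec$n_mutants, 0, sd_between))
  effect <- stats::setNames(rep(1, spec$n_mutants), orfs_m)
  g1_shift <- stats::setNames(rep(0, spec$n_mutants), orfs_m)
  fit_shift <- stats::setNames(rep(0L, spec$n_mutants), orfs_m)
  if (!is.null(spec$planted)) {
    unknown <- setdiff(spec$planted$orf, orfs_m)
    if (length(unknown) > 0) {
      stop("planted orf(s) not in panel: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    effect[spec$planted$orf] <- spec$planted$birth_effect
    g1_shift[spec$planted$orf] <- spec$planted$g1_shift
    fit_shift[spec$planted$orf] <- as.integer(spec$planted$fitness_shift)
  }
  B_m <- B_m * effect
  orfs <- c(orfs_w, orfs_m)
  role <- rep(c("wild_type", "mutant"), c(length(orfs_w), length(orfs_m)))
  B <- c(rep(spec$wt_birth_mean, length(orfs_w)), B_m)
  # every column is one culture: culture-to-culture replicate variation
  B <- B * exp(stats::rnorm(length(B), 0, sd_rep))

  grid <- spec$grid
  counts <- matrix(0, nrow = length(grid), ncol = length(orfs),
                   dimnames = list(NULL, orfs))
  mixes <- vector("list", length(orfs))
  noise_top <- exp(log(B) + stats::qnorm(0.001) *
                     sqrt(log(1 + spec$wt_birth_cv^2)))
  for (i in seq_along(orfs)) {
    mix <- strain_mixture(spec, B[i])
    mixes[[i]] <- mix
    sizes <- sample_strain_sizes(mix, spec$cells_per_strain)
    counts[, i] <- bin_sizes_onto_grid(sizes, grid)
    noise_ch <- which(grid < noise_top[i])
    if (length(noise_ch) > 0 && spec$noise_rate > 0) {
      counts[noise_ch, i] <- counts[noise_ch, i] +
        stats::rpois(length(noise_ch),
                     spec$noise_rate / length(noise_ch))
    }
  }
  panel <- strain_panel(grid, counts,
                        tibble::tibble(orf = orfs, role = role))
  mean_d <- vapply(mixes, function(m) {
    exp(m$meanlog_birth + m$sdlog_birth^2 / 2) *
      (exp(m$log_growth) - 1) / m$log_growth
  }, numeric(1))
  mean_m <- vapply(mixes, function(m) {
    exp(m$meanlog_mother + m$sdlog_mother^2 / 2)
  }, numeric(1))
  w <- spec$daughter_fraction
  truth <- tibble::tibble(
    orf = orfs, role = role, true_birth_fl = B,
    birth_effect = c(rep(1, length(orfs_w)), unname(effect)),
    g1_shift = c(rep(0, length(orfs_w)), unname(g1_shift)),
    fitness_shift = c(rep(0L, length(orfs_w)), unname(fit_shift)),
    true_label = dplyr::case_when(
      role == "wild_type" ~ "normal",
      c(rep(1, length(orfs_w)), unname(effect)) < 1 ~ "small",
      c(rep(1, length(orfs_w)), unname(effect)) > 1 ~ "large",
      TRUE ~ "normal"),
    true_mean_fl = w * mean_d + (1 - w) * mean_m,
    meanlog_birth = vapply(mixes, `[[`, numeric(1), "meanlog_birth"),
    sdlog_birth = vapply(mixes, `[[`, numeric(1), "sdlog_birth"),
    log_growth = vapply(mixes, `[[`, numeric(1), "log_growth"),
    meanlog_mother = vapply(mixes, `[[`, numeric(1), "meanlog_mother"),
    sdlog_mother = vapply(mixes, `[[`, numeric(1), "sdlog_mother"),
    weight_daughter = w
  )
  list(panel = panel, truth = truth)
}

#' Link phenotypes to synthetic ground truth
#'
#' Generates the published-phenotype layer for a synthetic panel. %G1 is a
#' baseline plus Gaussian noise; planted small-birth strains additionally
#' get the negative birth-size link (smaller birth, higher %G1, at
#' `g1_slope` percentage points per fl) and any per-strain planted shift.
#' Fitness is an ordinal rank 1..21 (1 = most fit), drawn near the fit end
#' for unplanted strains and worsened by `fitness_penalty` (plus planted
#' shifts) for birth-size outliers. The published mean size is the
#' analytic mixture mean plus measurement noise. Phenotypes for unplanted
#' strains carry no linked effects, so null strains probe type-I
#' behaviour. Values are clipped to valid ranges (%G1 to 0..100, rank to
#' 1..21).
#'
#' @param truth Ground-truth tibble from [generate_panel()].
#' @param g1_baseline Baseline %G1 (default 40).
#' @param g1_slope %G1 change per fl of birth-size deficit for planted
#'   small strains (default 1.5).
#' @param g1_noise_sd Gaussian noise SD on %G1 (default 5).
#' @param fitness_penalty Ranks added for planted outliers (default 6).
#' @param mean_size_noise_sd Measurement noise SD on published mean size,
#'   fl (default 1).
#' @param wt_birth_mean Reference birth size for the %G1 link (default
#'   23.7).
#' @param seed Integer seed for the phenotype draws.
#' @return Phenotype tibble (`orf`, `mean_size`, `fitness_rank`, `pct_g1`).
#' @export
phenotype_link <- function(truth, g1_baseline = 40, g1_slope = 1.5,
                           g1_noise_sd = 5, fitness_penalty = 6,
                           mean_size_noise_sd = 1, wt_birth_mean = 23.7,
                           seed = 1) {
  set.seed(seed)
  n <- nrow(truth)
  planted_small <- truth$birth_effect < 1
  outlier <- truth$birth_effect != 1
  g1 <- g1_baseline + truth$g1_shift +
    ifelse(planted_small,
           -g1_slope * (truth$true_birth_fl - wt_birth_mean), 0) +
    stats::rnorm(n, 0, g1_noise_sd)
  g1 <- pmin(100, pmax(0, g1))
  base_rank <- 1L + as.integer(round(abs(stats::rnorm(n, 0, 2.5))))
  rank <- base_rank + ifelse(outlier, fitness_penalty, 0L) +
    truth$fitness_shift
  rank <- pmin(21L, pmax(1L, as.integer(rank)))
  tibble::tibble(
    orf = truth$orf,
    mean_size = truth$true_mean_fl +
      stats::rnorm(n, 0, mean_size_noise_sd),
    fitness_rank = as.numeric(rank),
    pct_g1 = g1
  )
}
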