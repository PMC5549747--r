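# Multi-run optimization campaigns: independent seeded searches, summary
# statistics, and per-level weight distributions.

#' Run a campaign of independent Monte Carlo searches
#'
#' Executes `n_runs` independent [run_mc()] searches on the same dataset;
#' run i uses seed `base_seed + i - 1`, so the whole campaign is
#' reproducible from the manifest. The summary reports each run's final
#' fitness, the attempted moves needed to reach `threshold` (if given), the
#' elementwise mean of the unit-rescaled final scales, and, when `levels`
#' are requested, per-amino-acid weight means and SDs at each level.
#'
#' @param x A `proteome` tibble or a [profile_cache()].
#' @param n_runs Number of independent runs.
#' @param base_seed Integer base seed; run seeds are `base_seed + 0:(n_runs-1)`.
#' @param config An [mc_config()] shared by all runs (its seed is ignored).
#' @param threshold Optional fitness threshold for [moves_to_threshold()].
#' @param levels Optional fitness levels for
#'   [weight_statistics_at_levels()].
#' @param tolerance Level selection tolerance, default 0.01.
#' @return An `mc_campaign`: list with `runs` (tibble: `run`, `seed`,
#'   `final_R`, `n_accepted`, and `moves_to_threshold` when requested),
#'   `trajectories`, `mean_scale`, `weight_stats` (or `NULL`), `manifest`.
#' @export
run_campaign <- function(x, n_runs = 10L, base_seed = 1L, config = mc_config(),
                         threshold = NULL, levels = NULL, tolerance = 0.01) {
  stopifnot(n_runs >= 1L)
  base_seed <- as.integer(base_seed)
  if (base_seed + n_runs - 1L > .Machine$integer.max - 1L) {
    rlang::abort("`base_seed + n_runs` exceeds the integer seed range.")
  }
  if (!inherits(x, "profile_cache")) x <- profile_cache(x, targets = config$target)
  seeds <- base_seed + seq_len(n_runs) - 1L
  trajectories <- purrr::map(seeds, function(s) run_mc(x, config, seed = s))
  runs <- tibble::tibble(
    run = seq_len(n_runs),
    seed = seeds,
    final_R = purrr::map_dbl(trajectories, "final_R"),
    n_accepted = purrr::map_int(
      trajectories,
      function(t) sum(t$steps$accepted, na.rm = TRUE)
    )
  )
  if (!is.null(threshold)) {
    runs$moves_to_threshold <- purrr::map_int(
      trajectories, moves_to_threshold,
      threshold = threshold
    )
  }
  finals <- do.call(rbind, purrr::map(
    trajectories,
    function(t) .weights(t$final_scale)
  ))
  mean_scale <- affinity_scale(colMeans(finals),
    target = config$target,
    provenance = paste0("mean of ", n_runs, " MC-optimized scales")
  )
  weight_stats <- if (!is.null(levels)) {
    weight_statistics_at_levels(trajectories, levels, tolerance)
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("scalescape")),
    target = config$target, n_runs = n_runs, base_seed = base_seed,
    config = config, dataset_checksum = rlang::hash(x),
    n_pairs = length(x$ids), organism = x$organism
  )
  structure(
    list(
      runs = runs, trajectories = trajectories, mean_scale = mean_scale,
      weight_stats = weight_stats, manifest = manifest
    ),
    class = "mc_campaign"
  )
}

#' @export
print.mc_campaign <- function(x, ...) {
  cat(
    "# mc_campaign: ", nrow(x$runs), " run(s), target ", x$manifest$target,
    ", best <R> = ", format(min(x$runs$final_R), digits = 4),
    ", mean final <R> = ", format(mean(x$runs$final_R), digits = 4), "\n",
    sep = ""
  )
  invisible(x)
}

#' Per-amino-acid weight statistics at fitness levels
#'
#' For each requested level, selects from every trajectory the
#' unit-rescaled scale closest to that level (within `tolerance`) and
#' reports the per-amino-acid mean and standard deviation of the selected
#' weights. This traces how sharply each weight is defined as matching
#' improves: near `<R> = 0` the pooled SD approaches the uniform-null value
#' `1/sqrt(12)`, and it collapses only close to the optimum.
#'
#' @param trajectories List of `mc_trajectory` objects (>= 2).
#' @param levels Numeric fitness levels; it is an error if a level is
#'   represented in none of the trajectories.
#' @param tolerance Level selection tolerance, default 0.01.
#' @return Tibble with columns `level`, `n_scales`, `aa`, `mean`, `sd`.
#' @export
weight_statistics_at_levels <- function(trajectories, levels, tolerance = 0.01) {
  if (length(trajectories) < 2L) rlang::abort("Need at least 2 trajectories.")
  purrr::map_dfr(levels, function(lv) {
    scales <- purrr::compact(purrr::map(
      trajectories, select_scale_at_level,
      level = lv, tolerance = tolerance
    ))
    if (!length(scales)) {
      rlang::abort(paste0("Level ", lv, " is represented in no trajectory."))
    }
    M <- do.call(rbind, purrr::map(scales, .weights))
    tibble::tibble(
      level = lv, n_scales = nrow(M), aa = aa_letters,
      mean = unname(colMeans(M)),
      sd = unname(apply(M, 2L, stats::sd))
    )
  })
}

#' @rdname run_campaign
#' @param ... Unused.
#' @export
tidy.mc_campaign <- function(x, ...) x$runs

#' @rdname run_campaign
#' @export
glance.mc_campaign <- function(x, ...) {
  tibble::tibble(
    n_runs = nrow(x$runs),
    best_R = min(x$runs$final_R),
    mean_final_R = mean(x$runs$final_R),
    sd_final_R = stats::sd(x$runs$final_R),
    target = x$manifest$target,
    n_pairs = x$manifest$n_pairs
  )
}

#' Write campaign artifacts to a directory
#'
#' Per-run trajectory TSVs (`step amplitude proposal_R accepted current_R`,
#' thinned by the config's `record_every`), per-run final scale TSVs, the
#' mean scale, a run summary TSV and a plain-text manifest.
#'
#' @param campaign An `mc_campaign`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_campaign <- function(campaign, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(campaign$trajectories)) {
    tr <- campaign$trajectories[[i]]
    utils::write.table(
      tidy.mc_trajectory(tr),
      file.path(dir, sprintf("run%04d_trajectory.tsv", i)),
      sep = "\t", quote = FALSE, row.names = FALSE
    )
    write_scale(tr$final_scale, file.path(dir, sprintf("run%04d_scale.tsv", i)))
  }
  write_scale(campaign$mean_scale, file.path(dir, "mean_scale.tsv"))
  utils::write.table(campaign$runs, file.path(dir, "runs.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  if (!is.null(campaign$weight_stats)) {
    utils::write.table(campaign$weight_stats, file.path(dir, "weight_stats.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE
    )
  }
  m <- campaign$manifest
  writeLines(
    c(
      paste0("package_version\t", m$package_version),
      paste0("target\t", m$target),
      paste0("n_runs\t", m$n_runs),
      paste0("base_seed\t", m$base_seed),
      paste0("n_steps\t", m$config$n_steps),
      paste0("amp_start\t", m$config$amp_start),
      paste0("amp_end\t", m$config$amp_end),
      paste0("dataset_checksum\t", m$dataset_checksum),
      paste0("n_pairs\t", m$n_pairs)
    ),
    file.path(dir, "manifest.tsv")
  )
  invisible(dir)
}
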