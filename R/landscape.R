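# Hierarchical clustering of scale ensembles with the 1 - R distance and
# cluster-count landscapes across fitness levels.

#' Correlation distance between two scales
#'
#' `1 - scale_correlation(s1, s2)`: 0 for identical scales, 2 for exact
#' mirrors; lower numbers mean higher similarity.
#'
#' @param s1,s2 Affinity scales (or named weight vectors).
#' @return A number in `[0, 2]`.
#' @export
scale_distance <- function(s1, s2) {
  1 - scale_correlation(s1, s2)
}

# list of scales / matrix -> n x 20 weight matrix
.scale_matrix <- function(scales) {
  if (is.matrix(scales)) {
    stopifnot(ncol(scales) == 20L)
    colnames(scales) <- colnames(scales) %||% aa_letters
    return(scales[, aa_letters, drop = FALSE])
  }
  do.call(rbind, lapply(scales, .weights))
}

#' Hierarchically cluster an ensemble of scales
#'
#' Agglomerative clustering on the `1 - R` distance matrix between scales.
#' Merge heights are non-decreasing for the provided linkage methods.
#'
#' @param scales List of affinity scales, or an `n x 20` weight matrix.
#' @param linkage `"average"` (default), `"complete"` or `"single"`.
#' @return An [stats::hclust] dendrogram with attribute `linkage`.
#' @export
cluster_scales <- function(scales, linkage = c("average", "complete", "single")) {
  linkage <- match.arg(linkage)
  M <- .scale_matrix(scales)
  if (nrow(M) < 2L) rlang::abort("Need at least 2 scales to cluster.")
  cors <- suppressWarnings(stats::cor(t(M)))
  cors[!is.finite(cors)] <- 0 # degenerate scales: R = 0 convention
  diag(cors) <- 1
  hc <- stats::hclust(stats::as.dist(1 - cors), method = linkage)
  attr(hc, "linkage") <- linkage
  hc
}

#' Number of flat clusters at a distance cutoff
#'
#' Cuts the dendrogram so that all within-cluster merges have height
#' `<= cutoff` and counts the clusters.
#'
#' @param dendrogram An [stats::hclust] result from [cluster_scales()].
#' @param cutoff Upper cutoff for the `1 - R` distance, `>= 0`.
#' @return Integer cluster count.
#' @export
n_clusters <- function(dendrogram, cutoff) {
  stopifnot(cutoff >= 0)
  max(stats::cutree(dendrogram, h = cutoff))
}

#' Cluster-count landscape over fitness levels
#'
#' For each fitness level, selects from every trajectory the scale closest
#' to the level (within `tolerance`, via [select_scale_at_level()]); levels
#' represented by fewer than `n_required` scales are skipped. The retained
#' ensembles are clustered on the `1 - R` distance and the cluster count is
#' reported for each cutoff. At a fixed level, counts are non-increasing in
#' the cutoff; a funnel-shaped space shows many clusters at intermediate
#' levels and essentially one near the optimum.
#'
#' @param trajectories List of `mc_trajectory` objects (independent runs).
#' @param levels Numeric fitness levels.
#' @param cutoffs Numeric distance cutoffs (default `c(0.2, 0.4)`).
#' @param n_required Minimum ensemble size for a level to be reported
#'   (default 1000, the full-campaign convention).
#' @param tolerance Level selection tolerance, default 0.01.
#' @param linkage Linkage method, see [cluster_scales()].
#' @return Tibble with columns `level`, `n_scales`, `cutoff`, `n_clusters`
#'   and attribute `linkage`.
#' @export
landscape_table <- function(trajectories, levels, cutoffs = c(0.2, 0.4),
                            n_required = 1000L, tolerance = 0.01,
                            linkage = "average") {
  if (!length(trajectories)) rlang::abort("Need at least one trajectory.")
  if (!length(levels) || !length(cutoffs)) {
    rlang::abort("`levels` and `cutoffs` must be nonempty.")
  }
  rows <- purrr::map(levels, function(lv) {
    scales <- purrr::compact(purrr::map(
      trajectories, select_scale_at_level,
      level = lv, tolerance = tolerance
    ))
    if (length(scales) < max(n_required, 1L)) {
      return(NULL)
    }
    if (length(scales) == 1L) {
      return(tibble::tibble(
        level = lv, n_scales = 1L, cutoff = cutoffs, n_clusters = 1L
      ))
    }
    hc <- cluster_scales(scales, linkage)
    tibble::tibble(
      level = lv, n_scales = length(scales), cutoff = cutoffs,
      n_clusters = vapply(cutoffs, n_clusters, integer(1), dendrogram = hc)
    )
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "linkage") <- linkage
  out
}
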