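# ggplot2 views of profiles, trajectories, campaigns and landscapes.

#' Plot the two cognate profiles of one pair
#'
#' Overlays the mRNA nucleobase-density profile and the (unit-rescaled)
#' protein affinity profile of a single cognate pair. With a well-matching
#' affinity scale the two curves mirror each other (negative correlation).
#'
#' @inheritParams profile_table
#' @return A ggplot object.
#' @export
plot_profile_pair <- function(proteome, scale, id = NULL, target = "PUR",
                              window = 21L) {
  tab <- profile_table(proteome, scale, id = id, target = target, window = window)
  long <- tidyr::pivot_longer(tab, -"position",
    names_to = "profile", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(
    x = .data$position, y = .data$value, colour = .data$profile
  )) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "position (codon / residue)", y = "windowed value",
      colour = NULL,
      title = paste0("Cognate profiles, target ", .check_target(target))
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.mc_trajectory <- function(object, ...) {
  ggplot2::ggplot(
    object$steps,
    ggplot2::aes(x = .data$step, y = .data$current_R)
  ) +
    ggplot2::geom_step() +
    ggplot2::labs(
      x = "attempted move", y = "<R>",
      title = paste0(
        "MC trajectory (target ", object$config$target,
        ", final <R> = ", format(object$final_R, digits = 3), ")"
      )
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.mc_campaign <- function(object, ...) {
  if (!is.null(object$weight_stats)) {
    return(
      ggplot2::ggplot(
        object$weight_stats,
        ggplot2::aes(x = .data$mean, y = .data$level, colour = .data$aa)
      ) +
        ggplot2::geom_path() +
        ggplot2::geom_point(size = 0.8) +
        ggplot2::labs(
          x = "mean rescaled weight", y = "<R> level", colour = "amino acid",
          title = "Weight means vs matching level"
        ) +
        ggplot2::theme_minimal()
    )
  }
  steps <- purrr::imap_dfr(object$trajectories, function(t, i) {
    dplyr::mutate(t$steps, run = factor(i))
  })
  ggplot2::ggplot(steps, ggplot2::aes(
    x = .data$step, y = .data$current_R, group = .data$run
  )) +
    ggplot2::geom_step(alpha = 0.5) +
    ggplot2::labs(
      x = "attempted move", y = "<R>",
      title = paste0("Campaign of ", nrow(object$runs), " MC runs")
    ) +
    ggplot2::theme_minimal()
}

#' Plot a cluster-count landscape
#'
#' Cluster counts against the fitness level, one line per distance cutoff.
#' A funnel-shaped scale space shows many clusters at intermediate levels
#' and a collapse towards one cluster near the optimum.
#'
#' @param landscape A tibble from [landscape_table()].
#' @param log_y Log-scale the cluster count axis?
#' @return A ggplot object.
#' @export
plot_landscape <- function(landscape, log_y = FALSE) {
  p <- ggplot2::ggplot(landscape, ggplot2::aes(
    x = .data$level, y = .data$n_clusters,
    colour = factor(.data$cutoff), group = factor(.data$cutoff)
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "<R> level", y = "number of clusters", colour = "1 - R cutoff",
      title = "Affinity-scale landscape"
    ) +
    ggplot2::theme_minimal()
  if (log_y) p <- p + ggplot2::scale_y_log10()
  p
}
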