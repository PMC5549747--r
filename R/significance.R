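# Randomization significance of scale-vs-scale correlations, two-tailed
# conversion, and Fisher combination.

# n x 20 matrix of i.i.d. uniform [0,1] weights (the null ensemble)
.sample_scale_matrix <- function(n) {
  matrix(stats::runif(n * 20L), nrow = n, ncol = 20L,
    dimnames = list(NULL, aa_letters)
  )
}

#' Randomization p-value for a scale-vs-scale correlation
#'
#' Draws `n_random` null scales with 20 i.i.d. uniform `[0, 1]` weights,
#' correlates each with `reference_scale`, and reports the fraction at
#' least as extreme as `observed_R` in the chosen direction. The default
#' direction `"toward-observed"` tests negative observations against the
#' lower tail and positive ones against the upper tail; `"negative"` and
#' `"positive"` fix the tail. The estimate has Monte Carlo resolution
#' `1 / n_random`; an exact 0 should be read as `< 1/n_random` and floored
#' before Fisher combination.
#'
#' @param reference_scale The fixed scale the correlation was computed
#'   against (must not be degenerate).
#' @param observed_R Observed Pearson correlation.
#' @param n_random Number of null scales (default `1e6`).
#' @param direction `"toward-observed"` (default), `"negative"` or
#'   `"positive"`.
#' @param seed Integer seed (required).
#' @return A one-row `significance_result` tibble: `observed_R`,
#'   `direction`, `p_one_tailed`, `p_two_tailed`, `n_random`, `seed`.
#' @export
randomization_p <- function(reference_scale, observed_R, n_random = 1e6,
                            direction = c("toward-observed", "negative", "positive"),
                            seed = NULL) {
  direction <- match.arg(direction)
  if (is.null(seed)) rlang::abort("An explicit integer `seed` is required.")
  n_random <- as.integer(n_random)
  stopifnot(n_random >= 1L, is.finite(observed_R))
  r <- .weights(reference_scale)
  rc <- r - mean(r)
  sr2 <- sum(rc^2)
  if (sr2 <= .zero_var_tol * max(1, sum(r^2))) {
    rlang::abort("Degenerate (constant) reference scale.")
  }
  tail_dir <- if (direction == "toward-observed") {
    if (observed_R < 0) "negative" else "positive"
  } else {
    direction
  }
  chunk <- 100000L
  extreme <- 0
  withr::with_seed(as.integer(seed), {
    left <- n_random
    while (left > 0L) {
      m <- min(chunk, left)
      M <- .sample_scale_matrix(m)
      Mc <- M - rowMeans(M)
      num <- drop(Mc %*% rc)
      den <- sqrt(rowSums(Mc^2) * sr2)
      R <- ifelse(den > 0, num / den, 0)
      extreme <- extreme + if (tail_dir == "negative") {
        sum(R <= observed_R)
      } else {
        sum(R >= observed_R)
      }
      left <- left - m
    }
  })
  p1 <- extreme / n_random
  structure(
    tibble::tibble(
      observed_R = observed_R, direction = direction,
      p_one_tailed = p1, p_two_tailed = two_tailed(p1),
      n_random = n_random, seed = as.integer(seed)
    ),
    class = c("significance_result", class(tibble::tibble()))
  )
}

#' Two-tailed conversion of a one-tailed p-value
#'
#' `2 p` when `p < 0.5`, `1 - p` otherwise; continuous at 0.5 and mapping
#' `[0, 1]` onto `[0, 1]`.
#'
#' @param p_one One-tailed p-value(s) in `[0, 1]`.
#' @return Two-tailed p-value(s).
#' @examples
#' two_tailed(c(0.2, 0.5, 0.7))
#' @export
two_tailed <- function(p_one) {
  if (any(!is.finite(p_one) | p_one < 0 | p_one > 1)) {
    rlang::abort("One-tailed p-values must lie in [0, 1].")
  }
  ifelse(p_one < 0.5, 2 * p_one, 1 - p_one)
}

#' Combine independent p-values by Fisher's method
#'
#' `X^2 = -2 * sum(log(p))` referred to the upper tail of the chi-square
#' distribution with `2 k` degrees of freedom. A zero p-value gives an
#' infinite statistic and is an error: floor Monte Carlo zeros at
#' `1 / n_random` first.
#'
#' @param p_values Nonempty vector of p-values in `(0, 1]`.
#' @return Combined p-value.
#' @examples
#' fisher_combine(c(0.05, 0.05))
#' @export
fisher_combine <- function(p_values) {
  if (!length(p_values)) rlang::abort("Need at least one p-value.")
  if (any(!is.finite(p_values) | p_values > 1 | p_values < 0)) {
    rlang::abort("p-values must lie in (0, 1].")
  }
  if (any(p_values == 0)) {
    rlang::abort(
      "p = 0 gives an infinite statistic; floor randomization zeros at 1/n_random."
    )
  }
  stat <- -2 * sum(log(p_values))
  stats::pchisq(stat, df = 2 * length(p_values), lower.tail = FALSE)
}
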