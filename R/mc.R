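# Zero-temperature downhill Monte Carlo over scale space with a
# simulated-annealing schedule for the perturbation amplitude.

#' Monte Carlo search configuration
#'
#' At each attempted move, between `k_range[1]` and `k_range[2]` randomly
#' chosen weights are perturbed by offsets drawn uniformly from
#' `[-amplitude, amplitude]`; the amplitude ramps linearly from `amp_start`
#' at the first move to `amp_end` at the last. A proposal is accepted only
#' if it strictly lowers the proteome-average correlation (zero-temperature
#' downhill Metropolis).
#'
#' @param n_steps Total attempted moves. The default 1500 is at least three
#'   times the typical number of moves needed to reach a stable minimum.
#' @param k_range Integer range of weights perturbed per move, default
#'   `c(1, 4)`, drawn uniformly.
#' @param amp_start,amp_end Initial and final perturbation amplitude
#'   (defaults 0.1 and 0.01).
#' @param target Nucleobase target (default `"PUR"`).
#' @param seed Integer seed; required by [run_mc()], so the search is
#'   bitwise reproducible.
#' @param record_every Thinning interval used when trajectories are
#'   exported as tables; internally every state is kept.
#' @param shared_offset If `TRUE`, all perturbed weights of one move share
#'   a single offset; the default `FALSE` draws independent offsets.
#' @return An `mc_config` list.
#' @export
mc_config <- function(n_steps = 1500L, k_range = c(1L, 4L), amp_start = 0.1,
                      amp_end = 0.01, target = "PUR", seed = NULL,
                      record_every = 1L, shared_offset = FALSE) {
  n_steps <- as.integer(n_steps)
  k_range <- as.integer(k_range)
  stopifnot(
    n_steps >= 1L, amp_start >= amp_end, amp_end > 0,
    length(k_range) == 2L, 1L <= k_range[1], k_range[1] <= k_range[2],
    k_range[2] <= 20L, record_every >= 1L
  )
  structure(
    list(
      n_steps = n_steps, k_range = k_range, amp_start = amp_start,
      amp_end = amp_end, target = .check_target(target),
      seed = if (!is.null(seed)) as.integer(seed),
      record_every = as.integer(record_every), shared_offset = shared_offset
    ),
    class = "mc_config"
  )
}

#' Annealed perturbation amplitude at a given step
#'
#' Linear ramp from `amp_start` (step 0) to `amp_end` (step
#' `n_steps - 1`).
#'
#' @param step 0-based attempted-move index, `0 <= step < n_steps`.
#' @param config An [mc_config()].
#' @return Amplitude (numeric).
#' @export
anneal_amplitude <- function(step, config) {
  if (any(step < 0L | step >= config$n_steps)) {
    rlang::abort("`step` must satisfy 0 <= step < n_steps.")
  }
  if (config$n_steps == 1L) {
    return(rep(config$amp_start, length(step)))
  }
  config$amp_start +
    (config$amp_end - config$amp_start) * step / (config$n_steps - 1)
}

#' Propose a perturbed scale
#'
#' Draws k uniformly from `k_range`, picks k distinct amino acids uniformly
#' and shifts each by an offset uniform in `[-amplitude, amplitude]`
#' (independent offsets by default, one shared offset if `shared_offset`).
#' Uses the current RNG state; the input is not modified.
#'
#' @param weights Named 20-vector of current (raw) weights.
#' @param amplitude Positive perturbation amplitude.
#' @param k_range Integer range of entries to perturb.
#' @param shared_offset Share one offset across the perturbed entries?
#' @return Perturbed weight vector.
#' @export
propose_scale <- function(weights, amplitude, k_range = c(1L, 4L),
                          shared_offset = FALSE) {
  stopifnot(amplitude > 0, length(weights) == 20L)
  ks <- k_range[1]:k_range[2]
  k <- if (length(ks) == 1L) ks else ks[sample.int(length(ks), 1L)]
  idx <- sample.int(20L, k)
  off <- stats::runif(if (shared_offset) 1L else k, -amplitude, amplitude)
  weights[idx] <- weights[idx] + off
  weights
}

#' Downhill acceptance rule
#'
#' Accept iff the proposal strictly lowers the proteome-average Pearson R;
#' ties are rejected.
#'
#' @param old_R,new_R Current and proposed fitness values (finite).
#' @return Logical.
#' @export
accept_move <- function(old_R, new_R) {
  if (!is.finite(old_R) || !is.finite(new_R)) {
    rlang::abort("Fitness values must be finite.")
  }
  new_R < old_R
}

#' Run one seeded Monte Carlo search
#'
#' Starts from the uniform scale (all weights 0; its fitness is 0 by the
#' zero-variance convention, since every protein profile is constant) and
#' iterates propose / evaluate / accept for `n_steps` attempted moves,
#' minimizing the proteome-average Pearson correlation. The full state
#' sequence is recorded; the run is bitwise reproducible for a fixed seed.
#'
#' @param x A `proteome` tibble or (faster, reusable) a [profile_cache()].
#' @param config An [mc_config()]; `config$seed` must be set (or pass
#'   `seed`).
#' @param seed Optional override of `config$seed`.
#' @return An `mc_trajectory`: list with `steps` (tibble: `step`,
#'   `amplitude`, `proposal_R`, `accepted`, `current_R`; step 0 is the
#'   initial state), `scales` (matrix of raw current weights, one row per
#'   recorded state), `final_scale` (unit-rescaled scale of the final,
#'   minimal state), `final_R`, `config`, `n_pairs`.
#' @export
run_mc <- function(x, config = mc_config(), seed = NULL) {
  if (!inherits(x, "profile_cache")) x <- profile_cache(x, targets = config$target)
  seed <- seed %||% config$seed
  if (is.null(seed)) rlang::abort("An explicit integer `seed` is required.")
  config$seed <- as.integer(seed)
  target <- config$target
  n_steps <- config$n_steps
  amps <- anneal_amplitude(seq_len(n_steps) - 1L, config)
  cur_w <- stats::setNames(rep(0, 20L), aa_letters)
  cur_R <- mean(.cache_pair_R(x, cur_w, target)) # 0 by convention
  scales <- matrix(0, n_steps + 1L, 20L, dimnames = list(NULL, aa_letters))
  proposal_R <- rep(NA_real_, n_steps + 1L)
  accepted <- rep(NA, n_steps + 1L)
  current_R <- numeric(n_steps + 1L)
  current_R[1L] <- cur_R
  withr::with_seed(config$seed, {
    for (i in seq_len(n_steps)) {
      prop <- propose_scale(cur_w, amps[i], config$k_range, config$shared_offset)
      pR <- mean(.cache_pair_R(x, prop, target))
      acc <- accept_move(cur_R, pR)
      if (acc) {
        cur_w <- prop
        cur_R <- pR
      }
      proposal_R[i + 1L] <- pR
      accepted[i + 1L] <- acc
      current_R[i + 1L] <- cur_R
      scales[i + 1L, ] <- cur_w
    }
  })
  steps <- tibble::tibble(
    step = 0:n_steps,
    amplitude = c(NA_real_, amps),
    proposal_R = proposal_R,
    accepted = accepted,
    current_R = current_R
  )
  structure(
    list(
      steps = steps, scales = scales,
      final_scale = rescale_unit(affinity_scale(cur_w,
        target = target,
        provenance = paste0("MC-optimized (seed ", config$seed, ")")
      )),
      final_R = cur_R, config = config, n_pairs = length(x$ids)
    ),
    class = "mc_trajectory"
  )
}

#' @export
print.mc_trajectory <- function(x, ...) {
  cat(
    "# mc_trajectory: ", x$config$n_steps, " attempted moves, ",
    sum(x$steps$accepted, na.rm = TRUE), " accepted, final <R> = ",
    format(x$final_R, digits = 4), " (target ", x$config$target,
    ", seed ", x$config$seed, ")\n",
    sep = ""
  )
  invisible(x)
}

#' Attempted moves needed to reach a fitness threshold
#'
#' The 1-based index of the first attempted move whose accepted state has
#' `current_R <= threshold`; 0 if the initial state already qualifies.
#' Counting acceptances instead of attempts is available via `count`.
#'
#' @param trajectory An `mc_trajectory`.
#' @param threshold Fitness threshold (e.g. -0.86).
#' @param count `"attempted"` (default) or `"accepted"`.
#' @return Integer number of moves, or `NA_integer_` if the threshold is
#'   never reached.
#' @export
moves_to_threshold <- function(trajectory, threshold,
                               count = c("attempted", "accepted")) {
  count <- match.arg(count)
  st <- trajectory$steps
  hit <- which(st$current_R <= threshold)
  if (!length(hit)) {
    return(NA_integer_)
  }
  first <- hit[1L]
  if (count == "attempted") {
    st$step[first]
  } else {
    sum(st$accepted[seq_len(first)], na.rm = TRUE)
  }
}

#' Select the recorded scale closest to a fitness level
#'
#' Among the accepted states of a trajectory (including the initial one),
#' returns the scale whose fitness is closest to `level`, unit-rescaled, or
#' `NULL` if even the closest state is farther than `tolerance`. This is
#' how suboptimal-scale ensembles for the landscape are assembled: one
#' scale per independent run per level.
#'
#' @param trajectory An `mc_trajectory`.
#' @param level Target fitness level.
#' @param tolerance Maximum allowed |achieved - level|, default 0.01.
#' @return A unit-rescaled `affinity_scale`, or `NULL`.
#' @export
select_scale_at_level <- function(trajectory, level, tolerance = 0.01) {
  stopifnot(tolerance > 0)
  st <- trajectory$steps
  keep <- which(is.na(st$accepted) | st$accepted) # distinct visited states
  d <- abs(st$current_R[keep] - level)
  best <- keep[which.min(d)]
  if (min(d) > tolerance) {
    return(NULL)
  }
  out <- rescale_unit(affinity_scale(trajectory$scales[best, ],
    target = trajectory$config$target,
    provenance = paste0(
      "selected at level ", format(level),
      " (achieved ", format(st$current_R[best], digits = 4), ")"
    )
  ))
  attr(out, "achieved_R") <- st$current_R[best]
  out
}

#' @rdname run_mc
#' @param ... Unused.
#' @export
tidy.mc_trajectory <- function(x, ...) {
  st <- x$steps
  st[st$step %% x$config$record_every == 0L | st$step == x$config$n_steps, ]
}

#' @rdname run_mc
#' @export
glance.mc_trajectory <- function(x, ...) {
  tibble::tibble(
    n_steps = x$config$n_steps,
    n_accepted = sum(x$steps$accepted, na.rm = TRUE),
    final_R = x$final_R,
    target = x$config$target,
    seed = x$config$seed,
    n_pairs = x$n_pairs
  )
}
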