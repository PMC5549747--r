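test_that("the annealing ramp is linear between the two amplitudes", {
  cfg <- mc_config(n_steps = 1500)
  expect_equal(anneal_amplitude(0, cfg), 0.1)
  expect_equal(anneal_amplitude(1499, cfg), 0.01)
  cfg2 <- mc_config(n_steps = 11)
  expect_equal(anneal_amplitude(5, cfg2), 0.055)
  expect_error(anneal_amplitude(11, cfg2), "step")
  expect_error(anneal_amplitude(-1, cfg2), "step")
  # degenerate single-step schedule stays at the start amplitude
  expect_equal(anneal_amplitude(0, mc_config(n_steps = 1)), 0.1)
})

test_that("configuration invariants are enforced", {
  expect_error(mc_config(n_steps = 0))
  expect_error(mc_config(amp_start = 0.01, amp_end = 0.1))
  expect_error(mc_config(amp_end = 0))
  expect_error(mc_config(k_range = c(0, 4)))
  expect_error(mc_config(k_range = c(2, 21)))
})

test_that("proposals perturb 1-4 entries uniformly with bounded offsets", {
  set.seed(31)
  w <- stats::setNames(rep(0, 20), aa_letters)
  n_changed <- integer(1e4)
  max_off <- 0
  for (i in seq_len(1e4)) {
    prop <- propose_scale(w, amplitude = 0.1)
    changed <- which(prop != w)
    n_changed[i] <- length(changed)
    max_off <- max(max_off, abs(prop[changed]))
  }
  expect_true(all(n_changed %in% 1:4))
  expect_lte(max_off, 0.1)
  # uniform k: chi-squared against equal frequencies
  tab <- table(factor(n_changed, levels = 1:4))
  expect_gt(stats::chisq.test(tab)$p.value, 0.01)
  # input untouched
  expect_equal(unname(w), rep(0, 20))
})

test_that("shared-offset proposals move all perturbed entries together", {
  set.seed(32)
  w <- stats::setNames(rep(0, 20), aa_letters)
  for (i in 1:200) {
    prop <- propose_scale(w, 0.05, shared_offset = TRUE)
    offs <- prop[prop != 0]
    expect_lte(length(unique(round(offs, 12))), 1)
  }
})

test_that("proposal streams are reproducible under a fixed seed", {
  w <- stats::setNames(runif(20), aa_letters)
  a <- withr::with_seed(99, replicate(50, propose_scale(w, 0.1)))
  b <- withr::with_seed(99, replicate(50, propose_scale(w, 0.1)))
  expect_identical(a, b)
})

test_that("acceptance is strictly downhill with ties rejected", {
  expect_true(accept_move(-0.4, -0.5))
  expect_false(accept_move(-0.5, -0.5))
  expect_false(accept_move(-0.5, -0.4))
  expect_error(accept_move(NaN, 0), "finite")
  expect_error(accept_move(0, Inf), "finite")
})

test_that("runs start at the uniform scale with fitness 0 and descend", {
  cache <- small_cache()
  tr <- run_mc(cache, mc_config(n_steps = 200), seed = 5)
  expect_equal(tr$steps$current_R[1], 0)
  expect_equal(tr$steps$step[1], 0)
  # accepted fitness sequence is non-increasing
  expect_true(all(diff(tr$steps$current_R) <= 0))
  expect_equal(tr$final_R, min(tr$steps$current_R))
  expect_equal(tr$final_R, tr$steps$current_R[nrow(tr$steps)])
  # the final scale is unit-rescaled
  expect_equal(range(tr$final_scale$weight), c(0, 1))
  # single-step run still records the initial state
  tr1 <- run_mc(cache, mc_config(n_steps = 1), seed = 6)
  expect_equal(tr1$steps$current_R[1], 0)
  expect_equal(nrow(tr1$steps), 2)
})

test_that("runs are bitwise reproducible for a fixed seed", {
  cache <- small_cache()
  t1 <- run_mc(cache, mc_config(n_steps = 100), seed = 77)
  t2 <- run_mc(cache, mc_config(n_steps = 100), seed = 77)
  expect_identical(t1$steps, t2$steps)
  expect_identical(t1$scales, t2$scales)
  t3 <- run_mc(cache, mc_config(n_steps = 100), seed = 78)
  expect_false(identical(t1$steps$current_R, t3$steps$current_R))
  expect_error(run_mc(cache, mc_config(n_steps = 10)), "seed")
})

test_that("moves_to_threshold counts attempted moves to first crossing", {
  cache <- small_cache()
  tr <- run_mc(cache, mc_config(n_steps = 300), seed = 8)
  expect_equal(moves_to_threshold(tr, 0), 0L)
  expect_true(is.na(moves_to_threshold(tr, -2)))
  thr <- tr$final_R + 0.05
  m <- moves_to_threshold(tr, thr)
  expect_true(m >= 1 && m <= 300)
  expect_true(tr$steps$current_R[tr$steps$step == m] <= thr)
  expect_true(all(tr$steps$current_R[tr$steps$step < m] > thr))
  # accepted-move counting never exceeds attempted counting
  expect_lte(moves_to_threshold(tr, thr, count = "accepted"), m)
})

test_that("scales can be selected at intermediate fitness levels", {
  cache <- small_cache()
  tr <- run_mc(cache, mc_config(n_steps = 500), seed = 9)
  # the final level returns the final scale
  s_final <- select_scale_at_level(tr, tr$final_R)
  expect_equal(
    stats::setNames(s_final$weight, s_final$aa),
    stats::setNames(tr$final_scale$weight, tr$final_scale$aa)
  )
  # a level never visited returns NULL
  expect_null(select_scale_at_level(tr, 0.5))
  # an intermediate level is hit within tolerance
  lvl <- tr$final_R / 2
  s_mid <- select_scale_at_level(tr, lvl, tolerance = 0.05)
  expect_false(is.null(s_mid))
  expect_lte(abs(attr(s_mid, "achieved_R") - lvl), 0.05)
  expect_equal(range(s_mid$weight), c(0, 1))
})

test_that("converged searches reach at least the codon-scale optimum", {
  # the codon-content scale is the genetic-code-determined near-optimum:
  # a converged search must do at least as well (within 0.01)
  runs <- big_runs()
  codon_R <- proteome_mean_R(
    big_cache(), codon_content_scale(uniform_codon_usage(), "PUR"), "PUR"
  )$mean_R
  for (tr in runs) {
    expect_lte(tr$final_R, codon_R + 0.01)
  }
})
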