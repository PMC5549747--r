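test_that("mRNA density profiles match direct window counting", {
  # single window: each GCT codon carries one purine
  expect_equal(mrna_density_profile(codon_cds("GCT", 21), "PUR"), 1 / 3)
  # all-purine codons give a saturated profile
  expect_equal(
    mrna_density_profile(codon_cds("AAG", 25), "PUR"), rep(1, 5)
  )
  # 11 AAA then 11 TTT codons: brute-force counting over the literal string
  cds <- paste0(strrep("AAA", 11), strrep("TTT", 11), "TAA")
  expect_equal(
    mrna_density_profile(cds, "PUR"),
    oracle_mrna_profile(cds, "PUR")
  )
  expect_equal(oracle_mrna_profile(cds, "PUR"), c(33, 30) / 63)
  # random sequences, all targets
  p <- generate_proteome(20, c(22, 70), seed = 11)
  for (i in seq_len(nrow(p))) {
    for (t in nucleobase_targets) {
      expect_equal(
        mrna_density_profile(p$cds[i], t),
        oracle_mrna_profile(p$cds[i], t),
        tolerance = 1e-12
      )
    }
  }
})

test_that("profiles reject too-short sequences and bad characters", {
  expect_error(mrna_density_profile(codon_cds("AAA", 21), "PYR"))
  expect_error(mrna_density_profile(codon_cds("AAA", 20), "PUR"), "full window")
  expect_error(protein_window_matrix(strrep("K", 20)), "full window")
  expect_error(protein_window_matrix(paste0(strrep("K", 21), "X")), "non-canonical")
})

test_that("window matrix rows are window frequencies and profiles factorize", {
  W <- protein_window_matrix(strrep("K", 21))
  expect_equal(dim(W), c(1L, 20L))
  expect_equal(unname(W[1, "K"]), 1)
  expect_equal(sum(W), 1)
  p <- generate_proteome(10, c(22, 60), seed = 12)
  for (i in seq_len(nrow(p))) {
    W <- protein_window_matrix(p$protein[i])
    expect_equal(rowSums(W), rep(1, nrow(W)), tolerance = 1e-12)
  }
  # matrix . w equals the naive sliding mean of per-residue weights
  protein <- paste0("KF", strrep("A", 20))
  W <- protein_window_matrix(protein)
  set.seed(42)
  for (k in 1:100) {
    w <- random_weights()
    expect_equal(
      drop(W %*% w), oracle_protein_profile(protein, w),
      tolerance = 1e-12
    )
  }
})

test_that("protein profiles are affine in the scale", {
  protein <- generate_proteome(1, 60, seed = 13)$protein
  set.seed(7)
  w <- random_weights()
  base <- protein_profile(protein, w)
  expect_equal(protein_profile(protein, 2.5 * w - 3), 2.5 * base - 3)
  expect_equal(protein_profile(protein, stats::setNames(rep(4, 20), aa_letters)),
    rep(4, length(base)),
    tolerance = 1e-12
  )
})

test_that("pair correlation follows Pearson with the zero-variance convention", {
  expect_equal(pair_correlation(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(pair_correlation(c(1, 2, 3), c(3, 2, 1)), -1)
  expect_equal(pair_correlation(c(1, 2, 3), c(5, 5, 5)), 0)
  expect_error(pair_correlation(1:3, 1:4), "lengths")
  expect_error(pair_correlation(1, 1), "2 points")
  set.seed(8)
  x <- runif(50)
  y <- runif(50)
  expect_equal(pair_correlation(x, y), cor(x, y))
})

test_that("cache evaluation equals from-scratch evaluation", {
  p <- generate_proteome(30, c(25, 90), seed = 14)
  cache <- profile_cache(p)
  set.seed(9)
  for (k in 1:20) {
    w <- random_weights()
    for (t in c("PUR", "ADE", "CYT")) {
      fast <- proteome_mean_R(cache, w, t)
      slow <- proteome_mean_R(p, w, t)
      expect_equal(fast$per_pair$R, slow$per_pair$R, tolerance = 1e-10)
      expect_equal(fast$mean_R, mean(fast$per_pair$R))
    }
  }
})

test_that("fitness is the unweighted mean over pairs", {
  p <- generate_proteome(1, 60, seed = 15)
  cs <- codon_content_scale(uniform_codon_usage(), "PUR")
  single <- proteome_mean_R(p, cs, "PUR")
  expect_equal(single$mean_R, single$per_pair$R[1])
  expect_equal(single$n_pairs, 1L)
  # uniform scale: every protein profile constant, <R> = 0 by convention
  uni <- stats::setNames(rep(0.3, 20), aa_letters)
  p10 <- generate_proteome(10, c(22, 60), seed = 16)
  expect_equal(proteome_mean_R(p10, uni, "PUR")$mean_R, 0)
  expect_equal(proteome_mean_R(profile_cache(p10), uni, "PUR")$mean_R, 0)
})

test_that("fitness is invariant under affine rescaling of the scale", {
  p <- generate_proteome(10, c(60, 120), seed = 17)
  cache <- profile_cache(p, targets = "PUR")
  set.seed(10)
  w <- random_weights()
  base <- proteome_mean_R(cache, w, "PUR")$mean_R
  expect_equal(proteome_mean_R(cache, 3.7 * w + 11, "PUR")$mean_R, base,
    tolerance = 1e-12
  )
  expect_equal(proteome_mean_R(cache, 0.001 * w + 0.003, "PUR")$mean_R, base,
    tolerance = 1e-12
  )
  expect_equal(proteome_mean_R(cache, -2 * w + 1, "PUR")$mean_R, -base,
    tolerance = 1e-12
  )
})

test_that("PUR density is the elementwise sum of ADE and GUA densities", {
  p <- generate_proteome(10, c(22, 60), seed = 18)
  for (i in seq_len(nrow(p))) {
    expect_equal(
      mrna_density_profile(p$cds[i], "PUR"),
      mrna_density_profile(p$cds[i], "ADE") + mrna_density_profile(p$cds[i], "GUA"),
      tolerance = 1e-12
    )
  }
})

test_that("PYR profile is the exact complement of PUR and flips correlations", {
  expect_equal(pyr_density_profile(codon_cds("AAG", 25)), rep(0, 5))
  p <- generate_proteome(10, c(22, 60), seed = 19)
  set.seed(11)
  w <- random_weights()
  for (i in seq_len(nrow(p))) {
    pur <- mrna_density_profile(p$cds[i], "PUR")
    pyr <- pyr_density_profile(p$cds[i])
    expect_equal(pyr, 1 - pur)
    expect_equal(pyr, oracle_mrna_profile(p$cds[i], "PYR"), tolerance = 1e-12)
    prof <- protein_profile(p$protein[i], w)
    expect_equal(
      pair_correlation(pyr, prof), -pair_correlation(pur, prof)
    )
  }
})

test_that("profile lengths are protein length minus 20 for both molecules", {
  p <- generate_proteome(5, c(22, 80), seed = 20)
  for (i in seq_len(nrow(p))) {
    L <- nchar(p$protein[i])
    expect_length(mrna_density_profile(p$cds[i], "URA"), L - 20)
    expect_equal(nrow(protein_window_matrix(p$protein[i])), L - 20)
  }
  tab <- profile_table(p, codon_content_scale(uniform_codon_usage(), "PUR"),
    id = p$id[2]
  )
  expect_named(tab, c("position", "mrna_density", "protein_profile"))
  expect_equal(nrow(tab), nchar(p$protein[2]) - 20)
})
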