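test_that("affinity scales require exactly the 20 canonical amino acids", {
  w <- stats::setNames(runif(20), aa_letters)
  s <- affinity_scale(w, target = "PUR")
  expect_s3_class(s, "affinity_scale")
  expect_equal(s$aa, aa_letters)
  expect_error(affinity_scale(w[-1]), "Missing")
  expect_error(affinity_scale(c(w, X = 0.5)), "Non-canonical")
  w2 <- w
  w2[1] <- Inf
  expect_error(affinity_scale(w2), "finite")
})

test_that("unit rescaling maps to [0,1], is idempotent, flags degenerate scales", {
  w <- stats::setNames(c(2, 6, rep(4, 18)), aa_letters)
  s <- rescale_unit(w)
  expect_equal(range(s$weight), c(0, 1))
  expect_equal(sort(unique(s$weight)), c(0, 0.5, 1))
  expect_equal(rescale_unit(s)$weight, s$weight)
  flat <- rescale_unit(stats::setNames(rep(3, 20), aa_letters))
  expect_equal(flat$weight, rep(0.5, 20))
  expect_true(attr(flat, "degenerate"))
})

test_that("scale correlation matches Pearson on matched amino acids", {
  set.seed(21)
  w <- random_weights()
  s <- affinity_scale(w)
  expect_equal(scale_correlation(s, s), 1)
  expect_equal(scale_correlation(s, affinity_scale(1 - w)), -1)
  v <- random_weights()
  expect_equal(scale_correlation(w, v), cor(w[aa_letters], v[aa_letters]))
  # shuffled storage order must not matter: matched by letter
  perm <- sample(20)
  expect_equal(scale_correlation(w[perm], v), cor(w[aa_letters], v[aa_letters]))
  expect_equal(scale_correlation(rep(1, 20), v), 0)
})

test_that("codon usage from a dataset counts sense codons per amino acid", {
  p1 <- as_proteome(tibble::tibble(
    id = "p1", cds = codon_cds("AAA", 22), protein = strrep("K", 22)
  ))
  expect_warning(u <- codon_usage_from(p1), "uniform usage")
  lys <- u[u$aa == "K", ]
  expect_equal(lys$fraction[lys$codon == "AAA"], 1)
  expect_equal(lys$fraction[lys$codon == "AAG"], 0)
  # 3 AAA + 1 AAG
  p2 <- as_proteome(tibble::tibble(
    id = "p2",
    cds = paste0(strrep("AAA", 3), "AAG", strrep("GGG", 18), "TAA"),
    protein = paste0(strrep("K", 4), strrep("G", 18))
  ))
  expect_warning(u2 <- codon_usage_from(p2))
  lys2 <- u2[u2$aa == "K", ]
  expect_equal(lys2$fraction[lys2$codon == "AAA"], 0.75)
  expect_equal(lys2$fraction[lys2$codon == "AAG"], 0.25)
  # larger dataset against an independent single-pass counter
  p <- generate_proteome(40, c(30, 90), codon_usage = ecoli_codon_usage(), seed = 22)
  u3 <- codon_usage_from(p)
  cnt <- oracle_codon_counts(p)
  for (a in c("K", "L", "R", "G")) {
    cods <- u3$codon[u3$aa == a]
    expect_equal(
      u3$fraction[u3$aa == a],
      as.numeric(cnt[cods] / sum(cnt[cods]))
    )
  }
})

test_that("codon content scales encode genetic-code arithmetic", {
  uni <- uniform_codon_usage()
  content <- codon_content_scale(uni, "PUR", orientation = "content")
  w <- stats::setNames(content$weight, content$aa)
  # raw content: Lys (AAA/AAG) = 1, Glu (GAA/GAG) = 1, Phe (TTT/TTC) = 0;
  # unit rescaling keeps these at the extremes
  expect_equal(unname(w["K"]), 1)
  expect_equal(unname(w["E"]), 1)
  expect_equal(unname(w["F"]), 0)
  aff <- codon_content_scale(uni, "PUR")
  wa <- stats::setNames(aff$weight, aff$aa)
  expect_equal(unname(wa["F"]), 1)
  expect_equal(unname(wa["K"]), 0)
  expect_equal(unname(wa["E"]), 0)
  # Met has the single codon ATG: raw PUR content 2/3 under any usage
  raw_met <- sum(c("A", "G") %in% c("A", "T", "G")) # sanity of the arithmetic
  expect_equal(raw_met, 2)
  ec <- codon_content_scale(ecoli_codon_usage(), "PUR", orientation = "content")
  uni_met <- oracle_raw_content(uni, "PUR")["M"]
  ec_met <- oracle_raw_content(ecoli_codon_usage(), "PUR")["M"]
  expect_equal(unname(uni_met), 2 / 3)
  expect_equal(unname(ec_met), 2 / 3)
  # Phe CYT content under uniform usage: (0 + 1/3) / 2
  expect_equal(
    unname(oracle_raw_content(uni, "CYT")["F"]), 1 / 6
  )
  # the two orientations are exact mirrors
  expect_equal(scale_correlation(aff, content), -1)
})

test_that("scale TSV round trip is exact and malformed files error", {
  set.seed(23)
  s <- affinity_scale(random_weights(), target = "GUA", provenance = "unit test")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_scale(s, path)
  s2 <- read_scale(path)
  expect_identical(s2$weight, s$weight)
  expect_equal(attr(s2, "target"), "GUA")
  lines <- readLines(path)
  writeLines(lines[-which(startsWith(lines, "W\t"))], path)
  expect_error(read_scale(path), "Missing")
  writeLines(c(lines, "X\t0.5"), path)
  expect_error(read_scale(path), "Non-canonical")
  writeLines(sub("^(A\t).*", "\\1abc", lines), path)
  expect_error(read_scale(path), "Non-numeric")
})

test_that("the AAindex reader recovers a known single index", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c(
    "H TEST0001",
    "D Synthetic test index",
    "I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V",
    "    0.1     0.2     0.3     0.4     0.5     0.6     0.7     0.8     0.9     1.0",
    "    1.1     1.2     1.3     1.4     1.5     1.6     1.7     1.8     1.9     2.0",
    "//"
  ), path)
  s <- read_aaindex(path)
  w <- stats::setNames(s$weight, s$aa)
  expect_equal(unname(w["A"]), 0.1)
  expect_equal(unname(w["I"]), 1.0)
  expect_equal(unname(w["L"]), 1.1)
  expect_equal(unname(w["Y"]), 2.0)
  expect_match(attr(s, "provenance"), "TEST0001")
  expect_error(read_aaindex(path, "MISSING"), "not found")
})

test_that("codon usage recovered from generated data matches the generator", {
  # >= 1e5 codons: 400 pairs x ~300 residues
  p <- fixture("usage_recovery_proteome", function() {
    generate_proteome(400, "lognormal:300,0.4",
      codon_usage = ecoli_codon_usage(), seed = 24
    )
  })
  u <- codon_usage_from(p)
  truth <- ecoli_codon_usage()
  m <- merge(as.data.frame(u), as.data.frame(truth), by = c("codon", "aa"))
  expect_true(all(abs(m$fraction.x - m$fraction.y) <= 0.02))
})

test_that("affinity-oriented codon scales give non-positive matching", {
  for (seed in 1:20) {
    p <- generate_proteome(8, c(40, 80),
      codon_usage = if (seed %% 2) "uniform" else ecoli_codon_usage(),
      aa_frequencies = if (seed %% 3) NULL else ecoli_aa_frequencies(),
      seed = 2000 + seed
    )
    u <- suppressWarnings(codon_usage_from(p))
    for (t in c("PUR", "ADE", "URA")) {
      s <- codon_content_scale(u, t)
      expect_lte(proteome_mean_R(p, s, t)$mean_R, 0)
    }
  }
})
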