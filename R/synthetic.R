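# Seeded synthetic proteomes: random codon sequences drawn from a codon
# usage table, translated by the standard genetic code.

.parse_length_dist <- function(x) {
  if (is.numeric(x) && length(x) == 1L) {
    return(list(kind = "fixed", L = as.integer(x)))
  }
  if (is.numeric(x) && length(x) == 2L) {
    return(list(kind = "uniform", min = as.integer(x[1]), max = as.integer(x[2])))
  }
  if (is.list(x) && !is.null(x$kind)) {
    return(x)
  }
  if (is.character(x) && length(x) == 1L) {
    parts <- strsplit(x, "[:,]")[[1]]
    kind <- parts[1]
    nums <- as.numeric(parts[-1])
    return(switch(kind,
      fixed = list(kind = "fixed", L = as.integer(nums[1])),
      uniform = list(kind = "uniform", min = as.integer(nums[1]), max = as.integer(nums[2])),
      lognormal = list(kind = "lognormal", mean = nums[1], sdlog = nums[2]),
      rlang::abort(paste0("Unknown length distribution: ", kind))
    ))
  }
  rlang::abort("Cannot parse `length_distribution`.")
}

.draw_lengths <- function(dist, n) {
  L <- switch(dist$kind,
    fixed = rep(dist$L, n),
    uniform = sample(dist$min:dist$max, n, replace = TRUE),
    lognormal = {
      # parameterized by the mean protein length and sdlog
      mu <- log(dist$mean) - dist$sdlog^2 / 2
      as.integer(round(stats::rlnorm(n, mu, dist$sdlog)))
    },
    rlang::abort(paste0("Unknown length distribution kind: ", dist$kind))
  )
  pmax(L, 22L)
}

#' Generate a synthetic proteome of cognate pairs
#'
#' For each pair: draw a protein length, draw residues i.i.d. from
#' `aa_frequencies`, draw each residue's codon from `codon_usage`
#' conditioned on that amino acid, and append a stop codon. Every generated
#' pair passes [validate_pairs()] with translation checking on, and the
#' result is bit-reproducible under `seed`. Residues are i.i.d. (no
#' positional autocorrelation), so any profile complementarity in the
#' output is driven purely by the genetic code and codon usage — the
#' correct null for end-to-end tests of the search machinery.
#'
#' @param n_pairs Number of pairs (>= 1).
#' @param length_distribution Protein length distribution: a single number
#'   (fixed length), `c(min, max)` (uniform), or a string such as
#'   `"lognormal:300,0.4"` (mean protein length and sdlog) /
#'   `"uniform:100,500"` / `"fixed:300"`. Lengths below 22 are clamped
#'   to 22.
#' @param codon_usage A [codon_usage()] table or `"uniform"`.
#' @param aa_frequencies Optional named 20-vector of residue frequencies
#'   (default uniform over the 20 amino acids); see
#'   [ecoli_aa_frequencies()] for an organism-like preset.
#' @param seed Integer seed (required).
#' @param organism Label stored on the result (default `"synthetic"`).
#' @return A `proteome` tibble.
#' @examples
#' generate_proteome(3, 50, seed = 1)
#' @export
generate_proteome <- function(n_pairs, length_distribution = "lognormal:300,0.4",
                              codon_usage = "uniform", aa_frequencies = NULL,
                              seed = NULL, organism = "synthetic") {
  stopifnot(n_pairs >= 1L)
  if (is.null(seed)) rlang::abort("An explicit integer `seed` is required.")
  dist <- .parse_length_dist(length_distribution)
  usage <- if (identical(codon_usage, "uniform")) {
    uniform_codon_usage()
  } else if (inherits(codon_usage, "codon_usage")) {
    codon_usage
  } else {
    codon_usage(codon_usage)
  }
  if (is.null(aa_frequencies)) {
    aa_frequencies <- stats::setNames(rep(1 / 20, 20), aa_letters)
  }
  aa_frequencies <- aa_frequencies[aa_letters]
  if (any(is.na(aa_frequencies)) || any(aa_frequencies < 0)) {
    rlang::abort("`aa_frequencies` must be a named non-negative 20-vector.")
  }
  aa_frequencies <- aa_frequencies / sum(aa_frequencies)
  codons_by_aa <- split(usage$codon, usage$aa)
  fracs_by_aa <- split(usage$fraction, usage$aa)
  withr::with_seed(as.integer(seed), {
    L <- .draw_lengths(dist, n_pairs)
    total <- sum(L)
    res <- sample(aa_letters, total, replace = TRUE, prob = aa_frequencies)
    cod <- character(total)
    for (a in unique(res)) {
      sel <- which(res == a)
      cod[sel] <- sample(codons_by_aa[[a]], length(sel),
        replace = TRUE, prob = fracs_by_aa[[a]]
      )
    }
    stops <- sample(.stop_codons, n_pairs, replace = TRUE)
    grp <- rep.int(seq_len(n_pairs), L)
    protein <- vapply(split(res, grp), paste, character(1), collapse = "")
    cds <- paste0(vapply(split(cod, grp), paste, character(1), collapse = ""), stops)
  })
  as_proteome(
    tibble::tibble(
      id = sprintf("syn%05d", seq_len(n_pairs)),
      cds = unname(cds), protein = unname(protein)
    ),
    organism = organism
  )
}

#' Sample random scales from the uniform null
#'
#' `n` scales whose 20 weights are i.i.d. uniform on `[0, 1]` — the null
#' ensemble shared by the significance test and baseline experiments. The
#' weight standard deviation of this null is `1/sqrt(12) ~ 0.29`.
#'
#' @param n Number of scales (>= 1).
#' @param seed Integer seed (required).
#' @return A tibble with one row per scale: column `scale_id` plus one
#'   column per amino acid. Use [affinity_scale()] on a row's weights, or
#'   `as.matrix()` on the weight columns.
#' @export
sample_random_scales <- function(n, seed = NULL) {
  stopifnot(n >= 1L)
  if (is.null(seed)) rlang::abort("An explicit integer `seed` is required.")
  M <- withr::with_seed(as.integer(seed), .sample_scale_matrix(as.integer(n)))
  dplyr::bind_cols(
    tibble::tibble(scale_id = seq_len(nrow(M))),
    tibble::as_tibble(M)
  )
}

# Approximate E. coli K-12 codon usage (per-1000 codon frequencies from a
# standard whole-genome tabulation, normalized within each amino-acid
# class). An organism-LIKE preset for synthetic data, not a measurement of
# any specific dataset.
.ecoli_per1000 <- c(
  TTT = 22.2, TTC = 16.6, TTA = 13.9, TTG = 13.7, CTT = 11.0, CTC = 11.0,
  CTA = 3.9, CTG = 52.6, ATT = 30.3, ATC = 25.1, ATA = 4.4, ATG = 27.9,
  GTT = 18.3, GTC = 15.3, GTA = 10.9, GTG = 26.4, TCT = 8.5, TCC = 8.6,
  TCA = 7.2, TCG = 8.9, CCT = 7.0, CCC = 5.5, CCA = 8.4, CCG = 23.2,
  ACT = 9.0, ACC = 23.4, ACA = 7.1, ACG = 14.4, GCT = 15.3, GCC = 25.5,
  GCA = 20.1, GCG = 33.6, TAT = 16.2, TAC = 12.2, CAT = 12.9, CAC = 9.7,
  CAA = 15.3, CAG = 28.8, AAT = 17.7, AAC = 21.7, AAA = 33.6, AAG = 10.3,
  GAT = 32.1, GAC = 19.1, GAA = 39.4, GAG = 17.8, TGT = 5.2, TGC = 6.4,
  TGG = 15.2, CGT = 20.9, CGC = 22.0, CGA = 3.6, CGG = 5.4, AGT = 8.8,
  AGC = 16.1, AGA = 2.1, AGG = 1.2, GGT = 24.7, GGC = 29.6, GGA = 8.0,
  GGG = 11.1
)

#' Approximate E. coli-like codon usage preset
#'
#' Relative synonymous codon usage resembling E. coli K-12 (derived from a
#' standard whole-genome per-1000 tabulation). A labeled organism-like
#' preset for [generate_proteome()]; for analyses of a real dataset compute
#' the usage from the data itself with [codon_usage_from()].
#'
#' @return A `codon_usage` tibble.
#' @export
ecoli_codon_usage <- function() {
  codon_usage(.ecoli_per1000)
}

#' Approximate E. coli-like amino-acid frequencies preset
#'
#' Residue frequencies implied by the same per-1000 codon tabulation as
#' [ecoli_codon_usage()]. A labeled organism-like preset, not a default.
#'
#' @return Named numeric 20-vector summing to 1.
#' @export
ecoli_aa_frequencies <- function() {
  aa <- unname(.codon2aa()[names(.ecoli_per1000)])
  f <- tapply(.ecoli_per1000, aa, sum)
  out <- f[aa_letters] / sum(f)
  stats::setNames(as.numeric(out), aa_letters)
}
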