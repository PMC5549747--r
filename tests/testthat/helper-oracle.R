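# Independent brute-force oracles: literal per-window counting over the
# raw character strings, no matrix machinery from the package.

oracle_target_bases <- list(
  URA = "T", CYT = "C", ADE = "A", GUA = "G",
  PUR = c("A", "G"), PYR = c("C", "T")
)

# fraction of target bases among the 3*window nucleotides of codons
# i..i+window-1, computed by direct counting over the literal string
oracle_mrna_profile <- function(cds, target, window = 21L) {
  L <- nchar(cds) / 3 - 1
  chars <- strsplit(substr(cds, 1, 3 * L), "")[[1]]
  bases <- oracle_target_bases[[target]]
  vapply(seq_len(L - window + 1), function(i) {
    win <- chars[(3 * (i - 1) + 1):(3 * (i - 1) + 3 * window)]
    sum(win %in% bases) / (3 * window)
  }, numeric(1))
}

# naive sliding-window mean of per-residue weights
oracle_protein_profile <- function(protein, weights, window = 21L) {
  res <- strsplit(protein, "")[[1]]
  L <- length(res)
  vapply(seq_len(L - window + 1), function(i) {
    mean(weights[res[i:(i + window - 1)]])
  }, numeric(1))
}

oracle_pearson <- function(x, y) {
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(0)
  stats::cor(x, y)
}

oracle_mean_R <- function(proteome, weights, target, window = 21L) {
  mean(vapply(seq_len(nrow(proteome)), function(i) {
    m <- oracle_mrna_profile(proteome$cds[i], target, window)
    p <- oracle_protein_profile(proteome$protein[i], weights, window)
    oracle_pearson(m, p)
  }, numeric(1)))
}

# single-pass codon counter independent of codon_usage_from()
oracle_codon_counts <- function(proteome) {
  counts <- table(factor(character(0), levels = names(Biostrings::GENETIC_CODE)))
  for (cds in proteome$cds) {
    n <- nchar(cds)
    cod <- substring(cds, seq(1, n, 3), seq(3, n, 3))
    counts <- counts + table(factor(cod, levels = names(counts)))
  }
  counts
}

# flat clusters for single linkage: connected components of the graph with
# an edge wherever distance <= cutoff (transitive closure by sweep)
oracle_single_linkage_components <- function(D, cutoff) {
  n <- nrow(D)
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        if (D[i, j] <= cutoff && comp[i] != comp[j]) {
          comp[comp == comp[j]] <- comp[i]
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  length(unique(comp))
}

random_weights <- function() stats::setNames(stats::runif(20), scalescape::aa_letters)

# usage-weighted mean target-base fraction per amino acid (raw content)
oracle_raw_content <- function(usage, target) {
  bases <- oracle_target_bases[[target]]
  frac <- vapply(strsplit(usage$codon, ""), function(ch) sum(ch %in% bases) / 3,
    numeric(1)
  )
  tapply(usage$fraction * frac, usage$aa, sum)
}
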