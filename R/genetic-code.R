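# Alphabets and the standard genetic code (table from Biostrings).

#' The twenty canonical amino acids
#'
#' One-letter codes of the canonical amino acids, in alphabetical order.
#' This ordering is used for every weight vector and matrix column in the
#' package.
#'
#' @format Character vector of length 20.
#' @export
aa_letters <- c(
  "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"
)

.nucleotides <- c("A", "C", "G", "T")
.stop_codons <- c("TAA", "TAG", "TGA")

# target -> set of counted bases (DNA alphabet; U normalized to T on input)
.target_bases <- list(
  URA = "T", CYT = "C", ADE = "A", GUA = "G", PUR = c("A", "G")
)

#' Nucleobase targets
#'
#' The five nucleobase targets a scale can be optimized for: the four RNA
#' bases (URA, CYT, ADE, GUA) and PUR (adenine + guanine together). The
#' pyrimidine density is always `1 - PUR` density and is therefore exposed
#' only through [pyr_density_profile()], never as a search target.
#'
#' @format Character vector of length 5.
#' @export
nucleobase_targets <- names(.target_bases)

.check_target <- function(target) {
  target <- toupper(target)
  if (length(target) != 1L || !target %in% nucleobase_targets) {
    rlang::abort(paste0(
      "`target` must be one of ", paste(nucleobase_targets, collapse = ", "),
      " (PYR is available only via pyr_density_profile())."
    ))
  }
  target
}

#' Codon table of the standard genetic code
#'
#' @return A tibble with columns `codon` (DNA alphabet) and `aa` (one-letter
#'   amino-acid code, `"*"` for the three stop codons).
#' @examples
#' codon_table()
#' @export
codon_table <- function() {
  gc <- Biostrings::GENETIC_CODE
  tibble::tibble(codon = names(gc), aa = unname(gc))
}

# 61 sense codons in fixed order
.sense_codons <- function() {
  ct <- codon_table()
  ct$codon[ct$aa != "*"]
}

# named character: sense codon -> amino acid
.codon2aa <- function() {
  gc <- Biostrings::GENETIC_CODE
  gc[gc != "*"]
}

# split one CDS string into codons (no validation)
.codons_of <- function(cds) {
  n <- nchar(cds)
  substring(cds, seq.int(1L, n - 2L, by = 3L), seq.int(3L, n, by = 3L))
}

.normalize_nt <- function(x) {
  chartr("u", "T", chartr("U", "T", toupper(x)))
}

.is_canonical_cds <- function(x) {
  !grepl("[^ACGT]", x)
}

.is_canonical_protein <- function(x) {
  !grepl(paste0("[^", paste(aa_letters, collapse = ""), "]"), x)
}

#' Translate coding sequences with the standard genetic code
#'
#' Translates each coding sequence codon by codon. A single trailing stop
#' codon is allowed and excluded from the returned protein; a stop codon in
#' any other position is an error.
#'
#' @param cds Character vector of nucleotide sequences (`U` is accepted and
#'   normalized to `T`). Each length must be divisible by 3.
#' @return Character vector of amino-acid sequences.
#' @examples
#' translate_cds("ATGTAA")
#' translate_cds("AAAGAATAA")
#' @export
translate_cds <- function(cds) {
  vapply(cds, .translate_one, character(1), USE.NAMES = FALSE)
}

.translate_one <- function(cds) {
  cds <- .normalize_nt(cds)
  n <- nchar(cds)
  if (n == 0L || n %% 3L != 0L) {
    rlang::abort("CDS length must be a positive multiple of 3.")
  }
  if (!.is_canonical_cds(cds)) {
    rlang::abort("CDS contains non-canonical nucleotides.")
  }
  aa <- unname(Biostrings::GENETIC_CODE[.codons_of(cds)])
  k <- length(aa)
  if (aa[k] == "*") aa <- aa[-k]
  if (any(aa == "*")) {
    rlang::abort("CDS contains an internal stop codon.")
  }
  paste(aa, collapse = "")
}
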