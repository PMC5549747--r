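# Affinity scales: construction, unit rescaling, codon-content reference
# scales, comparison, and TSV / AAindex IO.

#' Construct an affinity scale
#'
#' An affinity scale assigns one finite weight to each of the 20 canonical
#' amino acids for a given nucleobase target. By the binding-free-energy
#' convention low weights mean strong affinity, so well-matching scales
#' yield negative proteome correlations. Scales are stored as tibbles with
#' columns `aa` and `weight`, ordered as [aa_letters].
#'
#' @param weights Named numeric vector (names = amino-acid letters) or a
#'   data frame with columns `aa` and `weight`. Exactly the 20 canonical
#'   amino acids, all weights finite.
#' @param target Optional nucleobase target label the scale refers to.
#' @param provenance Optional free-text provenance.
#' @return An `affinity_scale` tibble.
#' @examples
#' affinity_scale(stats::setNames(seq(0, 1, length.out = 20), aa_letters))
#' @export
affinity_scale <- function(weights, target = NULL, provenance = NULL) {
  if (is.data.frame(weights)) {
    if (!all(c("aa", "weight") %in% names(weights))) {
      rlang::abort("A scale data frame needs columns `aa` and `weight`.")
    }
    target <- target %||% attr(weights, "target")
    provenance <- provenance %||% attr(weights, "provenance")
    weights <- stats::setNames(weights$weight, weights$aa)
  }
  if (is.null(names(weights))) rlang::abort("Weights must be named by amino acid.")
  names(weights) <- toupper(names(weights))
  extra <- setdiff(names(weights), aa_letters)
  if (length(extra)) {
    rlang::abort(paste0("Non-canonical amino acid(s): ", paste(extra, collapse = ", ")))
  }
  if (anyDuplicated(names(weights))) rlang::abort("Duplicated amino acids in scale.")
  miss <- setdiff(aa_letters, names(weights))
  if (length(miss)) {
    rlang::abort(paste0("Missing amino acid(s): ", paste(miss, collapse = ", ")))
  }
  weights <- weights[aa_letters]
  if (!all(is.finite(weights))) rlang::abort("All 20 weights must be finite.")
  structure(
    tibble::tibble(aa = aa_letters, weight = unname(as.numeric(weights))),
    target = if (!is.null(target)) .check_target(target),
    provenance = provenance,
    class = c("affinity_scale", class(tibble::tibble()))
  )
}

# named weight vector in aa_letters order from scale-like input
.weights <- function(scale) {
  if (inherits(scale, "affinity_scale") || is.data.frame(scale)) {
    scale <- affinity_scale(scale)
    return(stats::setNames(scale$weight, scale$aa))
  }
  if (is.numeric(scale) && length(scale) == 20L) {
    if (is.null(names(scale))) names(scale) <- aa_letters
    s <- affinity_scale(scale)
    return(stats::setNames(s$weight, s$aa))
  }
  rlang::abort("Expected an affinity_scale, a 20-row data frame or a named 20-vector.")
}

#' @export
print.affinity_scale <- function(x, ...) {
  tg <- attr(x, "target")
  pv <- attr(x, "provenance")
  cat(
    "# affinity_scale",
    if (!is.null(tg)) paste0(" [", tg, "]"),
    if (isTRUE(attr(x, "degenerate"))) " (degenerate)",
    if (!is.null(pv)) paste0(": ", pv),
    "\n",
    sep = ""
  )
  NextMethod()
}

#' Rescale a scale to the unit interval
#'
#' Linearly maps the weights so the lowest becomes 0 and the highest 1.
#' Windowing and Pearson correlation are invariant under this map, so the
#' rescaled scale is the canonical representative of its equivalence class;
#' it is applied to every reported scale so that truly different scales can
#' be told apart from rescaled copies. An all-equal scale has no such map
#' and is returned as all 0.5 with attribute `degenerate = TRUE`.
#'
#' @param scale An [affinity_scale()] (or named weight vector).
#' @return A unit-rescaled `affinity_scale`.
#' @export
rescale_unit <- function(scale) {
  w <- .weights(scale)
  rng <- range(w)
  span <- rng[2] - rng[1]
  degenerate <- span <= 1e-15 * max(1, abs(rng[2]), abs(rng[1]))
  out <- affinity_scale(
    if (degenerate) stats::setNames(rep(0.5, 20), names(w)) else (w - rng[1]) / span,
    target = if (is.data.frame(scale)) attr(scale, "target"),
    provenance = if (is.data.frame(scale)) attr(scale, "provenance")
  )
  attr(out, "degenerate") <- degenerate
  out
}

#' Pearson correlation between two scales
#'
#' Correlation over the 20 paired weights, amino acids matched by letter.
#' A zero-variance (degenerate) scale yields 0, the same convention used
#' for constant profiles.
#'
#' @param s1,s2 Affinity scales (or named weight vectors).
#' @return A number in `[-1, 1]`.
#' @export
scale_correlation <- function(s1, s2) {
  pair_correlation(.weights(s1), .weights(s2))
}

#' Codon usage table
#'
#' Relative codon frequencies within each amino-acid class (61 sense
#' codons; the three stop codons are excluded). For every amino acid the
#' fractions of its codons sum to 1.
#'
#' @param fractions Named numeric vector over the 61 sense codons, or a
#'   data frame with columns `codon` and `fraction`. Values are normalized
#'   within each amino-acid class.
#' @return A `codon_usage` tibble with columns `codon`, `aa`, `fraction`.
#' @export
codon_usage <- function(fractions) {
  if (is.data.frame(fractions)) {
    fractions <- stats::setNames(fractions$fraction, fractions$codon)
  }
  sense <- .sense_codons()
  names(fractions) <- .normalize_nt(names(fractions))
  miss <- setdiff(sense, names(fractions))
  if (length(miss)) {
    rlang::abort(paste0("Missing sense codon(s): ", paste(utils::head(miss, 5), collapse = ", ")))
  }
  fractions <- fractions[sense]
  if (any(!is.finite(fractions) | fractions < 0)) {
    rlang::abort("Codon fractions must be finite and non-negative.")
  }
  aa <- unname(.codon2aa()[sense])
  out <- tibble::tibble(codon = sense, aa = aa, fraction = unname(fractions))
  sums <- tapply(out$fraction, out$aa, sum)
  if (any(sums == 0)) {
    rlang::abort(paste0(
      "Amino acid(s) with all-zero codon usage: ",
      paste(names(sums)[sums == 0], collapse = ", ")
    ))
  }
  out$fraction <- as.numeric(out$fraction / sums[out$aa])
  structure(out, class = c("codon_usage", class(tibble::tibble())))
}

#' Uniform codon usage
#'
#' Equal usage of every synonymous codon within each amino-acid class.
#'
#' @return A `codon_usage` tibble.
#' @export
uniform_codon_usage <- function() {
  codon_usage(stats::setNames(rep(1, 61), .sense_codons()))
}

#' Codon usage observed in a dataset
#'
#' Counts all sense codons in all coding sequences of the proteome (stop
#' codons excluded) and normalizes within each amino-acid class. Organism-
#' specific usage computed from the analyzed CDS themselves is what shapes
#' the organism-specific optimal scales. Amino acids absent from the data
#' get uniform usage, with a warning.
#'
#' @param proteome A `proteome` tibble.
#' @return A `codon_usage` tibble.
#' @export
codon_usage_from <- function(proteome) {
  proteome <- as_proteome(proteome)
  sense <- .sense_codons()
  counts <- integer(length(sense))
  names(counts) <- sense
  for (cds in proteome$cds) {
    cod <- .codons_of(cds)
    cod <- cod[!cod %in% .stop_codons]
    tab <- table(factor(cod, levels = sense))
    counts <- counts + as.integer(tab)
  }
  aa <- .codon2aa()[sense]
  present <- tapply(counts, aa, sum) > 0
  if (any(!present)) {
    rlang::warn(paste0(
      "Amino acid(s) absent from dataset get uniform usage: ",
      paste(names(present)[!present], collapse = ", ")
    ))
    for (a in names(present)[!present]) counts[aa == a] <- 1L
  }
  codon_usage(stats::setNames(as.numeric(counts), sense))
}

#' Genetic-code-derived nucleobase-content scale
#'
#' The reference scale determined by the genetic code and codon usage: for
#' each amino acid, the usage-weighted mean fraction of the target base in
#' its codons. With `orientation = "affinity"` (default) the content is
#' negated before unit rescaling, so amino acids encoded by target-rich
#' codons get low weights and the proteome correlation of the scale is
#' negative, following the binding-affinity sign convention; `"content"`
#' returns the plain fraction. The two orientations are exact affine
#' mirrors (scale correlation -1).
#'
#' @param usage A [codon_usage()] table (e.g. [uniform_codon_usage()] or
#'   [codon_usage_from()]).
#' @param target Nucleobase target.
#' @param orientation `"affinity"` (default) or `"content"`.
#' @return A unit-rescaled `affinity_scale`.
#' @examples
#' codon_content_scale(uniform_codon_usage(), "PUR")
#' @export
codon_content_scale <- function(usage, target = "PUR",
                                orientation = c("affinity", "content")) {
  orientation <- match.arg(orientation)
  target <- .check_target(target)
  if (!inherits(usage, "codon_usage")) usage <- codon_usage(usage)
  bases <- .target_bases[[target]]
  frac <- vapply(strsplit(usage$codon, "", fixed = TRUE),
    function(ch) sum(ch %in% bases) / 3, numeric(1)
  )
  content <- tapply(usage$fraction * frac, usage$aa, sum)
  raw <- if (orientation == "affinity") -content else content
  rescale_unit(affinity_scale(raw[aa_letters],
    target = target,
    provenance = paste0("codon ", target, "-content scale (", orientation, ")")
  ))
}

#' Read and write affinity scales as TSV
#'
#' Two tab-separated columns `aa` and `weight`, preceded by one `#` header
#' line carrying the target and provenance. Weights survive a write/read
#' round trip exactly.
#'
#' @param path File path.
#' @param scale An [affinity_scale()].
#' @return `read_scale()` returns an `affinity_scale`; `write_scale()`
#'   returns `scale` invisibly.
#' @export
read_scale <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  target <- NULL
  provenance <- NULL
  if (length(hdr)) {
    m <- regmatches(hdr[1], regexec("target=([A-Za-z]+)", hdr[1]))[[1]]
    if (length(m) == 2 && toupper(m[2]) %in% nucleobase_targets) target <- m[2]
    p <- regmatches(hdr[1], regexec("provenance=(.*)$", hdr[1]))[[1]]
    if (length(p) == 2) provenance <- trimws(p[2])
  }
  if (length(body) && identical(tolower(strsplit(body[1], "\t")[[1]][1]), "aa")) {
    body <- body[-1]
  }
  fields <- strsplit(body, "[\t ]+")
  if (any(lengths(fields) < 2L)) rlang::abort("Malformed scale file.")
  aa <- vapply(fields, `[`, "", 1L)
  wt <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 2L)))
  if (any(is.na(wt))) rlang::abort("Non-numeric weight in scale file.")
  affinity_scale(stats::setNames(wt, aa), target = target, provenance = provenance)
}

#' @rdname read_scale
#' @export
write_scale <- function(scale, path) {
  scale <- affinity_scale(scale)
  hdr <- paste0(
    "# affinity scale",
    if (!is.null(attr(scale, "target"))) paste0(" target=", attr(scale, "target")),
    if (!is.null(attr(scale, "provenance"))) paste0(" provenance=", attr(scale, "provenance"))
  )
  writeLines(
    c(hdr, "aa\tweight", paste0(scale$aa, "\t", sprintf("%.17g", scale$weight))),
    path
  )
  invisible(scale)
}

# AAindex1 column order of the two I-record value rows
.aaindex_order <- c(
  "A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
  "L", "K", "M", "F", "P", "S", "T", "W", "V", "Y"
)

#' Read one index from an AAindex1-format file
#'
#' Minimal reader for the AAindex1 flat-file format (`H` accession line,
#' `D` description, `I` line followed by two rows of ten values) so that
#' published single-property scales can be compared against optimized ones.
#'
#' @param path Path to an AAindex1-format file.
#' @param accession Accession to extract; default: the first entry.
#' @return An `affinity_scale` with the accession and description recorded
#'   as provenance.
#' @export
read_aaindex <- function(path, accession = NULL) {
  lines <- readLines(path, warn = FALSE)
  h <- which(startsWith(lines, "H "))
  if (!length(h)) rlang::abort("No AAindex entries (H lines) found.")
  acc <- trimws(sub("^H ", "", lines[h]))
  pick <- if (is.null(accession)) 1L else match(accession, acc)
  if (is.na(pick)) rlang::abort(paste0("Accession not found: ", accession))
  end <- c(h[-1] - 1L, length(lines))
  block <- lines[h[pick]:end[pick]]
  d <- block[startsWith(block, "D ")]
  i_line <- which(startsWith(block, "I "))
  if (!length(i_line) || length(block) < i_line + 2L) {
    rlang::abort("Malformed AAindex entry: missing I record.")
  }
  vals <- suppressWarnings(as.numeric(unlist(
    strsplit(trimws(block[i_line + 1:2]), "[[:space:]]+")
  )))
  if (length(vals) != 20L || any(is.na(vals))) {
    rlang::abort("AAindex entry does not contain 20 numeric values (NA not supported).")
  }
  affinity_scale(stats::setNames(vals, .aaindex_order),
    provenance = paste0(acc[pick], if (length(d)) paste0(": ", trimws(sub("^D ", "", d[1]))))
  )
}
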