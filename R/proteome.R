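# Paired CDS/protein datasets: validation, FASTA and space-separated IO.

#' Assemble a proteome of cognate CDS/protein pairs
#'
#' A proteome is a tibble with one row per cognate pair and columns `id`,
#' `cds` and `protein`. Construction enforces the pair invariants: the CDS
#' is `3 * protein length + 3` nucleotides long (trailing stop codon
#' present), both sequences use only canonical characters, the protein has
#' at least `min_protein_length` residues, and ids are unique. Invalid rows
#' are a hard error here; use [read_proteome()] to filter instead.
#'
#' @param data Data frame with character columns `id`, `cds`, `protein`.
#' @param organism Optional organism label, stored as an attribute.
#' @param min_protein_length Minimum protein length. The default 22 is the
#'   shortest protein giving a 2-point windowed profile.
#' @return A `proteome` tibble.
#' @examples
#' as_proteome(data.frame(
#'   id = "p1", cds = paste0(strrep("AAA", 22), "TAA"),
#'   protein = strrep("K", 22)
#' ))
#' @export
as_proteome <- function(data, organism = NULL, min_protein_length = 22L) {
  stopifnot(is.data.frame(data))
  if (!all(c("id", "cds", "protein") %in% names(data))) {
    rlang::abort("`data` must have columns `id`, `cds` and `protein`.")
  }
  out <- tibble::as_tibble(data[c("id", "cds", "protein")])
  out$id <- as.character(out$id)
  out$cds <- .normalize_nt(out$cds)
  out$protein <- toupper(out$protein)
  if (nrow(out) == 0L) rlang::abort("A proteome must contain at least one pair.")
  if (anyDuplicated(out$id)) {
    dup <- unique(out$id[duplicated(out$id)])
    rlang::abort(paste0(
      "Duplicate pair ids: ", paste(utils::head(dup, 5), collapse = ", ")
    ))
  }
  rep <- validate_pairs(out, min_protein_length = min_protein_length)
  if (!all(rep$valid)) {
    bad <- rep[!rep$valid, ]
    rlang::abort(paste0(
      sum(!rep$valid), " pair(s) violate the proteome invariants (first: id=",
      bad$id[1], ", reason=", bad$reason[1], ")."
    ))
  }
  structure(out,
    organism = organism %||% attr(data, "organism"),
    class = c("proteome", class(tibble::tibble()))
  )
}

#' Validate cognate CDS/protein pairs
#'
#' Checks each pair against the dataset rules: canonical alphabets, the
#' length rule `length(cds) = 3 * length(protein) + 3` (trailing stop codon
#' present), a minimum protein length, and optionally agreement between the
#' standard-genetic-code translation of the CDS and the stated protein.
#' Selection by the length rule alone (the default) mirrors how the
#' reference datasets were assembled; translation checking is stricter.
#'
#' @param data Data frame with columns `id`, `cds`, `protein`, or a single
#'   CDS string (then `protein` must be given).
#' @param protein Protein string when `data` is a single CDS string.
#' @param check_translation Also require that the CDS translates to
#'   `protein`? Default `FALSE`.
#' @param min_protein_length Minimum protein length (default 22).
#' @return A tibble with columns `id`, `valid` (logical) and `reason`
#'   (`"ok"`, `"non_canonical_cds"`, `"non_canonical_protein"`,
#'   `"length_rule"`, `"too_short"`, `"translation_mismatch"`).
#' @examples
#' validate_pairs(paste0(strrep("AAA", 21), "TAA"), strrep("K", 21),
#'   check_translation = TRUE
#' )
#' @export
validate_pairs <- function(data, protein = NULL, check_translation = FALSE,
                           min_protein_length = 22L) {
  if (is.character(data) && !is.null(protein)) {
    data <- tibble::tibble(id = "pair", cds = data, protein = protein)
  }
  stopifnot(is.data.frame(data))
  cds <- .normalize_nt(as.character(data$cds))
  prot <- toupper(as.character(data$protein))
  reason <- rep("ok", nrow(data))
  reason[nchar(cds) != 3L * nchar(prot) + 3L] <- "length_rule"
  reason[reason == "ok" & nchar(prot) < min_protein_length] <- "too_short"
  reason[!.is_canonical_protein(prot)] <- "non_canonical_protein"
  reason[!.is_canonical_cds(cds)] <- "non_canonical_cds"
  if (check_translation) {
    ok <- reason == "ok"
    tr <- vapply(which(ok), function(i) {
      tryCatch(.translate_one(substr(cds[i], 1L, 3L * nchar(prot[i]))),
        error = function(e) NA_character_
      )
    }, character(1))
    mismatch <- is.na(tr) | tr != prot[ok]
    reason[which(ok)[mismatch]] <- "translation_mismatch"
  }
  tibble::tibble(
    id = as.character(data$id),
    valid = reason == "ok",
    reason = reason
  )
}

#' @rdname validate_pairs
#' @param cds CDS string (single-pair convenience form).
#' @export
validate_pair <- function(cds, protein, check_translation = FALSE,
                          min_protein_length = 22L) {
  validate_pairs(cds, protein,
    check_translation = check_translation,
    min_protein_length = min_protein_length
  )
}

#' Read a paired CDS/protein dataset
#'
#' Reads either the space-separated dialect (one record per line:
#' `id cds protein`; extra columns are ignored with a warning) or a pair of
#' FASTA files (CDS and protein, matched by identical record ids). `U` is
#' normalized to `T` on input. Records failing the pair invariants are
#' dropped and the rejection counts are reported per reason.
#'
#' @param path Path to the space-separated file, or to the CDS FASTA when
#'   `protein_path` is given.
#' @param protein_path Path to the protein FASTA (FASTA-pair format only).
#' @param format `"s1"` (space-separated) or `"fasta"`; inferred from
#'   `protein_path` when `"auto"`.
#' @param min_protein_length,check_translation Passed to [validate_pairs()].
#' @param organism Optional organism label.
#' @param quiet Suppress the per-reason rejection report?
#' @return A `proteome` tibble (see [as_proteome()]).
#' @export
read_proteome <- function(path, protein_path = NULL,
                          format = c("auto", "s1", "fasta"),
                          min_protein_length = 22L, check_translation = FALSE,
                          organism = NULL, quiet = FALSE) {
  format <- match.arg(format)
  if (format == "auto") format <- if (is.null(protein_path)) "s1" else "fasta"
  if (!file.exists(path)) rlang::abort(paste0("File not found: ", path))
  if (format == "s1") {
    raw <- .read_s1(path)
  } else {
    if (is.null(protein_path) || !file.exists(protein_path)) {
      rlang::abort("FASTA-pair format needs an existing `protein_path`.")
    }
    raw <- .read_fasta_pair(path, protein_path)
  }
  if (anyDuplicated(raw$id)) {
    dup <- unique(raw$id[duplicated(raw$id)])
    rlang::abort(paste0(
      "Duplicate record ids in input: ", paste(utils::head(dup, 5), collapse = ", ")
    ))
  }
  raw$cds <- .normalize_nt(raw$cds)
  raw$protein <- toupper(raw$protein)
  rep <- validate_pairs(raw,
    check_translation = check_translation,
    min_protein_length = min_protein_length
  )
  if (!quiet && any(!rep$valid)) {
    tab <- table(rep$reason[!rep$valid])
    rlang::inform(paste0(
      "Dropped ", sum(!rep$valid), "/", nrow(raw), " record(s): ",
      paste(names(tab), tab, sep = "=", collapse = ", ")
    ))
  }
  kept <- raw[rep$valid, ]
  if (nrow(kept) == 0L) rlang::abort("No valid pairs in the dataset.")
  as_proteome(kept, organism = organism, min_protein_length = min_protein_length)
}

.read_s1 <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) rlang::abort("Empty dataset file.")
  fields <- strsplit(trimws(lines), "[[:space:]]+")
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    rlang::abort(paste0(
      "Line ", which(nf < 3L)[1], " has fewer than 3 whitespace-separated fields."
    ))
  }
  if (any(nf > 3L)) {
    rlang::warn(paste0(
      sum(nf > 3L), " line(s) carry extra columns; columns beyond `id cds protein` ignored."
    ))
  }
  tibble::tibble(
    id = vapply(fields, `[`, "", 1L),
    cds = vapply(fields, `[`, "", 2L),
    protein = vapply(fields, `[`, "", 3L)
  )
}

.read_fasta_pair <- function(cds_path, protein_path) {
  cds <- Biostrings::readBStringSet(cds_path)
  prot <- Biostrings::readBStringSet(protein_path)
  cid <- sub("\\s.*$", "", names(cds))
  pid <- sub("\\s.*$", "", names(prot))
  names(cds) <- cid
  names(prot) <- pid
  missing <- c(setdiff(cid, pid), setdiff(pid, cid))
  if (length(missing)) {
    rlang::abort(paste0(
      "CDS and protein FASTA id sets differ (e.g. ",
      paste(utils::head(missing, 5), collapse = ", "), ")."
    ))
  }
  tibble::tibble(
    id = cid,
    cds = unname(as.character(cds)),
    protein = unname(as.character(prot[cid]))
  )
}

#' Write a paired dataset
#'
#' Inverse of [read_proteome()]: writes either the space-separated dialect
#' or a FASTA pair. Reading the written file(s) back reproduces the
#' proteome exactly (CDS are written in the DNA alphabet).
#'
#' @param proteome A `proteome` tibble.
#' @param path Output path (space-separated), or CDS FASTA path.
#' @param protein_path Protein FASTA path (FASTA-pair format only).
#' @param format `"auto"`, `"s1"` or `"fasta"`.
#' @return `proteome`, invisibly.
#' @export
write_proteome <- function(proteome, path, protein_path = NULL,
                           format = c("auto", "s1", "fasta")) {
  proteome <- as_proteome(proteome)
  format <- match.arg(format)
  if (format == "auto") format <- if (is.null(protein_path)) "s1" else "fasta"
  if (format == "s1") {
    writeLines(paste(proteome$id, proteome$cds, proteome$protein), path)
  } else {
    if (is.null(protein_path)) {
      rlang::abort("FASTA-pair format needs a `protein_path`.")
    }
    cds <- Biostrings::DNAStringSet(stats::setNames(proteome$cds, proteome$id))
    prot <- Biostrings::AAStringSet(stats::setNames(proteome$protein, proteome$id))
    Biostrings::writeXStringSet(cds, path)
    Biostrings::writeXStringSet(prot, protein_path)
  }
  invisible(proteome)
}

#' @export
print.proteome <- function(x, ...) {
  org <- attr(x, "organism")
  cat(
    "# proteome: ", nrow(x), " cognate pair(s)",
    if (!is.null(org)) paste0(" [", org, "]"), "\n",
    sep = ""
  )
  NextMethod()
}
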