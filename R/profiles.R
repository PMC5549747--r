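# Windowed sequence profiles and the proteome-average Pearson fitness.
#
# Both profiles are evaluated at codon/residue resolution with full windows
# only: entry i of an mRNA profile is the fraction of target bases among the
# 63 nucleotides of codons i..i+20, entry i of a protein profile is the mean
# scale weight over residues i..i+20, so for a protein of length L both
# vectors have length L - 20 and are in exact register.

# relative variance threshold below which a profile counts as constant
# (well above the cancellation noise of the cached quadratic form, well
# below any genuine windowed-profile variance)
.zero_var_tol <- 1e-12

.cds_protein_length <- function(cds) {
  n <- nchar(cds)
  if (n %% 3L != 0L) rlang::abort("CDS length must be a multiple of 3.")
  n %/% 3L - 1L
}

#' mRNA nucleobase-density profile
#'
#' Window-averaged density of a nucleobase target along a coding sequence,
#' evaluated per codon: entry i is the fraction of target bases among the
#' `3 * window` nucleotides of codons i..i+window-1. The trailing stop codon
#' is excluded, and only full windows are used, so a CDS encoding L residues
#' yields `L - window + 1` points.
#'
#' @param cds Coding sequence (canonical nucleotides, trailing stop codon).
#' @param target One of `r paste(nucleobase_targets, collapse = ", ")`.
#' @param window Smoothing window in codons (default 21, i.e. 63 nt).
#' @return Numeric vector with values in `[0, 1]`.
#' @examples
#' mrna_density_profile(paste0(strrep("AAG", 25), "TAA"), "PUR")
#' @export
mrna_density_profile <- function(cds, target = "PUR", window = 21L) {
  target <- .check_target(target)
  cds <- .normalize_nt(cds)
  if (!.is_canonical_cds(cds)) rlang::abort("CDS contains non-canonical nucleotides.")
  L <- .cds_protein_length(cds)
  if (L < window) {
    rlang::abort(paste0("Protein length ", L, " < window ", window, ": no full window."))
  }
  chars <- strsplit(substr(cds, 1L, 3L * L), "", fixed = TRUE)[[1]]
  per_codon <- colSums(matrix(chars %in% .target_bases[[target]], nrow = 3L))
  .rolling_sum(per_codon, window) / (3 * window)
}

#' Pyrimidine-density profile
#'
#' The pyrimidine fraction of any window is one minus its purine fraction,
#' so PYR is never a search target; this helper returns
#' `1 - mrna_density_profile(cds, "PUR")`.
#'
#' @inheritParams mrna_density_profile
#' @return Numeric vector with values in `[0, 1]`.
#' @export
pyr_density_profile <- function(cds, window = 21L) {
  1 - mrna_density_profile(cds, "PUR", window = window)
}

# rolling sum over full windows via cumulative sums
.rolling_sum <- function(x, window) {
  cs <- c(0, cumsum(x))
  n <- length(x)
  cs[(window + 1L):(n + 1L)] - cs[1:(n - window + 1L)]
}

#' Windowed amino-acid composition matrix
#'
#' Row i holds the frequencies of the 20 amino acids among residues
#' i..i+window-1, so each row sums to 1 and the windowed profile of any
#' weight scale `w` is simply `matrix %*% w`. This factorization of
#' weighting from smoothing is what makes repeated scale evaluation cheap.
#'
#' @param protein Amino-acid sequence (canonical letters, length >= window + 1).
#' @param window Smoothing window in residues (default 21).
#' @return Numeric matrix of shape `(L - window + 1) x 20`, columns in
#'   [aa_letters] order.
#' @export
protein_window_matrix <- function(protein, window = 21L) {
  protein <- toupper(protein)
  if (!.is_canonical_protein(protein)) {
    rlang::abort("Protein contains non-canonical amino acids.")
  }
  L <- nchar(protein)
  if (L < window) {
    rlang::abort(paste0("Protein length ", L, " < window ", window, ": no full window."))
  }
  idx <- match(strsplit(protein, "", fixed = TRUE)[[1]], aa_letters)
  M <- matrix(0, nrow = L, ncol = 20L, dimnames = list(NULL, aa_letters))
  M[cbind(seq_len(L), idx)] <- 1
  cs <- rbind(0, apply(M, 2L, cumsum))
  (cs[(window + 1L):(L + 1L), , drop = FALSE] -
    cs[1:(L - window + 1L), , drop = FALSE]) / window
}

#' Scale-weighted protein affinity profile
#'
#' Window-averaged per-residue weights of a protein under an affinity
#' scale: the sliding mean of `scale[residue]` over `window` residues.
#'
#' @param protein Amino-acid sequence, or a matrix from
#'   [protein_window_matrix()].
#' @param scale An [affinity_scale()] (or named weight vector).
#' @param window Smoothing window in residues (ignored when `protein` is
#'   already a window matrix).
#' @return Numeric vector of length `L - window + 1`.
#' @export
protein_profile <- function(protein, scale, window = 21L) {
  w <- .weights(scale)
  W <- if (is.matrix(protein)) protein else protein_window_matrix(protein, window)
  drop(W %*% w)
}

#' Pearson correlation between two profiles
#'
#' Plain Pearson R with one convention on top: if either profile is
#' constant (zero variance, e.g. a protein profile under a uniform scale)
#' the correlation is undefined and 0 ("no matching") is returned.
#'
#' @param x,y Numeric vectors of equal length >= 2.
#' @return A number in `[-1, 1]`.
#' @examples
#' pair_correlation(c(1, 2, 3), c(3, 2, 1))
#' pair_correlation(c(1, 2, 3), c(5, 5, 5))
#' @export
pair_correlation <- function(x, y) {
  if (length(x) != length(y)) rlang::abort("Profiles have different lengths.")
  if (length(x) < 2L) rlang::abort("Profiles need at least 2 points.")
  xc <- x - mean(x)
  yc <- y - mean(y)
  sx2 <- sum(xc^2)
  sy2 <- sum(yc^2)
  if (sx2 <= .zero_var_tol * max(1, sum(x^2)) ||
    sy2 <= .zero_var_tol * max(1, sum(y^2))) {
    return(0)
  }
  sum(xc * yc) / sqrt(sx2 * sy2)
}

#' Precompute profiles for fast repeated scale evaluation
#'
#' Builds, per pair, the sufficient statistics that reduce the
#' proteome-average fitness of any candidate scale `w` to two matrix-vector
#' products: the centered cross-products of the mRNA density profile with
#' the windowed composition matrix, and the centered Gram matrix of the
#' composition windows. Evaluating a scale through the cache is equivalent
#' to from-scratch evaluation to near machine precision.
#'
#' @param proteome A `proteome` tibble.
#' @param targets Nucleobase targets to precompute (default all five).
#' @param window Smoothing window in codons/residues (default 21).
#' @return A `profile_cache` object.
#' @export
profile_cache <- function(proteome, targets = nucleobase_targets, window = 21L) {
  proteome <- as_proteome(proteome, min_protein_length = window + 1L)
  targets <- vapply(targets, .check_target, character(1), USE.NAMES = FALSE)
  n <- nrow(proteome)
  Q <- matrix(0, n, 400L)
  Wbar <- matrix(0, n, 20L)
  n_windows <- integer(n)
  A <- lapply(targets, function(t) matrix(0, n, 20L))
  names(A) <- targets
  sm2 <- lapply(targets, function(t) numeric(n))
  names(sm2) <- targets
  for (i in seq_len(n)) {
    W <- protein_window_matrix(proteome$protein[i], window)
    nw <- nrow(W)
    n_windows[i] <- nw
    cm <- colMeans(W)
    Wc <- W - rep(cm, each = nw)
    Q[i, ] <- as.vector(crossprod(Wc))
    Wbar[i, ] <- cm
    for (t in targets) {
      m <- mrna_density_profile(proteome$cds[i], t, window)
      mc <- m - mean(m)
      A[[t]][i, ] <- drop(crossprod(W, mc))
      sm2[[t]][i] <- sum(mc^2)
    }
  }
  structure(
    list(
      ids = proteome$id, n_windows = n_windows, Q = Q, Wbar = Wbar,
      A = A, sm2 = sm2, window = window, targets = targets,
      organism = attr(proteome, "organism")
    ),
    class = "profile_cache"
  )
}

#' @export
print.profile_cache <- function(x, ...) {
  cat(
    "# profile_cache: ", length(x$ids), " pair(s), window ", x$window,
    ", targets ", paste(x$targets, collapse = "/"), "\n",
    sep = ""
  )
  invisible(x)
}

# per-pair Pearson R of every cached pair against scale weights w
.cache_pair_R <- function(cache, w, target) {
  target <- .check_target(target)
  if (!target %in% cache$targets) {
    rlang::abort(paste0("Target ", target, " not precomputed in this cache."))
  }
  num <- drop(cache$A[[target]] %*% w)
  sp2 <- drop(cache$Q %*% as.vector(tcrossprod(w))) # sum (p - pbar)^2
  pbar <- drop(cache$Wbar %*% w)
  ssp <- sp2 + cache$n_windows * pbar^2 # sum p^2
  sm2 <- cache$sm2[[target]]
  ok <- sp2 > .zero_var_tol * pmax(1, ssp) & sm2 > .zero_var_tol
  R <- numeric(length(num))
  R[ok] <- num[ok] / sqrt(sm2[ok] * sp2[ok])
  R
}

#' Proteome-average profile matching of a scale
#'
#' The fitness of the search: the unweighted mean over cognate pairs of the
#' Pearson correlation between each pair's mRNA nucleobase-density profile
#' and its protein profile weighted by `scale`. Negative values indicate
#' matching, following the binding-affinity sign convention (low weight =
#' strong affinity).
#'
#' @param x A `proteome` tibble or a [profile_cache()] (much faster when
#'   many scales are evaluated).
#' @param scale An [affinity_scale()] or named weight vector.
#' @param target Nucleobase target (default `"PUR"`).
#' @param window Smoothing window (proteome input only).
#' @return A `fitness_result` with fields `mean_R`, `per_pair` (tibble
#'   `id`, `R`, `n_windows`), `n_pairs`, `target`.
#' @export
proteome_mean_R <- function(x, scale, target = "PUR", window = 21L) {
  UseMethod("proteome_mean_R")
}

#' @export
proteome_mean_R.profile_cache <- function(x, scale, target = "PUR", window = 21L) {
  w <- .weights(scale)
  R <- .cache_pair_R(x, w, target)
  .fitness_result(x$ids, R, x$n_windows, target)
}

#' @export
proteome_mean_R.data.frame <- function(x, scale, target = "PUR", window = 21L) {
  x <- as_proteome(x, min_protein_length = window + 1L)
  target <- .check_target(target)
  w <- .weights(scale)
  R <- numeric(nrow(x))
  nw <- integer(nrow(x))
  for (i in seq_len(nrow(x))) {
    m <- mrna_density_profile(x$cds[i], target, window)
    p <- protein_profile(x$protein[i], w, window)
    R[i] <- pair_correlation(m, p)
    nw[i] <- length(m)
  }
  .fitness_result(x$id, R, nw, target)
}

.fitness_result <- function(ids, R, n_windows, target) {
  structure(
    list(
      mean_R = mean(R),
      per_pair = tibble::tibble(id = ids, R = R, n_windows = n_windows),
      n_pairs = length(R),
      target = target
    ),
    class = "fitness_result"
  )
}

#' @export
print.fitness_result <- function(x, ...) {
  cat(
    "# <R> = ", format(x$mean_R, digits = 4), " over ", x$n_pairs,
    " pair(s), target ", x$target, "\n",
    sep = ""
  )
  invisible(x)
}

#' @rdname proteome_mean_R
#' @param object,... Method arguments.
#' @export
tidy.fitness_result <- function(x, ...) x$per_pair

#' @rdname proteome_mean_R
#' @export
glance.fitness_result <- function(x, ...) {
  tibble::tibble(mean_R = x$mean_R, n_pairs = x$n_pairs, target = x$target)
}

#' Profile table for one cognate pair
#'
#' Returns the two aligned profiles of a single pair as a tidy table, for
#' inspection or plotting (see [plot_profile_pair()]).
#'
#' @param proteome A `proteome` tibble.
#' @param id Pair id (defaults to the first pair).
#' @inheritParams proteome_mean_R
#' @return Tibble with columns `position` (central codon/residue, 1-based),
#'   `mrna_density`, `protein_profile`.
#' @export
profile_table <- function(proteome, scale, id = NULL, target = "PUR", window = 21L) {
  proteome <- as_proteome(proteome, min_protein_length = window + 1L)
  id <- id %||% proteome$id[1]
  row <- proteome[proteome$id == id, ]
  if (nrow(row) != 1L) rlang::abort(paste0("Pair id not found: ", id))
  m <- mrna_density_profile(row$cds, target, window)
  p <- protein_profile(row$protein, scale, window)
  half <- (window - 1L) %/% 2L
  tibble::tibble(
    position = seq_along(m) + half,
    mrna_density = m,
    protein_profile = p
  )
}
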