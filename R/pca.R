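#' One-hot encode binding-site sequences
#'
#' Represents each sequence position as a 21-element indicator block over
#' the pocket alphabet ([aa_alphabet()]): 20 amino acids in alphabetical
#' order, gap last.  `"A"` becomes `(1, 0, ..., 0)` and `"-"` becomes
#' `(0, ..., 0, 1)`; exactly one element per block is 1.
#'
#' @param x Either a character vector of equal-length residue strings, a
#'   data frame with a `pbs_string` column, or an `alignment_block`.
#' @return An object of class `encoded_matrix`: list with `matrix`
#'   (M x N binary matrix, N = 21 * P), `labels` (tibble of `position`,
#'   `letter` per channel), `M`, `P`, `N`.
#' @export
onehot_encode <- function(x) {
  rows <- if (inherits(x, "alignment_block")) {
    unname(x$rows)
  } else if (is.data.frame(x)) {
    x$pbs_string
  } else {
    as.character(x)
  }
  cm <- seq_char_matrix(rows)
  check_alphabet(cm)
  ab <- aa_alphabet()
  P <- ncol(cm)
  M <- nrow(cm)
  N <- 21L * P
  enc <- matrix(0, nrow = M, ncol = N)
  for (p in seq_len(P)) {
    block <- (p - 1L) * 21L
    idx <- match(cm[, p], ab)
    enc[cbind(seq_len(M), block + idx)] <- 1
  }
  labels <- tibble(
    position = rep(seq_len(P), each = 21L),
    letter = rep(ab, times = P)
  )
  colnames(enc) <- paste0(labels$position, labels$letter)
  structure(list(matrix = enc, labels = labels, M = M, P = P, N = N),
            class = "encoded_matrix")
}

#' @export
print.encoded_matrix <- function(x, ...) {
  cat("<encoded_matrix> ", x$M, " sequences x ", x$P, " positions (",
      x$N, " channels)\n", sep = "")
  invisible(x)
}

#' Fit a covariance-matrix PCA in one-hot sequence space
#'
#' Computes channel means and the N x N variance-covariance matrix of the
#' encoded sequences with the unbiased (M - 1) denominator, then
#' diagonalises it.  Eigenpairs are sorted by descending eigenvalue; exact
#' ties are broken by the ascending channel index of each eigenvector's
#' largest-magnitude component.  Eigenvector signs are fixed by requiring
#' that largest-magnitude component to be positive (biological orientation
#' of the leading axes is applied separately by [orient_axes()]).
#'
#' @param encoded An `encoded_matrix` with at least two sequences.
#' @return An object of class `pbs_pca`: list with `means`, `cov`,
#'   `vectors` (columns = eigenvectors), `values` (descending), `labels`,
#'   `M`, `P`, `N`, `flips` (orientation record, filled by
#'   [orient_axes()]).
#' @export
fit_pca <- function(encoded) {
  stopifnot(inherits(encoded, "encoded_matrix"))
  if (encoded$M < 2L) {
    stop("at least 2 sequences are required to estimate a covariance",
         call. = FALSE)
  }
  X <- encoded$matrix
  C <- cov(X)                       # (M - 1) denominator
  e <- eigen(C, symmetric = TRUE)
  values <- e$values
  vectors <- e$vectors
  # deterministic order: descending eigenvalue, ties by the channel index
  # of the largest-magnitude component
  lead <- apply(abs(vectors), 2L, which.max)
  ord <- order(-values, lead)
  values <- values[ord]
  vectors <- vectors[, ord, drop = FALSE]
  # deterministic sign: largest-magnitude component positive
  lead <- apply(abs(vectors), 2L, which.max)
  sgn <- sign(vectors[cbind(lead, seq_along(lead))])
  sgn[sgn == 0] <- 1
  vectors <- sweep(vectors, 2L, sgn, `*`)
  rownames(vectors) <- colnames(X)
  structure(
    list(means = colMeans(X), cov = C, vectors = vectors, values = values,
         labels = encoded$labels, M = encoded$M, P = encoded$P,
         N = encoded$N, flips = integer(0)),
    class = "pbs_pca"
  )
}

#' @export
print.pbs_pca <- function(x, ...) {
  cat("<pbs_pca> fitted on ", x$M, " sequences, ", x$N, " channels\n",
      "  leading eigenvalues: ",
      paste(signif(head(x$values, 5L), 4), collapse = ", "), "\n", sep = "")
  if (length(x$flips)) {
    cat("  oriented; flipped PCs: ",
        if (any(x$flips == -1)) paste(which(x$flips == -1), collapse = ", ")
        else "none", "\n", sep = "")
  }
  invisible(x)
}

#' Project encoded sequences on principal components
#'
#' In `"centered"` mode (the default, standard PCA) the projection of
#' sequence i on PC k is `(a_i - a_bar) . V_k`; in `"raw"` mode it is the
#' plain dot product `a_i . V_k`.  The two differ by the constant
#' `a_bar . V_k` for every sequence, so centering shifts all points
#' rigidly and cannot change their relative arrangement.
#'
#' @param model A `pbs_pca`.
#' @param encoded An `encoded_matrix` with the same channel labels.
#' @param k Integer vector of PC indices (default `1:2`).
#' @param centering `"centered"` or `"raw"`.
#' @return Numeric matrix, one row per sequence, one column per requested
#'   PC, with attribute `"oriented"` copied from the model.
#' @export
project <- function(model, encoded, k = 1:2,
                    centering = c("centered", "raw")) {
  stopifnot(inherits(model, "pbs_pca"), inherits(encoded, "encoded_matrix"))
  centering <- match.arg(centering)
  if (encoded$N != model$N ||
      !identical(encoded$labels$letter, model$labels$letter) ||
      !identical(encoded$labels$position, model$labels$position)) {
    stop("channel labels of the encoded matrix do not match the model",
         call. = FALSE)
  }
  if (any(k < 1L) || any(k > model$N)) {
    stop("PC index out of range 1..", model$N, call. = FALSE)
  }
  X <- encoded$matrix
  if (centering == "centered") X <- sweep(X, 2L, model$means)
  out <- X %*% model$vectors[, k, drop = FALSE]
  colnames(out) <- paste0("pc", k)
  attr(out, "oriented") <- length(model$flips) > 0L
  out
}

#' Composition-deviation profile along a principal component
#'
#' Describes how the per-position amino-acid composition deviates from the
#' dataset average as one moves a displacement `t` along PC k: the
#' deviation of channel (position, letter) is `t * v_k(channel)`.  At
#' `t = 0` (the mean point) all deviations vanish, and for any eigenvector
#' with non-zero eigenvalue the deviations within one position block sum
#' to zero, so composition is conserved position-wise.
#'
#' @param model A `pbs_pca`.
#' @param k Single PC index.
#' @param t_values Numeric vector of displacements along the PC.
#' @return Tibble with columns `t`, `position`, `letter`, `deviation`.
#' @export
composition_profile <- function(model, k, t_values = seq(-2, 2, by = 0.5)) {
  stopifnot(inherits(model, "pbs_pca"), length(k) == 1L)
  if (k < 1L || k > model$N) {
    stop("PC index out of range 1..", model$N, call. = FALSE)
  }
  v <- model$vectors[, k]
  out <- do.call(rbind, lapply(t_values, function(t) {
    tibble(t = t, position = model$labels$position,
           letter = model$labels$letter, deviation = t * v)
  }))
  as_tibble(out)
}
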