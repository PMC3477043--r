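#' Default orientation features for the bundled beta-tubulin pocket
#'
#' PC signs are arbitrary after diagonalisation; these features give the
#' leading axes their biological orientation.  PC1 is made positive for
#' carriers of Thr at the residue-23 column or Gly at the residue-26
#' column (the fungal side of the horizontal axis), and PC2 positive for
#' carriers of Ser at the residue-277 column (the paclitaxel-sensitive
#' side of the vertical axis).
#'
#' @return A list with elements `pc1` and `pc2`, each a list of
#'   `(column, letters)` feature definitions OR-ed together.
#' @export
default_orientation_features <- function() {
  list(
    pc1 = list(list(column = pbs_column(23), letters = "T"),
               list(column = pbs_column(26), letters = "G")),
    pc2 = list(list(column = pbs_column(277), letters = "S"))
  )
}

feature_carriers <- function(rows, features) {
  cm <- seq_char_matrix(rows)
  hit <- rep(FALSE, nrow(cm))
  for (f in features) {
    if (f$column > ncol(cm)) {
      stop("orientation feature column ", f$column,
           " exceeds alignment width ", ncol(cm), call. = FALSE)
    }
    hit <- hit | cm[, f$column] %in% f$letters
  }
  hit
}

#' Orient the leading principal components biologically
#'
#' Flips PC1 and/or PC2 of a fitted model so that the mean centered
#' projection of the sequences carrying each orientation feature is
#' positive; the applied flips are recorded in the model.  A model whose
#' axes already satisfy the features is returned unchanged (flips of +1).
#'
#' @param model A `pbs_pca`.
#' @param x The sequences the features are evaluated on (data frame with
#'   `pbs_string`, character vector, or `alignment_block`) — normally the
#'   records the model was fitted on.
#' @param features Feature definitions as in
#'   [default_orientation_features()].
#' @return The model with `vectors` sign-adjusted and `flips` recording
#'   +1/-1 per oriented PC.
#' @export
orient_axes <- function(model, x, features = default_orientation_features()) {
  stopifnot(inherits(model, "pbs_pca"))
  rows <- if (inherits(x, "alignment_block")) unname(x$rows)
          else if (is.data.frame(x)) x$pbs_string else as.character(x)
  enc <- onehot_encode(rows)
  pcs <- seq_along(features)
  proj <- project(model, enc, k = pcs, centering = "centered")
  flips <- rep(1L, length(pcs))
  for (j in pcs) {
    carriers <- feature_carriers(rows, features[[j]])
    if (!any(carriers)) {
      stop("orientation feature for PC", j, " matches no sequence",
           call. = FALSE)
    }
    if (mean(proj[carriers, j]) < 0) flips[[j]] <- -1L
  }
  model$vectors[, pcs] <- sweep(model$vectors[, pcs, drop = FALSE], 2L,
                                flips, `*`)
  model$flips <- flips
  model
}

#' Assign sensitivity groups by PC1/PC2 quadrant
#'
#' Under the biological orientation of [orient_axes()] (PC1 positive =
#' Thr23/Gly26 side, PC2 positive = Ser277 side), the four
#' paclitaxel-sensitivity groups are the four quadrants: (+,+) -> A,
#' (+,-) -> B, (-,+) -> C, (-,-) -> D.  Points within 1e-12 of an axis
#' are labelled with the non-negative side and flagged `on_axis`.
#'
#' @param proj Projection matrix from [project()] on an oriented model
#'   (columns pc1, pc2).
#' @return Tibble (`group_assignment`) with columns `pc1`, `pc2`, `group`,
#'   `on_axis`, `method`.
#' @export
assign_quadrant <- function(proj) {
  proj <- check_oriented_proj(proj)
  eps <- 1e-12
  p1 <- proj[, 1L]
  p2 <- proj[, 2L]
  group <- ifelse(p1 >= 0,
                  ifelse(p2 >= 0, "A", "B"),
                  ifelse(p2 >= 0, "C", "D"))
  out <- tibble(pc1 = p1, pc2 = p2, group = group,
                on_axis = abs(p1) < eps | abs(p2) < eps,
                method = "quadrant")
  class(out) <- c("group_assignment", class(out))
  out
}

check_oriented_proj <- function(proj) {
  if (is.null(attr(proj, "oriented")) || !isTRUE(attr(proj, "oriented"))) {
    stop("projections must come from an oriented model (see orient_axes)",
         call. = FALSE)
  }
  proj <- as.matrix(proj)
  if (ncol(proj) < 2L) stop("need pc1 and pc2 coordinates", call. = FALSE)
  if (any(!is.finite(proj[, 1:2]))) stop("non-finite coordinates", call. = FALSE)
  proj
}

#' Assign groups by nearest training centroid
#'
#' Labels each point with the group whose training centroid is nearest in
#' the PC1-PC2 plane (Euclidean distance); exact ties are broken
#' alphabetically.  Intended for out-of-sample sequences (e.g. human
#' isotypes projected onto a fit that excluded them).
#'
#' @param proj Projection matrix from [project()] on an oriented model.
#' @param training A data frame with columns `pc1`, `pc2`, `group` (e.g. a
#'   `group_assignment` of the fitted records); every group must be
#'   non-empty.
#' @return Tibble (`group_assignment`) with columns `pc1`, `pc2`, `group`,
#'   `on_axis` (always FALSE for this method), `method`.
#' @export
assign_nearest_centroid <- function(proj, training) {
  proj <- check_oriented_proj(proj)
  if (!all(c("pc1", "pc2", "group") %in% names(training))) {
    stop("training assignment needs pc1, pc2 and group columns", call. = FALSE)
  }
  groups <- sort(unique(training$group))
  if (length(groups) == 0L || any(!nzchar(groups))) {
    stop("training groups must be non-empty", call. = FALSE)
  }
  cent <- vapply(groups, function(g) {
    rows <- training$group == g
    if (!any(rows)) stop("empty training group: ", g, call. = FALSE)
    c(mean(training$pc1[rows]), mean(training$pc2[rows]))
  }, numeric(2L))
  d2 <- outer(proj[, 1L], cent[1L, ], "-")^2 +
    outer(proj[, 2L], cent[2L, ], "-")^2
  # which.min returns the first (alphabetically smallest) group on ties
  lab <- groups[apply(d2, 1L, which.min)]
  out <- tibble(pc1 = proj[, 1L], pc2 = proj[, 2L], group = lab,
                on_axis = FALSE, method = "nearest-centroid")
  class(out) <- c("group_assignment", class(out))
  out
}

#' Cluster-recovery partition: quadrant seed plus centroid refinement
#'
#' The published groups are clusters in the PC1-PC2 plane rather than
#' literal quadrants.  This partition seeds four groups with the quadrant
#' rule and then iterates nearest-centroid reassignment (k-means style,
#' centroids recomputed from the current labels) until the labels are
#' stable.  On the bundled dataset this recovers the published group
#' labels for every fitted record except the known duplicated
#' *Lentinus sajor-caju* row.
#'
#' @param proj Projection matrix from [project()] on an oriented model.
#' @param max_iter Maximum refinement iterations (default 25).
#' @return Tibble (`group_assignment`) with columns `pc1`, `pc2`, `group`,
#'   `on_axis`, `method`, plus attribute `"iterations"`.
#' @export
refine_groups <- function(proj, max_iter = 25L) {
  proj <- check_oriented_proj(proj)
  seed <- assign_quadrant(proj)
  lab <- seed$group
  it <- 0L
  for (it in seq_len(max_iter)) {
    train <- tibble(pc1 = proj[, 1L], pc2 = proj[, 2L], group = lab)
    new <- assign_nearest_centroid(proj, train)$group
    if (identical(new, lab)) break
    lab <- new
  }
  out <- tibble(pc1 = proj[, 1L], pc2 = proj[, 2L], group = lab,
                on_axis = seed$on_axis, method = "refined")
  attr(out, "iterations") <- it
  class(out) <- c("group_assignment", class(out))
  out
}

#' Sequence-logo frequency and information-content matrix
#'
#' Per alignment column: amino-acid frequencies (gaps excluded from the
#' frequencies but reported as a gap fraction), information content
#' IC = log2(20) - H where H is the column's Shannon entropy in bits, and
#' letter heights = frequency x IC.  The optional small-sample correction
#' subtracts e_n = 19 / (2 ln(2) n) from the IC.  Columns containing only
#' gaps have undefined IC and are reported as `NA` with a warning.
#'
#' @param x Sequences: character vector, data frame with `pbs_string`, or
#'   `alignment_block`.
#' @param small_sample_correction Logical, default `FALSE`.
#' @return An object of class `logo_matrix`: list with `freq` (20 x P),
#'   `ic` (length P), `heights` (20 x P), `gap_fraction` (length P),
#'   `majority` (letter per column), `n`.
#' @export
logo_matrix <- function(x, small_sample_correction = FALSE) {
  rows <- if (inherits(x, "alignment_block")) unname(x$rows)
          else if (is.data.frame(x)) x$pbs_string else as.character(x)
  if (length(rows) < 1L) stop("need at least one sequence", call. = FALSE)
  cm <- seq_char_matrix(rows)
  check_alphabet(cm)
  P <- ncol(cm)
  letters20 <- aa20()
  freq <- matrix(0, nrow = 20L, ncol = P, dimnames = list(letters20, NULL))
  ic <- numeric(P)
  gap_fraction <- numeric(P)
  majority <- character(P)
  n <- nrow(cm)
  for (p in seq_len(P)) {
    col <- cm[, p]
    gap_fraction[[p]] <- mean(col == "-")
    aa <- col[col != "-"]
    if (length(aa) == 0L) {
      warning("column ", p, " contains only gaps; information content ",
              "undefined", call. = FALSE)
      ic[[p]] <- NA_real_
      majority[[p]] <- NA_character_
      next
    }
    f <- table(factor(aa, levels = letters20)) / length(aa)
    freq[, p] <- as.numeric(f)
    pos <- freq[, p][freq[, p] > 0]
    H <- -sum(pos * log2(pos))
    icp <- log2(20) - H
    if (small_sample_correction) icp <- icp - 19 / (2 * log(2) * length(aa))
    ic[[p]] <- icp
    majority[[p]] <- letters20[[which.max(freq[, p])]]
  }
  heights <- sweep(freq, 2L, ifelse(is.na(ic), 0, ic), `*`)
  structure(list(freq = freq, ic = ic, heights = heights,
                 gap_fraction = gap_fraction, majority = majority, n = n),
            class = "logo_matrix")
}

#' @export
print.logo_matrix <- function(x, ...) {
  cat("<logo_matrix> ", ncol(x$freq), " columns over ", x$n,
      " sequences; IC (bits): ",
      paste(sprintf("%.2f", x$ic), collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Write a logo matrix as TSV
#'
#' One row per (column, letter) with frequency and height, plus per-column
#' information content and gap fraction.
#'
#' @param logo A `logo_matrix`.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_logo_table <- function(logo, path) {
  P <- ncol(logo$freq)
  out <- data.frame(
    column = rep(seq_len(P), each = 20L),
    letter = rep(rownames(logo$freq), times = P),
    freq = sprintf("%.6f", as.vector(logo$freq)),
    height = sprintf("%.6f", as.vector(logo$heights)),
    ic = sprintf("%.6f", rep(logo$ic, each = 20L)),
    gap_fraction = sprintf("%.6f", rep(logo$gap_fraction, each = 20L)),
    stringsAsFactors = FALSE
  )
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Dominant substitutions between two groups
#'
#' Compares the majority letters of two logo matrices column by column and
#' reports the columns where they differ, sorted by the product of the two
#' majority frequencies (most confident transitions first).  Applied to
#' the bundled groups this recovers the moves that define the PC axes,
#' e.g. T23V/G26D between groups A and C and A277S between D and C.
#'
#' @param logo1,logo2 `logo_matrix` objects over the same columns.
#' @return Tibble with columns `column`, `from` (majority of `logo1`),
#'   `to` (majority of `logo2`), `score`.
#' @export
dominant_transitions <- function(logo1, logo2) {
  stopifnot(inherits(logo1, "logo_matrix"), inherits(logo2, "logo_matrix"))
  if (ncol(logo1$freq) != ncol(logo2$freq)) {
    stop("logo matrices cover different column counts", call. = FALSE)
  }
  P <- ncol(logo1$freq)
  diff <- which(logo1$majority != logo2$majority)
  if (length(diff) == 0L) {
    return(tibble(column = integer(), from = character(),
                  to = character(), score = numeric()))
  }
  score <- vapply(diff, function(p) {
    logo1$freq[logo1$majority[[p]], p] * logo2$freq[logo2$majority[[p]], p]
  }, numeric(1L))
  out <- tibble(column = diff, from = logo1$majority[diff],
                to = logo2$majority[diff], score = score)
  out[order(-out$score, out$column), , drop = FALSE]
}
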