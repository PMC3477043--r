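#' The 21-letter pocket alphabet
#'
#' The encoding alphabet used throughout the package: the 20 standard amino
#' acids in alphabetical one-letter order, followed by the alignment gap
#' character `"-"` as the 21st symbol.  Channel order in every encoded
#' matrix follows this vector.
#'
#' @return Character vector of length 21.
#' @export
#' @examples
#' aa_alphabet()
aa_alphabet <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y", "-")
}

# amino acids only (no gap)
aa20 <- function() aa_alphabet()[1:20]

#' Residue numbers of the bundled PBS columns
#'
#' Maps the 14 columns of the bundled binding-site residue strings to
#' beta-tubulin residue numbers in the author numbering of PDB entry 1JFF.
#' Eight columns are anchored on functionally characterized substitutions
#' (23, 26, 229, 233, 272, 276, 277, 278); the remaining columns follow
#' published taxol-site contact lists for 1JFF in string order.
#'
#' @return Named integer vector of length 14; names are column indices.
#' @export
#' @examples
#' pbs_positions()[["2"]]  # column 2 is residue 23
pbs_positions <- function() {
  setNames(
    c(22L, 23L, 26L, 226L, 229L, 233L, 236L, 272L, 276L, 277L, 278L,
      369L, 370L, 371L),
    as.character(1:14)
  )
}

#' Alignment column for a PBS residue number
#'
#' Inverse lookup of [pbs_positions()]: given a 1JFF residue number that is
#' one of the 14 variable pocket positions, return its column index in the
#' bundled strings.
#'
#' @param resno Integer residue number (1JFF author numbering).
#' @return Integer column index in 1..14.
#' @export
#' @examples
#' pbs_column(277)
pbs_column <- function(resno) {
  pos <- pbs_positions()
  hit <- which(pos == resno)
  if (length(hit) != 1L) {
    stop("residue ", resno, " is not one of the 14 variable pocket columns",
         call. = FALSE)
  }
  as.integer(names(pos)[hit])
}

# split equal-length strings into a character matrix (rows = sequences)
seq_char_matrix <- function(x) {
  stopifnot(is.character(x), length(x) >= 1L)
  w <- unique(nchar(x))
  if (length(w) != 1L) {
    stop("sequences have unequal lengths (", paste(w, collapse = ", "), ")",
         call. = FALSE)
  }
  matrix(unlist(strsplit(x, "", fixed = TRUE)), nrow = length(x),
         ncol = w, byrow = TRUE)
}

# validate characters against the pocket alphabet; names the first offender
check_alphabet <- function(chars, context = "sequence") {
  bad <- setdiff(unique(as.vector(chars)), aa_alphabet())
  if (length(bad) > 0L) {
    stop("invalid character '", bad[[1L]], "' in ", context,
         " (allowed: 20 amino acids and '-')", call. = FALSE)
  }
  invisible(TRUE)
}
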