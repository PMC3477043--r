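#' Load the bundled beta-tubulin binding-site dataset
#'
#' Returns the 125 paclitaxel-binding-site (PBS) residue strings shipped
#' with the package: 38 animal, 29 fungal, 28 plant and 30 protist
#' beta-tubulin sequences (counted by table of origin), each a 14-character
#' string over the 20 amino acids plus gap, with organism, GI/RefSeq
#' accession and the published sensitivity-group label A-D.  The eight
#' human isotype rows originate from the animal table but carry
#' `family = "isotype"` so the analysis can be fitted with or without them.
#' Two rows are duplicates of the fungus *Lentinus sajor-caju* published
#' with conflicting group labels; both are retained and flagged in the
#' `anomaly` column.
#'
#' @param include_isotypes Logical; if `FALSE` the eight human isotype rows
#'   are dropped, leaving the 117 records used for the default PCA fit.
#' @return A tibble with columns `accession`, `organism`, `table`
#'   (table of origin: animal/fungi/plant/protist), `family` (as `table`
#'   but `"isotype"` for the eight human rows), `pbs_string`, `group`
#'   and `anomaly`.
#' @export
#' @examples
#' nrow(load_bundled_dataset())        # 125
#' nrow(load_bundled_dataset(FALSE))   # 117
load_bundled_dataset <- function(include_isotypes = TRUE) {
  path <- system.file("extdata", "pbs_dataset.tsv", package = "pocketpca",
                      mustWork = TRUE)
  d <- read.delim(path, colClasses = "character", na.strings = NULL)
  d$anomaly[is.na(d$anomaly)] <- ""
  if (!include_isotypes) {
    d <- d[d$family != "isotype", , drop = FALSE]
  }
  rownames(d) <- NULL
  as_tibble(d)
}

#' Read a multiple sequence alignment
#'
#' Reads an aligned FASTA or Clustal file into an alignment block: rows are
#' uppercased, `"."` is normalised to the gap character `"-"`, all rows
#' must have equal length, and every character must belong to the
#' 21-letter pocket alphabet.
#'
#' @param path Path to the alignment file.
#' @param format `"fasta"` or `"clustal"`.
#' @return An object of class `alignment_block`: a list with `ids`
#'   (unique sequence identifiers), `rows` (named character vector of
#'   aligned sequences) and `width` (column count).
#' @export
read_alignment <- function(path, format = c("fasta", "clustal")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "fasta") {
    # readAAStringSet tolerates ragged rows, so the shape check is ours
    set <- Biostrings::readAAStringSet(path, format = "fasta")
    ids <- names(set)
    rows <- as.character(set)
  } else {
    aln <- Biostrings::readAAMultipleAlignment(path, format = "clustal")
    rows <- as.character(aln)
    ids <- names(rows)
  }
  ids <- sub("\\s.*$", "", ids)
  if (anyDuplicated(ids)) {
    stop("duplicate sequence identifier: ", ids[duplicated(ids)][[1L]],
         call. = FALSE)
  }
  rows <- toupper(rows)
  rows <- gsub(".", "-", rows, fixed = TRUE)
  w <- unique(nchar(rows))
  if (length(w) != 1L) {
    stop("alignment-shape error: rows have unequal lengths (",
         paste(sort(w), collapse = ", "), ")", call. = FALSE)
  }
  check_alphabet(seq_char_matrix(rows), context = paste0("alignment ", path))
  structure(list(ids = ids, rows = setNames(rows, ids), width = w),
            class = "alignment_block")
}

#' @export
print.alignment_block <- function(x, ...) {
  cat("<alignment_block> ", length(x$ids), " rows x ", x$width,
      " columns\n", sep = "")
  invisible(x)
}

#' Write a PC-projection table
#'
#' Writes one row per record with its PC1/PC2 coordinates and group label
#' as a tab-separated file (header: organism, family, accession,
#' pbs_string, pc1, pc2, group), floats at fixed 6-decimal precision.
#'
#' @param records Data frame with columns `organism`, `family`,
#'   `accession`, `pbs_string` and optionally `group`.
#' @param coordinates Two-column numeric matrix or data frame of PC1/PC2
#'   coordinates, one row per record.
#' @param path Output file path.
#' @return Invisibly, the path.
#' @seealso [read_projection_table()]
#' @export
write_projection_table <- function(records, coordinates, path) {
  coordinates <- as.matrix(coordinates)
  if (nrow(coordinates) != nrow(records) || ncol(coordinates) < 2L) {
    stop("coordinates must supply one (pc1, pc2) pair per record",
         call. = FALSE)
  }
  grp <- if ("group" %in% names(records)) records$group else rep("", nrow(records))
  out <- data.frame(
    organism = records$organism,
    family = records$family,
    accession = records$accession,
    pbs_string = records$pbs_string,
    pc1 = sprintf("%.6f", coordinates[, 1L]),
    pc2 = sprintf("%.6f", coordinates[, 2L]),
    group = grp,
    stringsAsFactors = FALSE
  )
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read back a PC-projection table
#'
#' @param path Path written by [write_projection_table()].
#' @return Tibble with the table columns; `pc1`/`pc2` numeric.
#' @export
read_projection_table <- function(path) {
  d <- read.delim(path, colClasses = "character", na.strings = NULL)
  d$pc1 <- as.numeric(d$pc1)
  d$pc2 <- as.numeric(d$pc2)
  as_tibble(d)
}
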