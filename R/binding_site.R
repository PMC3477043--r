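#' Read a PDB structure into a structure model
#'
#' Parses ATOM and HETATM records of a PDB file.  Water residues (HOH,
#' WAT, DOD) are excluded by default.  When a residue carries alternate
#' locations, only the highest-occupancy location is kept (ties: the first
#' encountered).
#'
#' @param path Path to a PDB file.
#' @param keep_waters Logical; keep water residues (default `FALSE`).
#' @return An object of class `structure_model`: a list with an `atoms`
#'   tibble (columns `record`, `eleno`, `elety`, `alt`, `resid`, `chain`,
#'   `resno`, `insert`, `x`, `y`, `z`, `o`, `b`, `elesy`) and the source
#'   `path`.
#' @export
read_structure <- function(path, keep_waters = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, verbose = FALSE, rm.alt = FALSE)),
    error = function(e) {
      stop("failed to parse PDB file '", path, "': ", conditionMessage(e),
           call. = FALSE)
    }
  )
  a <- pdb$atom
  elesy <- a$elesy
  # infer missing element symbols from the atom-name column
  miss <- is.na(elesy) | elesy == ""
  if (any(miss)) {
    guess <- sub("^[0-9]*", "", a$elety[miss])
    elesy[miss] <- substr(guess, 1L, 1L)
  }
  atoms <- tibble(
    record = a$type,
    eleno = as.integer(a$eleno),
    elety = a$elety,
    alt = ifelse(is.na(a$alt), "", a$alt),
    resid = a$resid,
    chain = ifelse(is.na(a$chain), "", a$chain),
    resno = as.integer(a$resno),
    insert = ifelse(is.na(a$insert), "", a$insert),
    x = a$x, y = a$y, z = a$z,
    o = ifelse(is.na(a$o), 1, a$o),
    b = ifelse(is.na(a$b), 0, a$b),
    elesy = toupper(elesy)
  )
  if (!keep_waters) {
    atoms <- atoms[!(atoms$resid %in% c("HOH", "WAT", "DOD")), , drop = FALSE]
  }
  atoms <- drop_altloc(atoms)
  if (any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z))) {
    stop("non-finite coordinates in '", path, "'", call. = FALSE)
  }
  new_structure_model(atoms, path = path)
}

new_structure_model <- function(atoms, path = NA_character_) {
  structure(list(atoms = as_tibble(atoms), path = path),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  a <- x$atoms
  cat("<structure_model> ", nrow(a), " atoms, ",
      length(unique(paste(a$chain, a$resno, a$insert))), " residues, chains: ",
      paste(sort(unique(a$chain)), collapse = " "), "\n", sep = "")
  invisible(x)
}

# keep the highest-occupancy alternate location per (chain, resno, insert,
# elety); ties resolved in favour of the first record encountered
drop_altloc <- function(atoms) {
  key <- paste(atoms$chain, atoms$resno, atoms$insert, atoms$resid,
               atoms$elety, sep = "|")
  if (!anyDuplicated(key)) return(atoms)
  ord <- order(-atoms$o, seq_len(nrow(atoms)))
  keep <- ord[!duplicated(key[ord])]
  atoms[sort(keep), , drop = FALSE]
}

#' Write a structure model as a PDB file
#'
#' @param model A `structure_model`.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_structure <- function(model, path) {
  stopifnot(inherits(model, "structure_model"))
  a <- model$atoms
  bio3d::write.pdb(
    file = path,
    xyz = as.vector(t(as.matrix(a[, c("x", "y", "z")]))),
    type = a$record,
    resno = a$resno,
    resid = a$resid,
    eleno = a$eleno,
    elety = a$elety,
    chain = ifelse(a$chain == "", " ", a$chain),
    insert = ifelse(a$insert == "", "", a$insert),
    alt = ifelse(a$alt == "", "", a$alt),
    o = a$o,
    b = a$b,
    elesy = a$elesy
  )
  invisible(path)
}

is_heavy <- function(elesy) !(toupper(elesy) %in% c("H", "D"))

#' Select atoms of a structure model
#'
#' Returns the row indices of `model$atoms` matching all given filters
#' (each `NULL` filter matches everything).
#'
#' @param model A `structure_model`.
#' @param chain,resno,resid,elety,record Optional filters.
#' @param heavy_only Drop hydrogen/deuterium atoms (default `TRUE`).
#' @return Integer vector of atom row indices.
#' @export
select_atoms <- function(model, chain = NULL, resno = NULL, resid = NULL,
                         elety = NULL, record = NULL, heavy_only = TRUE) {
  a <- model$atoms
  keep <- rep(TRUE, nrow(a))
  if (!is.null(chain)) keep <- keep & a$chain %in% chain
  if (!is.null(resno)) keep <- keep & a$resno %in% resno
  if (!is.null(resid)) keep <- keep & a$resid %in% resid
  if (!is.null(elety)) keep <- keep & a$elety %in% elety
  if (!is.null(record)) keep <- keep & a$record %in% record
  if (heavy_only) keep <- keep & is_heavy(a$elesy)
  which(keep)
}

#' Extract ligand-contact residues by distance cutoff
#'
#' Finds every non-ligand residue having at least one heavy (non-hydrogen)
#' atom within `cutoff` angstrom (inclusive) of any heavy ligand atom.
#' This is the operation that defines a primary binding site such as the
#' paclitaxel-binding site of beta-tubulin (5 angstrom around the bound
#' taxol in 1JFF).
#'
#' @param model A `structure_model`.
#' @param ligand Ligand selector: a list with `chain` and/or `resname`
#'   and/or `resno` naming at least one HETATM residue.
#' @param cutoff Distance cutoff in angstrom (inclusive); default 5.0.
#' @param chains Chains searched for contacts.  Default `NULL` restricts
#'   the search to the ligand's own chain(s), so that e.g. only beta-chain
#'   residues are counted for a beta-chain ligand.  Use `chains = NA` to
#'   search all chains.
#' @return A tibble (`contact_set`) with columns `chain`, `resno`,
#'   `insert`, `resid`, `min_dist`, sorted by residue number; one row per
#'   contacting residue.
#' @export
extract_contact_residues <- function(model, ligand, cutoff = 5.0,
                                     chains = NULL) {
  stopifnot(inherits(model, "structure_model"))
  if (!is.numeric(cutoff) || cutoff <= 0) {
    stop("cutoff must be a positive distance in angstrom", call. = FALSE)
  }
  a <- model$atoms
  lig <- rep(a$record == "HETATM", length.out = nrow(a))
  if (!is.null(ligand$chain)) lig <- lig & a$chain %in% ligand$chain
  if (!is.null(ligand$resname)) lig <- lig & a$resid %in% ligand$resname
  if (!is.null(ligand$resno)) lig <- lig & a$resno %in% ligand$resno
  lig_idx <- which(lig & is_heavy(a$elesy))
  if (length(lig_idx) == 0L) {
    stop("ligand selector matched no HETATM residue: ",
         paste(names(ligand), unlist(ligand), sep = "=", collapse = ", "),
         call. = FALSE)
  }
  if (is.null(chains)) {
    chains <- unique(a$chain[lig_idx])
  } else if (length(chains) == 1L && is.na(chains)) {
    chains <- unique(a$chain)
  }
  lig_key <- unique(paste(a$chain[lig_idx], a$resno[lig_idx], a$insert[lig_idx]))
  cand <- which(is_heavy(a$elesy) & a$chain %in% chains &
                  !(paste(a$chain, a$resno, a$insert) %in% lig_key))
  if (length(cand) == 0L) {
    return(empty_contact_set())
  }
  lx <- as.matrix(a[lig_idx, c("x", "y", "z")])
  cx <- as.matrix(a[cand, c("x", "y", "z")])
  # min distance from each candidate atom to any ligand atom
  d2 <- outer(rowSums(cx^2), rowSums(lx^2), "+") - 2 * cx %*% t(lx)
  d2[d2 < 0] <- 0
  dmin_atom <- sqrt(apply(d2, 1L, min))
  key <- paste(a$chain[cand], a$resno[cand], a$insert[cand], sep = "|")
  dmin_res <- tapply(dmin_atom, key, min)
  hit <- names(dmin_res)[dmin_res <= cutoff]
  if (length(hit) == 0L) return(empty_contact_set())
  parts <- strsplit(hit, "|", fixed = TRUE)
  out <- tibble(
    chain = vapply(parts, `[[`, "", 1L),
    resno = as.integer(vapply(parts, `[[`, "", 2L)),
    insert = vapply(parts, function(p) if (length(p) >= 3L) p[[3L]] else "", ""),
    resid = vapply(hit, function(k) {
      i <- which(key == k)[[1L]]
      a$resid[cand[i]]
    }, "", USE.NAMES = FALSE),
    min_dist = as.numeric(dmin_res[hit])
  )
  out <- out[order(out$chain, out$resno, out$insert), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("contact_set", class(out))
  out
}

empty_contact_set <- function() {
  out <- tibble(chain = character(), resno = integer(), insert = character(),
                resid = character(), min_dist = numeric())
  class(out) <- c("contact_set", class(out))
  out
}

#' Map structure residue numbers to alignment columns
#'
#' Given a reference row of an alignment that corresponds to the structure
#' sequence, maps each residue number to the alignment column whose
#' reference-row residue (counting non-gap positions, starting at
#' `first_resno`) has that number.
#'
#' @param resnos Integer vector of residue numbers to map (e.g. the
#'   `resno` column of a contact set).
#' @param alignment An `alignment_block` from [read_alignment()].
#' @param reference_id Identifier of the reference row.
#' @param first_resno Residue number of the first non-gap reference
#'   position (default 1).
#' @return Named integer vector: alignment column per residue number.
#' @export
map_residues_to_columns <- function(resnos, alignment, reference_id,
                                    first_resno = 1L) {
  stopifnot(inherits(alignment, "alignment_block"))
  if (!reference_id %in% alignment$ids) {
    stop("reference row '", reference_id, "' not present in alignment",
         call. = FALSE)
  }
  ref <- strsplit(alignment$rows[[reference_id]], "", fixed = TRUE)[[1L]]
  nongap <- which(ref != "-")
  numbers <- first_resno + seq_along(nongap) - 1L
  cols <- integer(length(resnos))
  for (i in seq_along(resnos)) {
    hit <- which(numbers == resnos[[i]])
    if (length(hit) != 1L) {
      stop("residue ", resnos[[i]],
           " maps to a gap or lies outside the reference row", call. = FALSE)
    }
    cols[[i]] <- nongap[[hit]]
  }
  setNames(cols, as.character(resnos))
}
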