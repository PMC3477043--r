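# Geometric operators used to reason about the structural consequences of
# binding-site substitutions: in silico point mutation, chi1 rotamer scans,
# and hydrogen-bond / salt-bridge / hydrophobic-staple / helix H-bond
# detection.  All detectors are purely geometric: no energies are modelled.

residue_rows <- function(model, site) {
  a <- model$atoms
  keep <- a$resno == site$resno
  if (!is.null(site$chain)) keep <- keep & a$chain %in% site$chain
  if (!is.null(site$insert)) keep <- keep & a$insert %in% site$insert
  idx <- which(keep)
  if (length(idx) == 0L) {
    stop("no residue matches chain=", site$chain %||% "*", " resno=",
         site$resno, call. = FALSE)
  }
  idx
}

`%||%` <- function(a, b) if (is.null(a)) b else a

atom_xyz <- function(model, idx) {
  as.numeric(model$atoms[idx, c("x", "y", "z")])
}

residue_atom <- function(model, rows, name, required = TRUE) {
  hit <- rows[model$atoms$elety[rows] == name]
  if (length(hit) == 0L) {
    if (required) {
      stop("residue lacks required atom ", name, call. = FALSE)
    }
    return(NA_integer_)
  }
  hit[[1L]]
}

measure_chi1 <- function(model, rows) {
  resid <- model$atoms$resid[rows[[1L]]]
  gatom <- chi1_atom(resid)
  if (is.null(gatom)) return(NA_real_)
  n <- residue_atom(model, rows, "N", required = FALSE)
  ca <- residue_atom(model, rows, "CA", required = FALSE)
  cb <- residue_atom(model, rows, "CB", required = FALSE)
  g <- residue_atom(model, rows, gatom, required = FALSE)
  if (anyNA(c(n, ca, cb, g))) return(NA_real_)
  dihedral_points(atom_xyz(model, n), atom_xyz(model, ca),
                  atom_xyz(model, cb), atom_xyz(model, g))
}

build_sidechain <- function(model, rows, resid, chi1) {
  tmpl <- sidechain_templates()[[resid]]
  if (is.null(tmpl)) {
    stop("no side-chain template for residue type ", resid, call. = FALSE)
  }
  coords <- list(
    N = atom_xyz(model, residue_atom(model, rows, "N")),
    CA = atom_xyz(model, residue_atom(model, rows, "CA")),
    C = atom_xyz(model, residue_atom(model, rows, "C"))
  )
  cb <- residue_atom(model, rows, "CB", required = FALSE)
  coords$CB <- if (!is.na(cb)) atom_xyz(model, cb)
               else ideal_cb(coords$N, coords$CA, coords$C)
  placed <- list()
  for (row in tmpl) {
    tor <- if (row$chi) chi1 + row$tor else row$tor
    refs <- lapply(row$refs, function(r) {
      coords[[r]] %||% stop("missing reference atom ", r, call. = FALSE)
    })
    coords[[row$atom]] <- place_atom(refs[[1L]], refs[[2L]], refs[[3L]],
                                     row$dist, row$angle, tor)
    placed[[row$atom]] <- coords[[row$atom]]
  }
  list(CB = coords$CB, placed = placed, had_cb = !is.na(cb))
}

guess_element <- function(elety) {
  sym <- substr(sub("^[0-9]*", "", elety), 1L, 1L)
  if (sym %in% c("C", "N", "O", "S", "P", "H")) sym else "C"
}

replace_residue_atoms <- function(model, rows, resid, keep_names, new_coords) {
  a <- model$atoms
  proto <- a[rows[[1L]], , drop = FALSE]
  keep_idx <- rows[a$elety[rows] %in% keep_names]
  kept <- a[keep_idx, , drop = FALSE]
  kept$resid <- resid
  if (length(new_coords) > 0L) {
    added <- do.call(rbind, lapply(names(new_coords), function(nm) {
      row <- proto
      row$elety <- nm
      row$x <- new_coords[[nm]][[1L]]
      row$y <- new_coords[[nm]][[2L]]
      row$z <- new_coords[[nm]][[3L]]
      row$o <- 1
      row$b <- 0
      row$alt <- ""
      row$elesy <- guess_element(nm)
      row$resid <- resid
      row
    }))
    kept <- rbind(kept, added)
  }
  # rebuild atom table with the residue replaced in place
  before <- model$atoms[setdiff(seq_len(min(rows) - 1L), rows), , drop = FALSE]
  after <- model$atoms[setdiff(seq(min(rows), nrow(model$atoms)), rows),
                       , drop = FALSE]
  out <- rbind(before, kept, after)
  out$eleno <- seq_len(nrow(out))
  model$atoms <- out
  model
}

#' Point-mutate a residue in silico
#'
#' Replaces the side chain of one residue with idealised geometry built on
#' the existing backbone.  Backbone atoms (N, CA, C, O and OXT if present)
#' are never moved; the existing CB is preserved when the target residue
#' has one.  Mutations to Gly or Ala truncate the side chain with
#' renaming.  Where the original residue has a chi1 dihedral and the new
#' side chain supports one, the original rotameric state is maintained;
#' otherwise chi1 defaults to the common -60 degree rotamer.
#'
#' @param model A `structure_model`.
#' @param site List with `resno` and optionally `chain`, `insert`.
#' @param new_res Target residue, one- or three-letter code (Pro and Trp
#'   are not supported).
#' @return The mutated `structure_model`.
#' @export
mutate_residue <- function(model, site, new_res) {
  stopifnot(inherits(model, "structure_model"))
  new_res <- aa_three(new_res)
  if (new_res %in% c("PRO", "TRP")) {
    stop("mutation to ", new_res, " is not supported", call. = FALSE)
  }
  rows <- residue_rows(model, site)
  a <- model$atoms
  old_res <- a$resid[rows[[1L]]]
  backbone <- c("N", "CA", "C", "O")
  if (!all(backbone %in% a$elety[rows])) {
    stop("residue ", old_res, " ", site$resno,
         " lacks backbone atoms (N, CA, C, O required)", call. = FALSE)
  }
  if (new_res == old_res && new_res %in% c("ALA", "GLY")) {
    return(model)  # nothing to rebuild
  }
  keep <- c(backbone, "OXT")
  if (new_res == "GLY") {
    return(replace_residue_atoms(model, rows, "GLY", keep, list()))
  }
  if (new_res == "ALA") {
    if ("CB" %in% a$elety[rows]) {
      return(replace_residue_atoms(model, rows, "ALA", c(keep, "CB"), list()))
    }
    n <- atom_xyz(model, residue_atom(model, rows, "N"))
    ca <- atom_xyz(model, residue_atom(model, rows, "CA"))
    cc <- atom_xyz(model, residue_atom(model, rows, "C"))
    return(replace_residue_atoms(model, rows, "ALA", keep,
                                 list(CB = ideal_cb(n, ca, cc))))
  }
  chi1 <- measure_chi1(model, rows)
  if (is.na(chi1)) chi1 <- -60
  built <- build_sidechain(model, rows, new_res, chi1)
  keep2 <- if (built$had_cb) c(keep, "CB") else keep
  coords <- built$placed
  if (!built$had_cb) coords <- c(list(CB = built$CB), coords)
  replace_residue_atoms(model, rows, new_res, keep2, coords)
}

#' Enumerate chi1 rotameric states of a residue
#'
#' Rebuilds the side chain beyond CB at each requested chi1 dihedral with
#' idealised geometry (only chi1 is scanned; distal torsions stay at their
#' canonical values).  The backbone and CB are untouched.
#'
#' @param model A `structure_model`.
#' @param site List with `resno` and optionally `chain`, `insert`.
#' @param angles Chi1 angles in degrees; default the three canonical
#'   rotamers `c(-60, 60, 180)`.
#' @return List of rotamer states, each a list with `chi1_requested`,
#'   `chi1` (measured on the rebuilt model) and `model`.
#' @export
scan_chi1 <- function(model, site, angles = c(-60, 60, 180)) {
  stopifnot(inherits(model, "structure_model"))
  rows <- residue_rows(model, site)
  resid <- model$atoms$resid[rows[[1L]]]
  if (is.null(chi1_atom(resid)) || resid %in% c("GLY", "ALA")) {
    stop("chi1 is undefined for residue type ", resid, call. = FALSE)
  }
  if (is.null(sidechain_templates()[[resid]])) {
    stop("no side-chain template for residue type ", resid, call. = FALSE)
  }
  lapply(angles, function(chi) {
    built <- build_sidechain(model, rows, resid, chi)
    keep <- c("N", "CA", "C", "O", "OXT", "CB")
    coords <- built$placed
    if (!built$had_cb) coords <- c(list(CB = built$CB), coords)
    m2 <- replace_residue_atoms(model, rows, resid, keep, coords)
    rows2 <- residue_rows(m2, site)
    list(chi1_requested = chi, chi1 = measure_chi1(m2, rows2), model = m2)
  })
}

resolve_selection <- function(model, sel) {
  if (is.numeric(sel)) return(as.integer(sel))
  do.call(select_atoms, c(list(model = model), sel))
}

# heavy atoms covalently bonded to `idx` (distance-based, <= 1.8 A)
antecedents <- function(model, idx, exclude = integer(0)) {
  a <- model$atoms
  p <- atom_xyz(model, idx)
  xyz <- as.matrix(a[, c("x", "y", "z")])
  d <- sqrt(colSums((t(xyz) - p)^2))
  which(d > 1e-6 & d <= 1.8 & is_heavy(a$elesy) &
          !(seq_len(nrow(a)) %in% c(idx, exclude)))
}

#' Detect hydrogen bonds between donor and acceptor selections
#'
#' Hydrogen-free geometric criterion suitable for low-resolution
#' structures: a donor N/O and acceptor N/O pair is reported when their
#' distance is at most `d_max` and the largest
#' antecedent-donor-acceptor angle (over heavy atoms covalently bonded to
#' the donor) is at least `angle_min`.  Pairs within one residue are
#' skipped.
#'
#' @param model A `structure_model`.
#' @param donors,acceptors Atom selections: integer indices or selector
#'   lists for [select_atoms()].
#' @param d_max Maximum donor-acceptor distance in angstrom (default 3.5).
#' @param angle_min Minimum antecedent angle in degrees (default 120).
#' @return Tibble with one row per H-bond: donor/acceptor chain, resno,
#'   resid, elety, `distance`, `angle`.
#' @export
find_hbonds <- function(model, donors, acceptors, d_max = 3.5,
                        angle_min = 120) {
  stopifnot(inherits(model, "structure_model"))
  don <- resolve_selection(model, donors)
  acc <- resolve_selection(model, acceptors)
  if (length(don) == 0L || length(acc) == 0L) {
    stop("empty donor or acceptor selection", call. = FALSE)
  }
  a <- model$atoms
  don <- don[a$elesy[don] %in% c("N", "O")]
  acc <- acc[a$elesy[acc] %in% c("N", "O")]
  out <- list()
  for (d in don) {
    pd <- atom_xyz(model, d)
    for (ac in acc) {
      if (ac == d) next
      same_res <- a$chain[d] == a$chain[ac] & a$resno[d] == a$resno[ac] &
        a$insert[d] == a$insert[ac]
      if (same_res) next
      pa <- atom_xyz(model, ac)
      dist <- sqrt(sum((pd - pa)^2))
      if (dist > d_max || dist < 2.0) next
      ante <- antecedents(model, d, exclude = ac)
      if (length(ante) == 0L) next
      ang <- max(vapply(ante, function(i) {
        angle_points(atom_xyz(model, i), pd, pa)
      }, numeric(1L)))
      if (ang < angle_min) next
      out[[length(out) + 1L]] <- tibble(
        donor_chain = a$chain[d], donor_resno = a$resno[d],
        donor_resid = a$resid[d], donor_atom = a$elety[d],
        acceptor_chain = a$chain[ac], acceptor_resno = a$resno[ac],
        acceptor_resid = a$resid[ac], acceptor_atom = a$elety[ac],
        distance = dist, angle = ang)
    }
  }
  if (length(out) == 0L) {
    return(tibble(donor_chain = character(), donor_resno = integer(),
                  donor_resid = character(), donor_atom = character(),
                  acceptor_chain = character(), acceptor_resno = integer(),
                  acceptor_resid = character(), acceptor_atom = character(),
                  distance = numeric(), angle = numeric()))
  }
  do.call(rbind, out)
}

#' Detect a salt bridge between a basic and an acidic residue
#'
#' Present when any charged-nitrogen to carboxylate-oxygen distance is at
#' most `d_max` (Lys NZ / Arg NE, NH1, NH2 versus Glu OE1, OE2 / Asp OD1,
#' OD2).
#'
#' @param model A `structure_model`.
#' @param basic_site,acidic_site Lists with `resno` and optionally
#'   `chain`; the residues must be Lys/Arg and Glu/Asp respectively.
#' @param d_max Distance cutoff in angstrom (default 4.0).
#' @return List with `present` (logical) and `min_dist`.
#' @export
find_salt_bridge <- function(model, basic_site, acidic_site, d_max = 4.0) {
  stopifnot(inherits(model, "structure_model"))
  a <- model$atoms
  brows <- residue_rows(model, basic_site)
  arows <- residue_rows(model, acidic_site)
  bres <- a$resid[brows[[1L]]]
  ares <- a$resid[arows[[1L]]]
  batoms <- switch(bres, LYS = "NZ", ARG = c("NE", "NH1", "NH2"),
                   stop("basic site must be Lys or Arg, got ", bres,
                        call. = FALSE))
  aatoms <- switch(ares, GLU = c("OE1", "OE2"), ASP = c("OD1", "OD2"),
                   stop("acidic site must be Glu or Asp, got ", ares,
                        call. = FALSE))
  bi <- brows[a$elety[brows] %in% batoms]
  ai <- arows[a$elety[arows] %in% aatoms]
  if (length(bi) == 0L || length(ai) == 0L) {
    stop("charged-group atoms missing (", paste(batoms, collapse = "/"),
         " or ", paste(aatoms, collapse = "/"), ")", call. = FALSE)
  }
  dmin <- min(vapply(bi, function(b) {
    min(vapply(ai, function(x) {
      sqrt(sum((atom_xyz(model, b) - atom_xyz(model, x))^2))
    }, numeric(1L)))
  }, numeric(1L)))
  list(present = dmin <= d_max, min_dist = dmin)
}

#' Detect a three-centre hydrophobic staple
#'
#' Present when all three pairwise minimum side-chain carbon-carbon
#' distances between the three residues are at most `d_max`.  Such a
#' staple (e.g. Ile278-Leu217-Leu219 in yeast beta-tubulin) can stabilise
#' a loop-loop interaction.
#'
#' @param model A `structure_model`.
#' @param sites List of three site lists (`resno`, optional `chain`).
#' @param d_max Distance cutoff in angstrom (default 5.0).
#' @return List with `present` (logical) and `pairs` (tibble of pairwise
#'   minimum side-chain C-C distances).
#' @export
find_hydrophobic_staple <- function(model, sites, d_max = 5.0) {
  stopifnot(inherits(model, "structure_model"), length(sites) == 3L)
  a <- model$atoms
  sc <- lapply(sites, function(s) {
    rows <- residue_rows(model, s)
    if (a$resid[rows[[1L]]] == "GLY") {
      stop("Gly at resno ", s$resno, " has no side-chain carbon atoms",
           call. = FALSE)
    }
    idx <- rows[a$elesy[rows] == "C" & !(a$elety[rows] %in% c("N", "CA", "C", "O", "OXT"))]
    if (length(idx) == 0L) {
      stop("no side-chain carbon atoms at resno ", s$resno, call. = FALSE)
    }
    idx
  })
  combs <- list(c(1L, 2L), c(1L, 3L), c(2L, 3L))
  pairs <- do.call(rbind, lapply(combs, function(p) {
    d <- min(vapply(sc[[p[1L]]], function(i) {
      min(vapply(sc[[p[2L]]], function(j) {
        sqrt(sum((atom_xyz(model, i) - atom_xyz(model, j))^2))
      }, numeric(1L)))
    }, numeric(1L)))
    tibble(resno1 = sites[[p[1L]]]$resno, resno2 = sites[[p[2L]]]$resno,
           min_dist = d)
  }))
  list(present = all(pairs$min_dist <= d_max), pairs = pairs)
}

#' Tabulate i to i+4 helix backbone hydrogen bonds
#'
#' For each residue i in the range, reports whether the backbone carbonyl
#' O(i) and amide N(i+4) satisfy the geometric H-bond criterion of
#' [find_hbonds()].  Residues with missing backbone atoms are flagged, not
#' fatal.  A distorted or unwound helix shows up as unsatisfied pairs.
#'
#' @param model A `structure_model`.
#' @param chain Chain identifier.
#' @param resno_range Integer range of residue numbers (length >= 5).
#' @param d_max,angle_min H-bond criterion (defaults 3.5 angstrom, 120
#'   degrees).
#' @return List with `table` (tibble: `resno_i`, `resno_i4`, `distance`,
#'   `angle`, `satisfied`, `missing`) and `fraction` (satisfied fraction
#'   over non-missing pairs).
#' @export
helix_backbone_hbonds <- function(model, chain, resno_range,
                                  d_max = 3.5, angle_min = 120) {
  stopifnot(inherits(model, "structure_model"))
  resnos <- seq(min(resno_range), max(resno_range))
  if (length(resnos) < 5L) {
    stop("residue range must span at least 5 residues", call. = FALSE)
  }
  a <- model$atoms
  rows <- lapply(resnos, function(r) {
    which(a$chain == chain & a$resno == r)
  })
  out <- do.call(rbind, lapply(seq_len(length(resnos) - 4L), function(k) {
    ri <- rows[[k]]
    rj <- rows[[k + 4L]]
    oi <- ri[a$elety[ri] == "O"]
    nj <- rj[a$elety[rj] == "N"]
    if (length(oi) == 0L || length(nj) == 0L) {
      return(tibble(resno_i = resnos[[k]], resno_i4 = resnos[[k + 4L]],
                    distance = NA_real_, angle = NA_real_,
                    satisfied = NA, missing = TRUE))
    }
    po <- atom_xyz(model, oi[[1L]])
    pn <- atom_xyz(model, nj[[1L]])
    dist <- sqrt(sum((po - pn)^2))
    ante <- antecedents(model, nj[[1L]], exclude = oi[[1L]])
    ang <- if (length(ante) == 0L) NA_real_ else {
      max(vapply(ante, function(i) angle_points(atom_xyz(model, i), pn, po),
                 numeric(1L)))
    }
    tibble(resno_i = resnos[[k]], resno_i4 = resnos[[k + 4L]],
           distance = dist, angle = ang,
           satisfied = dist <= d_max & !is.na(ang) & ang >= angle_min,
           missing = FALSE)
  }))
  ok <- !out$missing
  list(table = out,
       fraction = if (any(ok)) mean(out$satisfied[ok]) else NA_real_)
}
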