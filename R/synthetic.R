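# Synthetic data: family-structured alignments with planted substitution
# modes, and minimal PDB fixtures with controlled geometry.  Every
# generator takes an explicit seed; no global random state is consumed.

#' Specify a synthetic binding-site alignment
#'
#' Defines a generator for alignments built from a consensus string plus
#' independent planted substitution modes: each mode is a set of
#' (position, alternative letter) substitutions toggled jointly per
#' sequence with Bernoulli probability `prob`, emulating co-varying
#' binding-site axes such as the joint 23/26 substitution and the single
#' 277 substitution of beta-tubulin.  Independent background noise
#' substitutes each position to a random different amino acid with rate
#' `noise`.
#'
#' @param n Number of sequences.
#' @param consensus Consensus residue string (alphabet: 20 amino acids and
#'   gap).
#' @param modes List of modes, each a list with integer `positions`,
#'   character `letters` (same length) and scalar `prob` in \[0, 1\].
#'   Mode positions must be disjoint between modes.
#' @param noise Per-position background substitution rate in \[0, 1).
#' @param seed Integer random seed (required; generation is deterministic
#'   given the spec).
#' @return Object of class `synthetic_spec`.
#' @export
synthetic_alignment_spec <- function(n, consensus, modes = list(),
                                     noise = 0, seed = 1L) {
  P <- nchar(consensus)
  check_alphabet(seq_char_matrix(consensus), context = "consensus")
  used <- integer(0)
  for (m in modes) {
    if (length(m$positions) != length(m$letters)) {
      stop("mode positions and letters must have equal length", call. = FALSE)
    }
    if (any(m$positions < 1L) || any(m$positions > P)) {
      stop("mode position out of range 1..", P, call. = FALSE)
    }
    if (any(m$positions %in% used)) {
      stop("mode positions must be disjoint between modes", call. = FALSE)
    }
    if (m$prob < 0 || m$prob > 1) {
      stop("mode probability must lie in [0, 1]", call. = FALSE)
    }
    check_alphabet(matrix(m$letters, nrow = 1L), context = "mode letters")
    used <- c(used, m$positions)
  }
  if (noise < 0 || noise >= 1) {
    stop("noise rate must lie in [0, 1)", call. = FALSE)
  }
  structure(list(n = as.integer(n), P = P, consensus = consensus,
                 modes = modes, noise = noise, seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a synthetic alignment with planted modes
#'
#' Deterministic given the spec's seed.  Each sequence carries a
#' ground-truth mode-membership vector; a family label is derived from the
#' membership pattern (`"consensus"`, `"mode1"`, `"mode2"`,
#' `"mode1+mode2"`, ...).
#'
#' @param spec A `synthetic_spec`.
#' @return List with `records` (tibble: `id`, `family`, `pbs_string`) and
#'   `modes` (n x n_modes logical matrix of true memberships).
#' @export
generate_alignment <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  withr::with_seed(spec$seed, {
    n <- spec$n
    cons <- strsplit(spec$consensus, "", fixed = TRUE)[[1L]]
    P <- spec$P
    nm <- length(spec$modes)
    z <- matrix(FALSE, nrow = n, ncol = max(nm, 1L))
    if (nm > 0L) {
      for (m in seq_len(nm)) {
        z[, m] <- stats::runif(n) < spec$modes[[m]]$prob
      }
    }
    cm <- matrix(rep(cons, each = n), nrow = n)
    if (nm > 0L) {
      for (m in seq_len(nm)) {
        rows <- which(z[, m])
        for (j in seq_along(spec$modes[[m]]$positions)) {
          cm[rows, spec$modes[[m]]$positions[[j]]] <- spec$modes[[m]]$letters[[j]]
        }
      }
    }
    if (spec$noise > 0) {
      hit <- matrix(stats::runif(n * P) < spec$noise, nrow = n)
      idx <- which(hit, arr.ind = TRUE)
      for (r in seq_len(nrow(idx))) {
        cur <- cm[idx[r, 1L], idx[r, 2L]]
        pool <- setdiff(aa20(), cur)
        cm[idx[r, 1L], idx[r, 2L]] <- sample(pool, 1L)
      }
    }
    fam <- apply(z[, seq_len(max(nm, 1L)), drop = FALSE], 1L, function(zz) {
      on <- which(zz)
      if (length(on) == 0L) "consensus" else paste0("mode", on, collapse = "+")
    })
    records <- tibble(
      id = sprintf("syn%04d", seq_len(n)),
      family = fam,
      pbs_string = apply(cm, 1L, paste0, collapse = "")
    )
    list(records = records, modes = z[, seq_len(max(nm, 0L)), drop = FALSE])
  })
}

#' Unit channel contrast of a planted mode
#'
#' The encoded-space direction a planted mode moves sequences along:
#' +1 on the alternative-letter channels, -1 on the consensus-letter
#' channels of the mode's positions, normalised to unit length.  Used to
#' check that PCA recovers planted modes (|cosine| with an eigenvector).
#'
#' @param spec A `synthetic_spec`.
#' @param mode Mode index.
#' @return Unit numeric vector of length 21 * P.
#' @export
mode_contrast <- function(spec, mode) {
  stopifnot(inherits(spec, "synthetic_spec"))
  m <- spec$modes[[mode]]
  cons <- strsplit(spec$consensus, "", fixed = TRUE)[[1L]]
  ab <- aa_alphabet()
  v <- numeric(21L * spec$P)
  for (j in seq_along(m$positions)) {
    p <- m$positions[[j]]
    block <- (p - 1L) * 21L
    v[block + match(m$letters[[j]], ab)] <- 1
    v[block + match(cons[[p]], ab)] <- -1
  }
  v / sqrt(sum(v^2))
}

helix_backbone <- function(n_res, phi = -57, psi = -47, omega = 180) {
  # standard bond geometry; first residue placed in the xy-plane
  bNCA <- 1.458; bCAC <- 1.525; bCN <- 1.329; bCO <- 1.231
  aNCAC <- 111.2; aCACN <- 116.2; aCNCA <- 121.7; aCACO <- 120.5
  atoms <- list()
  N <- c(0, 0, 0)
  CA <- c(bNCA, 0, 0)
  ang <- aNCAC * pi / 180
  C <- CA + bCAC * c(-cos(ang), sin(ang), 0)
  for (i in seq_len(n_res)) {
    atoms[[length(atoms) + 1L]] <- list(i, "N", N)
    atoms[[length(atoms) + 1L]] <- list(i, "CA", CA)
    atoms[[length(atoms) + 1L]] <- list(i, "C", C)
    Nn <- place_atom(N, CA, C, bCN, aCACN, psi)
    O <- place_atom(N, CA, C, bCO, aCACO, psi + 180)
    atoms[[length(atoms) + 1L]] <- list(i, "O", O)
    if (i == n_res) break
    CAn <- place_atom(CA, C, Nn, bNCA, aCNCA, omega)
    Cn <- place_atom(C, Nn, CAn, bCAC, aNCAC, phi)
    N <- Nn; CA <- CAn; C <- Cn
  }
  atoms
}

# evenly spread unit directions (deterministic golden spiral)
spread_directions <- function(k) {
  i <- seq_len(k) - 0.5
  theta <- acos(1 - 2 * i / k)
  phi <- pi * (1 + sqrt(5)) * i
  cbind(sin(theta) * cos(phi), sin(theta) * sin(phi), cos(theta))
}

fixture_atoms <- function(rows) {
  # rows: list of list(resno, elety, xyz, resid, chain, record)
  do.call(rbind, lapply(rows, function(r) {
    tibble(record = r$record %||% "ATOM", eleno = 0L, elety = r$elety,
           alt = "", resid = r$resid %||% "ALA", chain = r$chain %||% "A",
           resno = as.integer(r$resno), insert = "",
           x = r$xyz[[1L]], y = r$xyz[[2L]], z = r$xyz[[3L]],
           o = 1, b = 0, elesy = guess_element(r$elety))
  }))
}

#' Generate a minimal synthetic structure fixture
#'
#' Builds small, exactly controlled structure models for exercising the
#' geometric operators without any external structure files:
#'
#' * `"contact_shell"`: a single-atom HETATM ligand (`LIG`, chain X) at
#'   the origin with one-atom residues placed at the requested
#'   `distances`; residues listed in `hydrogen_only` get a hydrogen
#'   instead of a heavy atom.
#' * `"ideal_helix"`: poly-Ala backbone built at the requested `phi`/`psi`
#'   (defaults -57/-47, an ideal alpha helix; use 180/180 for a fully
#'   extended chain).
#' * `"hbond_pair"`: a donor N with a CA antecedent and an acceptor O at
#'   exactly the requested `distance` and antecedent `angle`.
#' * `"staple_triangle"`: three residues whose CB atoms sit at pairwise
#'   distances `d12`, `d13`, `d23` (triangle inequality enforced).
#'
#' @param kind Fixture kind (see above).
#' @param ... Kind-specific parameters: `distances`, `hydrogen_only`;
#'   `n_res`, `phi`, `psi`; `distance`, `angle`; `d12`, `d13`, `d23`.
#' @return A `structure_model`.
#' @export
generate_structure_fixture <- function(kind = c("contact_shell",
                                                "ideal_helix",
                                                "hbond_pair",
                                                "staple_triangle"), ...) {
  kind <- match.arg(kind)
  p <- list(...)
  rows <- switch(
    kind,
    contact_shell = {
      distances <- p$distances %||% c(4.0, 4.9, 5.1)
      if (any(distances <= 0)) stop("distances must be positive", call. = FALSE)
      hyd <- p$hydrogen_only %||% integer(0)
      dirs <- spread_directions(length(distances))
      c(list(list(resno = 900L, elety = "C1", xyz = c(0, 0, 0),
                  resid = "LIG", chain = "X", record = "HETATM")),
        lapply(seq_along(distances), function(i) {
          list(resno = i, elety = if (i %in% hyd) "H1" else "CA",
               xyz = distances[[i]] * dirs[i, ], chain = "A")
        }))
    },
    ideal_helix = {
      n_res <- p$n_res %||% 12L
      bb <- helix_backbone(n_res, phi = p$phi %||% -57, psi = p$psi %||% -47)
      lapply(bb, function(at) {
        list(resno = at[[1L]], elety = at[[2L]], xyz = at[[3L]])
      })
    },
    hbond_pair = {
      d <- p$distance %||% 2.9
      th <- (p$angle %||% 150) * pi / 180
      if (d <= 0) stop("distance must be positive", call. = FALSE)
      N <- c(1.458, 0, 0)
      O <- N + d * c(-cos(th), sin(th), 0)
      list(list(resno = 1L, elety = "CA", xyz = c(0, 0, 0), resid = "GLY"),
           list(resno = 1L, elety = "N", xyz = N, resid = "GLY"),
           list(resno = 10L, elety = "O", xyz = O, resid = "GLY"))
    },
    staple_triangle = {
      d12 <- p$d12 %||% 4.0; d13 <- p$d13 %||% 4.0; d23 <- p$d23 %||% 4.0
      if (d12 + d13 <= d23 || d12 + d23 <= d13 || d13 + d23 <= d12) {
        stop("triangle inequality violated by (", d12, ", ", d13, ", ",
             d23, ")", call. = FALSE)
      }
      x3 <- (d12^2 + d13^2 - d23^2) / (2 * d12)
      y3 <- sqrt(max(0, d13^2 - x3^2))
      verts <- list(c(0, 0, 0), c(d12, 0, 0), c(x3, y3, 0))
      unlist(lapply(1:3, function(i) {
        list(list(resno = i, elety = "CA", xyz = verts[[i]] + c(0, 0, 1.53),
                  resid = "LEU"),
             list(resno = i, elety = "CB", xyz = verts[[i]], resid = "LEU"))
      }), recursive = FALSE)
    }
  )
  atoms <- fixture_atoms(rows)
  atoms$eleno <- seq_len(nrow(atoms))
  new_structure_model(atoms, path = paste0("<synthetic:", kind, ">"))
}

#' Write alignment records as FASTA
#'
#' @param records Data frame with `id` and `pbs_string` columns.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_fasta <- function(records, path) {
  set <- Biostrings::AAStringSet(setNames(records$pbs_string, records$id))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}
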