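#' Read an atomistic structure into per-residue records
#'
#' Thin wrapper over [bio3d::read.pdb()]. Multi-model PDB files become
#' trajectory frames. Coordinates are converted from Angstrom to nm.
#' Alternate location 'A' is preferred when altloc codes are present;
#' insertion codes are rejected.
#'
#' @param path PDB file path
#' @param helix_of optional named character vector mapping chain id to helix
#'   id; default assigns every chain to helix "H1".
#' @return list with `residues` (data.frame: chain_id, helix_id, res_index,
#'   res_name, atom_name, atom_row) and `frames` (list of n_atoms x 3
#'   matrices, nm).
#' @export
read_structure <- function(path, helix_of = NULL) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  at <- pdb$atom
  keep <- at$type %in% c("ATOM", "HETATM")
  if (any(!is.na(at$insert) & at$insert != "")) {
    stop("insertion codes are not supported: ", path)
  }
  alt_ok <- is.na(at$alt) | at$alt %in% c("", "A")
  keep <- keep & alt_ok
  idx <- which(keep)
  at <- at[idx, , drop = FALSE]
  nfr <- nrow(pdb$xyz)
  frames <- lapply(seq_len(nfr), function(i) {
    m <- matrix(pdb$xyz[i, ], ncol = 3L, byrow = TRUE)[idx, , drop = FALSE] / 10
    colnames(m) <- c("x", "y", "z")
    m
  })
  chain <- ifelse(is.na(at$chain), "A", at$chain)
  helix <- if (is.null(helix_of)) rep("H1", nrow(at)) else {
    h <- helix_of[chain]
    if (any(is.na(h))) stop("helix_of lacks an entry for chain(s): ",
                            paste(unique(chain[is.na(h)]), collapse = ", "))
    unname(h)
  }
  residues <- data.frame(
    chain_id = chain,
    helix_id = helix,
    res_index = at$resno,
    res_name = at$resid,
    atom_name = at$elety,
    atom_row = seq_len(nrow(at)),
    stringsAsFactors = FALSE
  )
  list(residues = residues, frames = frames)
}

#' Map atomistic backbone atoms to one backbone bead per residue
#'
#' Each residue contributes a single BB bead positioned at the unweighted
#' center of geometry of its backbone atoms, per frame. Residue, chain and
#' helix identity are preserved on the bead.
#'
#' @param residues atom-level data.frame as returned by [read_structure()]
#'   (`$residues`): columns chain_id, helix_id, res_index, res_name,
#'   atom_name, atom_row.
#' @param frames list of n_atoms x 3 coordinate matrices (nm).
#' @param backbone_atom_names atom names included in the center of geometry.
#'   Default is the standard protein backbone set `N, CA, C, O`; whether the
#'   carbonyl O belongs in the BB center is configurable here.
#' @param box optional per-frame box vectors passed through to the result.
#' @return a [cg_trajectory] with one BB bead per residue.
#' @export
map_backbone <- function(residues, frames,
                         backbone_atom_names = c("N", "CA", "C", "O"),
                         box = NULL) {
  if (is.matrix(frames)) frames <- list(frames)
  key <- paste(residues$chain_id, residues$res_index, sep = "\r")
  ukey <- unique(key)
  sel <- residues$atom_name %in% backbone_atom_names
  rows_of <- split(residues$atom_row[sel], factor(key[sel], levels = ukey))
  first <- match(ukey, key)
  bad <- lengths(rows_of) == 0L
  if (any(bad)) {
    i <- which(bad)[1L]
    stop("residue with no backbone atoms matching {",
         paste(backbone_atom_names, collapse = ","), "}: chain ",
         residues$chain_id[first[i]], " res ", residues$res_index[first[i]])
  }
  beads <- data.frame(
    bead_label = "BB",
    chain_id = residues$chain_id[first],
    helix_id = residues$helix_id[first],
    res_index = residues$res_index[first],
    res_name = residues$res_name[first],
    stringsAsFactors = FALSE
  )
  cg_frames <- lapply(frames, function(fr) {
    if (!all(is.finite(fr))) stop("non-finite atomistic coordinates")
    m <- t(vapply(rows_of, function(rows) colMeans(fr[rows, , drop = FALSE]),
                  numeric(3)))
    dimnames(m) <- list(NULL, c("x", "y", "z"))
    m
  })
  cg_trajectory(beads, cg_frames, box = box)
}

# displacement b - a with orthorhombic minimum image when box given
.mi_disp <- function(a, b, box = NULL) {
  d <- b - a
  if (!is.null(box)) d <- d - round(d / box) * box
  d
}

.vec_angle <- function(u, v) {
  cosang <- sum(u * v) / sqrt(sum(u * u) * sum(v * v))
  acos(max(-1, min(1, cosang))) * 180 / pi
}

# IUPAC right-handed signed torsion, degrees in (-180, 180]
.vec_dihedral <- function(b1, b2, b3) {
  n1 <- .cross3(b1, b2)
  n2 <- .cross3(b2, b3)
  x <- sum(n1 * n2)
  y <- sum(.cross3(n1, n2) * b2) / sqrt(sum(b2 * b2))
  ang <- atan2(y, x) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

.cross3 <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

#' Measure bonded degrees of freedom on a CG trajectory
#'
#' Walks every run of consecutive beads within a chain (tuples never span
#' chain boundaries) and collects per-frame bond lengths (nm), interior
#' angles (degrees, in `[0, 180]`) or signed torsions (degrees, IUPAC
#' right-handed convention, in `(-180, 180]`). With box vectors present the
#' minimum-image displacement is used.
#'
#' @param traj a [cg_trajectory]
#' @param term_kind one of `"bond"`, `"angle"`, `"dihedral"`
#' @return list with `tuples` (data.frame of bead index tuples and the
#'   chain), `samples` (list of numeric vectors, one per tuple, one value
#'   per valid frame) and `diagnostics` (number of frames excluded per tuple
#'   because consecutive beads coincide).
#' @export
measure_bonded <- function(traj, term_kind = c("bond", "angle", "dihedral")) {
  term_kind <- match.arg(term_kind)
  span <- c(bond = 2L, angle = 3L, dihedral = 4L)[[term_kind]]
  beads <- traj$beads
  tuples <- list()
  for (ch in unique(beads$chain_id)) {
    idx <- which(beads$chain_id == ch)
    if (length(idx) < span) next
    for (s in seq_len(length(idx) - span + 1L)) {
      tuples[[length(tuples) + 1L]] <- idx[s:(s + span - 1L)]
    }
  }
  if (length(tuples) == 0L) {
    stop("no chain long enough for term kind '", term_kind, "'")
  }
  tup_mat <- do.call(rbind, tuples)
  samples <- vector("list", length(tuples))
  excluded <- integer(length(tuples))
  for (f in seq_along(traj$frames)) {
    fr <- traj$frames[[f]]
    box <- if (!is.null(traj$box)) traj$box[[f]] else NULL
    for (t in seq_along(tuples)) {
      p <- fr[tuples[[t]], , drop = FALSE]
      val <- switch(term_kind,
        bond = {
          d <- .mi_disp(p[1, ], p[2, ], box)
          sqrt(sum(d * d))
        },
        angle = {
          u <- .mi_disp(p[2, ], p[1, ], box)
          v <- .mi_disp(p[2, ], p[3, ], box)
          if (sum(u * u) == 0 || sum(v * v) == 0) NA_real_ else .vec_angle(u, v)
        },
        dihedral = {
          b1 <- .mi_disp(p[1, ], p[2, ], box)
          b2 <- .mi_disp(p[2, ], p[3, ], box)
          b3 <- .mi_disp(p[3, ], p[4, ], box)
          if (sum(b1 * b1) == 0 || sum(b2 * b2) == 0 || sum(b3 * b3) == 0) {
            NA_real_
          } else .vec_dihedral(b1, b2, b3)
        }
      )
      if (is.na(val)) excluded[t] <- excluded[t] + 1L else {
        samples[[t]] <- c(samples[[t]], val)
      }
    }
  }
  tup_df <- as.data.frame(tup_mat)
  names(tup_df) <- paste0("bead", seq_len(span))
  tup_df$chain_id <- beads$chain_id[tup_mat[, 1]]
  tup_df$first_res <- beads$res_name[tup_mat[, 1]]
  list(tuples = tup_df, samples = samples,
       diagnostics = data.frame(tuple = seq_along(tuples), excluded = excluded))
}

#' Pool bonded samples into one vector
#'
#' Convenience for feeding [fit_gaussian()] / [fit_bimodal()].
#'
#' @param measured result of [measure_bonded()]
#' @return numeric vector of all samples pooled across tuples and frames
#' @export
pool_samples <- function(measured) {
  unlist(measured$samples, use.names = FALSE)
}
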