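#' Construct a coarse-grained bead trajectory
#'
#' A `cg_trajectory` holds an ordered bead table (identity) plus per-frame
#' coordinates. It is the central container passed between the mapping,
#' topology and analysis functions. All coordinates are in nanometres.
#'
#' @param beads data.frame with columns `bead_label`, `chain_id`, `helix_id`,
#'   `res_index` (1-based integer, strictly increasing within a chain) and
#'   `res_name` (3-letter code, `HYP` allowed).
#' @param frames list of numeric matrices, each `n_beads x 3`, one per frame
#'   (nm). A single matrix is promoted to a one-frame list.
#' @param box optional list of per-frame box vectors; each entry either a
#'   length-3 numeric (orthorhombic box lengths, nm) or `NULL`.
#' @param time optional numeric vector of frame times (ns).
#'
#' @return An object of class `cg_trajectory` with elements `beads`,
#'   `frames`, `box`, `time`.
#' @export
cg_trajectory <- function(beads, frames, box = NULL, time = NULL) {
  stopifnot(is.data.frame(beads))
  required <- c("bead_label", "chain_id", "helix_id", "res_index", "res_name")
  missing_cols <- setdiff(required, names(beads))
  if (length(missing_cols) > 0L) {
    stop("beads table is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (is.matrix(frames)) frames <- list(frames)
  if (!is.list(frames) || length(frames) == 0L) {
    stop("frames must be a non-empty list of coordinate matrices")
  }
  nb <- nrow(beads)
  for (i in seq_along(frames)) {
    fr <- frames[[i]]
    if (!is.matrix(fr) || ncol(fr) != 3L || nrow(fr) != nb) {
      stop("frame ", i, " is not an n_beads x 3 matrix (expected ", nb, " beads)")
    }
    if (!all(is.finite(fr))) stop("frame ", i, " contains non-finite coordinates")
  }
  # res_index strictly increasing within each chain
  for (ch in unique(beads$chain_id)) {
    ri <- beads$res_index[beads$chain_id == ch]
    if (any(diff(ri) <= 0)) {
      stop("res_index not strictly increasing within chain ", ch)
    }
  }
  if (!is.null(box)) {
    if (!is.list(box)) box <- rep(list(box), length(frames))
    stopifnot(length(box) == length(frames))
  }
  if (!is.null(time)) stopifnot(length(time) == length(frames))
  structure(
    list(beads = beads, frames = frames, box = box, time = time),
    class = "cg_trajectory"
  )
}

#' @export
print.cg_trajectory <- function(x, ...) {
  cat("cg_trajectory:", nrow(x$beads), "beads x", length(x$frames), "frame(s)\n")
  cat("  chains:", paste(unique(x$beads$chain_id), collapse = " "), "\n")
  cat("  helices:", paste(unique(x$beads$helix_id), collapse = " "), "\n")
  if (!is.null(x$box)) cat("  box: present\n")
  invisible(x)
}

#' Number of frames / beads in a cg_trajectory
#' @param traj a [cg_trajectory] object
#' @return integer count
#' @export
n_frames <- function(traj) length(traj$frames)

#' @rdname n_frames
#' @export
n_beads <- function(traj) nrow(traj$beads)

#' Write a cg_trajectory as a multi-model PDB of pseudo-atoms
#'
#' Beads become pseudo-atoms with the bead label in the atom-name field and
#' the residue/chain identity preserved; frames become MODEL records.
#' Coordinates are converted from nm to Angstrom on write.
#'
#' @param traj a [cg_trajectory]
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_cg_pdb <- function(traj, path) {
  nb <- n_beads(traj)
  xyz <- do.call(rbind, lapply(traj$frames, function(fr) as.numeric(t(fr)) * 10))
  chain <- substr(as.character(traj$beads$chain_id), 1L, 1L)
  bio3d::write.pdb(
    file = path,
    xyz = xyz,
    type = rep("ATOM", nb),
    resno = traj$beads$res_index,
    resid = traj$beads$res_name,
    eleno = seq_len(nb),
    elety = substr(traj$beads$bead_label, 1L, 4L),
    chain = chain
  )
  invisible(path)
}

#' Write the bead identity table as CSV
#'
#' @param traj a [cg_trajectory]
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_bead_table <- function(traj, path) {
  utils::write.csv(traj$beads, path, row.names = FALSE)
  invisible(path)
}
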