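#' Default Martini 3 backbone parameter set for collagen
#'
#' Returns the fine-tuned backbone bonded parameters: two bond potentials
#' (the sequence-specific dual-bond rule: a short bond where the first
#' residue is proline-like, a general bond otherwise), one angle and one
#' proper dihedral. Bond force constants are the values refit under
#' constant-force pulling; angle/dihedral force constants come from
#' equilibrium inversion.
#'
#' @return named list with `bond_general`, `bond_short`, `angle`, `dihedral`
#'   (`bonded_parameter` objects)
#' @export
backbone_params <- function() {
  list(
    bond_general = bonded_parameter("bond", eq_value = 0.356,
                                    force_constant = 18000,
                                    source = "force_fine_tuned"),
    bond_short = bonded_parameter("bond", eq_value = 0.320,
                                  force_constant = 34000,
                                  source = "force_fine_tuned"),
    angle = bonded_parameter("angle", eq_value = 138, force_constant = 152,
                             k_unit = "kJ mol-1", source = "equilibrium_inversion"),
    dihedral = bonded_parameter("dihedral", eq_value = 76, force_constant = 17,
                                k_unit = "kJ mol-1", source = "equilibrium_inversion")
  )
}

.PROLINE_LIKE <- c("PRO", "HYP")

.STANDARD_RES <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                   "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
                   "THR", "TRP", "TYR", "VAL", "HYP")

#' Classify a backbone bond by its first residue
#'
#' The short bond potential applies to HYP/PRO-X pairs (X any residue):
#' the first residue of the bond decides the class.
#'
#' @param first_res,second_res 3-letter residue codes (HYP allowed)
#' @return `"short_class"` if `first_res` is PRO or HYP, else
#'   `"general_class"`
#' @export
classify_bond <- function(first_res, second_res) {
  unknown <- setdiff(unique(c(first_res, second_res)), .STANDARD_RES)
  if (length(unknown) > 0L) {
    stop("unknown residue code(s): ", paste(unknown, collapse = ", "))
  }
  ifelse(first_res %in% .PROLINE_LIKE, "short_class", "general_class")
}

#' Derive the bond-class assignment from measured bond lengths
#'
#' Applies the bimodal threshold as a filter on measured BB-BB bond
#' samples: for every first-residue type, the fraction of its bond samples
#' below the threshold is computed; types with fraction > 0.5 are assigned
#' the short bond class. Residue types with fewer than 50 samples are
#' flagged low-confidence and fall back to the sequence rule
#' ([classify_bond()]).
#'
#' @param traj a [cg_trajectory]
#' @param threshold bond-length threshold in nm (default [x0_default()],
#'   the crossing of the two fitted bond modes)
#' @return data.frame with one row per first-residue type: `res_name`,
#'   `n_samples`, `fraction_below`, `assigned_class`, `low_confidence`
#' @export
classify_from_trajectory <- function(traj, threshold = x0_default()) {
  if (n_frames(traj) < 1L) stop("trajectory must have at least one frame")
  mb <- measure_bonded(traj, "bond")
  first_res <- mb$tuples$first_res
  res_types <- unique(first_res)
  rows <- lapply(res_types, function(rt) {
    s <- unlist(mb$samples[first_res == rt], use.names = FALSE)
    frac <- mean(s < threshold)
    low <- length(s) < 50L
    cls <- if (low) {
      classify_bond(rt, "GLY")
    } else if (frac > 0.5) "short_class" else "general_class"
    data.frame(res_name = rt, n_samples = length(s), fraction_below = frac,
               assigned_class = cls, low_confidence = low,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Construct a CG topology object
#'
#' @param molecule_name molecule name
#' @param beads data.frame with columns `index`, `bead_type`, `name`,
#'   `residue`, `res_index`, `charge`, `mass` (and optionally `chain_id`,
#'   `helix_id`)
#' @param bonds,angles,dihedrals data.frames of bonded terms with bead index
#'   columns `i`,`j`(,`k`,`l`), `eq_value`, `force_constant`, `funct`
#' @param exclusions data.frame with columns `i`, `j`
#' @param go_contacts data.frame with columns `i`, `j`, `sigma_lj`, `epsilon`
#' @return object of class `cg_topology`
#' @export
cg_topology <- function(molecule_name, beads,
                        bonds = NULL, angles = NULL, dihedrals = NULL,
                        exclusions = NULL, go_contacts = NULL) {
  empty <- function(cols) {
    df <- as.data.frame(stats::setNames(rep(list(numeric(0)), length(cols)), cols))
    df
  }
  if (is.null(bonds)) bonds <- empty(c("i", "j", "eq_value", "force_constant", "funct"))
  if (is.null(angles)) angles <- empty(c("i", "j", "k", "eq_value", "force_constant", "funct"))
  if (is.null(dihedrals)) dihedrals <- empty(c("i", "j", "k", "l", "eq_value", "force_constant", "funct"))
  if (is.null(exclusions)) exclusions <- empty(c("i", "j"))
  if (is.null(go_contacts)) go_contacts <- empty(c("i", "j", "sigma_lj", "epsilon"))
  top <- structure(
    list(molecule_name = molecule_name, beads = beads, bonds = bonds,
         angles = angles, dihedrals = dihedrals, exclusions = exclusions,
         go_contacts = go_contacts),
    class = "cg_topology"
  )
  validate_topology(top)
  top
}

#' Validate a cg_topology's structural invariants
#'
#' Checks bead index contiguity, that every bonded/exclusion/contact index
#' refers to an existing bead, and that the net charge is integral to 1e-6.
#'
#' @param top a `cg_topology`
#' @return `top` invisibly; stops on violation
#' @export
validate_topology <- function(top) {
  idx <- top$beads$index
  if (anyDuplicated(idx) || !identical(as.integer(idx), seq_along(idx))) {
    stop("bead indices must be unique and contiguous from 1")
  }
  all_ref <- c(top$bonds$i, top$bonds$j, top$angles$i, top$angles$j,
               top$angles$k, top$dihedrals$i, top$dihedrals$j,
               top$dihedrals$k, top$dihedrals$l, top$exclusions$i,
               top$exclusions$j, top$go_contacts$i, top$go_contacts$j)
  if (length(all_ref) && (min(all_ref) < 1 || max(all_ref) > length(idx))) {
    stop("bonded term refers to a bead index outside the bead table")
  }
  q <- sum(top$beads$charge)
  if (abs(q - round(q)) > 1e-6) stop("net charge is not integral: ", q)
  if (any(abs(top$beads$charge) > 1)) stop("bead charge outside [-1, 1] e")
  invisible(top)
}

#' @export
print.cg_topology <- function(x, ...) {
  cat("cg_topology:", x$molecule_name, "\n")
  cat(sprintf("  %d beads | %d bonds | %d angles | %d dihedrals | %d exclusions | %d Go contacts\n",
              nrow(x$beads), nrow(x$bonds), nrow(x$angles), nrow(x$dihedrals),
              nrow(x$exclusions), nrow(x$go_contacts)))
  cat(sprintf("  net charge: %+.3f e\n", sum(x$beads$charge)))
  invisible(x)
}

# standard Martini bead masses by size prefix (amu)
.bead_mass <- function(bead_type) {
  ifelse(startsWith(bead_type, "T"), 36,
         ifelse(startsWith(bead_type, "S"), 54, 72))
}

#' Build the backbone topology of a (multi-chain) collagen molecule
#'
#' Emits N-1 bonds, N-2 angles and N-3 dihedrals per chain of N residues.
#' Bonds follow the sequence rule: a pair whose first residue is PRO/HYP
#' gets the short bond potential, all other pairs the general one. Terms
#' whose span exceeds the chain length are omitted for that chain.
#'
#' @param sequences list of character vectors of 3-letter codes, one per
#'   chain (a single vector is promoted to a one-chain list)
#' @param params parameter set as returned by [backbone_params()]
#' @param molecule_name molecule name for the topology
#' @param bead_type Martini bead type used for every BB bead (default P2)
#' @param angle_funct GROMACS functional code for angles: 1 (harmonic,
#'   default) or 2 (cosine-harmonic G96 form); the printed numbers are kept
#'   either way
#' @return a `cg_topology`
#' @export
build_backbone_topology <- function(sequences, params = backbone_params(),
                                    molecule_name = "collagen_bb",
                                    bead_type = "P2", angle_funct = 1L) {
  if (!is.list(sequences)) sequences <- list(sequences)
  if (any(vapply(sequences, length, 1L) < 2L)) stop("each chain needs >= 2 residues")
  beads <- do.call(rbind, lapply(seq_along(sequences), function(c_i) {
    seqc <- sequences[[c_i]]
    data.frame(index = 0L, bead_type = bead_type, name = "BB",
               residue = seqc, res_index = seq_along(seqc),
               charge = 0, mass = .bead_mass(bead_type),
               chain_id = sprintf("C%d", c_i), stringsAsFactors = FALSE)
  }))
  beads$index <- seq_len(nrow(beads))
  bonds <- angles <- dihedrals <- list()
  offset <- 0L
  for (seqc in sequences) {
    n <- length(seqc)
    cls <- classify_bond(seqc[-n], seqc[-1])
    p_bond <- ifelse(cls == "short_class",
                     list(params$bond_short), list(params$bond_general))
    bonds[[length(bonds) + 1L]] <- data.frame(
      i = offset + seq_len(n - 1L), j = offset + seq_len(n - 1L) + 1L,
      eq_value = vapply(p_bond, function(p) p$eq_value, 1),
      force_constant = vapply(p_bond, function(p) p$force_constant, 1),
      funct = 1L, class = cls, stringsAsFactors = FALSE)
    if (n >= 3L) {
      angles[[length(angles) + 1L]] <- data.frame(
        i = offset + seq_len(n - 2L), j = offset + seq_len(n - 2L) + 1L,
        k = offset + seq_len(n - 2L) + 2L,
        eq_value = params$angle$eq_value,
        force_constant = params$angle$force_constant, funct = as.integer(angle_funct))
    }
    if (n >= 4L) {
      dihedrals[[length(dihedrals) + 1L]] <- data.frame(
        i = offset + seq_len(n - 3L), j = offset + seq_len(n - 3L) + 1L,
        k = offset + seq_len(n - 3L) + 2L, l = offset + seq_len(n - 3L) + 3L,
        eq_value = params$dihedral$eq_value,
        force_constant = params$dihedral$force_constant, funct = 1L)
    }
    offset <- offset + n
  }
  cg_topology(molecule_name, beads,
              bonds = do.call(rbind, bonds),
              angles = if (length(angles)) do.call(rbind, angles) else NULL,
              dihedrals = if (length(dihedrals)) do.call(rbind, dihedrals) else NULL)
}

#' Build intrahelical Go contacts from a reference frame
#'
#' A structure-based attractive network stabilizes the triple helix: every
#' BB pair within the same helix whose reference distance falls in
#' `[cutoff_low, cutoff_high]` and whose sequence separation within a chain
#' is at least `min_seq_sep` (pairs on different chains of the same helix
#' always qualify) receives a Lennard-Jones well of depth `epsilon` with
#' its minimum at the native distance (`sigma_lj = r_ij / 2^(1/6)`).
#' Pairs in different helices are never emitted.
#'
#' @param traj a [cg_trajectory]; the reference frame is `frame`
#' @param frame frame index used as the native structure (default 1)
#' @param cutoff_low,cutoff_high distance window in nm (defaults 0.3/1.1)
#' @param min_seq_sep minimum intra-chain sequence separation (default 3)
#' @param epsilon LJ well depth in kJ mol^-1 (default 9.414)
#' @return data.frame `i`, `j` (bead indices, i < j), `r_native`,
#'   `sigma_lj`, `epsilon`; zero rows triggers a warning
#' @export
build_go_contacts <- function(traj, frame = 1L, cutoff_low = 0.3,
                              cutoff_high = 1.1, min_seq_sep = 3L,
                              epsilon = 9.414) {
  stopifnot(cutoff_low < cutoff_high)
  xyz <- traj$frames[[frame]]
  b <- traj$beads
  n <- nrow(b)
  dm <- as.matrix(stats::dist(xyz))
  pairs <- which(upper.tri(dm) & dm >= cutoff_low & dm <= cutoff_high,
                 arr.ind = TRUE)
  if (nrow(pairs) > 0L) {
    i <- pairs[, 1]; j <- pairs[, 2]
    same_helix <- b$helix_id[i] == b$helix_id[j]
    same_chain <- b$chain_id[i] == b$chain_id[j]
    sep_ok <- !same_chain | abs(b$res_index[j] - b$res_index[i]) >= min_seq_sep
    keep <- same_helix & sep_ok
    i <- i[keep]; j <- j[keep]
  } else {
    i <- j <- integer(0)
  }
  if (length(i) == 0L) {
    warning("no Go contacts found in the distance window")
    return(data.frame(i = integer(0), j = integer(0), r_native = numeric(0),
                      sigma_lj = numeric(0), epsilon = numeric(0)))
  }
  r <- dm[cbind(i, j)]
  data.frame(i = i, j = j, r_native = r, sigma_lj = r / 2^(1 / 6),
             epsilon = epsilon)
}

#' Cross-link fragment specifications (HLKNL and PYD)
#'
#' Builds the bead table and internal bonded terms of a mature collagen
#' cross-link fragment.
#'
#' `HLKNL` (divalent hydroxylysino-5-keto-norleucine): a symmetric scheme
#' around a small `SP1d` bead for the central secondary amine, a polar `P1`
#' bead for the 1-propanol group on one arm and an `N6a` bead for the
#' 1-propanone group on the other; net charge 0.
#'
#' `PYD` (trivalent pyridinoline): the protonated pyridine ring is four
#' tiny beads in a rhombic bond arrangement (R1 = `TQ2p` ring nitrogen,
#' R2 = `TP1q` phenol, R3 = `TC6q` benzene moiety, R4 = `TC4` ortho-bridging
#' carbon toward the lysine C-alpha), bonded R1-R2, R1-R3, R2-R4, R3-R4 as
#' plain harmonic bonds (never constraints; the two nontrivial rhombus
#' bonds are what keeps the ring stable under force). Ring charges +0.7,
#' +0.2, +0.1 e sum to +1 (a compensating counter-ion is implied). An `SP1`
#' bead links the ring nitrogen toward the first C-alpha attachment; `TC4`
#' beads sit at the C-alpha connections. No ring dihedral is defined (it
#' destabilizes pulling simulations); angles position the arm beads.
#'
#' Internal bond/angle values are read from the shipped parameter table
#' (`inst/extdata/crosslink_params_synthetic.csv`, supplementary-derived
#' stand-in values) and can be overridden.
#'
#' @param xl_type `"HLKNL"` or `"PYD"`
#' @param param_file CSV of internal bonded values; default the shipped one
#' @return a `cg_topology` with attribute `attachment_sites` (bead names
#'   that bond to helix beads)
#' @export
build_crosslink <- function(xl_type = c("HLKNL", "PYD"),
                            param_file = system.file("extdata",
                                                     "crosslink_params_synthetic.csv",
                                                     package = "collagencg")) {
  xl_type <- match.arg(xl_type)
  pars <- utils::read.csv(param_file, stringsAsFactors = FALSE)
  pars <- pars[pars$xl_type == xl_type, , drop = FALSE]
  getp <- function(term, nm) {
    row <- pars[pars$term == term & pars$name == nm, , drop = FALSE]
    if (nrow(row) != 1L) stop("missing crosslink parameter: ", xl_type, " ", term, " ", nm)
    row
  }
  if (xl_type == "HLKNL") {
    beads <- data.frame(
      index = 1:3,
      bead_type = c("P1", "SP1d", "N6a"),
      name = c("PRO1", "AMN", "KET1"),
      residue = "HLK", res_index = 1L,
      charge = c(0, 0, 0),
      mass = .bead_mass(c("P1", "SP1d", "N6a")),
      stringsAsFactors = FALSE
    )
    bnames <- c("PRO1-AMN", "AMN-KET1")
    bonds <- do.call(rbind, lapply(seq_along(bnames), function(k) {
      p <- getp("bond", bnames[k])
      data.frame(i = k, j = k + 1L, eq_value = p$eq_value,
                 force_constant = p$force_constant, funct = 1L)
    }))
    p <- getp("angle", "PRO1-AMN-KET1")
    angles <- data.frame(i = 1L, j = 2L, k = 3L, eq_value = p$eq_value,
                         force_constant = p$force_constant, funct = 1L)
    top <- cg_topology("HLKNL", beads, bonds = bonds, angles = angles)
    attr(top, "attachment_sites") <- c("PRO1", "KET1")
  } else {
    beads <- data.frame(
      index = 1:6,
      bead_type = c("TQ2p", "TP1q", "TC6q", "TC4", "SP1", "TC4"),
      name = c("R1", "R2", "R3", "R4", "LNK", "CA3"),
      residue = "PYD", res_index = 1L,
      charge = c(0.7, 0.2, 0.1, 0, 0, 0),
      mass = .bead_mass(c("TQ2p", "TP1q", "TC6q", "TC4", "SP1", "TC4")),
      stringsAsFactors = FALSE
    )
    ring <- list(c(1L, 2L), c(1L, 3L), c(2L, 4L), c(3L, 4L))
    rnames <- c("R1-R2", "R1-R3", "R2-R4", "R3-R4")
    arm <- list(c(1L, 5L), c(3L, 6L))
    anames <- c("R1-LNK", "R3-CA3")
    bonds <- do.call(rbind, lapply(seq_along(c(rnames, anames)), function(k) {
      nm <- c(rnames, anames)[k]
      ij <- c(ring, arm)[[k]]
      p <- getp("bond", nm)
      data.frame(i = ij[1], j = ij[2], eq_value = p$eq_value,
                 force_constant = p$force_constant, funct = 1L)
    }))
    angs <- list(c(2L, 1L, 5L), c(3L, 1L, 5L), c(1L, 3L, 6L), c(4L, 3L, 6L))
    gnames <- c("R2-R1-LNK", "R3-R1-LNK", "R1-R3-CA3", "R4-R3-CA3")
    angles <- do.call(rbind, lapply(seq_along(gnames), function(k) {
      p <- getp("angle", gnames[k])
      ijk <- angs[[k]]
      data.frame(i = ijk[1], j = ijk[2], k = ijk[3], eq_value = p$eq_value,
                 force_constant = p$force_constant, funct = 1L)
    }))
    top <- cg_topology("PYD", beads, bonds = bonds, angles = angles)
    attr(top, "attachment_sites") <- c("LNK", "CA3", "R4")
  }
  top
}
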