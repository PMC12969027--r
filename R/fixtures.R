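#' Build an ideal (optionally thermalized) collagen-like triple helix
#'
#' Generates bead coordinates on `n_chains` phase-shifted ideal helices
#' sharing one axis (z): bead i of a chain sits at angle
#' `2*pi*i/residues_per_turn + phase` on a circle of `radius`, at height
#' `i * rise`. This is a single-minor-helix model (no supercoil), built to
#' exercise the helix analyzers, not to reproduce real collagen geometry.
#' Optional isotropic Gaussian positional noise; deterministic per seed.
#'
#' @param n_residues residues per chain
#' @param rise rise per residue (nm), default 0.290
#' @param residues_per_turn residues per turn (> 2), default 3.28
#' @param radius helix radius (nm), default 0.15
#' @param n_chains number of chains (default 3)
#' @param phase_offsets chain phase offsets in radians; default evenly
#'   spaced `2*pi/n_chains`
#' @param sequence repeating 3-letter residue pattern, default GLY-PRO-HYP
#' @param n_frames number of frames (default 1)
#' @param noise_sd isotropic positional noise SD (nm, default 0)
#' @param helix_id helix label for all chains (default "H1")
#' @param seed RNG seed used when `noise_sd > 0`
#' @return a [cg_trajectory]
#' @export
build_triple_helix <- function(n_residues, rise = 0.290,
                               residues_per_turn = 3.28, radius = 0.15,
                               n_chains = 3L,
                               phase_offsets = NULL,
                               sequence = c("GLY", "PRO", "HYP"),
                               n_frames = 1L, noise_sd = 0,
                               helix_id = "H1", seed = 1L) {
  stopifnot(residues_per_turn > 2, radius >= 0, n_residues >= 1)
  if (is.null(phase_offsets)) {
    phase_offsets <- 2 * pi * (seq_len(n_chains) - 1L) / n_chains
  }
  stopifnot(length(phase_offsets) == n_chains)
  i <- seq_len(n_residues)
  beads <- do.call(rbind, lapply(seq_len(n_chains), function(c_i) {
    data.frame(bead_label = "BB",
               chain_id = sprintf("C%d", c_i), helix_id = helix_id,
               res_index = i,
               res_name = rep_len(sequence, n_residues),
               stringsAsFactors = FALSE)
  }))
  base <- do.call(rbind, lapply(seq_len(n_chains), function(c_i) {
    ang <- 2 * pi * (i - 1L) / residues_per_turn + phase_offsets[c_i]
    cbind(x = radius * cos(ang), y = radius * sin(ang), z = (i - 1L) * rise)
  }))
  frames <- if (noise_sd > 0) {
    old <- .restore_seed(seed)
    on.exit(old(), add = TRUE)
    lapply(seq_len(n_frames), function(f) {
      base + matrix(stats::rnorm(length(base), sd = noise_sd), ncol = 3L)
    })
  } else {
    rep(list(base), n_frames)
  }
  cg_trajectory(beads, frames)
}

#' Draw bonded-term samples from a Gaussian mixture
#'
#' I.i.d. draws from a stated mixture of Gaussian components, clipped to
#' the variable's legal range (bond > 0 nm; angle in [0, 180] deg;
#' dihedral in (-180, 180] deg). Deterministic per seed.
#'
#' @param kind `"bond"`, `"angle"` or `"dihedral"`
#' @param components list of lists with `mu`, `sigma`
#' @param weights mixture weights summing to 1
#' @param n number of samples
#' @param seed RNG seed
#' @return numeric vector of length `n`
#' @export
sample_bonded <- function(kind = c("bond", "angle", "dihedral"), components,
                          weights, n, seed = 1L) {
  kind <- match.arg(kind)
  stopifnot(length(components) == length(weights),
            abs(sum(weights) - 1) < 1e-9)
  old <- .restore_seed(seed)
  on.exit(old(), add = TRUE)
  comp <- sample.int(length(weights), n, replace = TRUE, prob = weights)
  mus <- vapply(components, function(c) c$mu, 1)
  sds <- vapply(components, function(c) c$sigma, 1)
  x <- stats::rnorm(n, mean = mus[comp], sd = sds[comp])
  switch(kind,
         bond = pmax(x, 1e-6),
         angle = pmin(pmax(x, 0), 180),
         dihedral = {
           x <- (x + 180) %% 360 - 180
           x[x == -180] <- 180
           x
         })
}

#' Generate a Crooks-consistent pair of Gaussian work distributions
#'
#' Forward works are drawn from
#' `N(planted_dg + sigma_w^2 / (2 kB T), sigma_w^2)` and backward
#' (reverse-transition) works from
#' `N(-planted_dg + sigma_w^2 / (2 kB T), sigma_w^2)`; for Gaussian work
#' distributions this construction satisfies the Crooks fluctuation theorem
#' with the planted free energy exactly. `sigma_w = 0` gives dissipation-free
#' delta distributions.
#'
#' @param planted_dg true free energy difference (kJ mol^-1)
#' @param sigma_w work distribution SD (kJ mol^-1, >= 0)
#' @param n_f,n_b number of forward/backward samples
#' @param temperature temperature in K
#' @param seed RNG seed
#' @return a [work_set()]
#' @export
gen_work_sets <- function(planted_dg, sigma_w = 5, n_f = 100L, n_b = 100L,
                          temperature = 300, seed = 1L) {
  stopifnot(sigma_w >= 0)
  diss <- sigma_w^2 / (2 * .KB * temperature)
  old <- .restore_seed(seed)
  on.exit(old(), add = TRUE)
  fw <- stats::rnorm(n_f, planted_dg + diss, sigma_w)
  bw <- stats::rnorm(n_b, -planted_dg + diss, sigma_w)
  work_set(fw, bw, temperature)
}

#' Build a toy gap/overlap fibril with a per-segment strain schedule
#'
#' Beads are laid along z between `n_boundaries` cross-link positions; the
#' segments between consecutive boundaries alternate overlap (dense bead
#' spacing) and gap (sparse spacing). Each frame applies the per-segment
#' schedule affinely: a segment's length becomes `L0 * (1 + strain)`
#' (mode `"strain"`) or `L0 + elongation` (mode `"elongation"`), beads
#' inside move affinely, and downstream segments shift to keep the chain
#' contiguous. A matching harmonic bond topology (bond rest lengths = the
#' reference spacings) is emitted.
#'
#' @param n_boundaries number of cross-link positions (>= 2), default 10
#' @param overlap_len,gap_len reference segment lengths (nm); defaults
#'   split a 67 nm D-band period as 37.2/29.8 nm
#' @param overlap_spacing,gap_spacing bead spacing in each segment type
#'   (nm)
#' @param schedule data.frame with per-frame columns `overlap` and `gap`
#'   (fractional strains, or elongations in nm under mode "elongation");
#'   default one unstrained frame
#' @param schedule_mode `"strain"` or `"elongation"`
#' @param first_segment parity of the first complete segment (default
#'   `"overlap"`: 10 boundaries give five overlap and four gap segments)
#' @param bond_k harmonic force constant for the emitted topology
#' @return list: `traj` ([cg_trajectory]), `segmentation`
#'   ([segment_fibril()] result), `lengths_t` (per-frame segment length
#'   matrix), `topology` (`cg_topology`), `boundary_beads` (bead index of
#'   each boundary)
#' @export
build_toy_fibril <- function(n_boundaries = 10L,
                             overlap_len = 37.2, gap_len = 29.8,
                             overlap_spacing = 0.4, gap_spacing = 0.8,
                             schedule = NULL,
                             schedule_mode = c("strain", "elongation"),
                             first_segment = c("overlap", "gap"),
                             bond_k = 18000) {
  schedule_mode <- match.arg(schedule_mode)
  first_segment <- match.arg(first_segment)
  stopifnot(n_boundaries >= 2L, overlap_len > 0, gap_len > 0)
  if (is.null(schedule)) schedule <- data.frame(overlap = 0, gap = 0)
  k <- n_boundaries - 1L
  types <- rep(c(first_segment, setdiff(c("overlap", "gap"), first_segment)),
               length.out = k)
  len0 <- ifelse(types == "overlap", overlap_len, gap_len)
  boundaries0 <- c(0, cumsum(len0))
  seg <- segment_fibril(boundaries0, first_segment = first_segment)
  # reference bead layout: fractional positions within each segment
  frac <- vector("list", k)
  for (s in seq_len(k)) {
    sp <- if (types[s] == "overlap") overlap_spacing else gap_spacing
    npt <- max(2L, ceiling(len0[s] / sp) + 1L)
    f <- seq(0, 1, length.out = npt)
    if (s > 1L) f <- f[-1]  # boundary bead shared with previous segment
    frac[[s]] <- f
  }
  seg_of <- rep(seq_len(k), lengths(frac))
  frac_all <- unlist(frac)
  nb <- length(frac_all)
  boundary_beads <- c(1L, cumsum(lengths(frac)) )
  mk_frame <- function(ov_s, gp_s) {
    add <- if (schedule_mode == "strain") {
      len0 * (1 + ifelse(types == "overlap", ov_s, gp_s))
    } else {
      len0 + ifelse(types == "overlap", ov_s, gp_s)
    }
    bt <- c(0, cumsum(add))
    z <- bt[seg_of] + frac_all * add[seg_of]
    cbind(x = 0, y = 0, z = z)
  }
  frames <- lapply(seq_len(nrow(schedule)), function(t) {
    mk_frame(schedule$overlap[t], schedule$gap[t])
  })
  beads <- data.frame(bead_label = "BB", chain_id = "F1", helix_id = "H1",
                      res_index = seq_len(nb), res_name = "GLY",
                      stringsAsFactors = FALSE)
  traj <- cg_trajectory(beads, frames)
  bpos <- do.call(rbind, lapply(frames, function(fr) fr[boundary_beads, "z"]))
  lengths_t <- segment_lengths(seg, bpos)
  if (is.null(dim(lengths_t))) lengths_t <- matrix(lengths_t, nrow = 1L)
  r0 <- diff(mk_frame(0, 0)[, "z"])  # rest lengths from the unstrained layout
  top_beads <- data.frame(index = seq_len(nb), bead_type = "P2", name = "BB",
                          residue = "GLY", res_index = seq_len(nb),
                          charge = 0, mass = 72, stringsAsFactors = FALSE)
  bonds <- data.frame(i = seq_len(nb - 1L), j = seq_len(nb - 1L) + 1L,
                      eq_value = r0, force_constant = bond_k, funct = 1L)
  top <- cg_topology("toy_fibril", top_beads, bonds = bonds)
  list(traj = traj, segmentation = seg, lengths_t = lengths_t,
       topology = top, boundary_beads = boundary_beads)
}
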