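#' End-to-end distance time series
#'
#' Per-frame distance between the centers of geometry of two bead groups.
#'
#' @param traj a [cg_trajectory]
#' @param group_a,group_b integer vectors of bead indices
#' @return numeric vector, one distance (nm) per frame
#' @export
end_to_end <- function(traj, group_a, group_b) {
  if (length(group_a) == 0L || length(group_b) == 0L) {
    stop("bead selections must be non-empty")
  }
  vapply(traj$frames, function(fr) {
    ca <- colMeans(fr[group_a, , drop = FALSE])
    cb <- colMeans(fr[group_b, , drop = FALSE])
    sqrt(sum((cb - ca)^2))
  }, numeric(1))
}

# Local helix parameters from a window of consecutive bead positions.
# Axis from the rotation geometry: the second differences of consecutive
# bead vectors point at the axis; their pairwise cross products give the
# axis direction. Twist from projected angles about the fitted circle
# center, rise from the axial component of the steps.
.window_helix <- function(p) {
  nw <- nrow(p)
  d <- diff(p)                       # (nw-1) x 3 steps
  u <- diff(d)                       # (nw-2) x 3 bisector vectors
  if (nrow(u) < 2L) return(NULL)
  axes <- matrix(0, nrow(u) - 1L, 3L)
  for (i in seq_len(nrow(u) - 1L)) {
    h <- .cross3(u[i, ], u[i + 1L, ])
    nh <- sqrt(sum(h * h))
    if (nh < 1e-12) return(list(degenerate = TRUE))
    axes[i, ] <- h / nh
  }
  # align signs with the first axis estimate, then average
  for (i in seq_len(nrow(axes))[-1]) {
    if (sum(axes[i, ] * axes[1, ]) < 0) axes[i, ] <- -axes[i, ]
  }
  h <- colMeans(axes)
  h <- h / sqrt(sum(h * h))
  rise <- mean(d %*% h)
  if (rise < 0) { h <- -h; rise <- -rise }
  # project onto the plane perpendicular to h through the centroid
  ctr <- colMeans(p)
  q <- sweep(p, 2, ctr)
  q <- q - (q %*% h) %*% t(h)
  # algebraic circle fit (Kasa) in the plane spanned by e1, e2
  e1 <- q[1, ] - q[2, ]
  e1 <- e1 - sum(e1 * h) * h
  n1 <- sqrt(sum(e1 * e1))
  if (n1 < 1e-12) return(list(degenerate = TRUE))
  e1 <- e1 / n1
  e2 <- .cross3(h, e1)
  xy <- cbind(q %*% e1, q %*% e2)
  A <- cbind(2 * xy[, 1], 2 * xy[, 2], 1)
  bvec <- xy[, 1]^2 + xy[, 2]^2
  sol <- tryCatch(qr.solve(A, bvec), error = function(e) NULL)
  if (is.null(sol)) return(list(degenerate = TRUE))
  ctr2 <- sol[1:2]
  rel <- sweep(xy, 2, ctr2)
  radius <- mean(sqrt(rowSums(rel^2)))
  if (radius < 1e-9) return(list(degenerate = TRUE))
  ang <- atan2(rel[, 2], rel[, 1])
  dang <- diff(ang)
  dang <- (dang + pi) %% (2 * pi) - pi
  twist <- mean(abs(dang)) * 180 / pi
  if (twist < 1e-9) return(list(degenerate = TRUE))
  list(degenerate = FALSE, rise = rise, twist = twist,
       residues_per_turn = 360 / twist, radius = radius)
}

#' Local helix metrics along a chain
#'
#' Estimates rise per residue, twist per residue and residues per turn from
#' sliding windows of consecutive bead positions (rotation-fit: local axis
#' from the step-bisector geometry, twist from the angles of the beads
#' projected about the fitted circle center). Windows whose geometry is
#' collinear (zero helix radius) are flagged and excluded from pooling.
#'
#' @param traj a [cg_trajectory]
#' @param chain chain id to analyze (default: first chain)
#' @param window window length in residues (>= 4, default 7)
#' @return list: `rise_per_residue`, `twist_per_residue`,
#'   `residues_per_turn` (vectors pooled over windows and frames),
#'   `n_degenerate` (windows excluded), and the per-window data.frame
#'   `windows`
#' @export
helix_metrics <- function(traj, chain = NULL, window = 7L) {
  b <- traj$beads
  if (is.null(chain)) chain <- b$chain_id[1]
  idx <- which(b$chain_id == chain)
  if (length(idx) < window || window < 4L) {
    stop("chain must have at least `window` (>= 4) beads")
  }
  rows <- list()
  n_degen <- 0L
  for (f in seq_along(traj$frames)) {
    fr <- traj$frames[[f]]
    for (s in seq_len(length(idx) - window + 1L)) {
      p <- fr[idx[s:(s + window - 1L)], , drop = FALSE]
      wh <- .window_helix(p)
      if (is.null(wh)) next
      if (wh$degenerate) { n_degen <- n_degen + 1L; next }
      rows[[length(rows) + 1L]] <- data.frame(
        frame = f, start = s, rise = wh$rise, twist = wh$twist,
        residues_per_turn = wh$residues_per_turn, radius = wh$radius)
    }
  }
  if (length(rows) == 0L) {
    return(list(rise_per_residue = numeric(0), twist_per_residue = numeric(0),
                residues_per_turn = numeric(0), n_degenerate = n_degen,
                windows = NULL))
  }
  w <- do.call(rbind, rows)
  list(rise_per_residue = w$rise, twist_per_residue = w$twist,
       residues_per_turn = w$residues_per_turn, n_degenerate = n_degen,
       windows = w)
}

#' Segment a fibril axis into alternating gap/overlap regions
#'
#' Boundaries (cross-link region centers along the fibril axis, or explicit
#' positions) delimit alternating segments. Terminal incomplete segments
#' (before the first and after the last boundary) are dropped; k boundaries
#' give k-1 complete segments of alternating parity.
#'
#' @param boundaries strictly increasing positions along the axis (nm)
#' @param first_segment parity of the first complete segment: `"gap"`
#'   (default) or `"overlap"`
#' @param axis axis unit vector label, default `"z"`
#' @return object of class `fibril_segmentation`: data.frame `segments`
#'   (`start`, `end`, `length0`, `type`) plus `axis`
#' @export
segment_fibril <- function(boundaries, first_segment = c("gap", "overlap"),
                           axis = "z") {
  first_segment <- match.arg(first_segment)
  if (length(boundaries) < 2L) stop("need at least 2 boundaries")
  if (any(diff(boundaries) <= 0)) stop("boundaries must be strictly increasing")
  k <- length(boundaries) - 1L
  types <- rep(c(first_segment, setdiff(c("gap", "overlap"), first_segment)),
               length.out = k)
  seg <- data.frame(
    start = boundaries[-length(boundaries)],
    end = boundaries[-1],
    type = types, stringsAsFactors = FALSE)
  seg$length0 <- seg$end - seg$start
  structure(list(segments = seg, axis = axis, boundaries = boundaries),
            class = "fibril_segmentation")
}

#' @export
print.fibril_segmentation <- function(x, ...) {
  tb <- table(x$segments$type)
  cat("fibril_segmentation:", nrow(x$segments), "complete segments (",
      paste(names(tb), tb, collapse = ", "), ") along", x$axis, "\n")
  invisible(x)
}

#' Track per-frame segment lengths from boundary beads
#'
#' Given per-frame axial positions of the segment boundaries, returns the
#' per-frame length of every complete segment.
#'
#' @param seg a [segment_fibril()] result (reference geometry)
#' @param boundary_positions matrix `n_frames x n_boundaries` of axial
#'   positions (nm) of the same boundaries at each frame
#' @return matrix `n_frames x n_segments` of segment lengths
#' @export
segment_lengths <- function(seg, boundary_positions) {
  nb <- length(seg$boundaries)
  stopifnot(ncol(boundary_positions) == nb)
  t(apply(boundary_positions, 1, diff))
}

#' Overlap/gap strain ratio time series
#'
#' Per frame, the ratio of the mean overlap-segment elongation to the mean
#' gap-segment elongation relative to the reference lengths:
#' \deqn{\frac{\langle \epsilon_{overlap,t}\rangle}{\langle \epsilon_{gap,t}\rangle}
#'  = \frac{\langle l_{overlap,t} - l_{overlap,0}\rangle}
#'         {\langle l_{gap,t} - l_{gap,0}\rangle}.}
#' Uncertainty by first-order propagation from the SDs of the segment
#' elongations: `ratio * sqrt((sd_num/num)^2 + (sd_den/den)^2)`. Frames
#' with zero mean gap elongation are masked (`NA`).
#'
#' @param seg a [segment_fibril()] result carrying reference lengths
#' @param lengths_t matrix `n_frames x n_segments` of per-frame segment
#'   lengths (same segment order as `seg$segments`)
#' @param time optional frame times (ns)
#' @param zero_tol mean gap elongations with magnitude at or below this
#'   value (nm) count as zero and mask the frame
#' @return data.frame: `time`, `ratio`, `sigma_ratio`
#' @export
strain_ratio <- function(seg, lengths_t, time = NULL, zero_tol = 1e-9) {
  segs <- seg$segments
  stopifnot(ncol(lengths_t) == nrow(segs))
  ov <- which(segs$type == "overlap")
  gp <- which(segs$type == "gap")
  if (length(ov) == 0L || length(gp) == 0L) {
    stop("segmentation must contain both overlap and gap segments")
  }
  nfr <- nrow(lengths_t)
  ratio <- sigma <- rep(NA_real_, nfr)
  for (f in seq_len(nfr)) {
    e_ov <- lengths_t[f, ov] - segs$length0[ov]
    e_gp <- lengths_t[f, gp] - segs$length0[gp]
    num <- mean(e_ov)
    den <- mean(e_gp)
    if (abs(den) <= zero_tol) next
    r <- num / den
    s_num <- stats::sd(e_ov)
    s_den <- stats::sd(e_gp)
    ratio[f] <- r
    sigma[f] <- if (num == 0) 0 else {
      abs(r) * sqrt((s_num / num)^2 + (s_den / den)^2)
    }
  }
  data.frame(time = if (is.null(time)) seq_len(nfr) else time,
             ratio = ratio, sigma_ratio = sigma)
}

# 1 kJ mol^-1 nm^-1 in pN
.KJMOLNM_TO_PN <- 1.66054

#' Binned bond-force profile along the fibril axis
#'
#' For every harmonic BB-BB bond the force magnitude `F = k|r - r0|`
#' (converted to pN) is assigned to the axial coordinate of the bond
#' midpoint; forces are averaged in `n_bins` bins evenly spaced along the
#' axis span.
#'
#' @param traj a [cg_trajectory]
#' @param top a `cg_topology` whose bonds carry `eq_value` and
#'   `force_constant`
#' @param n_bins number of bins (default 300)
#' @param axis axis index 1-3 or `"x"`, `"y"`, `"z"` (default z)
#' @param frames frame indices to pool (default all)
#' @return data.frame: `bin_center` (nm), `mean_force` (pN), `count`,
#'   `spread` (SD, pN)
#' @export
bond_force_profile <- function(traj, top, n_bins = 300L, axis = "z",
                               frames = NULL) {
  ax <- if (is.character(axis)) match(axis, c("x", "y", "z")) else as.integer(axis)
  bonds <- top$bonds
  if (nrow(bonds) == 0L) stop("topology has no bonds")
  if (any(!is.finite(bonds$eq_value)) || any(!is.finite(bonds$force_constant))) {
    bad <- which(!is.finite(bonds$eq_value) | !is.finite(bonds$force_constant))[1]
    stop("bond without parameters: ", bonds$i[bad], "-", bonds$j[bad])
  }
  if (is.null(frames)) frames <- seq_along(traj$frames)
  zs <- fs <- numeric(0)
  for (f in frames) {
    fr <- traj$frames[[f]]
    d <- fr[bonds$j, , drop = FALSE] - fr[bonds$i, , drop = FALSE]
    r <- sqrt(rowSums(d^2))
    force <- bonds$force_constant * abs(r - bonds$eq_value) * .KJMOLNM_TO_PN
    mid <- (fr[bonds$i, ax] + fr[bonds$j, ax]) / 2
    zs <- c(zs, mid)
    fs <- c(fs, force)
  }
  rng <- range(zs)
  brk <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  bin <- findInterval(zs, brk, rightmost.closed = TRUE, all.inside = TRUE)
  out <- data.frame(bin_center = (brk[-1] + brk[-length(brk)]) / 2,
                    mean_force = NA_real_, count = 0L, spread = NA_real_)
  agg_mean <- tapply(fs, bin, mean)
  agg_n <- tapply(fs, bin, length)
  agg_sd <- tapply(fs, bin, stats::sd)
  ii <- as.integer(names(agg_mean))
  out$mean_force[ii] <- agg_mean
  out$count[ii] <- agg_n
  out$spread[ii] <- agg_sd
  out
}

# deterministic golden-spiral unit sphere lattice
.sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Shrake-Rupley solvent-accessible surface area of a bead set
#'
#' Classic sphere-point SASA: a deterministic golden-spiral lattice of
#' `n_points` test points is placed on each bead's expanded sphere
#' (radius + probe); points inside any other expanded sphere are buried.
#' Per-bead SASA is the accessible fraction of the expanded sphere area.
#'
#' @param xyz `n x 3` bead coordinates (nm)
#' @param radii per-bead radii (nm); standard Martini sizing is 0.264
#'   (regular), 0.230 (small), 0.191 (tiny)
#' @param probe probe radius in nm (default 0.191, a tiny-bead water probe)
#' @param n_points lattice points per bead (default 960)
#' @return list: `total` (nm^2), `per_bead` (numeric vector)
#' @export
bead_sasa <- function(xyz, radii, probe = 0.191, n_points = 960L) {
  xyz <- as.matrix(xyz)
  n <- nrow(xyz)
  stopifnot(length(radii) == n, all(radii > 0), probe >= 0)
  sp <- .sphere_points(n_points)
  rexp <- radii + probe
  per <- numeric(n)
  for (i in seq_len(n)) {
    pts <- sweep(sp * rexp[i], 2, xyz[i, ], "+")
    acc <- rep(TRUE, n_points)
    for (j in seq_len(n)) {
      if (j == i) next
      dj <- sweep(pts, 2, xyz[j, ])
      acc <- acc & (rowSums(dj^2) > rexp[j]^2)
      if (!any(acc)) break
    }
    per[i] <- 4 * pi * rexp[i]^2 * mean(acc)
  }
  list(total = sum(per), per_bead = per)
}

#' Martini-size SASA radii for a bead-type vector
#'
#' @param bead_type character vector of Martini bead type labels
#' @param regular,small,tiny radii (nm) by size class
#' @return numeric vector of radii
#' @export
martini_radii <- function(bead_type, regular = 0.264, small = 0.230,
                          tiny = 0.191) {
  ifelse(startsWith(bead_type, "T"), tiny,
         ifelse(startsWith(bead_type, "S"), small, regular))
}
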