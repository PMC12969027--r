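# Independent oracles used across the suite. Each deliberately takes a
# different computational route than the implementation it checks.

# signed torsion by the two-plane-normal construction: magnitude from the
# normals' acos, sign from the scalar triple product
oracle_dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  cr <- function(u, v) c(u[2] * v[3] - u[3] * v[2],
                         u[3] * v[1] - u[1] * v[3],
                         u[1] * v[2] - u[2] * v[1])
  n1 <- cr(b1, b2); n2 <- cr(b2, b3)
  cosang <- sum(n1 * n2) / sqrt(sum(n1^2) * sum(n2^2))
  ang <- acos(max(-1, min(1, cosang))) * 180 / pi
  s <- sign(sum(cr(n1, n2) * b2))
  if (s == 0) s <- 1
  s * ang
}

# dense-grid density crossing between two Gaussian components
oracle_intersection <- function(lower, upper, n_grid = 2e6) {
  x <- seq(lower$mu, upper$mu, length.out = n_grid)
  d <- lower$amplitude * exp(-0.5 * (x - lower$mu)^2 / lower$sigma^2) -
    upper$amplitude * exp(-0.5 * (x - upper$mu)^2 / upper$sigma^2)
  i <- which(diff(sign(d)) != 0)[1]
  (x[i] + x[i + 1]) / 2
}

# Monte-Carlo surface integration of the accessible area of overlapping
# spheres: random points on each expanded sphere, rejected if buried
oracle_sasa_mc <- function(xyz, radii, probe, n_mc = 2e5, seed = 99) {
  set.seed(seed)
  rexp <- radii + probe
  total <- 0
  for (i in seq_len(nrow(xyz))) {
    v <- matrix(rnorm(3 * n_mc), ncol = 3)
    v <- v / sqrt(rowSums(v^2))
    pts <- sweep(v * rexp[i], 2, xyz[i, ], "+")
    acc <- rep(TRUE, n_mc)
    for (j in seq_len(nrow(xyz))) {
      if (j == i) next
      acc <- acc & (rowSums(sweep(pts, 2, xyz[j, ])^2) > rexp[j]^2)
    }
    total <- total + 4 * pi * rexp[i]^2 * mean(acc)
  }
  total
}

# all-pairs double loop applying the Go contact filters explicitly
oracle_go_contacts <- function(traj, frame = 1, cutoff_low = 0.3,
                               cutoff_high = 1.1, min_seq_sep = 3) {
  xyz <- traj$frames[[frame]]
  b <- traj$beads
  out <- NULL
  for (i in seq_len(nrow(b) - 1)) {
    for (j in (i + 1):nrow(b)) {
      if (b$helix_id[i] != b$helix_id[j]) next
      if (b$chain_id[i] == b$chain_id[j] &&
          abs(b$res_index[j] - b$res_index[i]) < min_seq_sep) next
      r <- sqrt(sum((xyz[j, ] - xyz[i, ])^2))
      if (r < cutoff_low || r > cutoff_high) next
      out <- rbind(out, data.frame(i = i, j = j, r_native = r))
    }
  }
  out
}

# random rigid-body motion (proper rotation + translation)
random_rigid <- function(seed) {
  set.seed(seed)
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  R <- matrix(c(
    1 - 2 * (q[3]^2 + q[4]^2), 2 * (q[2] * q[3] - q[1] * q[4]), 2 * (q[2] * q[4] + q[1] * q[3]),
    2 * (q[2] * q[3] + q[1] * q[4]), 1 - 2 * (q[2]^2 + q[4]^2), 2 * (q[3] * q[4] - q[1] * q[2]),
    2 * (q[2] * q[4] - q[1] * q[3]), 2 * (q[3] * q[4] + q[1] * q[2]), 1 - 2 * (q[2]^2 + q[3]^2)
  ), nrow = 3, byrow = TRUE)
  list(R = R, t = rnorm(3, sd = 2))
}

apply_rigid <- function(xyz, rt) sweep(xyz %*% t(rt$R), 2, rt$t, "+")

# minimal atomistic fixture: n_res residues, 4 backbone atoms each,
# arranged so per-residue centers of geometry lie on a helix
make_atomistic <- function(n_res = 10, n_frames = 1, seed = 5) {
  set.seed(seed)
  res <- NULL
  frames <- vector("list", n_frames)
  centers <- cbind(0.15 * cos(2 * pi * (1:n_res) / 3.3),
                   0.15 * sin(2 * pi * (1:n_res) / 3.3),
                   0.29 * (1:n_res))
  offs <- matrix(c(0.05, 0, 0, -0.05, 0, 0, 0, 0.05, 0, 0, -0.05, 0),
                 ncol = 3, byrow = TRUE)
  names3 <- rep(c("GLY", "PRO", "HYP"), length.out = n_res)
  for (r in 1:n_res) {
    for (a in 1:4) {
      res <- rbind(res, data.frame(
        chain_id = "A", helix_id = "H1", res_index = r,
        res_name = names3[r], atom_name = c("N", "CA", "C", "O")[a],
        atom_row = (r - 1) * 4 + a, stringsAsFactors = FALSE))
    }
  }
  for (f in 1:n_frames) {
    xyz <- NULL
    for (r in 1:n_res) {
      jitter <- matrix(rnorm(12, sd = 0.002), ncol = 3)
      xyz <- rbind(xyz, sweep(offs + jitter, 2, centers[r, ], "+"))
    }
    frames[[f]] <- xyz
  }
  list(residues = res, frames = frames)
}
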