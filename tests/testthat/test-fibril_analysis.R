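test_that("end-to-end distance handles single beads and groups", {
  beads <- data.frame(bead_label = "BB", chain_id = "A", helix_id = "H1",
                      res_index = 1:6, res_name = "GLY",
                      stringsAsFactors = FALSE)
  fr <- rbind(c(0, 0, 0), c(0, 0, 0), c(0, 0, 0),
              c(0, 0, 335), c(0, 0, 335), c(0, 0, 335))
  traj <- cg_trajectory(beads, list(fr))
  expect_equal(end_to_end(traj, 1, 4), 335)
  # degenerate groups of coincident beads
  expect_equal(end_to_end(traj, 1:3, 4:6), 335)
  expect_error(end_to_end(traj, integer(0), 4), "non-empty")
})

test_that("affine stretching scales the end-to-end distance exactly", {
  fib <- build_toy_fibril(schedule = data.frame(overlap = c(0, 0.02),
                                                gap = c(0, 0.02)))
  e <- end_to_end(fib$traj, 1, n_beads(fib$traj))
  expect_equal(e[2] / e[1], 1.02, tolerance = 1e-12)
})

test_that("helix metrics recover generator parameters on ideal helices", {
  cases <- list(c(rise = 0.290, rpt = 3.28), c(rise = 0.1, rpt = 4))
  for (cs in cases) {
    traj <- build_triple_helix(30, rise = cs[["rise"]],
                               residues_per_turn = cs[["rpt"]], n_chains = 1)
    hm <- helix_metrics(traj, window = 7)
    expect_lt(abs(mean(hm$rise_per_residue) - cs[["rise"]]) / cs[["rise"]],
              0.01)
    expect_lt(abs(mean(hm$residues_per_turn) - cs[["rpt"]]) / cs[["rpt"]],
              0.01)
    expect_equal(hm$n_degenerate, 0)
  }
})

test_that("residues per turn is 360 over twist per residue", {
  traj <- build_triple_helix(25, n_chains = 1)
  hm <- helix_metrics(traj)
  expect_equal(hm$residues_per_turn, 360 / hm$twist_per_residue)
})

test_that("collinear beads are flagged as degenerate, not errors", {
  traj <- build_triple_helix(15, radius = 0, n_chains = 1)
  hm <- helix_metrics(traj, window = 6)
  expect_gt(hm$n_degenerate, 0)
  expect_equal(length(hm$residues_per_turn), 0)
})

test_that("helix metrics are invariant under rigid-body motion", {
  traj <- build_triple_helix(20, n_chains = 1)
  rt <- random_rigid(33)
  moved <- traj
  moved$frames <- lapply(traj$frames, apply_rigid, rt = rt)
  h0 <- helix_metrics(traj)
  h1 <- helix_metrics(moved)
  expect_equal(h1$rise_per_residue, h0$rise_per_residue, tolerance = 1e-9)
  expect_equal(h1$residues_per_turn, h0$residues_per_turn, tolerance = 1e-9)
})

test_that("segmentation alternates parity and drops nothing interior", {
  seg <- segment_fibril(seq(0, 335, length.out = 10),
                        first_segment = "overlap")
  tb <- table(seg$segments$type)
  expect_equal(unname(tb[["overlap"]]), 5)
  expect_equal(unname(tb[["gap"]]), 4)
  expect_equal(nrow(seg$segments), 9)
  # single D-band period
  seg1 <- segment_fibril(c(0, 67))
  expect_equal(seg1$segments$length0, 67)
  expect_error(segment_fibril(c(0, 10, 5)), "strictly increasing")
  expect_error(segment_fibril(42), "at least 2")
})

test_that("jittered boundaries give lengths equal to pairwise differences", {
  set.seed(12)
  b <- sort(cumsum(runif(8, 20, 40)))
  seg <- segment_fibril(b)
  expect_equal(seg$segments$length0, diff(b))
  # per-frame boundary tracking
  shift <- rbind(b, b * 1.01, b + 3)
  lt <- segment_lengths(seg, shift)
  expect_equal(lt[1, ], diff(b))
  expect_equal(lt[2, ], diff(b) * 1.01)
  expect_equal(lt[3, ], diff(b))
})

test_that("strain ratio reproduces planted per-segment elongations", {
  fib <- build_toy_fibril(schedule = data.frame(overlap = 1.0, gap = 2.0),
                          schedule_mode = "elongation")
  sr <- strain_ratio(fib$segmentation, fib$lengths_t)
  expect_equal(sr$ratio, 0.5, tolerance = 1e-10)
  expect_equal(sr$sigma_ratio, 0, tolerance = 1e-7)
  # identical elongations everywhere: ratio 1, sigma 0
  fib1 <- build_toy_fibril(schedule = data.frame(overlap = 1.5, gap = 1.5),
                           schedule_mode = "elongation")
  sr1 <- strain_ratio(fib1$segmentation, fib1$lengths_t)
  expect_equal(sr1$ratio, 1, tolerance = 1e-10)
  expect_equal(sr1$sigma_ratio, 0, tolerance = 1e-7)
})

test_that("zero gap elongation masks the ratio", {
  fib <- build_toy_fibril(schedule = data.frame(overlap = c(0.5, 0),
                                                gap = c(0, 0)),
                          schedule_mode = "elongation")
  sr <- strain_ratio(fib$segmentation, fib$lengths_t)
  expect_true(all(is.na(sr$ratio)))
})

test_that("strain ratio is scale-covariant in the elongations", {
  seg <- segment_fibril(seq(0, 270, by = 30))
  l0 <- seg$segments$length0
  set.seed(7)
  elong <- abs(rnorm(length(l0), 1, 0.2))
  for (c_scale in c(1, 3, 0.1)) {
    lt <- matrix(l0 + c_scale * elong, nrow = 1)
    sr <- strain_ratio(seg, lt)
    if (c_scale == 1) base <- sr$ratio
    expect_equal(sr$ratio, base, tolerance = 1e-9)
  }
})

test_that("propagated ratio uncertainty matches a Monte-Carlo oracle", {
  seg <- segment_fibril(seq(0, 270, by = 30))
  l0 <- seg$segments$length0
  ov <- seg$segments$type == "overlap"
  set.seed(41)
  elong <- ifelse(ov, 1.0, 2.0) + rnorm(length(l0), 0, 0.03)
  lt <- matrix(l0 + elong, nrow = 1)
  sr <- strain_ratio(seg, lt)
  num <- mean(elong[ov]); den <- mean(elong[!ov])
  s_num <- sd(elong[ov]); s_den <- sd(elong[!ov])
  set.seed(42)
  mc <- rnorm(2e5, num, s_num) / rnorm(2e5, den, s_den)
  expect_equal(sr$ratio, num / den)
  expect_lt(abs(sr$sigma_ratio - sd(mc)) / sd(mc), 0.05)
})

test_that("bond forces vanish at equilibrium and convert units correctly", {
  fib <- build_toy_fibril()
  prof <- bond_force_profile(fib$traj, fib$topology, n_bins = 50)
  expect_true(all(prof$mean_force[prof$count > 0] < 1e-8))
  expect_equal(sum(prof$count), nrow(fib$topology$bonds))
  # one bond with known extension: F = k dr = 180 kJ/mol/nm = 298.9 pN
  beads <- data.frame(index = 1:2, bead_type = "P2", name = "BB",
                      residue = "GLY", res_index = 1:2, charge = 0, mass = 72)
  bonds <- data.frame(i = 1, j = 2, eq_value = 0.35, force_constant = 18000,
                      funct = 1)
  top <- cg_topology("pair", beads, bonds = bonds)
  tb <- data.frame(bead_label = "BB", chain_id = "A", helix_id = "H1",
                   res_index = 1:2, res_name = "GLY",
                   stringsAsFactors = FALSE)
  traj <- cg_trajectory(tb, list(cbind(0, 0, c(0, 0.36))))
  prof1 <- bond_force_profile(traj, top, n_bins = 1)
  expect_equal(prof1$mean_force[1], 18000 * 0.01 * 1.66054, tolerance = 1e-6)
  expect_equal(prof1$mean_force[1], 298.9, tolerance = 1e-3)
})

test_that("a uniformly strained fibril has a flat profile matching per-bond forces", {
  # equal bead spacing everywhere so affine strain loads every bond equally
  fib <- build_toy_fibril(overlap_len = 36, gap_len = 28,
                          overlap_spacing = 0.4, gap_spacing = 0.4,
                          schedule = data.frame(overlap = 0.01, gap = 0.01))
  prof <- bond_force_profile(fib$traj, fib$topology, n_bins = 300)
  expect_equal(sum(prof$count), nrow(fib$topology$bonds))
  # brute-force per-bond oracle
  fr <- fib$traj$frames[[1]]
  bd <- fib$topology$bonds
  r <- abs(fr[bd$j, 3] - fr[bd$i, 3])
  f_or <- bd$force_constant * abs(r - bd$eq_value) * 1.66054
  occupied <- prof$count > 0
  expect_equal(stats::weighted.mean(prof$mean_force[occupied],
                                    prof$count[occupied]),
               mean(f_or), tolerance = 1e-9)
  # 1% affine strain on every bond: forces identical everywhere
  expect_lt(diff(range(prof$mean_force[occupied])) /
              mean(prof$mean_force[occupied]), 1e-6)
})

test_that("missing bond parameters are reported by bead pair", {
  fib <- build_toy_fibril()
  fib$topology$bonds$force_constant[3] <- NA
  expect_error(bond_force_profile(fib$traj, fib$topology),
               "bond without parameters: 3-4")
})

test_that("SASA of isolated spheres is analytic", {
  s1 <- bead_sasa(matrix(0, 1, 3), radii = 1, probe = 0)
  expect_equal(s1$total, 4 * pi, tolerance = 1e-12)
  expect_equal(s1$total, 12.566, tolerance = 1e-3)
  # two beads beyond contact: exactly twice one bead
  s2 <- bead_sasa(rbind(c(0, 0, 0), c(5, 0, 0)), radii = c(1, 1),
                  probe = 0.2)
  expect_equal(s2$total, 2 * 4 * pi * 1.2^2, tolerance = 1e-12)
  expect_equal(s2$per_bead[1], s2$per_bead[2])
})

test_that("overlapping-sphere SASA matches Monte-Carlo integration", {
  xyz <- rbind(c(0, 0, 0), c(0.3, 0, 0))
  radii <- c(0.264, 0.230)
  est <- bead_sasa(xyz, radii, probe = 0.191, n_points = 5000)
  mc <- oracle_sasa_mc(xyz, radii, probe = 0.191)
  expect_lt(abs(est$total - mc) / mc, 0.01)
})

test_that("SASA error decreases with the lattice density and is rotation invariant", {
  # analytic accessible area of two overlapping expanded spheres
  two_sphere <- function(d, R1, R2) {
    h1 <- R1 - (d^2 + R1^2 - R2^2) / (2 * d)
    h2 <- R2 - (d^2 + R2^2 - R1^2) / (2 * d)
    (4 * pi * R1^2 - 2 * pi * R1 * h1) + (4 * pi * R2^2 - 2 * pi * R2 * h2)
  }
  xyz <- rbind(c(0, 0, 0), c(0.3, 0, 0))
  radii <- c(0.264, 0.230)
  truth <- two_sphere(0.3, 0.264 + 0.191, 0.230 + 0.191)
  errs <- vapply(c(60, 240, 960, 3840), function(np) {
    abs(bead_sasa(xyz, radii, probe = 0.191, n_points = np)$total - truth)
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[length(errs)] / truth, 0.001)
  rt <- random_rigid(55)
  rot <- bead_sasa(apply_rigid(xyz, rt), radii, n_points = 960)
  expect_equal(rot$total, bead_sasa(xyz, radii, n_points = 960)$total,
               tolerance = 2e-3)
})

test_that("martini_radii assigns size classes by type prefix", {
  expect_equal(martini_radii(c("P2", "SP1d", "TQ2p")),
               c(0.264, 0.230, 0.191))
})
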