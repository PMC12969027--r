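test_that("bond classification follows the first-residue rule", {
  expect_equal(classify_bond("PRO", "GLY"), "short_class")
  expect_equal(classify_bond("HYP", "ALA"), "short_class")
  expect_equal(classify_bond("GLY", "PRO"), "general_class")
  expect_error(classify_bond("XXX", "GLY"), "XXX")
  # (GPO)10 chain: enumerate all 29 bonds
  seqc <- rep(c("GLY", "PRO", "HYP"), 10)
  cls <- classify_bond(seqc[-30], seqc[-1])
  expect_equal(sum(cls == "short_class"), 19)
  expect_equal(sum(cls == "general_class"), 10)
})

test_that("trajectory-based classification recovers the rule on synthetic bonds", {
  # chain alternating PRO/GLY with bond lengths set by the first residue
  n <- 120
  seqc <- rep(c("PRO", "GLY"), n / 2)
  z <- cumsum(c(0, ifelse(seqc[-n] == "PRO", 0.318, 0.354)))
  beads <- data.frame(bead_label = "BB", chain_id = "A", helix_id = "H1",
                      res_index = 1:n, res_name = seqc,
                      stringsAsFactors = FALSE)
  traj <- cg_trajectory(beads, list(cbind(0, 0, z)))
  cl <- classify_from_trajectory(traj, threshold = 0.329)
  pro <- cl[cl$res_name == "PRO", ]
  gly <- cl[cl$res_name == "GLY", ]
  expect_equal(pro$fraction_below, 1)
  expect_equal(pro$assigned_class, "short_class")
  expect_equal(gly$fraction_below, 0)
  expect_equal(gly$assigned_class, "general_class")
  # agreement with the sequence rule itself
  expect_equal(pro$assigned_class, unname(classify_bond("PRO", "GLY")))
  expect_equal(gly$assigned_class, unname(classify_bond("GLY", "PRO")))
})

test_that("uniform bond lengths above threshold classify everything general", {
  n <- 80
  beads <- data.frame(bead_label = "BB", chain_id = "A", helix_id = "H1",
                      res_index = 1:n, res_name = rep(c("ALA", "GLY"), n / 2),
                      stringsAsFactors = FALSE)
  traj <- cg_trajectory(beads, list(cbind(0, 0, 0.34 * (0:(n - 1)))))
  cl <- classify_from_trajectory(traj, threshold = 0.329)
  expect_true(all(cl$fraction_below == 0))
  expect_true(all(cl$assigned_class == "general_class"))
})

test_that("low-sample residue types fall back to the sequence rule", {
  # 3 beads only: PRO appears once as a first residue -> low confidence
  beads <- data.frame(bead_label = "BB", chain_id = "A", helix_id = "H1",
                      res_index = 1:3, res_name = c("PRO", "GLY", "ALA"),
                      stringsAsFactors = FALSE)
  traj <- cg_trajectory(beads, list(cbind(0, 0, c(0, 0.4, 0.8))))
  cl <- classify_from_trajectory(traj)
  expect_true(all(cl$low_confidence))
  expect_equal(cl$assigned_class[cl$res_name == "PRO"], "short_class")
  expect_equal(cl$assigned_class[cl$res_name == "GLY"], "general_class")
})

test_that("the default classification threshold is the shipped crossing", {
  expect_equal(x0_default(), 0.329)
  expect_equal(formals(classify_from_trajectory)$threshold, quote(x0_default()))
})

test_that("backbone topology emits the dual-bond rule with shipped values", {
  seqc <- rep(c("GLY", "PRO", "HYP"), 10)
  top <- build_backbone_topology(list(seqc))
  expect_equal(nrow(top$bonds), 29)
  expect_equal(nrow(top$angles), 28)
  expect_equal(nrow(top$dihedrals), 27)
  short <- top$bonds$class == "short_class"
  expect_equal(sum(short), 19)
  expect_true(all(top$bonds$eq_value[short] == 0.320))
  expect_true(all(top$bonds$force_constant[short] == 34000))
  expect_true(all(top$bonds$eq_value[!short] == 0.356))
  expect_true(all(top$bonds$force_constant[!short] == 18000))
  expect_true(all(top$angles$eq_value == 138))
  expect_true(all(top$angles$force_constant == 152))
  expect_true(all(top$dihedrals$eq_value == 76))
  expect_true(all(top$dihedrals$force_constant == 17))
})

test_that("short chains omit unsupported term classes", {
  top <- build_backbone_topology(list(c("GLY", "ALA")))
  expect_equal(nrow(top$bonds), 1)
  expect_equal(nrow(top$angles), 0)
  expect_equal(nrow(top$dihedrals), 0)
  expect_error(build_backbone_topology(list("GLY")), ">= 2")
})

test_that("multi-chain topologies never bond across chains", {
  top <- build_backbone_topology(rep(list(rep(c("GLY", "PRO", "HYP"), 4)), 3))
  expect_equal(nrow(top$bonds), 3 * 11)
  chain_of <- top$beads$chain_id
  expect_true(all(chain_of[top$bonds$i] == chain_of[top$bonds$j]))
  expect_true(all(chain_of[top$angles$i] == chain_of[top$angles$k]))
})

test_that("Go contacts match a brute-force all-pairs oracle", {
  traj <- build_triple_helix(15, n_chains = 3)
  go <- build_go_contacts(traj)
  orc <- oracle_go_contacts(traj)
  expect_equal(nrow(go), nrow(orc))
  ord_g <- order(go$i, go$j)
  ord_o <- order(orc$i, orc$j)
  expect_equal(go$i[ord_g], orc$i[ord_o])
  expect_equal(go$j[ord_g], orc$j[ord_o])
  expect_equal(go$r_native[ord_g], orc$r_native[ord_o])
  expect_true(all(go$i < go$j))
  expect_true(all(go$epsilon == 9.414))
  expect_equal(go$sigma_lj, go$r_native / 2^(1 / 6))
})

test_that("Go contacts are strictly intrahelical", {
  # two helices side by side, within LJ range of each other
  h1 <- build_triple_helix(12, helix_id = "HA")
  h2 <- build_triple_helix(12, helix_id = "HB")
  h2$beads$chain_id <- paste0(h2$beads$chain_id, "b")
  h2$frames[[1]][, 1] <- h2$frames[[1]][, 1] + 0.5
  both <- cg_trajectory(rbind(h1$beads, h2$beads),
                        list(rbind(h1$frames[[1]], h2$frames[[1]])))
  go <- build_go_contacts(both)
  hel <- both$beads$helix_id
  expect_gt(nrow(go), 0)
  expect_true(all(hel[go$i] == hel[go$j]))
  # cross-helix bead pairs inside the window exist but are never emitted
  cross <- outer(hel, hel, "!=")
  dm <- as.matrix(dist(both$frames[[1]]))
  expect_gt(sum(cross & dm >= 0.3 & dm <= 1.1) / 2, 0)
})

test_that("an empty contact window warns rather than errors", {
  beads <- data.frame(bead_label = "BB", chain_id = "A", helix_id = "H1",
                      res_index = 1:2, res_name = "GLY",
                      stringsAsFactors = FALSE)
  traj <- cg_trajectory(beads, list(cbind(0, 0, c(0, 5))))
  expect_warning(go <- build_go_contacts(traj), "no Go contacts")
  expect_equal(nrow(go), 0)
})

test_that("PYD fragment has the rhombic ring and +1 charge", {
  top <- build_crosslink("PYD")
  ring <- top$beads[top$beads$name %in% c("R1", "R2", "R3", "R4"), ]
  expect_equal(nrow(ring), 4)
  expect_true(all(startsWith(ring$bead_type, "T")))
  expect_equal(ring$bead_type, c("TQ2p", "TP1q", "TC6q", "TC4"))
  expect_equal(ring$charge, c(0.7, 0.2, 0.1, 0))
  expect_equal(sum(top$beads$charge), 1.0)
  # the four rhombic ring bonds, as plain bonds (funct 1, never constraints)
  ring_idx <- ring$index
  rb <- top$bonds[top$bonds$i %in% ring_idx & top$bonds$j %in% ring_idx, ]
  expect_equal(nrow(rb), 4)
  expect_true(all(rb$funct == 1))
  expect_setequal(paste(rb$i, rb$j), c("1 2", "1 3", "2 4", "3 4"))
  # no dihedral on the ring; arm beads positioned by angles
  expect_equal(nrow(top$dihedrals), 0)
  expect_gt(nrow(top$angles), 0)
  # SP1 linker toward C-alpha 1, TC4 at the C-alpha connections
  expect_equal(top$beads$bead_type[top$beads$name == "LNK"], "SP1")
  expect_true("R4" %in% attr(top, "attachment_sites"))
})

test_that("HLKNL fragment is neutral and symmetric about the amine bead", {
  top <- build_crosslink("HLKNL")
  expect_equal(sum(top$beads$charge), 0)
  expect_equal(top$beads$bead_type, c("P1", "SP1d", "N6a"))
  expect_equal(nrow(top$bonds), 2)
  # both arms bond to the central amine
  expect_true(all(top$bonds$i == c(1, 2) & top$bonds$j == c(2, 3)))
  expect_error(build_crosslink("XYZ"))
})

test_that("topology invariants are enforced", {
  beads <- data.frame(index = 1:2, bead_type = "P2", name = "BB",
                      residue = "GLY", res_index = 1:2, charge = c(0.5, 0),
                      mass = 72, stringsAsFactors = FALSE)
  expect_error(cg_topology("x", beads), "not integral")
  beads$charge <- c(0.5, 0.5)
  bad_bonds <- data.frame(i = 1, j = 5, eq_value = 0.35,
                          force_constant = 1000, funct = 1)
  expect_error(cg_topology("x", beads, bonds = bad_bonds), "outside")
})
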