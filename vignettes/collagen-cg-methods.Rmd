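---
title: "Methods: coarse-graining collagen with Martini 3"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coarse-graining collagen with Martini 3}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(collagencg)
```

This vignette documents the models, estimators and numerical choices
behind `collagencg`: what each component assumes, which parameters matter,
and where the design was genuinely open.

## The model

Collagen type I is built from triple helices with a Gly-X-Y repeat (X
typically proline, Y typically 4-hydroxyproline). In the coarse-grained
representation used here, each residue is a single backbone bead (BB)
placed at the center of geometry of the residue's backbone atoms, and the
triple helix is held together by three ingredients:

1. **Bonded terms between consecutive BBs** — harmonic bonds, angles and
   proper dihedrals whose parameters come from Boltzmann inversion of the
   mapped atomistic distributions.
2. **A structure-based (Gō) contact network** restricted to bead pairs
   within the same triple helix, because the base force field alone does
   not preserve helical secondary structure.
3. **Cross-link fragments** (divalent HLKNL and trivalent PYD) with their
   own bead types, charges and internal bonded terms, connecting helices
   into fibrils.

### Center-of-geometry mapping

`map_backbone()` uses the *unweighted* mean of the selected backbone
atoms. The default atom set is `{N, CA, C, O}`, the standard protein
backbone; whether the carbonyl O belongs in the BB center is not uniquely
fixed by convention, so the set is an argument
(`backbone_atom_names`) rather than a constant. Coordinates are carried
in nm throughout (PDB Å are converted on read), the fibril axis
convention is z, and torsions follow the IUPAC right-handed sign
convention (fixed by a unit test against `bio3d::torsion.xyz`). When box
vectors are present, bonded measurements use the orthorhombic
minimum-image displacement; without a box, raw coordinates. Multi-model
PDB files are treated as trajectory frames; alternate location `A` is
preferred; insertion codes are rejected outright rather than guessed at.

### Boltzmann inversion and the dual bond rule

For a bonded degree of freedom q, a Gaussian
P(q) = C·exp(−(q−μ)²/2σ²) is fitted by least squares to the
density-normalized histogram, and equating it with the Boltzmann density
of a harmonic potential gives k = k_BT/σ² (T defaults to 300 K, the
simulation temperature; k_B·T = 2.494 kJ/mol at 300 K). Angles and
torsions are handled in degrees at the interface and converted to radians
inside the inversion, so angle/dihedral force constants are in
kJ mol⁻¹ rad⁻².

Histogram binning is Freedman–Diaconis with a floor of 50 bins — a
robust default for the 10⁴–10⁶-sample regime these fits operate in.
Whether the reference fits were amplitude-free or density-normalized is
not fixed by the procedure itself; the fitter uses least squares with a
free amplitude on the density histogram (the default), which reduces to
the normalized case when the data are unimodal Gaussian. An
expectation-maximization alternative was considered and rejected as the
default because the fitting target is explicitly the *histogram density*,
not the sample likelihood.

Collagen's BB bond lengths are bimodal: bonds whose **first** residue is
proline-like (PRO or HYP) are systematically shorter. `fit_bimodal()`
fits a two-component Gaussian mixture density (components are relabeled
so `lower$mu < upper$mu`, making the fit invariant to the initial guess
order), and the crossing point x₀ of the two component densities between
their means — solved analytically from the log-density quadratic, with a
bracketed numerical fallback — becomes the classification threshold.
Non-separable fits (|μ₂−μ₁| < σ₁+σ₂, or no density crossing between the
means) raise a `unimodal_fallback` flag instead of reporting a
meaningless threshold.

The shipped default threshold is `x0_default()` = 0.329 nm. This value
cannot be recomputed exactly from the two component means and SDs alone —
the crossing also depends on the fitted amplitudes, which are not part of
the shipped parameter set — so the constant is shipped as the documented
default while `bimodal_intersection()` always reports the crossing
actually computed from a user's own fit.

Equilibrium inversion yields force constants that reproduce equilibrium
fluctuation widths but underestimate stiffness under load. The bond force
constants in the shipped backbone set (`backbone_params()`) are therefore
the values refit under constant-force pulling — 18,000 kJ mol⁻¹ nm⁻²
(general, r₀ = 0.356 nm) and 34,000 kJ mol⁻¹ nm⁻² (HYP/PRO-X,
r₀ = 0.320 nm) — applied through `apply_fine_tuning()`, which records
both the equilibrium and the overridden constant in the parameter's
metadata. The angle (138°, 152 kJ mol⁻¹) and dihedral (76°, 17 kJ mol⁻¹)
terms keep their equilibrium-derived constants.

### Topology generation choices

- **Angle functional form.** The angle numbers are stated as value/force
  constant without a functional-form code; the builder defaults to
  harmonic (GROMACS funct 1) and exposes cosine-harmonic (funct 2) as an
  option, keeping the numbers exactly as shipped either way.
- **Dihedrals** are proper dihedrals, funct 1, multiplicity 1.
- **Gō contacts.** All same-helix BB pairs with reference distance in
  [0.3, 1.1] nm and intra-chain sequence separation ≥ 3 (inter-chain
  pairs within a helix always qualify) get an LJ well of depth
  ε = 9.414 kJ mol⁻¹ with σ_LJ = r_native/2^(1/6). The window and
  separation defaults follow the common Gō-Martini scheme settings and
  are arguments. Contacts are emitted once (i < j) and written as explicit
  pair interactions in a separate include file; virtual-site bookkeeping
  is a format-compatibility concern, not a mechanical one — the contract
  (an LJ minimum of depth ε at the native distance) is identical.
- **Cross-links.** The PYD pyridine ring is four tiny beads bonded as a
  rhombus (R1–R2, R1–R3, R2–R4, R3–R4) with *plain bonds, never
  constraints* — the rhombus is what keeps the two arms attached to the
  same helix from separating under force. No dihedral is placed on the
  ring: a planarity dihedral destabilizes high-force simulations, and the
  four bonds plus the arm-positioning angles maintain the geometry. Ring
  charges (+0.7, +0.2, +0.1 e on TQ2p/TP1q/TC6q) sum to +1 e for the
  protonated ring nitrogen, implying one compensating counter-ion at the
  system level; charges below 0.25 e are retained as assigned rather than
  zeroed. The *internal* bond/angle values of both fragments are not part
  of the main shipped parameter set; the package ships stand-in values in
  `inst/extdata/crosslink_params_synthetic.csv` (marked synthetic,
  supplementary-derived) and every builder accepts an override file.
  Which helix chains a PYD arm attaches to is structure-dependent and is
  taken from input connectivity, never hard-coded.
- **Masses** default to the standard Martini sizing: 72/54/36 amu for
  regular/small/tiny beads.

### Free energies from nonequilibrium work

Solvation free energies come from bidirectional nonequilibrium work data
via the Bennett/Crooks maximum-likelihood estimator: ΔG solves the
Fermi-function-weighted balance of forward and backward work including
the ln(n_F/n_R) term. The convention is fixed and logged: *forward* work
couples the solute (∅→S); *backward* work is the work of the reverse
transition, so Crooks reads P_F(W)/P_R(−W) = exp[(W−ΔG)/k_BT], and
swapping the two arrays negates ΔG exactly. The root is found by
bracketed bisection on [min(W)−50, max(W)+50] kJ mol⁻¹ (expanded if
needed) to 1e-8; the balance function is monotone in ΔG so the root is
unique. Uncertainties: 1000 bootstrap resamples per direction, seeded.
A forward/backward overlap diagnostic flags non-overlapping
distributions instead of failing.

Transfer free energies are plain differences with quadrature errors, and
logP = −ΔΔG_W→O/(ln10·RT) with an explicit sign-convention flag recorded
in the output (the default makes hydrophilic compounds negative). The
relation between a reported transfer free energy and a reported logP can
depend on unstated averaging or temperature conventions, so the package
reports the formula result plus its convention metadata and does not
massage either number.

### Fibril observables

- **Helix metrics.** A sliding window (default 7 residues) over each
  chain estimates the local axis from the step-bisector geometry (the
  cross products of successive second differences of bead positions),
  the rise as the mean axial step, and the twist from the angles of the
  beads projected about a circle center fitted in the normal plane
  (algebraic Kåsa fit). The estimator's contract is recovery of generator
  parameters on ideal helices within 1%; collinear windows (zero radius)
  are flagged degenerate and excluded from pooling rather than producing
  spurious twists.
- **Strain ratio.** Cross-link positions along the axis delimit
  alternating gap/overlap segments; terminal incomplete segments are
  dropped (ten boundaries give five complete segments of one parity and
  four of the other). The ratio ⟨l_ov,t − l_ov,0⟩/⟨l_gap,t − l_gap,0⟩ is
  computed per frame; its uncertainty uses first-order propagation from
  the SDs of the per-segment elongations
  (ratio·sqrt((σ_num/num)² + (σ_den/den)²)). Resampling was the
  alternative; first-order propagation was chosen for determinism and is
  cross-checked against a Monte-Carlo oracle in the tests (they agree
  within 5% in the regimes exercised). Frames with |mean gap elongation|
  ≤ 1e-9 nm are masked as 0/0. Which alternating parity is "gap" is
  decided by a bead-density heuristic in the fixtures (overlap is denser)
  and is always overridable, since the definition is structural.
- **Force profiles.** Per-bond harmonic force magnitude F = k·|r−r₀|,
  converted at 1 kJ mol⁻¹ nm⁻¹ = 1.66054 pN, assigned to the bond
  midpoint's axial coordinate (symmetric and binning-stable), averaged in
  300 bins by default.
- **SASA.** Shrake–Rupley with a deterministic golden-spiral lattice
  (default 960 points/bead) rather than random sampling, so results are
  exactly reproducible at fixed settings; default radii follow Martini
  sizing (0.264/0.230/0.191 nm) with a 0.191 nm probe, all configurable
  since no single convention is canonical at CG resolution.

## What the fixtures emulate — and what they do not

The generators produce exactly the structures the analyzers measure:
ideal phase-shifted helices (single minor helix, *no* 7/2 supercoil —
sufficient for analyzer round trips, a deliberate simplification of real
collagen), Gaussian-mixture bonded samples clipped to each variable's
legal range, Gaussian work pairs satisfying the Crooks relation by
construction, and toy fibrils with alternating dense/sparse segments
strained affinely per segment type. Passing the round-trip suite
therefore shows the estimators are *correct*, not that the physical model
is *accurate*: fixture data contain no anharmonicity, no correlated
noise, no helix unwinding, and no cross-link tilting — the places where
real AA/CG discrepancies live.

Problem sizes in the tests and acceptance script were chosen so every
stochastic check is comfortably inside its statistical tolerance:
10⁵ samples for mixture fits, 10⁶ for inversion round trips (2%
recovery), 100 work values per direction with 1000 bootstrap resamples
(matching the production protocol of 100 transitions per direction), and
20-seed replication for the stochastic criteria.

## Degenerate inputs and tie-breaks

- Coincident consecutive beads make angles/torsions undefined: the frame
  is excluded for that tuple and counted in a diagnostics table.
- Zero-variance samples are a hard error in `fit_gaussian()` (degenerate
  distribution), as are histograms with fewer than five occupied bins.
- Residue types with fewer than 50 bond samples in
  `classify_from_trajectory()` are flagged low-confidence and fall back
  to the sequence rule.
- An empty Gō contact list warns and returns zero rows (a legitimate
  outcome for sparse structures), it does not error.
- Chains shorter than a term's span silently omit that term class, so
  dipeptides still produce valid topologies.

## Known limitations

- The helix estimator assumes locally regular helices; strongly bent or
  partially unwound windows bias rise/twist rather than failing loudly
  (the degenerate flag only catches exact collinearity).
- Minimum-image handling is orthorhombic; triclinic boxes are not
  supported.
- The cross-link internal bonded values shipped are stand-ins: anyone
  using the fragments quantitatively should supply their own parameter
  file.
- The bimodal fitter targets histogram density; for very small samples
  (n < 1000 it refuses outright) an EM fit would be preferable.
- logP values for charged species (PYD) are ill-defined observables in
  the first place; the toolkit computes the formula and records the
  convention, nothing more.
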