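---
title: "radcell: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{radcell: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`radcell` simulates, cell by cell, how a low-LET x-ray dose fraction to a
multicellular tumor becomes DNA double-strand breaks (DSBs), illegitimate
free-end rejoinings, and cell death. This vignette explains the model, its
assumptions, the tunable parameters, how the surrogate track generator was
calibrated, and what a passing test suite does and does not establish.

## 1. Geometry

A cubic volume (default side 0.2 mm) is filled with non-overlapping
ellipsoidal cells by random sequential addition: centers uniform (subject to
the whole ellipsoid fitting in the box), orientations uniform over proper
rotations, major axis uniform on 14–20 µm, both minor axes fixed at 14 µm.
The fixed minor axes are forced by the stated cell-volume range
1437–2053 µm³ = (π/6)·d₁·14·14 with d₁ ∈ [14, 20]. Each cell has a
concentric, similar nucleus with volume fraction 0.08 (linear scale
0.08^(1/3)), i.e. nuclear volumes 115–164 µm³. The default block holds 1224
cells — 1.53·10⁸ cells/cm³, a tumor-mimetic density — a packing fraction of
about 27 %, well within reach of random sequential addition.

The overlap test is a bounding-sphere prescreen, an inscribed-sphere quick
reject, then mutual surface-point sampling (256 quasi-uniform points per
cell) against the exact ellipsoid interior test. Overlaps smaller than the
surface-sampling resolution (≈ 2 µm patches) could in principle slip
through; the test suite re-checks accepted configurations with a 4000-point
oracle.

Voxelization classifies each 2 µm voxel by its **center point**: nucleus if
the center lies in the nucleus ellipsoid, else cytoplasm if in the cell
ellipsoid, else intercellular. Two integer arrays hold the voxel type and
the owning cell id (the id array is zero exactly where the type is zero).
The index-to-coordinate map is `X = −(box/2 − vox/2) + vox·i` per axis, the
0.2 mm / 2 µm case being `X = −99 + 2 i` µm.

## 2. Surrogate track structure

The package replaces a Monte Carlo transport engine with a calibrated
surrogate. What is modeled per nucleus:

* **Tracks** are isotropic uniform random chords of the nucleus bounding
  sphere; their number is Poisson with mean `fluence × dose × π r_b²`, so
  bigger nuclei are hit more often in proportion to cross-section.
* **Interaction clusters** are Poisson-spaced along each chord and retained
  only where they fall inside a nucleus voxel of the owning cell (chemistry
  is only generated inside nucleus voxels). Uniform chords make the
  retained cluster positions uniform over the nucleus volume.
* **Direct events**: each cluster emits a random number of energy
  depositions with energies 10.79 eV + Exp(29.21 eV) (mean 40 eV),
  positions jittered by an isotropic Gaussian around the cluster.
* **Indirect events**: a Poisson number of •OH interaction positions
  (1.3 per direct event), displaced from the cluster position by an
  isotropic Gaussian with radial RMS √(6 D t) = 6.48 nm
  (D = 2.8·10⁻⁹ m² s⁻¹, t = 2.5 ns, the 4·10⁸ s⁻¹ scavenging capacity).
  •OH that leave the nucleus voxels are dropped; no other radical species
  is modeled, and the late chemical-stage •OH source is omitted (its DSB
  contribution is negligible).

The cluster linear density is *derived* from energy conservation
(`fluence · density · events/cluster · mean energy = 6241.5 eV µm⁻³ Gy⁻¹`),
so the mean nucleus dose equals the prescribed dose by construction;
per-nucleus dose at 1 Gy comes out approximately Normal(1.00, 0.06) Gy with
the default fluence of 10 tracks µm⁻² Gy⁻¹ (≈ 350 chords per nucleus).

Two deliberate design choices deserve emphasis:

* **Direct jitter equals the •OH spread.** The per-cluster direct jitter σ
  is set to the •OH displacement σ (3.74 nm per axis), so direct and
  indirect events form one exchangeable cloud. This is what makes the
  direct-only ablation behave correctly: removing indirect events halves
  the event density inside segments and the (density-squared) DSB yield
  drops to ≈ 46 %, with the complex-DSB share collapsing by an order of
  magnitude.
* **Cluster-size distribution.** Directs per cluster follow a truncated
  geometric (mean 10.2, cap 25) plus a rare, narrow "dense track-end"
  component (5.5 % of clusters, 39 + Poisson(3) directs). The dense
  component supplies the complex-DSB tail; its narrowness matters, because
  a cluster far above the complexity threshold would emit *several*
  co-located cDSBs whose guaranteed mutual misrejoining would inflate the
  linear (same-track) component of the misrejoining dose response far
  above the near-zero value the model is meant to produce.

These are calibration choices, constrained only by dose, dose spread, the
energy threshold, the •OH displacement law, and the damage-level targets
below. Real track structure differs in ways the surrogate does not capture:
there is no secondary-electron transport between cells, no energy-dependent
LET spectrum, no correlated cluster sequences at track ends, and the
direct-only oxygen enhancement ratio stays at the full-model value
(~4.5) instead of dropping toward ~2.6 as species-dependent chemistry
would make it.

## 3. Damage induction

Events of one nucleus are clustered greedily into **10 bp DNA segments**:
an event joins the nearest existing segment whose centroid lies within the
capture radius — the half-diagonal of the B-DNA cylinder (3.4 nm × 2.3 nm),
2.05 nm — else it seeds a new segment. A new segment within twice the
capture radius of an existing one continues that segment's **chain** at the
next 10 bp genomic offset; otherwise it starts a new chain, genomically
unrelated to everything else. (The merge rule below presupposes a genomic
coordinate that spatial clustering does not natively have; chains are the
surrogate's answer, and segments in different chains never merge.)

Each event is assigned a base pair (uniform 1–10), a strand (uniform), and
a moiety — sugar with probability 0.5 (direct) or 0.2 (•OH, reflecting the
base preference of radical attack), else base. Duplicate (bp, strand)
sites collapse. Sugar radicals convert to strand breaks with the
oxygen-dependent probability

P(pO₂) = p_anox + (p_oxic − p_anox) · pO₂ / (pO₂ + k_half),

a hyperbolic saturation curve with k_half = 3 mmHg (the classical
radiobiological half-effect pressure; the source experiments only exercise
the endpoints 0 and 760 mmHg). Base radicals become modified bases, never
breaks.

**DSB calling.** A segment with ≥ 2 strand breaks, at least one per strand
(the opposite-strand requirement is the default; a switch restores the
literal two-breaks-in-10-bp reading), is a DSB candidate. Candidates on a
chain separated by fewer than 10 *undamaged* base pairs merge into one DSB
whose multiplicity counts the merged candidates. A DSB's **elementary
damages** (strand breaks + modified bases + modified sugars) are all
lesions of its contiguous damaged region — damaged base pairs connected to
its breaks through undamaged runs shorter than 10 bp. A DSB with more than
15 elementary damages is **complex** (cDSB); only cDSB free-ends
participate in misrejoining. Finally the DSB list is thinned: each DSB is
kept with probability equal to the DNA volume fraction, independently and
irrespective of complexity (complexity is classified before thinning).

**Calibration.** The preset was calibrated once, with
`calibrate_damage()`, against three targets: whole-nucleus (unthinned)
oxic DSB yield such that the printed DNA-volume fractions map to yields of
roughly 20/30/40 per Gy per cell (achieved raw yield 159 / Gy / cell, so a
target of 30.1 uses a fraction of 0.189); cDSB share 9.6 % of DSBs; and
OER_DSB = 4.6 (tuning p_anox = 0.2135 against p_oxic = 0.47). Emergent —
not fitted — properties then match the modeled system: OER_cDSB ≈ 4.2
(< OER_DSB), ≈ 99 % of DSBs with unit multiplicity at 1 Gy, anoxic DSBs
slightly more complex on average than oxic ones, and DSB counts linear in
dose through the origin.

## 4. Misrejoining and cell death

For the N cDSBs of one nucleus, every free-end combination is tried once,
in a fixed order (ends of cDSB_i against ends of cDSB_j for i < j, first
ends first). A trial is attempted only if both ends are still free and
succeeds with probability exp(−d_ij/r₀), where d_ij is the distance
between the two cDSB centroids (both ends of a cDSB share its position)
and r₀ = 0.7 µm by default. Success binds both ends permanently. One
uniform deviate is consumed per *attempted* trial, in trial order — this
fixes the RNG stream so any cell is replayable.

Counting follows three assumptions: cDSBs with both ends free restitute
faithfully (no terminal deletions); a cDSB with one joined end resolves
its other end within the exchange chain, uncounted (no incomplete
exchanges); and when two cDSBs explicitly join both end pairs, the second
join is not counted. Each counted misrejoining is independently lethal
with probability 1 − P_nlmr (default P_nlmr = 0.5, the probability that
the exchange is symmetric), so P_surv = P_nlmr^N_mr. The closed-chain
correction — a cycle of N ≥ 3 cDSBs carrying N explicit joins counts
N − 1 — is available behind `corrected_chains = TRUE` and off by default,
matching the published (uncorrected) counting.

The test suite checks the simulation against an exact enumeration oracle
(all ordered Bernoulli trial outcomes with end blocking, N ≤ 3), and the
pipeline-level consequences: E[N_mr] grows essentially quadratically in
dose (β_mr ≈ 0.35 Gy⁻² at the defaults under full oxia, ≈ 0.03 under
anoxia), −ln(mean survival) fits β_killing ≈ β_mr/2 at P_nlmr = 0.5, and
the linear components are near zero because same-track cDSB pairs are
rare.

## 5. Dose–response analysis

Yields are fit through the origin (m = ΣDN/ΣD²). Misrejoinings per cell
are fit unweighted to αD + βD²; if α < 0 (strictly), the fit is redone as
a pure quadratic and flagged. Survival fits apply the same rule to
−ln(mean survival) — the mean of survival across cells, not the mean of
the logs, is fitted. OERs are slope ratios for yields and D10 ratios for
killing; D10 solves αD + βD² = ln 10; SF2 extrapolates the fitted curve to
2 Gy. SEM-weighted fitting is deliberately not the default (no weighting
is stated for the reference analysis); fits are exact on noiseless
synthetic curves over the 10-dose schedule {0.001, …, 1} Gy.

## 6. Oxygenation of the 1 mm³ tumor

The 0.2 mm block is replicated 5 × 5 × 5 into a 1 mm cube (153 000 cells;
the voxel arrays are never materialized at the assembled scale). A
connected vessel network is grown as a branching random walk of tubes
(radius 6 µm) from one entry face: near-straight runners (per-step turning
σ = 0.1) that branch with probability 0.005 per step, all descending from
one tree — so the network is connected by construction (verified by flood
fill) — until the painted voxel fraction reaches the relative vascular
volume, 2.1 %.

Each cell's distance d to the nearest vessel voxel comes from an exact
Euclidean distance transform of the 500³ lattice. Cells with d < 7 µm
(the minor semi-axis) are replaced by vessel units; cells with d > 130 µm
(the necrosis distance) are necrotic; the rest are viable with
pO₂ = max(floor, 30 · exp(−d/L)) mmHg. The real oxygen transport model
behind the reference tumor is not published with it; the exponential decay
is this package's stand-in, with L the single calibrated parameter
(`calibrate_oxygenation()` solves mean viable pO₂ = 9.4 mmHg; L ≈ 28 µm,
frozen as the default). The vessel morphology parameters were fixed once
so that, after that 1-D calibration, the distance distribution also
reproduces the published hypoxia ladder: HP10 ≈ 0.57 (58 %), HP5 ≈ 0.32
(34 %), HP2.5 ≈ 0.18 (20 %), HP1 ≈ 0.07 (11 %), median pO₂ ≈ 8.5 mmHg
(8.2), necrotic fraction ≈ 2–12 % (9.4 % by volume) across seeds. The
exponential form with p0 = 30 and ND = 130 cannot reach HP1 = 11 %
exactly (pO₂ at the necrosis boundary is ≈ 30·e^(−130/28) ≈ 0.3 mmHg, so
the sub-1-mmHg mass depends on the extreme tail); the ladder is monotone,
and HP10 — the calibration-grade quantity — lands within a few percent.

For the whole-tumor dose simulation, the same tracks (per block cell) are
reused across all 125 copies via a separate track seed, while lesion
placement, thinning and misrejoining are re-randomized per copy and the
strand-break probability follows each cell's pO₂ — so every copy's DSB
distribution differs, as it should.

## 7. Seeds and determinism

Every operation takes an explicit seed. Child streams are derived with a
splitmix64 mixer (`child_seed(seed, label, label)`), with fixed stage
codes (0 tracks, 1 clustering, 2 lesions, 3 thinning, 4 misrejoining), so
the fused C++ kernel and the modular R operations reproduce each other
cell-for-cell — the suite asserts exact agreement. All seeds are kept
below 2³¹. Compiled kernels use a self-contained xoshiro256++ generator,
never R's global RNG, so R-level `set.seed` has no hidden interactions.

## 8. What a green suite establishes — and what it does not

The acceptance tests certify that the *surrogate, calibrated once*,
reproduces the analytic anchors (•OH displacement law, geometry closed
forms, fit closed forms, the misrejoining oracle), the calibration targets
(yields, OER, cDSB share, β_mr, β_killing, mean pO₂, HP10) and the
directional properties (oxygen and ablation orderings, unit-multiplicity
dominance). They do not certify microdosimetric realism: absolute event
yields per track, the spatial fine structure of real electron tracks, the
direct-only OER shift, chromosome-territory geometry (so aberration types
are not identified), repair kinetics, or any non-targeted effect. Within
the modeled mechanism, terminal deletions and incomplete exchanges are
assumed away, which is precisely why the linear killing component here is
far below clinically fitted α values — that gap is a finding, not a bug.
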