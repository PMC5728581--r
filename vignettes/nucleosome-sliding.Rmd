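---
title: "Modelling nucleosome sliding: potentials, coordinates and kinetic models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling nucleosome sliding: potentials, coordinates and kinetic models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nucleoslide)
```

# The problem

A nucleosome wraps ~147 bp of DNA in ~1.7 left-handed superhelical turns
around a histone octamer. Spontaneous repositioning ("sliding") along the
DNA is central to chromatin accessibility, and it can proceed in
qualitatively different ways: a *rotation-coupled* corkscrew motion in
1-bp steps that preserves the histone–DNA contact phasing; abrupt
*rotation-uncoupled* jumps of 5–10 bp that transiently break the
hydrogen-bond network; or, hypothetically, reptation of a loop (bulge)
defect across the wrap. Which mode dominates is decided by the balance
between sequence-dependent DNA bending energy and the histone–DNA
hydrogen bonds anchored at the half-integer superhelical locations
(SHLs), where the minor groove faces the core.

`nucleoslide` implements the computational layer of this problem for
coarse-grained models (one bead per amino acid at the Cα; phosphate,
sugar and base beads per nucleotide): the interaction terms, the
trajectory coordinates, free-energy estimation with bond-strength
reweighting, and small kinetic models. It deliberately contains **no MD
integrator**: energies and analyses only.

Internal units are Å, degrees, and kBT at 300 K (1 kBT = 0.5961
kcal/mol, exposed as `kBT300_kcal`). Residues are 1-based per chain;
base pairs are 0-based from the first base pair of strand 1, with
strand 2 assumed antiparallel.

# The sliding-invariant hydrogen-bond potential

Gō-type native contacts pin the DNA to one register and cannot describe
sliding. The bond potential used here instead scores each native bond
*i* — a donor Cα with reference geometry (r₀, θ₀, φ₀) — against **every**
phosphate *j* of both strands:

$$V_{hb} = -\varepsilon \sum_i \sum_j f(r_{ij}-r_{i,0})\,
  g(\theta_{ij}-\theta_{i,0})\, g(\varphi_{ij}-\varphi_{i,0})$$

* $f(\Delta r) = e^{-\Delta r^2/\sigma^2}$, σ = 1 Å;
* $g(\Delta\varphi)$ = 1 for $|\Delta\varphi| \le \Delta_\varphi$, the
  shoulder $1-\cos^2(\pi\Delta\varphi/2\Delta_\varphi)$ up to
  $2\Delta_\varphi$, 0 beyond; $\Delta_\varphi$ = 10°;
* θ is measured at the donor against the direction of its two chain
  neighbours, φ at the phosphate against the sugar of the same
  nucleotide — so both angles are defined purely from bead geometry.

When the DNA advances one base pair in a screw-like motion, each bound
phosphate is replaced by the next one in the same relative orientation,
and $V_{hb}$ is unchanged. The narrow widths make each bond specific to
one phosphate (occupancies within 0.01 of 1 on the ideal fixture), so
nothing is double-counted.

Two choices deserve comment:

* **Sign.** The formula above is written with an explicit −ε so a
  perfectly formed bond contributes −ε (stabilizing); the raw positive
  sum is returned separately as the per-bond *occupancy*. ε defaults to
  1.2 kBT — about the smallest value that keeps a nucleosome stable at
  low salt while still allowing disassembly at high salt; values up to
  ~2.4 kBT remain compatible with the salt-dependent unwrapping
  behaviour. All parameters are arguments, not constants.
* **Cutoff.** Phosphates beyond r₀ + 6σ contribute < 10⁻¹⁵ through f and
  are skipped; evaluation is O(bonds × local phosphates).
* **Averaging.** `extract_hbond_model()` takes plain arithmetic means of
  (r, θ, φ) over the available copies (e.g. two reference structures ×
  two symmetric halves, via an optional `group` column); native angles
  sit far from the 0°/360° wrap, so no circular statistics are needed.
  Donors on flexible tails are rejected, because the geometric bond
  evaluation assumes a stable near-native protein conformation.

# Non-bonded terms

Excluded volume is a pure r⁻¹² repulsion over protein–DNA pairs with
$\sigma_{ij} = 1.1\,(R_i+R_j)/2$; the 1.1 rescaling keeps tails from
threading between strands. The per-kind default radii and the energy
scale (0.2 kcal/mol) are generic placeholders — the literature values
live in forcefield-specific tables — and are user-replaceable via the
bead table and `interaction_params()`.

Debye–Hückel electrostatics uses the Bjerrum and Debye lengths from the
ionic strength and a dielectric model: either a constant, or an
empirical temperature- and salt-dependent form (quadratic in T, cubic in
molarity) as used with coarse-grained DNA forcefields; at 298 K and
vanishing salt it evaluates to 78.5. Phosphate charges are
class-specific: −0.6e within DNA (Oosawa–Manning condensation), −1e
against protein. The two classes are evaluated separately rather than by
mutating bead state, so results cannot depend on evaluation order.

`count_contacts()` counts phosphates within 12 Å (1.2 nm) of any
non-tail histone bead — the unwrapping observable whose mean over an
ensemble, plotted against salt, gives the familiar sigmoidal titration
curve (`titration_curve()`, with per-condition burn-in and standard
errors).

# Analysis coordinates

**DNA axis.** Ten contours are drawn on the DNA tube: contour *j* is a
natural cubic spline (chord-length parameterized) through the strand-1
phosphates with bp index ≡ *j* (mod 10), i.e. one helical repeat apart.
Each spline segment is subdivided into 10 equal parameter steps; for a
given phosphate the nearest subdivision point on each contour is
collected, the ten points are plane-fitted (SVD) and projected, and the
axis point is the center of an algebraic (Kåsa) circle fit — exact on
noiseless circles. One numerical choice matters: the nearest-point
search is restricted to subdivision points within one helical repeat
(10 bp) of the phosphate's own index. On a strongly curved superhelix
the unrestricted minimum can drift far along contours on the inside of
the bend (the minima are shallow), which destroys the circle fit; the
restriction recovers the intended cross-section ring, and on the ideal
fixture the axis is then accurate to ~0.03 Å. Ends are handled by
shortening: the axis is defined only where phosphates exist one repeat
away on both sides.

**Symmetry axis.** A total-least-squares line through the midpoints of
symmetric Cα pairs across the two histone copies (tails excluded); the
direction is oriented toward a caller-supplied reference point (the
tracked base pair) and kept consistent frame-to-frame.

**Sliding ζ and its bp conversion.** ζ is the signed angle, about the
superhelix normal, between the symmetry axis and the vector from the
core centroid to the tracked base-pair center (all available P/S/B beads
of both strands). The normal is the smallest principal axis of the
strand-1 phosphate cloud, oriented so the bp index increases
counter-clockwise; the sign of ζ is then intrinsic to the bp ordering,
which makes +bp motion positive — and, as a consequence, ζ is invariant
under mirror images (the convention re-orients with the handedness).
Angles are converted to slid base pairs through a strictly monotone
initial-frame table (`zeta_table()`, default ±30 bp around the tracked
base pair; wider windows would wrap past ±180° and lose monotonicity),
with linear interpolation inside and warned extrapolation outside.

**Rotation η.** The signed angle, in the plane perpendicular to the
local DNA tangent, from the axis→core-centroid direction to the
axis→strand-1-phosphate direction, unwrapped along the trajectory. On a
screw trajectory η advances by one twist step per bp slid (36°/bp at 10
bp/turn). Note an honest subtlety: the reference direction is anchored
at the *fixed* core centroid while the axis point climbs along the
superhelix pitch, so the measured slope carries a small secular offset
(~0.46°/bp on the ideal fixture, i.e. ~355° rather than 360° per 10 bp)
plus a periodic wobble from the centroid's in-plane offset. This is a
property of the coordinate's definition, not noise; the same effect
makes η drift by ~2.3° across a rigid 5-bp jump instead of being exactly
constant.

**RMSD, per-SHL sliding, ΔR.** `rmsd_central()` superposes on the
non-tail histone beads (Kabsch, via `bio3d::fit.xyz`) and measures the
central 20 bp of DNA. `shl_sliding()` tracks the base pairs initially at
requested SHLs with local ζ tables, distinguishing cooperative motion
(screw/jump: all SHLs step together) from sequential loop propagation.
`loop_delta_r()` is the increase of the bp-center-to-core distance over
a reference — values above ~1 Å flag extra base pairs stored in a bulge.

# Free-energy surfaces and ε-reweighting

`free_energy_surface()` histograms the sliding (default bin 0.25 bp) and
optionally rotation (default 9°) coordinates and reports F = −ln P in
kBT, minimum shifted to zero. Empty bins stay masked: pseudocounts would
fabricate free energies in unvisited regions. Because $V_{hb}$ is exactly
linear in ε, an ensemble sampled at ε can be reweighted to ε′ with
per-frame weights $w \propto \exp(-(\varepsilon'/\varepsilon - 1)V_{hb})$
— only the bond term enters, all other terms being ε-independent. The
effective sample size $(\sum w)^2/\sum w^2$ is attached to the surface;
it equals N only at ε′ = ε and shrinks as ε′ departs, which is the
honest limit of single-reference reweighting (no multi-ensemble
WHAM/MBAR is attempted). Burn-in (`burn_in()`) discards initial frames
per independent trajectory to remove initial-configuration bias.

# Kinetic models of the repositioning routes

Repositioning from the initial position to the 10-bp-shifted one is
summarized by 3-state models (start → intermediate → shifted): the
rotation-uncoupled route through the 5-bp-shifted state, the
rotation-coupled route through a 5-bp-rotated state, and the reptation
route through a loop defect at one end. `mfpt()` solves the first-step
equations exactly; `gillespie()` is the stochastic oracle. Rates not
measurable directly are completed by detailed balance,
$k_{fwd} = k_{rev} e^{-\Delta F}$, with ΔF the intermediate's free
energy relative to the start. The shipped loop parameterization —
dissipation 1/(8×10⁴ steps), diffusion to the far end 1/(7×10⁶ steps),
ΔF = 15 kBT — yields

```{r}
mfpt(route_model("loop"), "crystal", "shifted10")
```

about 2.3×10¹³ MD steps, which is why reptation cannot compete with the
observed ~10⁹–10¹¹-step routes. Times are reported in MD steps
throughout; no mapping to seconds is attempted. The numeric rates of the
other two routes are not fully constrained by published main-text
numbers, so they are left caller-parameterized.

# The synthetic fixture: what it emulates and what it does not

`build_ideal_nucleosome()` places DNA beads on an analytic left-handed
superhelix (defaults: 147 wrapped bp, radius 41.9 Å, pitch 25.9 Å,
38-bp straight linkers, 3.4 Å of contour per bp) with pseudo-histone
donor triplets at every half-integer SHL from ±0.5 to ±6.5, two per site
(one per strand), making 28 native bonds. The construction is exactly
C2-symmetric, so the symmetry-axis fit and the ζ = 0 origin are exact.
The DNA twist is fixed at exactly 10.0 bp/turn — not the physical ~10.17
— so that rotation-coupling tests have the closed-form 36°/bp slope;
the physical value is one argument away. Phases are tied to path
positions, which makes `advance_screw()` an *exact* symmetry of the
hydrogen-bond energy (the invariance tests assert relative drift
< 10⁻⁶; numerically it is 0).

Trajectory modes are kinematic, not dynamical: screw (register ramp or
±1-bp random walk), jump (register shift with the DNA counter-rotated so
its phase at any fixed base pair is constant; reflecting walls default to
±10 bp, the five-state landscape of a strong positioning sequence), loop
(a Gaussian radial bulge propagating from the +SHL end, with a smooth
10-bp register step across the moving front), and static. Gaussian
positional noise is optional and seeded; all generators are
deterministic given their seed.

What the fixture does **not** emulate — and hence what passing tests do
not show about real data: thermal DNA breathing and unwrapping,
sequence-dependent bending, histone tails and their charges (the
pseudo-core is a sparse set of donor sites, so only inward-facing
phosphates fall within the 12 Å contact cutoff — about 160 of the 294
wrapped-region phosphates), bead-level excluded-volume packing, and any
actual dynamics. The fixture proves the *analysis machinery* correct;
claims about real nucleosomes still require real trajectories.

The sequence library ships the central ~81-bp (±4 SHL) region of the
Widom 601 sequence and of polyCG-601 (a polyCG background with the two
TTAAA/TTTAA positioning motifs at the 601 offsets), plus generators for
polyCG and polyAA at any length. The full 145-bp 601 core is not
embedded; users supply it via `sequence_construct()` when needed.
`build_construct()` adds alternating-CG linkers: 147 + 2×38 = 223 bp for
polyCG-style constructs, 145 + 2×39 = 223 bp for 601-style ones.

# Numerical choices and degenerate inputs

* Spline type: natural cubic, chord-length parameterized; circle fit:
  Kåsa (linear least squares), exact on noiseless circles and stable for
  10 points.
* η unwrapping adds the multiple of 360° minimizing frame-to-frame
  jumps; ζ tables are unwrapped along bp before the monotonicity check.
* Zero-length pair distances raise singularity errors rather than
  returning Inf; empty ensembles, empty tables, tail donors, terminus
  donors, unreachable Markov targets and over-long burn-ins raise typed
  errors or warnings as appropriate.
* The moving-average smoother for coordinate time series (trailing
  window, e.g. 10 frames) is exposed as an option and never applied
  silently.
* Problem sizes in the test-suite and acceptance computations are
  desk-scale by design: the 21-frame screw sweep, 10⁴–10⁵-sample
  Boltzmann toys and 10⁴ Gillespie replicates each run in seconds while
  leaving the statistical tolerances (3 SE / 3 SEM) meaningful.

# Known limitations

* Energies only — no forces, no integrator, no sampling engine.
* Single-reference ε-reweighting degrades (small ESS) far from the
  reference strength; the surfaces report ESS so users can judge.
* The η coordinate's secular pitch offset (above) means "360° per 10 bp"
  is recovered to ~1–2%, not exactly, even on noise-free fixtures.
* The bead-TSV dialect and multi-model PDB cover the package's own I/O;
  mmCIF is out of scope, and reference crystal structures are expected
  to be supplied by the user.
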