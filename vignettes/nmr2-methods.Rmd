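---
title: "NMR molecular replacement: model, calibration and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{NMR molecular replacement: model, calibration and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Protein-observed NOESY data on a ligand-receptor complex contain, in
principle, everything needed to place the ligand in the binding site: every
cross peak between a ligand proton and a receptor methyl encodes a distance
below ~5-6 Å. What makes classical NMR structure determination slow is not
the distances but the *assignment*: knowing which methyl resonance belongs
to which residue. NMR molecular replacement (NMR2) sidesteps sequential
assignment entirely. Given a published receptor structure (apo or holo) and
unassigned, ambiguous NOE restraints, it enumerates the possible
resonance-to-methyl assignments, calculates a ligand pose under each, and
lets the structure-calculation target function decide: the assignment whose
restraints can be satisfied best *is* the assignment, and its pose ensemble
is the structure. The approach is particularly effective with selectively
ILV-methyl-labeled, otherwise deuterated receptors, where the spectra are
sparse, sensitive and relatively free of spin diffusion.

This package implements that workflow end to end: build-up curve fitting,
rate-to-distance conversion, restraint calibration (including anti-NOEs and
prochiral pairing), assignment enumeration, simulated-annealing pose
search, and a full relaxation-matrix NOESY simulator that provides ground
truth for validation.

## Relaxation model

Throughout the package the spectral density is the plain Lorentzian of
isotropic rigid tumbling,

$$J(\omega) = \frac{\tau_c}{1 + \omega^2\tau_c^2},$$

so that $J(0) = \tau_c$, a convention chosen because it keeps the
cross-relaxation expression in its widely used form and makes $J(0)$
directly testable. The isolated two-spin cross-relaxation rate is

$$\sigma_{ij} = \left(\frac{\mu_0}{4\pi}\right)^2
\frac{\hbar^2\gamma_H^4}{10\, r_{ij}^6}\,\bigl[6J(2\omega_H) - J(0)\bigr],$$

negative in the slow-tumbling regime relevant here (bromodomain-sized
receptors, $\tau_c \approx 10$ ns). `sigma_from_distance()` and
`distance_from_sigma()` are exact algebraic inverses; all internal units
are SI with Ångström only at API boundaries, which removes an entire class
of prefactor bugs.

Diagonal peaks decay as $M(t) = M_0 e^{-\rho t}$; cross peaks follow the
symmetric two-spin solution

$$\Delta M_{ij}(t) = -M_0\,\frac{\sigma}{\Delta}\,
\sinh(\Delta t)\, e^{-\bar\rho t}, \qquad
\Delta = \sqrt{\tfrac{(\rho_i-\rho_j)^2}{4} + \sigma^2},$$

which reduces to the familiar $-M_0\,\sigma\,t\,e^{-\bar\rho t}$ initial
rate and handles unequal autorelaxation. Fitting is a deterministic
bounded scalar least squares in $\sigma$ (amplitudes come from the
diagonal fits), run separately on the negative and positive branch — no
random initialization, bit-reproducible results.

The rotational correlation time can be estimated from backbone ¹⁵N
R1/R1ρ rates by inverting the isotropic R2/R1 ratio relation
(`estimate_tau_c()`); R1ρ is treated as R2 with no exchange contribution.
This is a deliberate simplification of full diffusion-tensor analyses:
anisotropy, chemical exchange and internal motion are all neglected, which
is adequate for the ~2% distance effect that a ~10% τc error produces
(distances go as $\sigma^{-1/6}$).

## Restraint calibration

Two protocol variants are provided, selected by a flag:

* **`trim24`-style** (uniformly labeled receptor, anchors available):
  upper limit = fitted distance + 0.5 Å, no floors, no anti-NOEs.
* **`brd4`-style** (ILV labeling, tolerant): curves that follow the
  two-spin model closely (normalized RMS residual ≤ 0.05 of the peak
  maximum) keep their fitted distance plus a 1.5 Å tolerance; curves with
  a *slight deviation* from the two-spin shape get a large tolerance
  floor — 5.5 Å when a single ligand proton is involved, 6.5 Å when two
  methyl groups are involved — and no lower limit. The exported
  `calibrate_upper_limit()` implements the floor rule; the pipeline
  driver applies the two-tier logic.

The 1.5 Å tier-1 tolerance is not arbitrary: on synthetic benchmark data
the relay (spin-diffusion) bias of well-fitting two-spin distances reaches
−1.4 Å in the worst case over 20 pocket geometries, and a calibration
tolerance must cover its calibration error, otherwise the true pose is
infeasible under its own restraints. The floor values are the protocol's
published constants and are exposed in the run configuration.

A *fit-quality threshold* of 0.15 (normalized RMS residual) decides
acceptance outright: badly relayed or noisy curves are discarded, which is
the protocol's "poor fit" rule with a concrete, configurable number.

**Anti-NOEs.** A missing cross peak is interpreted conservatively: only
when both resonances show visible NOEs to *other* partners can the absence
be attributed to distance rather than dynamics or artifacts
(`build_anti_noe()` returns nothing otherwise). Accepted anti-NOEs become
lower limits of 3.0 Å (one methyl involved) or 3.6 Å (two methyls) —
deliberately far below the actual detection radius (~5 Å), trading
information for robustness.

**Prochiral methyls.** The geminal methyl pairs of Leu and Val are grouped
from the strong intraresidue methyl-methyl NOE in the receptor-receptor
region of the spectra (`pair_prochirals()`, mutual-strongest greedy
matching above a σ threshold equivalent to 3.0 Å). Two consequences:

1. during enumeration, a paired resonance duo must map onto a geminal
   methyl duo (either orientation), collapsing the combinatorics;
2. upper limits referencing a paired resonance are evaluated against
   *both* geminal methyls with the $(\sum d^{-6})^{-1/6}$ pseudo-group
   effective distance, the standard treatment for stereospecifically
   unassigned methyls.

Because of (2), hypotheses that differ only by swapping geminal partners
are exactly tied — stereospecific assignment is not obtainable from this
data, and no claim is made. Benchmark assignment recovery is therefore
scored modulo prochiral swaps (strict equality is also reported).

**Residue-type classes.** Externally supplied class annotations (Met, Thr,
Ala, ILV from characteristic shifts, CT-HSQC sign or TOCSY patterns — the
classification itself is an input, not computed here) restrict each
resonance's candidate set; Met/Thr resonances whose class has exactly one
binding-site member become fixed anchors.

## The engine

`enumerate_assignments()` produces every injective mapping consistent with
candidate sets, anchors and pairing (count = permanent of the candidate
matrix; a configurable cap aborts hopeless combinatorics with advice).
Each hypothesis is scored by `optimize_pose()`: multi-start simulated
annealing over the ligand's six rigid-body degrees of freedom plus
rotatable torsions, geometric cooling, followed by deterministic
derivative-free polishing. The target function is the classical
restrained-structure-calculation form: squared upper-limit violations,
squared lower-limit violations, and a hard-sphere repulsion
$\sum (r_{min}-d)^2$ over ligand-receptor atom pairs closer than their
scaled contact distance (per-element radii H 1.0, C 1.5, N 1.4, O 1.3,
S 1.7 Å, overlap factor 0.8; all configurable). It is implemented in
compiled code with a cell-list over the static receptor atoms; an
independent naive R evaluator in the test suite agrees to 10⁻⁹.

Determinism is strict: a single master seed fans out per-restart streams
as `seed * 1000003 + restart` inside the compiled annealer (own
SplitMix64-based generator, independent of R's RNG state), and ranking
ties break lexicographically on the serialized mapping — identical inputs
and seed give bit-identical rankings. Exact ties (symmetric or
prochiral-degenerate hypotheses) are detected and reported.

`run_nmr2()` screens every hypothesis with a cheap schedule, refines the
best `top_k` with the full schedule, and reports the winner's mapping as
the inferred assignment together with the retained pose ensemble.

`refine_backbone_restrained()` provides a simplified vacuum analog of
restrained explicit-solvent refinement: selected receptor methyls move in
Cartesian coordinates under harmonic tethers $k\lvert x-x_0\rvert^2$
jointly with the ligand pose, letting a flexible binding-site loop bend
toward the ligand to relieve residual violations. Solvent, electrostatics
and force-field terms are out of scope.

## The synthetic world

`make_toy_complex()` builds the validation universe: a pocket of methyl
pseudoatoms of a stated residue composition (default 1 Met, 1 Thr, 2 Ala,
2 Leu, 2 Val = 12 methyls, geminal partners 2.5 Å apart) on a shell of
radius 6 Å around the pocket center, and a rigid fragment-like ligand
(aromatic core, ring methyl, out-of-plane tail with one rotatable torsion,
8 proton groups) at the center in a random orientation. A wall of
clash-only pseudoatoms packs against the ligand envelope with a ~55°
solvent opening, emulating the steric complementarity of a concave
binding site; without it a 12-point methyl cloud leaves the ligand about
1.5-2.5 Å of restraint-free play and no restraint set of this size can pin
a pose to 1 Å. Infeasible random draws (crowded shells, uninformative
geometry) are rejected and redrawn from deterministically derived
sub-seeds.

`simulate_noesy()` builds the *full* relaxation matrix — σ from every
pairwise distance, diagonal rates $\rho_i = \sum_j \lvert\sigma_{ij}\rvert
+ \rho_{leak}$ with a 1 s⁻¹ external leak — and propagates
$M(t) = e^{-Rt}M(0)$, so spin diffusion is fully present in the synthetic
build-ups; this is what makes the quality filter and the tolerance tiers
testable. Peaks below the detection threshold are suppressed and recorded
in the visibility table (the anti-NOE substrate).

Conventions worth knowing:

* Proton groups are **unit pseudo-spins** at pseudoatom positions; methyl
  multiplicity affects calibration floors (methyl flags) but no intensity
  scaling. Consequently the multiplicity-correction hook
  (`sigma_scale` in `fit_crossrelaxation()`) defaults to 1; its scaling
  behavior ($\sigma/3 \Rightarrow r \times 3^{1/6}$) is unit-tested
  separately.
* The detection threshold defaults to **0.3%** of the largest diagonal
  intensity. Under the unit pseudo-spin convention this corresponds to a
  ~5 Å detection radius at 200 ms — the field-typical methyl-NOESY range —
  whereas a 2% cutoff would imply an unrealistically short ~3.8 Å radius
  and starve the benchmark of cross peaks.

What the generator does *not* emulate: chemical shifts and overlap,
J-coupling and zero-quantum artifacts, exchange broadening, multiplicity
intensity effects, internal receptor motion, and real rotamer chemistry
(the receptor is pseudoatoms plus walls). A green end-to-end test
therefore establishes that the *protocol logic* — fitting, calibration,
anti-NOE rules, enumeration, scoring — recovers a stated world; it does
not establish performance on real spectra.

## The flagship benchmark

`run_benchmark()` chains everything at stated-world defaults: 12 pocket
methyls, 10 observed resonances (the 2 with the weakest ligand NOE
evidence are treated as unobserved, so the mapping is injective into a
larger set), 2 anchors (Met/Thr), 25 intermolecular NOE upper limits,
15 anti-NOE lower limits, intraligand restraints, noise-free. Restraint
selection is coverage-aware and deterministic: every resonance and ligand
group keeps its best-quality NOE before remaining slots fill by global
quality, and anti-NOEs fill the least-NOE-covered resonances first — an
unrestrained resonance would be a free rider that creates artificial
assignment degeneracy. Success criteria: the winning hypothesis equals the
generating assignment (modulo prochiral swaps) and the best pose is within
1.0 Å heavy-atom RMSD of the truth; removing the anti-NOEs must not
improve the mean RMSD over 20 seeds.

## Numerical choices

* Diagonal fits profile the amplitude out in closed form and search the
  rate on a bounded interval (`optimize`, tol 10⁻¹²); non-decaying data
  are flagged, not thrown.
* Cross fits bound σ in ±100 s⁻¹; quality is RMS residual / max |I|.
* τc root-finding brackets [1 ps, 1 µs] with 10⁻¹⁸ tolerance; ratios
  below the extreme-narrowing minimum are a hard error.
* Degenerate pocket draws raise generation errors; the retry loop is
  deterministic (sub-seed = seed + k·100003).
* Annealing defaults: 50 restarts × 2000 steps, T 5 → 0.005, move sizes
  1 Å / 0.4 rad / 0.5 rad; the benchmark uses lighter schedules (12 × 3000
  refinement, 3 × 500 screening, top 15 refined) that converge on the toy
  problem in seconds.
* Tie threshold for reporting: |Δtarget| ≤ 10⁻⁹.

## Known limitations

* Stereospecific prochiral assignment is not attempted (tied by
  construction under pseudo-group evaluation).
* At some pocket geometries two methyls of the same class can be genuinely
  interchangeable given floored restraints; the engine then reports an
  exact tie and lexicographic order decides. This is a property of the
  data, not a defect of the search.
* Side-chain flexibility is limited to harmonically tethered Cartesian
  displacement of methyl pseudoatoms in the refinement step; full rotamer
  chemistry is out of scope for the toy receptor.
* The simulator's unit pseudo-spin intensities make absolute detection
  thresholds convention-dependent (see above); only relative comparisons
  within the synthetic world are meaningful.
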