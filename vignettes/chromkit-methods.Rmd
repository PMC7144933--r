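---
title: "chromkit: models, conventions and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{chromkit: models, conventions and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromkit)
```

This vignette is the package's own account of the science it implements:
the models and their assumptions, the parameters that matter (with units and
defaults), what the synthetic generators do and do not emulate, the
numerical choices, and the places where the design was genuinely open. It
states no empirical result that the test suite or the acceptance script do
not themselves compute.

## The system and the observables

A chromatosome is a nucleosome core particle (147 bp of DNA wrapped around
the histone octamer) plus a linker histone bound near the dyad and ~20 bp of
linker DNA on each side. The analyses here all operate on labelled
coordinates (a `StructureFrame` topology plus per-frame coordinate matrices
in Å); no chemistry (bonds, charges, force fields) is represented, and
running MD itself is out of scope.

### Nucleosomal plane and linker-DNA α/β angles

The nucleosomal DNA C1′ atoms are divided into four quadrants. The centres
of mass of the two quadrants *distal* from the linker DNA give two plane
points (p1, p2); the C1′ centre of mass of the dyad base pair gives the
third (p3). The plane normal is `unit((p1 − p3) × (p2 − p3))`.

Per frame and per linker arm, the arm vector v runs from the origin base
pair's C1′ centre of mass to the terminal base pair's. The out-of-plane
angle is β = asin(v̂·n̂) — positive on the +normal side, i.e. "away from the
plane". The in-plane angle α is the signed rotation, about the normal, from
the in-plane *anti-dyad* direction (from p3 toward the midpoint of p1 and
p2 — the only dyad-axis proxy available from the plane construction) to the
projected arm, with the sense flipped between the entry and exit arms so
that positive α is motion toward the dyad axis for both. Frames where the
arm is parallel to the normal have no in-plane direction; α is recorded as
`NA` there, never fabricated.

Two conventions were genuinely open:

* **Handedness.** A rule such as "normal points away from the core-histone
  centre of mass" is degenerate when the core COM lies essentially in the
  plane (which it does for any approximately flat nucleosome). Handedness is
  therefore fixed deterministically by the *order* of the two distal
  quadrants supplied to `define_nucleosomal_plane()`; an optional
  `orient_ref` point restores the away-from-reference rule when it is well
  posed.
* **Quadrant membership** is user-supplied (residue ranges in a config), not
  inferred, because base numbering is construct-specific.

### β-loop angles φ₁/φ₂

The loop vector runs from the centre of mass of the α3 helix to that of the
β-loop; φ₁ is its angle to the α1-helix axis and φ₂ to the β-sheet axis.
Helix/sheet axes are the first principal component of the selection's
coordinates oriented from the first atom to the last (N→C). Published
definitions of these groups live in supplementary material that varies
between studies, so the atom groups are configuration, not code. φ₂ below
~60° indicates the closed loop state; ~100° the open state.

### Distribution statistics

Angle series are binned on fixed common grids when systems are compared
(default 50 bins per axis) because a KL divergence between systems is only
defined on a shared grid. Conventions, stated in the output metadata because
the field uses both:

* MI and entropies in **bits**; NMI = MI/√(HₓH_y) (geometric-mean
  normalization — the standard choice that is bounded in [0, 1]); NMI := 0
  when a marginal entropy vanishes.
* KL in **nats**: D(P‖Q) = Σ P ln(P/Q), P the system under study (e.g.
  chromatosome angles), Q the reference (nucleosome). `0·log 0 := 0` for
  MI. KL is undefined on empty reference bins, so a pseudo-mass ε (default
  `1/(10·n)` per cell) is added to both distributions, which are then
  renormalized; ε → 0 as sampling grows, and KL decreases monotonically in ε
  when Q has empty cells (property-tested).

Histogram MI estimators are positively biased at finite n — roughly
(B−1)²/(2n ln 2) bits for B×B bins — which is why the independent-series
check in the tests uses n = 10⁵, where the bias is far below the 0.01 NMI
threshold.

### WHAM

Standard self-consistent WHAM on 1-D umbrella windows:
p(b) = Σᵢ nᵢ(b) / Σᵢ Nᵢ exp[(fᵢ − wᵢ(b))/kT] and
fᵢ = −kT ln Σ_b p(b) exp(−wᵢ(b)/kT), iterated until the largest change in
the fᵢ drops below the tolerance (default 10⁻⁶ kcal/mol); output
F = −kT ln p shifted to minimum 0. Parameters that matter:

* **Bias convention**: w(ξ) = k(ξ−c)² *without* the ½ factor — the
  colvars/Grossfield convention used by the toolchain this layer mirrors; a
  `half_k` flag switches to ½k(ξ−c)² since other codes differ.
* k_B = 0.0019872041 kcal·mol⁻¹·K⁻¹; T defaults to 300 K.
* Default 100 bins over the sampled (or supplied) range; the coordinate is
  treated as non-periodic (the β-loop coordinate spans ~40–120°, far from
  wrap-around).
* Coverage is validated: adjacent windows (by centre) must share at least
  one occupied bin, otherwise a coverage error names the gap.

**Statistical inefficiency** g = 1 + 2ΣC(t), the normalized autocorrelation
summed to its first non-positive value (FFT-based autocovariance, biased
1/n normalization), clamped to g ≥ 1; N_eff = N/g. This classic truncation
rule is implemented exactly as stated; note that single-series estimates at
strong correlation (ρ ≈ 0.9, n = 10⁵) still scatter by ~5–20% because the
drawn series itself does — the test suite therefore checks the mean over
replicate series against the AR(1) closed form (1+ρ)/(1−ρ).

**Bootstrap errors**: each of the (default 100) trials redraws ⌈Nᵢ/gᵢ⌉
samples per window with replacement, re-solves WHAM on the common grid, and
aligns to minimum 0; the per-bin SD over trials is the reported error. Trials
that fail (e.g. coverage loss under resampling) propagate; more than 20%
failures aborts with a bootstrap-instability error. **Convergence** re-solves
on cumulative time blocks and flags when the final two blocks deviate by
more than 0.5 kcal/mol (default).

### PRE back-calculation

The condensed intensity-ratio model is

I_ox/I_red = exp(−β(r+d)⁻⁶) / (1 + α(r+d)⁻⁶),  α = 4.5×10⁸, β = 3.4×10⁷,
d = 9.0 Å,

with r the probe→methyl distance in Å. **The exponent is negative.** The
positive exponent that appears in print is non-physical: it would make the
ratio diverge as r → 0, while the underlying relaxation model
(ratio = R₂·exp(−R₂ˢᵖt)/(R₂+R₂ˢᵖ), R₂ˢᵖ ∝ r⁻⁶) forces the ratio to 0 near
the probe and 1 far from it. The implemented form has exactly those limits
and is strictly increasing on [0, ∞) into (0, 1]. Both modes are available;
`derive_condensed_constants()` regenerates (α, β) from physical parameters
(K, τ_c, ω_h, R₂, t_evol), and a consistency test verifies the two routes
agree.

Ensemble averaging follows the "time-averaged ratio" reading: per frame the
methyl-a and methyl-b ratios are computed and averaged, then averaged over
frames — *not* the ratio of the mean distance (the two differ measurably
because of the r⁻⁶ nonlinearity; a test pins this down). The 80% confidence
band is the empirical 10th/90th percentile of the per-frame means —
percentile rather than Gaussian, because per-frame ratio distributions near
the [0, 1] boundaries are skewed. No MTSL probe is modelled: distances use
wild-type proxy atoms (lysine terminal N, threonine terminal methyl C), as
in the simulation practice this mirrors.

### MM/GBSA assembly and strain

The package consumes per-frame energy-component tables (internal,
electrostatic, van der Waals; totals validated as their sum) and assembles
the three-trajectory estimate ΔE_X = mean(X_complex) − mean(X_receptor) −
mean(X_ligand). The "±" on every reported quantity is the per-frame standard
deviation, combined in quadrature across the three independent
trajectories — SD, not SEM, is the interpretation adopted (the convention is
usually left unstated in publications; it is labelled here). ΔΔE between
binding modes and the strain decomposition ΔΔE_strain = ΔE(complexed) −
ΔE(isolated) are linear in the component means, so linearity,
antisymmetry, and constant-shift invariance are exact and property-tested.
Polar-solvation and nonpolar-surface terms are expected to be folded into
the electrostatic and van der Waals columns upstream; equilibration and
frame decimation also happen upstream of ingestion.

### Clustering

Frames are superposed once onto a common reference via the fit selection
(e.g. core-histone helical CA) and the pairwise RMSD of the measure
selection (linker-histone helical CA) is computed between aligned frames —
matching the "RMSD with respect to the core" phrasing; pairwise mutual
superposition is available as an option. Agglomeration is average-linkage
(`stats::hclust`) with the dendrogram cut at the distance cutoff (default
2.0 Å); clusters are relabelled by descending population with deterministic
ties (lowest member frame), the representative is the medoid, and
`top_fraction()` returns the smallest population-ordered prefix reaching the
requested mass (default 90%). The linkage criterion in the original
toolchain is unstated; average linkage is its default and is exposed in the
result for provenance.

## Synthetic data: what it emulates, what it does not

The generators exist so that every analysis has a known ground truth. Their
defaults encode the stated experimental world: 147 bp core, 41 umbrella
windows every 2° with k = 0.1 kcal·mol⁻¹·deg⁻², experimental-scale PRE
noise (σ = 0.05 on the ratio), MM/GBSA component scales of hundreds of
kcal/mol, two-state poses separated by several Å of RMSD.

* **Toy chromatosome** (`make_toy_chromatosome`): C1′ pseudo-atoms on a
  *circular* core path in the z = 0 plane (a flattened superhelix), straight
  pseudo-atom linker arms leaving the core gap at prescribed α/β (built by
  composing the inverse of the analyzer's decomposition in the ideal plane
  frame), and a pseudo-domain of CA strings for the linker histone. Per-atom
  Gaussian jitter supplies frames. It emulates the *geometry* that the angle
  machinery consumes — not DNA mechanics, sequence effects, superhelical
  pitch, or correlated (collective) motions; a green round-trip test
  establishes that the analyzer inverts the stated construction, not that
  real linker DNA behaves this way.
* **Umbrella windows** (`sample_umbrella_windows`): the spec sketched a
  Metropolis sampler with AR(1)-style proposals; implemented instead as a
  Gaussian AR(1) copula mapped through the grid inverse-CDF of the biased
  density. This gives samples whose marginal is the *exact* biased Boltzmann
  distribution (so WHAM's truth is exact, not asymptotic) with lag-1
  autocorrelation directly set by `ar1_rho` — the two properties the tests
  need — at the cost of not emulating Metropolis rejection artefacts.
* **PRE / energy / two-state generators** draw iid Gaussian noise around
  known truths; they do not emulate systematic experimental error, force-field
  bias, or slow conformational drift.

Every generator is a pure function of its parameter record including the
seed, and returns a machine-readable truth record consumed by the tests.

## Numerical choices and degenerate inputs

* Angles: cosines are clamped to [−1, 1] before `acos`/`asin`; zero vectors
  raise degenerate-geometry errors rather than returning NaN.
* COM uses atomic masses where elements are known, unit masses otherwise
  (pseudo-atom models carry "C" labels, so this rarely matters, but it is
  documented behaviour).
* Kabsch superposition uses SVD with a determinant sign correction, so
  reflections are never returned.
* WHAM's fixed-point iteration anchors f₁ = 0 each sweep; probabilities in
  unoccupied bins are reported as `NA` free energy rather than ∞.
* `hierarchical_cluster` validates symmetry/non-negativity; a zero matrix
  short-circuits to a single cluster (hclust needs ≥ 2 distinct heights).
* The PDB writer emits fixed-width records rounded to 10⁻³ Å; round-trip
  tests use that as the tolerance. Residue numbering is preserved from the
  source file (crystallographic, 1-based) everywhere.

## Known limitations

* 1-D, non-periodic WHAM only (no 2-D, no MBAR, no replica exchange).
* No k-NN/continuous MI estimators and no time-lagged information measures.
* The PRE layer does not model probe rotamers, spectral simulation, or τ_c
  fitting; distances come from proxy atoms.
* No GB/PB energy evaluation — the energetics module is an assembler of
  upstream per-frame tables.
* The selection grammar is deliberately small (segid/resid/resname/name/
  element + `and`); it is not a general MD selection language.
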