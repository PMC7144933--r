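# chromkit

Analysis toolkit for chromatosome and nucleosome molecular-dynamics studies.

A chromatosome is a nucleosome core particle plus a linker histone (H1
family) and ~20 bp of linker DNA. Simulation studies of these systems keep
re-implementing the same analysis layer: linker-DNA entry/exit angles
relative to the nucleosomal plane, linker-histone β-loop metrics,
umbrella-sampling free-energy profiles, PRE back-calculation against NMR
data, MM/GBSA binding-energy decompositions, RMSD clustering of binding
poses, and contact maps. `chromkit` packages that layer as tested, reusable
R, together with synthetic-data generators with known ground truth so every
stage can be validated without running MD.

## What it computes

- **Linker-DNA α/β angles** — the nucleosomal plane is defined from the C1′
  centres of mass of the two DNA quadrants distal from the linker DNA plus
  the dyad base pair; per frame, each linker arm's in-plane deflection (α,
  DNA "breathing" toward the dyad) and out-of-plane deflection (β) are
  signed angles of the arm vector against that plane.
- **β-loop angles φ₁/φ₂** — angle of the α3-helix→β-loop vector against the
  α1-helix axis (φ₁) and the β-sheet axis (φ₂); φ₂ separates open (~100°)
  from closed (~50–60°) loop states.
- **Distribution statistics** — 2-D angle histograms; mutual information in
  bits with geometric-mean normalization, NMI = MI/√(HₓH_y) ∈ [0, 1]; and
  the Kullback–Leibler divergence D(P‖Q) = Σ P ln(P/Q) (nats) of a
  chromatosome angle distribution P from a nucleosome reference Q, with
  ε-regularization for empty reference bins.
- **WHAM** — self-consistent weighted-histogram reconstruction of a 1-D PMF
  from harmonic umbrella windows, p(b) = Σᵢnᵢ(b) / Σᵢ Nᵢ exp[(fᵢ−wᵢ(b))/kT],
  with statistical-inefficiency-aware Monte-Carlo bootstrap errors and
  cumulative-block convergence checks. Bias convention w(ξ) = k(ξ−c)²
  (colvars/Grossfield), switchable to ½k(ξ−c)².
- **PRE back-calculation** — I_ox/I_red = exp(−β(r+d)⁻⁶) / (1 + α(r+d)⁻⁶)
  with α = 4.5×10⁸, β = 3.4×10⁷, d = 9.0 Å, applied per frame to
  probe→methyl distances, methyl-a/b averaged, time-averaged, with an 80%
  percentile confidence band and comparison statistics against experimental
  ratio tables. (Note the *negative* exponent; the positive form sometimes
  printed is non-physical.)
- **MM/GBSA assembly** — three-trajectory ΔE per component
  (mean complex − mean receptor − mean ligand, spreads in quadrature),
  on/off-dyad ΔΔE, and the strain decomposition
  ΔΔE_strain = ΔE(complexed) − ΔE(isolated) per species.
- **Clustering & contacts** — pairwise-RMSD (fit on one selection, measure
  on another) average-linkage agglomerative clustering with a distance
  cutoff, cluster populations and top-90% selection; heavy-atom
  residue–residue contacts at a 4.0 Å cutoff.

## Worked example

Reconstruct a free-energy profile from synthetic umbrella windows whose
generating potential is known (double well, 3.0 kcal/mol barrier at 80°,
minima at 60°/100°), using the 41-window / 2° / k = 0.1 kcal·mol⁻¹·deg⁻²
protocol:

```r
library(chromkit)

pot <- synthetic_potential("double_well", barrier = 3.0, minima = c(60, 100))
sam <- sample_umbrella_windows(pot, centers = seq(40, 120, by = 2),
                               force_constant = 0.1, n_per_window = 2000,
                               seed = 42)
cfg  <- wham_config(n_bins = 100, bootstrap_trials = 50, seed = 42,
                    range = c(40, 120))
prof <- bootstrap_pmf(sam$windows, cfg)

i80 <- which.min(abs(prof$bin_centers - 80))
sprintf("barrier %.2f +/- %.2f kcal/mol at %.1f deg; min at %.1f deg",
        prof$free_energy[i80], prof$stderr[i80],
        prof$bin_centers[i80],
        prof$bin_centers[which.min(prof$free_energy)])
#> "barrier 3.02 +/- 0.04 kcal/mol at 79.6 deg; min at 60.4 deg"
```

The recovered barrier (3.02 ± 0.04) reproduces the generating truth (3.0)
within the bootstrap error. The same pattern works for the geometry layer —
build a toy chromatosome with prescribed angles and recover them:

```r
sim <- make_toy_chromatosome(toy_chromatosome_params(
  alpha_entry = 25, beta_exit = -12.1, n_frames = 5,
  coordinate_noise_sd = 0.3, seed = 42))
re <- compute_linker_angles(sim$trajectory, sim$config$plane_spec,
                            sim$config$arm_entry)
rx <- compute_linker_angles(sim$trajectory, sim$config$plane_spec,
                            sim$config$arm_exit)
sprintf("alpha_entry %.2f +/- %.2f ; beta_exit %.2f +/- %.2f",
        mean(re$alpha), sd(re$alpha), mean(rx$beta), sd(rx$beta))
#> "alpha_entry 25.07 +/- 0.35 ; beta_exit -11.86 +/- 0.70"
```

Here α_entry = 25° is the DNA-breathing scale typically observed in
chromatosome simulations and β_exit = −12.1° is an on-dyad-style inward
deflection of the exit arm; both are recovered from the jittered coordinates
within the noise.

## Command line

```sh
inst/cli/chromkit wham --meta meta.csv --temp 300 --bins 100 --bootstrap 100 --seed 1 --out-dir out/
inst/cli/chromkit cluster --fit "segid CORE and name CA" --measure "segid LH and name CA" traj.pdb
inst/cli/chromkit simulate chromatosome --seed 3 --out-dir out/
```

Subcommands: `angles`, `dyndist`, `wham`, `pre`, `gbsa`, `cluster`,
`contacts`, `simulate`; every run echoes a provenance line (version, seed,
arguments) to the log.

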