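# idpcryo

Quantitative analysis chain connecting the secondary and quaternary
structure of an intrinsically disordered protein (IDP) to its membrane- and
enzyme-protective function during freeze-thaw stress.

Late-embryogenesis-abundant (LEA) proteins such as the chloroplast-stroma
IDPs of *Arabidopsis* are disordered when hydrated, fold into amphipathic
helices and self-assemble into oligomers as water activity drops, and
protect membranes and enzymes during freezing.  Linking those three levels
— conformation, association state, and protective function — takes four
kinds of quantitative analysis, which this package implements end to end
with a synthetic-data module providing every input with known ground truth:

1. **Trajectory statistics** (`trajectory-analysis`): Kabsch-superposed
   backbone RMSD, hydrogen bonds (donor–acceptor ≤ 3.5 Å, donor–H–acceptor
   angle > 120°), residue contact-probability maps (closest heavy-atom
   distance ≤ 3.5 Å, pooled over replicate trajectories) with intra/inter
   chain labels, DSSP-style helix/coil timelines from the i→i+4 H-bond
   pattern, backbone orientational correlation |⟨v_i·v_j⟩| of Cα_i→Cα_{i+1}
   vectors, and Eisenberg helical-wheel hydrophobic moments.
2. **Small-angle scattering** (`scattering`): Guinier fits
   ln I ~ −R_G²q²/3 with a self-consistent low-q window satisfying
   q_max·R_G ≤ 1.3 (SAXS) or 1.1 (SANS); the Guinier–Porod generalized
   model with C¹-continuous crossover Q1 = √(3d/2)/R_G, yielding the
   power-law compaction exponent d (2 = Gaussian coil, 4 = globule); and
   dimensionless Kratky diagnostics ((qR_G)² I/I0, peak at √3 ≈ 1.73 for a
   pure Guinier scatterer).
3. **Solution biophysics** (`solution`): DLS cumulant analysis and
   Tikhonov-regularized non-negative inversion of g₂(τ)−1 correlograms,
   Stokes–Einstein radii R_S = k_B T/(6πηD), SLS apparent masses
   M = R_θ/(Kc) with toluene normalization, infinite-dilution extrapolation
   to relative masses M_rel = M/M_monomer, crowder volume fractions
   φ = cν/10, and CD helicity from θ_MRW at 222 nm.
4. **Protection assays** (`assays`): surface-occupancy normalization
   c_prot·a_prot·n_l,tot·MW_lipid/(a_target·c_lipid·MW_prot) built on
   per-vesicle lipid counts n_l,tot = Σ f_l[4πR² + 4π(R−d_bl)²]/a_l;
   four-parameter-logistic dose-response fits
   y = low + (high−low)/(1+10^(logEC50−x)) of carboxyfluorescein leakage
   (the high-occupancy asymptote is the liposome stabilization capacity),
   electrolyte-leakage LT₅₀, and LDH activity retention across freeze-thaw
   cycles.

## Worked example

```r
library(idpcryo)

# a synthetic SAXS curve from a Guinier-Porod scatterer: a 30 A coil (d = 2)
curve <- make_guinier_porod_curve(
  guinier_porod_truth(R_G = 30, d = 2, noise_frac = 0.01, seed = 42))

guinier_fit(curve, limit = 1.3)
#> Guinier fit: R_G = 29.873 +/- 0.112 A, I0 = 0.9998, 94 points, qmax*R_G = 1.285 (limit 1.30)

guinier_porod_fit(make_guinier_porod_curve(guinier_porod_truth(30, 2)))
#> Guinier-Porod fit: R_G = 30.000 A, d = 2.000, G = 1, Q1 = 0.0577 1/A (residual 1.917e-11)
```

The Guinier window was chosen automatically: 94 low-q points whose realized
q_max·R_G = 1.285 stays inside the 1.3 validity bound, recovering the true
30 Å radius within 0.5%.  The noise-free Guinier–Porod fit recovers the
compaction exponent d = 2 (a Gaussian coil) and the crossover
Q1 = √3/30 = 0.0577 Å⁻¹ exactly.

```r
# an unraveling helix-loop-helix dimer with a protected helical core
traj <- make_helix_coil_trajectory(
  helix_coil_params(n_res = 89, n_frames = 30, n_chains = 2,
                    unravel_rate = 0.15, core_span = c(40, 60), seed = 1))
hel <- assign_helicity(traj)
round(range(hel$helix_fraction), 3)
#> [1] 0.562 0.966
```

The per-frame helix fraction decays from 0.97 toward the protected core as
the termini unravel.  One command reproduces the whole synthetic study
(trajectory statistics, scattering fits, DLS/SLS, occupancy, dose-response
capacities, LT₅₀):

```r
res <- run_pipeline(run_config(list(seed = 11, out_dir = "out")))
```

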