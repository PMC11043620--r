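---
title: "Models and methods: from disordered-protein structure to cryoprotective function"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(idpcryo)
```

# Scope and model overview

`idpcryo` analyzes the structure-function chain of intrinsically disordered
cryoprotective proteins at four levels: molecular-dynamics-style trajectory
statistics, small-angle scattering compaction analysis, solution
hydrodynamics, and surface-occupancy-normalized protection assays.  It does
not run molecular dynamics, reduce instrument data, or model form factors
beyond the Guinier–Porod family; curves and trajectories arrive reduced.
Every analysis is exercised against a synthetic-data module that generates
its inputs with known ground truth, which is what the test suite and the
acceptance report rely on.

# The synthetic world

## Helix–coil trajectories

Chains are built from ideal internal coordinates (trans peptides, standard
bond lengths, N–Cα–C angle 110.0°, Cα–C–N 116.2°) by sequential
natural-extension placement, so a conformation is fully specified by its
per-residue (φ, ψ).  Helical residues use the canonical α-helix
(φ = −57°, ψ = −47°), which with these internal coordinates yields a 1.53 Å
rise (5.5 Å per 3.6-residue turn), 3.80 Å Cα–Cα distances, and i→i+4
H-bonds of 2.96 Å N···O at a 164° donor–H–acceptor angle.  Coil residues
draw (φ, ψ) uniformly from the broad β/PPII basin (φ ∈ [−180°, −60°],
ψ ∈ [60°, 180°]), redrawn every frame; this basin produces *zero* i→i+4
H-bonds, so the helicity detector separates the two classes by
construction.  Amide hydrogens are generated explicitly (1.01 Å on the
outward bisector of C(i−1)–N–Cα), so H-bond criteria need no inference.

Unfolding is a terminal-erosion Markov chain: per frame and per terminus
the outermost helical residue converts to coil with probability
`unravel_rate`, never eroding into the protected `core_span`.  This
emulates the statistical signature of a helix that unravels from its
termini toward a residually helical core — the feature the downstream
statistics detect — and nothing more; there is no force field, no
excluded volume, and water (when requested) is an uncorrelated random
shell used only to exercise the protein–water H-bond bookkeeping.  A green
round-trip therefore establishes that the analysis recovers the stated
statistical signatures, not that it would agree with a physical simulation
in detail.

Dimers place two independently eroding chains antiparallel (principal Cα
axes aligned to ±z) at a configurable inter-axis distance, 10 Å by
default.  At 10 Å the backbone-only chains make no inter-chain contacts at
the 3.5 Å cutoff; tests that need inter-chain contact labels use a closer
arrangement explicitly.

## Scattering curves, correlograms, assay tables

Scattering fixtures follow the Guinier–Porod forward model (below) with
multiplicative Gaussian noise and σ = noise_frac · I_model.  DLS fixtures
follow g₂(τ)−1 = β(Σᵢ wᵢ e^(−Γᵢτ))² with Γᵢ = Dᵢq² and Dᵢ from
Stokes–Einstein; the default instrument is a 532 nm, 90° setup with water
at 23 °C (η = 0.932 mPa·s, n = 1.332) — explicit inputs, not hidden
constants.  Assay fixtures draw replicates from the four-parameter
logistic with Hill slope 1 plus Gaussian noise; the LDH variant adds a 0–5
freeze–thaw-cycle dimension with a multiplicative per-cycle decay
(default 0.8/cycle).  All generators are pure functions of
(parameters, seed): seeds are mandatory arguments, the caller's RNG stream
is never touched, and identical inputs give bit-identical outputs.

# Trajectory statistics

**Superposition.**  RMSD uses the Kabsch SVD solution with a reflection
guard (det +1), each frame fitted independently over backbone N, Cα, C, O.
The test suite checks it against the closed-form quaternion eigenvalue
solution — an algebraically independent route to the same global minimum.

**Hydrogen bonds.**  A bond is any donor/H/acceptor triplet with
donor–acceptor distance ≤ 3.5 Å and donor–H–acceptor angle strictly
> 120°; donors are N/O heavy atoms carrying a hydrogen, acceptors N/O
heavy atoms, same-residue pairs excluded.  With the canonical helix
geometry the i→i+3 pairs sit at 3.2 Å but only a 109° angle, so the angle
criterion alone cleanly removes them — an 18-residue ideal helix has
exactly its 14 i→i+4 bonds.

**Helicity.**  Full DSSP is deliberately reduced to its α-helix criterion:
a turn starts at residue i when O(i)···H–N(i+4) satisfies the H-bond
criteria, and two consecutive turns (i−1, i) mark the donor-side residues
i..i+3 helical.  We attribute helicity to the donor-side residues (the
DSSP convention) rather than to the turn-start residue because the
carbonyl O of residue i is rigid in the i/i+1 peptide plane: the turn at
core_start−1 exists whenever the core itself is helical, so turn-start
attribution would always leak one residue beyond a rigid helix boundary.
Only the helix/coil dichotomy is reported; 3₁₀/π/turn/bridge classes are
not distinguished, and the combined-variant question collapses because
only the α pattern is evaluated.

**Contacts.**  P(i,j) is the fraction of pooled frames — all replicates
with equal weight — in which the closest heavy-atom distance between
residues i and j is ≤ 3.5 Å (the length of an H-bond).  Persistent
contacts are those with P ≥ 0.75, sequence-adjacent pairs (|i−j| ≤ 2
within a chain) excluded, reported as (chain, 1-based residue) pairs.

**Orientational correlation.**  Entry (i,j) is |⟨vᵢ·vⱼ⟩| over frames for
per-frame-normalized Cα_i→Cα_{i+1} vectors; random and constantly
orthogonal orientations both average to zero, rigid parallel segments
to one.  The matrix is invariant under global rigid rotation of every
frame.

**Hydrophobic moment.**  Eisenberg consensus scale, helical-wheel angular
step 100°/residue, vector magnitude normalized per residue; with a window
shorter than the sequence every position is evaluated and the
maximum-magnitude window reported.

# Scattering analysis

The generalized ("Guinier–Porod") model with zero dimensionality shift is

$$I(q) = G\,e^{-q^2R_G^2/3} \;(q \le Q_1), \qquad
  I(q) = D\,q^{-d} \;(q > Q_1),$$

with $Q_1 = \sqrt{3d/2}/R_G$ and $D = G\,e^{-d/2}Q_1^d$ fixed by
continuity of I and dI/dq.  This is the only cited generalized form that
yields both R_G and the compaction exponent d, which is why it implements
the "generalized Gauss function" fits.  Fitting runs in log-intensity
space (σ-weighted via weights (I/σ)² when uncertainties are present,
unweighted otherwise — recorded in the output), multi-started over
d ∈ {1.5, 2, 3, 4} with L-BFGS-B on (ln G, ln R_G, d) and best-residual
selection; d pinned at a bound raises a warning.  An optional flat
background is *not* floated by default (the upstream fits' behavior is
unstated; the conservative choice is fewer parameters, and the synthetic
world has no background).

The Guinier window is chosen self-consistently: starting from the full
usable curve, fit ln I ~ q², compute R_G = √(3|slope|), keep the largest
low-q prefix with q_max·R_G ≤ limit, and iterate until the window is
stable (≤ 50 rounds; an oscillating pair resolves to the smaller window).
Starting wide rather than from a minimal 8-point window matters at
realistic noise: over a tiny q range the log-intensity decrement is
smaller than 1% noise and the initial slope sign would be random.  The
limit defaults to 1.3 (SAXS) with 1.1 (SANS) available — both printed
validity bounds, not tuning knobs.  When limit·√(2/(3d)) < 1 the accepted
window never crosses the crossover Q1.

The dimensionless Kratky transform is x = qR_G, y = x²I/I0.  Peak
detection uses a 3-point running median only (no spline, keeping the peak
location bias-free) and requires an interior maximum exceeding both
smoothed endpoints by a 10⁻⁶ relative prominence — enough to reject the
float jitter of an exactly flat q⁻² curve, far below any physical
feature.  A pure Guinier scatterer peaks at x = √3 ≈ 1.732 (the analytic
maximum of x²e^(−x²/3)).

# Solution hydrodynamics

**Cumulants.**  ln √(g₂−1) = ln √β − Γτ (+ μ₂τ²/2 at order 2) fitted over
lags above a 10⁻³ relative noise floor; D = Γ/q², R_S = k_BT/(6πηD), and
PDI = μ₂/Γ².  Second-order is the default method; the Stokes–Einstein
round trip R_S→D→R_S is exact by construction.

**Regularized inversion.**  The classical constrained-regularization
inversion is replaced by an equivalent documented contract: non-negative
least squares on g₁ = √((g₂−1)/β) over a log-spaced decay-time grid
(80 nodes by default) with a second-difference Tikhonov penalty, fixed
default α = 0.1 and an explicit override — no L-curve automation, so runs
are reproducible.  Fully decayed lags are truncated first (tail noise
estimate, 3σ floor): square-rooting positive-clipped noise would otherwise
masquerade as slow modes.  Peak positions are refined by log-parabolic
interpolation around grid maxima, giving sub-grid-resolution mode
positions; the reported mean R_S is intensity-weighted.  The NNLS solver
is a small Lawson–Hanson implementation (no NNLS package is available in
the target environment).

**SLS.**  M_app = R_θ/(Kc) with K = 4π²n²(dn/dc)²/(N_Aλ⁴) in cgs units
and R_θ from a configurable toluene Rayleigh-ratio standard (2.79×10⁻⁵
cm⁻¹ at 532 nm by default).  dn/dc is an input, not computed from
sequence.  Apparent masses and radii measured at several concentrations
are extrapolated to infinite dilution by ordinary least squares; the
intercept divided by the monomer mass is M_rel, the average association
state.

**CD helicity.**  f_H = (θ₂₂₂ − θ_coil)/(θ_helix − θ_coil) with fixed
default constants θ_coil = −2340, θ_helix = −32640 deg·cm²·dmol⁻¹
(equivalently f_H = −(θ₂₂₂+2340)/30300); the chain-length-corrected helix
reference −39500(1 − 2.57/n) is available via `n_residues`.  Fixed
constants are the default because the exact constant set used upstream is
not stated; both variants are exposed.  Values outside [0,1] are clipped
with a warning, the raw value retained.

# Protection assays

Surface occupancy normalizes protectant dose by both mass and size: the
protectant presents a disc a_prot = πR_S² to a spherical target area
a_target = 4πR_S,target².  For liposome targets the lipid mass
concentration converts to vesicles through
n_l,tot = Σ_l f_l[4πR² + 4π(R−d_bl)²]/a_l (outer plus inner leaflet over
the per-species head-group area; the bilayer thickness is named d_bl to
avoid colliding with the scattering exponent d).  Default geometry: 50 nm
vesicle radius (100 nm extrusion pore), 4 nm bilayer, head-group areas
MGDG 0.66, DGDG 0.80, SQDG 0.66, EPG 0.64 nm² — packaged defaults, always
overridable, inputs rather than fitted truth.  The protein-target default
is tetrameric LDH (R_S 4.3 nm, 140 kg/mol).  Occupancy is homogeneous of
degree +1 in protectant and −1 in target concentration.

CF leakage is 100(F_post − F_pre)/(F_triton − F_pre) — the standard
self-quenching release normalization consistent with the measurement
order (the cited source prints no formula) — clipped to [0,100] with the
raw value retained.

All dose-response data share one model, the four-parameter logistic with
Hill slope 1 on a base-10 abscissa,
y = low + (high − low)/(1 + 10^(logEC50 − x)), parameterized by low-x and
high-x asymptotes rather than min/max so that descending CF-leakage curves
and ascending electrolyte-leakage curves need no relabeling; y(logEC50) is
exactly the mid-span.  CF fits run on log₁₀(occupancy) (the 10^(logEC50−x)
form presupposes a log abscissa); LT₅₀ fits run on plain temperature, where
the "logEC50" parameter is simply the temperature of half release.
Fitting is `nls` (port) multi-started from data quantiles.  Variants are
fitted independently (a shared-asymptote option across variants is a
deliberate non-feature: independent fits are the conservative default and
the upstream choice is unstated).

Electrolyte leakage per sample is 100·cond_before/cond_after, normalized
to the unfrozen control by 100(L − L₀)/(100 − L₀): the control anchors
zero and full release stays at 100.  The synthetic LT₅₀ table therefore
uses a warm-end asymptote of exactly 0 after normalization, making the
control rows and the logistic tail mutually consistent and noise-free
recovery exact.  LDH retention divides each activity by the unfrozen
no-protectant control and averages technical replicates with standard
errors.

# Numerical choices and degenerate inputs

* Constant dose-response data return a flagged degenerate fit (both
  asymptotes at the mean) instead of failing.
* A non-decaying correlogram (total fitted decay < 10⁻³) is an error, as
  is an all-zero inversion solution (suggesting smaller α).
* Guinier fits require ≥ 8 usable points and a negative slope; windows
  never shrink below 5 points.
* Chains shorter than 5 residues are assigned all-coil with a warning.
* Missing amide hydrogens are an error that names the geometric placement
  utility rather than silently inferring them.

# Limitations

The synthetic trajectories carry no physical energetics; scattering
fixtures have uncorrelated Gaussian noise (real detectors correlate
neighboring q bins); DLS noise is additive white (real correlators have
τ-dependent statistics); and the packaged mature-chain sequence is a
*synthetic stand-in* (see `inst/extdata/cor15a_mature_synthetic.fasta`)
constructed offline to the documented length and formal net charge — the
counterion bookkeeping is validated as a computation, not against the
database record.  Instrument data reduction, virial analysis, multi-angle
light scattering and form-factor modeling beyond Guinier–Porod are out of
scope.
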