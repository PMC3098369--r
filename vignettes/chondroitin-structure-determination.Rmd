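---
title: "Determining chondroitin 3D structure from NMR restraints"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Determining chondroitin 3D structure from NMR restraints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gagnmr)
library(dplyr)
```

## The problem

Chondroitin is a glycosaminoglycan built from the repeating disaccharide
GlcA-β(1→3)-GalNAc, with consecutive disaccharides joined by β(1→4)
linkages. Its sulfated forms decorate proteoglycans throughout vertebrate
tissue, and how sulfation changes the backbone shape is a long-standing
structural question. Solution structures of short oligosaccharides (the
hexasaccharide CN6 is the shortest length that already behaves like the
polymer) are determined from NMR observables: NOESY cross-peak intensities,
vicinal scalar couplings, and amide-proton temperature coefficients.

`gagnmr` implements that determination end to end:

1. **NOE calibration** — the isolated spin-pair model `I = k·r⁻⁶` is fitted
   through the origin to reference cross-peaks between protons whose
   separation is fixed by the rigid pyranose ring.
2. **Restraint generation** — the calibrated model converts the
   conformationally dependent inter-residue peak intensities into distances,
   which are binned into flat-bottom wells: *strong* (1.8–2.7 Å) and
   *medium* (2.8–3.8 Å).
3. **Restrained simulated annealing** — torsion-space Monte Carlo with a
   1 K → 500 K → 0 K heat/hold/cool schedule, repeated over independent
   rounds; the lowest-energy 10% of final models form the reported ensemble.
4. **Validation analytics** — back-calculated ³J couplings (generalized
   Karplus), ring-pucker checks, circular torsion statistics, RMSD spread,
   hydrogen bonds, and temperature-coefficient classification.

## The model and its assumptions

### Spin-pair calibration

For short mixing times and isolated proton pairs, cross-relaxation makes the
NOESY cross-peak intensity proportional to `r⁻⁶`. The calibration constant
`k` is the zero-intercept least-squares slope of intensity against `r⁻⁶`
over five intra-residue reference pairs (1,3-diaxial protons of the chair,
e.g. H1–H3 and H1–H5 of internal residues, all near 2.4–2.6 Å). The
inversion `r = (k/I)^{1/6}` compresses intensity errors about six-fold,
which is why even 20% multiplicative noise moves distances by only a few
percent. Spin diffusion and mixing-time build-up are outside the model; the
wide flat-bottom bins absorb the residual systematic error.

Overlapped cross-peaks from chemically equivalent linkages are summed in the
spectrum; their intensities are divided by the overlap multiplicity (3
β(1→3) linkages and 2 β(1→4) linkages in CN6) before calibration. Division
is the only direction consistent with per-linkage distances.

### The chain model

Residues are rigid, idealised ⁴C₁ chairs built from tetrahedral internal
coordinates (C–C 1.52 Å, C–O 1.43 Å, anomeric C1–O1 1.41 Å, ring torsions
alternating ±60°, the D-series chirality verified against an independent
cheminformatics construction). GalNAc carries the axial O4 that
distinguishes the galacto configuration — visible directly in the
back-calculated ³J₃,₄ (gauche, ~2–3 Hz) against GlcA's trans ~8–9 Hz — plus
an N-acetyl group at C2 and a hydroxymethyl at C5; GlcA carries a C5
carboxylate. The degrees of freedom are the glycosidic (φ, ψ) pair of every
linkage (IUPAC heavy-atom definitions, degrees in (−180°, 180°]) and the
GalNAc exocyclic torsions ω (O5–C5–C6–O6) and acetamido (H2–C2–N–HN), both
defaulting to trans; the acetamido trans orientation is what the observed
8–10 Hz ³J(HN,H2) couplings imply. Glycosidic bond geometry is C1–O1
1.41 Å, O1–Cx 1.43 Å, C1–O1–Cx 117°. Hydroxyl hydrogens are fixed anti;
the GlcA carboxylate orientation is fixed, which is why the idealised
fixture shows the amide-to-carboxylate contact at ~3 Å rather than the 2 Å
a full force field relaxes it to.

Requested torsions are reproduced exactly by construction (NeRF placement
plus a rigid-body frame match), so set-then-measure round-trips to below
10⁻⁶ degrees — the property the whole annealer relies on.

### The annealer

The published protocol used restrained all-atom molecular dynamics with a
carbohydrate force field and continuum solvent. This package deliberately
replaces that engine with Metropolis Monte Carlo in torsion space — the
central desk-scale simplification. What is kept identical: the eight NOE
restraints with force constant 10 kcal/mol/Å², flat-bottom ring-torsion
restraints of 100 kcal/mol/rad² on the ±(60 ± 20)° windows (rigid templates
satisfy them identically, but the term guards models read from files), the
1 → 500 → 0 K linear schedule, 250 independent rounds, and the
lowest-10%-by-energy selection. What replaces the force field: a soft-sphere
steric term (k = 5 kcal/mol/Å², 3.0 Å cutoff, heavy-atom pairs more than
three bonds apart; intra-residue pairs are rigid and therefore constant and
omitted). Temperatures enter through kT with R = 0.0019872 kcal/mol/K.

Moves perturb one randomly chosen torsion by a Gaussian step whose width
shrinks linearly with temperature from 30° at 500 K to 2° near 0 K. Each
round ends with a greedy zero-temperature quench followed by a
derivative-free Nelder–Mead polish of the torsion vector — the stand-in for
the published gradient minimisation; the polish is deterministic, so a fixed
seed fixes the whole ensemble (round *i* uses seed + *i* − 1; energy ties
are broken by round index). Default problem sizes (50 heat, 50 hold, 100
cool steps at 2 moves per step, 200 quench moves, 1200 polish iterations)
were chosen so one round converges reliably on a laptop-scale budget; a
250-round run takes a few minutes on one core.

Because the simplified potential has no electrostatics or solvent, absolute
energies and the exact φ/ψ basin positions are **not** comparable to the
published force-field ensemble; the package therefore asserts only the
restraint-violation bound (≤ 0.03 Å for the lowest-energy conformer) and
ring integrity, and *reports* the RMSD spread and torsion statistics for
inspection.

### Couplings

Ring ³J(H,H) couplings are back-calculated with the generalized
(substituent-corrected) Karplus equation
`J(θ) = P₁cos²θ + P₂cosθ + P₃ + Σᵢ Δχᵢ[P₄ + P₅cos²(ξᵢθ + P₆|Δχᵢ|)]`.
The coefficients, the group electronegativities (ether/hydroxyl oxygen,
amide nitrogen, carbon) and the amide `A cos²θ + B cosθ + C` form all live
in an editable YAML registry (`karplus_registry()`), not in code: the
original empirical parameterisations are configuration a user may swap. The
orientation sign ξ is derived geometrically — +1 when the substituent sits
at +120° from the coupled proton on its own carbon. Substituents are found
by geometric adjacency so glycosidic oxygens contributed by the
neighbouring residue are counted correctly. Couplings are computed from a
single conformer, not ensemble-averaged.

### Shift analytics

Temperature coefficients are ordinary least-squares slopes of δ against
temperature, ×1000 (ppb/°C); with two points the line is exact.
Coefficients beyond ±3 ppb/°C in magnitude indicate no persistent
intra-molecular hydrogen bond (free exchange sits near −11 ppb/°C); the
boundary is classed as hydrogen-bond-consistent (closed interval).
The published tables this package ships as CSV fixtures print shifts to one
decimal, so coefficients recomputed *from the printed table* are close to,
but not identical with, the printed coefficients — those were evidently
computed from unrounded shifts. Differences *between* printed coefficients
are reproduced exactly, and that is what the tests assert. One further
transcription quirk: in the coupling table, one row prints a
chondroitin-hyaluronan difference whose chondroitin operand is n/d; that
cell cannot be recomputed and is excluded. The hyaluronan-octasaccharide row
of the torsion-comparison table prints deviations computed from unrounded
torsions, so it too is excluded from exact checks.

## What the synthetic generators emulate

`simulate_noesy()` is the calibration model's exact inverse
(`I = k·r⁻⁶` on the model's true distances, with optional multiplicative
lognormal noise — peak volumes are positive, so noise is multiplicative,
with sdlog equal to the fractional sd), including the 3:2 overlap grouping.
`simulate_shift_series()` draws from the straight line the coefficient
estimator assumes. `reference_torsion_fixture()` builds CN6 at the
consensus solution-structure torsions (φ ≈ −73° throughout; ψ ≈ +108°
across β(1→3), ≈ −117° across β(1→4)); it is labelled synthetic because it
is an idealised chain, not the deposited experimental ensemble. The
closure property — restraints generated from the fixture's own noiseless
peaks score zero restraint energy on the fixture — is what makes the
full-pipeline test meaningful.

What the generators do *not* emulate: spin diffusion, mixing-time build-up,
lineshapes, solvent dynamics, conformational averaging of intensities.
Passing tests therefore demonstrate the correctness of the estimators and
the annealer under the stated model, not the fidelity of that model to any
particular spectrometer.

## Worked pipeline

```{r pipeline, eval = FALSE}
fixture <- reference_torsion_fixture()

peaks <- simulate_noesy(fixture, k_true = 100, overlap_grouping = TRUE)
calibration <- peaks |>
  filter(role == "reference") |>
  select(intensity, distance) |>
  fit_noe_calibration()
glance(calibration)

restraints <- build_restraint_set(peaks, calibration)

ensemble <- generate_ensemble(fixture, restraints,
                              n_rounds = 250, keep_fraction = 0.10,
                              seed = 1)
glance(ensemble)
torsion_statistics(ensemble)
ensemble_rmsd(ensemble)

write_multimodel_pdb(ensemble, "cn6_ensemble.pdb")

back_calculate_ring_couplings(ensemble$model[[1]])
hydrogen_bonds(ensemble$model[[1]])
```

A smaller schedule (e.g. `anneal_schedule(heat_steps = 10, hold_steps = 10,
cool_steps = 20)`) is useful for interactive exploration.

## Design choices and limitations

* **Bin gap.** The strong/medium categories leave a 2.7–2.8 Å gap;
  calibrated distances are split at the 2.75 Å midpoint. Distances beyond
  3.8 Å produce no restraint.
* **Through-origin fit.** The spin-pair model has no intercept, so the
  calibration line is constrained through the origin.
* **Circular statistics.** Torsion means and standard deviations use
  unit-vector averaging with sd = √(−2 ln R̄); for the tight distributions
  of restrained ensembles this coincides with the linear sd while staying
  correct across the ±180° wrap.
* **Hydrogen-bond defaults.** H···A ≤ 2.5 Å and D–H···A ≥ 120°; published
  ensembles report distances only, so the angular criterion is this
  package's choice.
* **All-atom RMSD** uses heavy atoms plus polar hydrogens by default
  (selectable).
* **PDB naming.** Written files use NGA (GalNAc) and BDP (GlcA); the reader
  accepts the common GAG residue-name variants via an overridable mapping
  table, since deposition naming is inconsistent.
* **Limitations.** No boat/skew ring conformers, no iduronic acid, no
  sulfo-group chemistry, no relaxation-matrix treatment, no
  ensemble-averaged couplings, and no claim that the simplified potential
  reproduces force-field torsion basins. The command-line surface is the R
  API itself; scripts/acceptance.R shows a complete scripted run.
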