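# gagnmr

NMR-based 3D structure determination for chondroitin oligosaccharides, as a
tidyverse-native R package. It covers the full route from NOESY cross-peak
intensities to an energy-ranked conformer ensemble, plus the analytics used
to validate and interpret such structures.

Chondroitin is the glycosaminoglycan repeat GlcA-β(1→3)-GalNAc, with
β(1→4) linkages between disaccharides. Its solution structure is determined
from sparse NMR observables:

* **NOE calibration.** Cross-peak intensity follows the isolated spin-pair
  model *I* = *k·r*⁻⁶. The constant *k* is the zero-intercept least-squares
  slope of *I* against *r*⁻⁶ over five intra-residue reference pairs whose
  separation is fixed by the rigid ⁴C₁ chair; inverting the model
  (*r* = (*k*/*I*)^(1/6)) converts the conformationally dependent
  inter-residue intensities into distances, binned into flat-bottom
  restraints — strong (1.8–2.7 Å) or medium (2.8–3.8 Å).
* **Restrained simulated annealing.** Torsion-space Metropolis Monte Carlo
  over the glycosidic φ/ψ and exocyclic torsions of a rigid-ring chain,
  with the restraint force constants 10 kcal/mol/Å² (distances) and
  100 kcal/mol/rad² (ring-pucker windows ±(60 ± 20)°), a linear
  1 K → 500 K → 0 K schedule, 250 independent rounds, and the
  lowest-energy 10% kept as the ensemble.
* **Validation analytics.** Generalized-Karplus back-calculation of
  ³J(H,H) and amide ³J(HN,H2) couplings, circular φ/ψ statistics, optimal
  superposition RMSD, hydrogen-bond detection, amide temperature
  coefficients (|Δδ/ΔT| > 3 ppb/°C ⇒ no persistent hydrogen bond), and the
  ~0.5 ppm downfield sulfation offset of H-4/H-6.

All functions take and return tibbles (or tibble-backed model objects), so
pipelines compose with the pipe; fitted objects support `tidy()`,
`glance()` and `autoplot()`. Multi-model PDB ensembles are read and
written; published reference tables ship as CSV fixtures
(`reference_table()`), and every stage has a synthetic-data generator that
is the exact inverse of the model it feeds.

## Worked example

```r
library(gagnmr)
library(dplyr)

fixture <- reference_torsion_fixture()   # synthetic CN6 at consensus torsions

peaks <- simulate_noesy(fixture, k_true = 100, overlap_grouping = TRUE)
calibration <- peaks |>
  filter(role == "reference") |>
  select(intensity, distance) |>
  fit_noe_calibration()
glance(calibration)
#> # A tibble: 1 × 3
#>       k fit_residual n_references
#>   <dbl>        <dbl>        <int>
#> 1   100     6.83e-32            5

restraints <- build_restraint_set(peaks, calibration)
restraints |> select(type, res_a, atom_a, res_b, atom_b, distance, bin)
#> # A tibble: 8 × 7
#>   type  res_a atom_a res_b atom_b distance bin
#>   <chr> <chr> <chr>  <chr> <chr>     <dbl> <chr>
#> 1 b13   N1    HN     U2    H1         3.11 medium
#> 2 b13   N1    H3     U2    H1         2.24 strong
#> 3 b14   N3    H1     U2    H4         2.30 strong
#> 4 b13   N3    HN     U4    H1         3.11 medium
#> 5 b13   N3    H3     U4    H1         2.24 strong
#> 6 b14   N5    H1     U4    H4         2.30 strong
#> 7 b13   N5    HN     U6    H1         3.11 medium
#> 8 b13   N5    H3     U6    H1         2.24 strong
```

The calibration recovers the generating constant exactly (noiseless peaks),
and the eight restraints reproduce the published pattern: GalNAc HN–GlcA H1
medium and GalNAc H3–GlcA H1 strong across each β(1→3) linkage, GalNAc
H1–GlcA H4 strong across each β(1→4) linkage. A short annealing run (the
full protocol uses `n_rounds = 250`):

```r
ensemble <- generate_ensemble(fixture, restraints,
                              n_rounds = 20, keep_fraction = 0.10, seed = 1)
glance(ensemble)
#> # A tibble: 1 × 6
#>   n_kept n_generated kept_fraction energy_min energy_max max_violation_best
#>    <int>       <dbl>         <dbl>      <dbl>      <dbl>              <dbl>
#> 1      2          20           0.1          0          0                  0
```

Both kept conformers satisfy every restraint exactly
(`max_violation_best = 0` Å, against the ≤ 0.03 Å tolerance of the full
protocol) with intact ⁴C₁ rings. Temperature-coefficient analysis of a
simulated amide shift series:

```r
series <- simulate_shift_series(-7.2, intercept = 8.35,
                                temps = c(5, 25, 35),
                                noise_sd = 0.005, seed = 2)
tc <- temperature_coefficient(series)
classify_hbond_from_coefficient(tc$slope_ppb_per_C)
#> # A tibble: 1 × 3
#>   slope_ppb_per_C classification      delta_from_free_exchange
#>             <dbl> <chr>                                  <dbl>
#> 1           -6.81 no-persistent-hbond                     4.19
```

A −6.8 ppb/°C coefficient exceeds the ±3 ppb/°C threshold, so the amide
proton is not in a persistent intra-molecular hydrogen bond — it sits much
closer to the free-exchange value of about −11 ppb/°C.

See the vignette (`vignettes/chondroitin-structure-determination.Rmd`) for
the model, its assumptions, and the design decisions.

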