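# hgbind

Thermodynamic and structural analysis of host–guest binding for
cucurbit[7]uril (CB[7]) complexes with phenylpiperazine-type guests.

CB[7] is a barrel-shaped macrocycle whose carbonyl-lined portals and
hydrophobic cavity bind protonated piperazine fragments — a scaffold
common to many CNS drugs — with micromolar affinity. Dissecting *why* a
given halogenated guest binds better than another requires stitching
together several desk-side analyses that normally live in separate
vendor or quantum-chemistry tools. hgbind implements that pipeline as a
tested R package for supramolecular and medicinal chemists:

* **ITC** — forward-model and fit the one-site (Wiseman) isotherm. The
  cumulative binding heat follows from the 1:1 mass-balance quadratic
  with overflow-cell dilution; the heat of injection *i* is
  `q_i = Q_i − Q_{i−1} + (dV_i/V0)(Q_i + Q_{i−1})/2`. Fits report
  `n`, `K_D`, `ΔH` with curvature-based standard errors, support fixing
  `n = 1` for weak binders, blank subtraction, and Wiseman-`c` warnings.
* **Free-energy bookkeeping** — `ΔG = RT ln(K_D/c°)`,
  `−TΔS = ΔG − ΔH`, the additive six-term estimate
  `ΔG_calcd = ΔE_int + ΔE_disp + ΔG_solv − TΔS + E_def,host +
  E_def,guest`, and Boltzmann combination over binding conformers,
  `ΔG_tot = −RT ln Σ_i exp(−ΔG_i/RT)`.
* **QTAIM classification** — from tabulated bond-critical-point
  properties, derive `G = (¼∇²ρ − V)/2` (local virial theorem),
  `H = V + G` (Cremer–Kraka), the Afonin interaction energy
  `E = (−172.5 V + 0.33) kcal/mol`, and the Hayashi (pCS/rCS/SS) and
  Jeffrey (geometric/energetic) classifications plus interaction typing
  (ionic hydrogen bonds, fluorine contacts, dihydrogen, n→π*).
* **Binding-pose geometry** — occupancy-aware crystal coordinates (a
  minimal CIF subset or labelled XYZ), least-squares portal/equatorial
  planes and centroids, and the pose descriptors `d(N29⋯Plane1)`,
  `∠(Cen1-Cen2-N29)`, `∠(Phenyl⋯Plane2)` per disorder group.
* **Correlation and reporting** — join computed and experimental free
  energies, closed-form OLS with `R²`, and a plain-text report that
  surfaces every consistency flag (Gibbs-relation violations, virial
  violations, experimental-source discrepancies).
* **Synthetic data** — seeded generators for titrations, energy-term
  tables, BCP tables (virial identity exact by construction) and toy
  host–guest complexes, each with embedded ground truth, so the entire
  pipeline is testable without instruments or quantum chemistry.

The study's printed tables ship as curated reference data
(`cb7_thermo()`, `cb7_energy_terms()`, `cb7_bcp()`).

## Worked example

Simulate a titration at the study's concentration regime, fit it, then
reproduce the computed-vs-experimental correlation and the QTAIM
annotation from the reference tables:

```r
library(hgbind)

prot <- titration_protocol(cell_volume_ul = 200, cell_conc = 1e-3,
                           syringe_conc = 1e-2,
                           injection_volumes_ul = rep(2, 20))
sim <- gen_titration(list(n = 1, K_D = 2e-5, dH = -15), prot, seed = 7)
fit_one_site(sim$heats, prot)
#> One-site binding fit
#>   n    = 1.002 (se 0.00347)
#>   K_D  = 1.959e-05 M (se 8.91e-07)
#>   dH   = -14.930 kJ/mol (se 0.0713)
#>   converged: TRUE; residual norm 1.11e-05; c = 51.2
```

At the default 1% heat noise the planted parameters (`n = 1`,
`K_D = 2×10⁻⁵ M`, `ΔH = −15 kJ/mol`) come back within a fraction of a
percent. Next, assemble the six-term decomposition, Boltzmann-combine
the conformers of each complex, and regress experiment on computation:

```r
ens <- assemble_energy_table(cb7_energy_terms())
ens$combined
#>   complex_id n_conformers dg_combined
#> 1     CB7.1a            2   -65.80000
#> 2     CB7.1b            1   -27.90000
#> 3     CB7.1h            2   -73.70967
#> 4     CB7.1i            2  -104.30189
#> 5     CB7.2a            2   -21.80001

cmp <- ens$combined
cmp$dg_exp <- cb7_energy_terms()$dg_exp_reported[
  match(cmp$complex_id, cb7_energy_terms()$complex_id)]
ols_fit(cmp$dg_combined, cmp$dg_exp)
#> OLS fit (n = 5): y = 0.1490 x -18.9711, R^2 = 0.85
```

The combined value for the ortho-fluorinated guest 1h (−73.7 kJ/mol) is
0.3 kJ/mol below its best conformer — the second conformer contributes —
while for 1i the 17.9 kJ/mol conformer gap makes the correction
negligible. The regression slope (0.149) and `R²` (0.85) match the
published correlation. Finally, annotate the bond-critical-point table:

```r
ann <- annotate_bcp(cb7_bcp())
head(ann[, c("complex_id", "conformer", "bond", "H", "E", "EC", "HC")], 4)
#>   complex_id conformer       bond        H         E       EC  HC
#> 1     CB7.1a         1 [O1]1..HN4  1.85250  5.133768     Weak pCS
#> 2     CB7.1a         1 [O1]2..HN4  1.87250  5.205942     Weak pCS
#> 3     CB7.1a         2 [O1]1..HN4  0.37250 17.042478 Moderate pCS
#> 4     CB7.1b         1 [O1]1..HN4 -0.41875 18.630306 Moderate rCS
```

The portal hydrogen bond of the para-bromo guest (row 4) is the only
contact with `H < 0` — a regular closed-shell interaction with partial
covalent character, and the strongest in the inventory at 18.6 kJ/mol.

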