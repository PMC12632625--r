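---
title: "Host-guest binding thermodynamics with hgbind: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Host-guest binding thermodynamics with hgbind}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hgbind)
```

hgbind implements the complete desk-side analysis of a host-guest binding
study of cucurbit[7]uril (CB[7]) with phenylpiperazine and
piperazinylpyrimidine guests: fitting one-site ITC isotherms, assembling
additive binding free energies with Boltzmann averaging over binding
conformers, classifying QTAIM bond-critical-point (BCP) interactions, and
measuring crystallographic binding-pose descriptors. Everything upstream
of these steps — quantum chemistry, molecular dynamics, calorimeter
hardware, crystallographic refinement — enters only as tabulated numbers;
the package never computes electronic structure. This vignette explains
the models, the parameters that matter, the numerical choices, and what
the synthetic-data generators do and do not emulate.

## The one-site ITC model

An ITC experiment titrates guest (syringe concentration $X_s$) into host
(initial cell concentration $M_0$, active volume $V_0$) and integrates
the heat of each injection. For a 1:1 complex with association constant
$K_a = 1/K_D$ and molar enthalpy $\Delta H$, the heat content of the cell
after injection $i$ is

$$Q_i = n\,[M]_i\,\Theta_i\,\Delta H\,V_0,$$

where $\Theta_i$ solves the mass-balance quadratic
$\Theta^2 - \Theta\left(1 + \tfrac{X_i}{nM_i} + \tfrac{1}{nK_aM_i}\right)
 + \tfrac{X_i}{nM_i} = 0$ (smaller root). Because the cell overflows, each
injection both dilutes the host and displaces part of the cell content;
we adopt the standard mean-displacement bookkeeping

$$[M]_i = M_0\,\frac{1 - v_i/2V_0}{1 + v_i/2V_0}, \qquad
  [X]_i = X_s\,\frac{v_i/V_0}{1 + v_i/2V_0},$$

with $v_i$ the cumulative injected volume, and the observed heat

$$q_i = Q_i - Q_{i-1} + \frac{dV_i}{V_0}\,\frac{Q_i + Q_{i-1}}{2}.$$

Instrument vendors differ in the details of this convention at the
sub-percent level; hgbind uses one convention consistently in both the
simulator (`gen_titration()`) and the fitter (`fit_one_site()`), so
parameter-recovery tests are exact by construction and fitted constants
are internally consistent. A consequence worth knowing: past saturation
the displacement term can return a sliver of positive heat as bound
complex is pushed out of the active volume — this is a property of the
convention, not a bug.

`fit_one_site()` performs bounded weighted least squares
(Levenberg-Marquardt via minpack.lm) with $K_a$ parameterised on the log
scale. Initialisation uses the integral heat for $\Delta H$ and a
mid-range Wiseman $c = nK_aM_0 \approx 30$ for $K_a$, with a small
multi-start over $\log K_a$ if the first attempt stalls. For weak binders
the isotherm loses its inflection and $n$ becomes unidentifiable; the
standard remedy, fixing $n = 1$ (`fix_n = TRUE`), is supported and
flagged in the result. A $c$ value outside the informative range
$[1, 1000]$ attaches a warning string rather than failing, and an all-zero
heat vector yields an explicit "uninformative" result instead of an
exception. Standard errors come from the local curvature of the
least-squares surface; the $K_D$ error follows by the delta method.

## Free-energy bookkeeping

Experimental tables are related through two exact identities:
$\Delta G = RT\ln(K_D/c^\circ)$ at the standard state $c^\circ = 1$ M
(`dg_from_kd()`, with $R = 8.31446$ J mol$^{-1}$ K$^{-1}$ and a default
$T = 298.15$ K), and the Gibbs relation stored as
$-T\Delta S = \Delta G - \Delta H$ (`entropy_term()`). The entropy column
keeps the sign convention of the printed tables — negative is favourable —
and `check_thermo_consistency()` flags any row violating the Gibbs
relation beyond 0.15 kJ/mol, the worst case from rounding three
one-decimal columns.

The calculated binding free energy is the additive six-term estimate

$$\Delta G_{calcd} = \Delta E_{int} + \Delta E_{disp} + \Delta G_{solv}
  - T\Delta S + E_{def,host} + E_{def,guest},$$

an exact linear sum over supplied columns (`hostas_assemble()`). Terms
computed once per complex (in practice the solvation free energy) are
inherited by all conformers of that complex and flagged as inherited
(`assemble_energy_table()`); a term missing with no complex-level
fallback is an error naming the term.

When a guest binds in $N$ distinguishable conformations the effective
association constants add, giving

$$\Delta G_{tot} = -RT\ln\sum_{i=1}^{N} e^{-\Delta G_i/RT},$$

implemented with a log-sum-exp shift (`boltzmann_combine()`). The limits
pin the behaviour: a single conformer returns itself, $N$ equal values
return $g - RT\ln N$, the $T \to 0$ limit is the minimum, and adding a
conformer can only lower the combined value. On the study's decomposition
table this combination followed by ordinary least squares of experimental
against combined computed free energies reproduces the published
correlation (slope 0.149, $R^2$ 0.85 over five complexes) — a useful
end-to-end regression check, with the caveat that five points lend the
slope little statistical weight.

Two bookkeeping caveats surfaced by the data itself: the decomposition
table's experimental column disagrees with the ITC table for two
complexes (1a: -27.5 vs -26.9; 1b: -23.2 vs -28.2 kJ/mol). hgbind stores
both, lets `assemble_comparison()` select the source
(`source_policy = "paired"` or `"itc"`), and has `hg_report()` print the
discrepancy rather than resolve it. The published correlation is
reproduced only with the paired (decomposition-table) values.

## QTAIM bond-critical-point classification

At a BCP the local virial theorem links the Laplacian of the electron
density to the kinetic ($G$) and potential ($V$) energy densities; in
atomic units

$$\tfrac{1}{4}\nabla^2\rho = 2G + V
  \quad\Rightarrow\quad G = \tfrac{1}{2}\left(\tfrac{1}{4}\nabla^2\rho - V\right),$$

and the Cremer-Kraka total energy density is $H = V + G$. Published BCP
tables typically print $\rho$, $\nabla^2\rho$ and $V$ (in au $\times
10^3$) but not always $G$ and $H$, so `annotate_bcp()` re-derives them;
when a $G$ column is present it is checked against the identity
(default tolerance $5\times10^{-5}$ au) and violations are flagged.
Re-deriving $H$ from inputs printed at two decimals reproduces the
printed $H$ within $\pm 0.05\times10^{-3}$ au on every hydrogen-bond row;
for the fluorine-contact rows, printed at one decimal, the input rounding
alone justifies a slightly wider band (the tests use 0.08).

Three classifications are attached per row:

* **Hayashi** (electronic): $\nabla^2\rho > 0,\ H > 0$ → pure
  closed-shell (pCS); $\nabla^2\rho > 0,\ H \le 0$ → regular closed-shell
  (rCS, partial covalency); $\nabla^2\rho \le 0$ → shared shell (SS). The
  SS branch is retained even though no tabulated host-guest contact
  exercises it.
* **Jeffrey geometric**: H...acceptor distance bands $<1.5$ /
  $[1.5, 2.2)$ / $[2.2, 3.2]$ Å for strong/moderate/weak. Jeffrey's
  criteria are cited qualitatively in the literature; these cutoffs are
  the conventional reading and reproduce every printed geometric label.
  Contacts beyond 3.2 Å stay "Weak" but carry a flag. Boundary values
  join the class whose lower edge they sit on.
* **Jeffrey energetic**: $<16.7$ / $[16.7, 62.8)$ / $\ge 62.8$ kJ/mol
  (the classical 4 and 15 kcal/mol boundaries).

Interaction energies use the Afonin correlation
$E = -172.5\,V_{BCP} + 0.33$ with $V$ in au and $E$ in kcal/mol,
converted to kJ/mol ($\times 4.184$). The correlation was calibrated on
hydrogen bonds; the study applies it to organic-fluorine contacts as
well, and hgbind follows that usage — `afonin_energy()` documents the
extrapolation and warns on positive $V$. `type_interaction()` implements
the rule table separating ionic hydrogen bonds (protonated piperazinium
donor), ordinary hydrogen bonds, dihydrogen bonds, fluorine contacts and
n→π* interactions.

## Binding-pose descriptors

The pose of a piperazinium guest in CB[7] is summarised by three
quantities defined from host planes and centroids: the portal-oxygen
plane and centroid (Plane1/Cen1), the equatorial-carbon plane and
centroid (Plane2/Cen2), the distance of the charged nitrogen N29 from
Plane1, the angle Cen1-Cen2-N29 (vertex at Cen2, so small angles mean the
nitrogen sits on the portal axis), and the tilt of the phenyl plane
against Plane2, folded to $[0, 90]°$. Planes are total-least-squares
planes through the selection centroid (smallest principal direction of
the centered coordinates), which is the residual-minimising plane; the
tests verify this against a brute-force orientation-grid search. Host
selections are used unweighted; guest descriptors are computed separately
per crystallographic disorder group with the refined occupancy carried
through — alternative conformers are reported side by side, never
occupancy-mixed, and any collapsing across groups is left to the user.

Structures enter either as a minimal CIF subset (cell parameters plus the
`atom_site` loop with fractional coordinates, occupancies and disorder
groups, converted to Cartesian once on read via the standard
crystallographic matrix) or as a labelled XYZ dialect with Cartesian
coordinates, occupancy and disorder-group columns. Only those fields are
honoured; symmetry expansion, anisotropic displacement and hydrogen
placement are out of scope. The published pose and hydrogen-bond tables
themselves require the deposited crystal structures, which are external
data; the geometry module is therefore validated against generated toy
complexes with known descriptors rather than against those tables.

## Synthetic data: what it emulates, what it does not

Each generator produces the table one pipeline stage consumes plus the
ground truth that generated it:

* `gen_titration()` draws i.i.d. Gaussian noise around the package's own
  forward model. The default noise scale, 1% of the first-injection
  heat, is a repository convention chosen as typical integrated-heat
  reproducibility for a modern calorimeter — the study reports no noise
  figure. The default protocol in the tests (200 µL cell, 1 mM host,
  10 mM guest, 20 × 2 µL injections, 298.15 K) sits inside the study's
  stated concentration ranges and gives Wiseman $c = 50$ for the
  reference guest ($K_D = 2\times10^{-5}$ M, $\Delta H = -15$ kJ/mol).
  What it does not emulate: baseline drift, injection-volume error,
  heat-of-dilution structure, or raw power-compensation thermograms —
  so parameter-recovery results here bound only statistical error, not
  systematic calorimetric effects.
* `gen_energy_table()` draws the six terms uniformly inside ranges
  matching the magnitudes seen for CB[7] complexes, with solvation drawn
  once per complex to exercise term inheritance. The embedded truth is
  the exact sum and exact Boltzmann combination.
* `gen_bcp_table()` constructs rows that satisfy the virial identity to
  machine precision by drawing $(\nabla^2\rho, H)$ inside the target
  Hayashi region and solving $V = 2H - \tfrac14\nabla^2\rho$,
  $G = \tfrac14\nabla^2\rho - H$; Jeffrey distances are drawn inside
  their bands with a margin, so planted labels are recoverable at 100%
  by construction. Real BCP tables carry rounding and near-boundary
  cases the generator deliberately avoids.
* `gen_toy_complex()` builds a 7-fold-symmetric pseudo-host (two portal
  oxygen rings flanking an equatorial carbon ring, default portal radius
  3.0 Å, equatorial radius 4.0 Å, portal planes at ±3.05 Å) and places
  guests so each descriptor takes its requested value exactly, then
  applies a seeded random rigid-body transform. It is a geometric
  scaffold, not a chemical model: no glycoluril atoms, no hydrogens, no
  realistic bond lengths beyond the 1.39 Å phenyl ring.

Seeding: every generator takes one integer seed, draws from its own
substream (a fixed per-generator offset), and restores the caller's RNG
state, so adding a generator never perturbs another's output and
generated artifacts are byte-identical across calls.

## Numerical choices and degenerate inputs

* Gas constant 8.31446 J mol$^{-1}$ K$^{-1}$; 1 kcal = 4.184 kJ;
  1 hartree = 2625.4996 kJ/mol; all conversions exact, round trips to
  machine precision.
* `boltzmann_combine()` uses a min-shifted log-sum-exp, safe for
  conformers separated by hundreds of kJ/mol.
* `fit_plane()` rejects selections with fewer than 3 atoms or with a
  vanishing second singular value (collinear input); `vertex_angle()`
  rejects zero-length arms; plane-plane angles clamp the cosine before
  `acos` to avoid NaN at exactly parallel normals.
* `fit_one_site()` never throws on bad data: non-convergence,
  uninformative (all-zero) heats and out-of-range $c$ values are all
  reported in the returned object.
* Negative deformation energies and negative virial-derived kinetic
  energy densities warn but proceed, since both can arise from rounded
  published inputs.

## Problem sizes

The test suite and the acceptance script run on the study's own printed
tables (9 decomposition rows, 22 BCP rows, 14 ITC rows), 100-seed
noisy-titration replicates at 20 injections each, 500-row synthetic BCP
tables, and toy complexes of ~40 atoms; the whole suite completes in a
few seconds on one core.

## Known limitations

Only 1:1 binding is modelled — no competitive, multi-site or displacement
isotherms, and no integration of raw thermograms. The exact
dilution/displacement convention of instrument software is not public;
fitted constants can differ from vendor software at the sub-percent
level. The five-complex regression is reproduced as published but is
statistically fragile. Pose descriptors for the real crystal structures
require the external coordinate deposits. The Afonin energies for
fluorine contacts inherit the correlation's hydrogen-bond calibration.
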