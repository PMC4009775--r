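---
title: "Conformational free energies from GBSA enthalpies and dihedral-histogram entropies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conformational free energies from GBSA enthalpies and dihedral-histogram entropies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(confree)
```

## The problem

Given an ensemble of conformations of one molecule -- snapshots of a
trajectory, models of an NMR bundle, or synthetic samples -- which of two
forms is more stable in solution, and what does the free-energy landscape
between them look like? `confree` answers this with an implicit-solvent
free energy split into an enthalpy-like term evaluated per snapshot and a
conformational-entropy term estimated from the distribution of the
molecule's torsion angles over the ensemble:

$$G_1 = \langle E^{MM}\rangle + \langle E^{ASA}\rangle - T S, \qquad
  G_2 = \langle E^{MM}\rangle + \langle E^{ASA}\rangle .$$

$G_1$ includes the conformational entropy, $G_2$ omits it; the difference
$G_2 - G_1 = TS$ holds identically for every record the package produces.
Comparing the two differences between forms separates entropy-driven from
enthalpy-driven stability: a form may be enthalpically favored (lower
$G_2$) yet entropically penalized enough that the other form wins in
$G_1$. The motivating application is the catalytic domain of the DNA
deaminase APOBEC3G (A3Gctd), whose solution (NMR) and crystal structures
differ in loops near the catalytic zinc; the package itself is
system-agnostic.

## The enthalpy term: GBSA on stripped snapshots

Each snapshot is evaluated in vacuum with solvent represented implicitly
(waters and counter-ions are removed first by `strip_solvent()`, which
reports what it removed -- stripping is never silent).

$E^{MM}$ is the sum of classical force-field terms and the polar
solvation energy:

* harmonic bonds $\sum k_b (b - b_0)^2$ and angles
  $\sum k_\theta(\theta-\theta_0)^2$, cosine torsions
  $\sum (V_n/2)(1+\cos(n\phi - \gamma_n))$;
* 12-6 Lennard-Jones with $R_{min}/2$ + $\sqrt{\epsilon}$ combination and
  Coulomb $k_e q_i q_j / r$, with 1-2/1-3 pairs excluded and 1-4 pairs
  scaled (defaults $1/1.2$ electrostatic, $1/2$ Lennard-Jones, the common
  convention for this functional form; configurable). No distance cutoffs
  are applied -- snapshot evaluation at this scale does not need them;
* the generalized-Born energy in the Still pairwise form
  $-\tfrac{k_e}{2}\left(\tfrac{1}{\epsilon_{in}}-\tfrac{1}{\epsilon_{out}}\right)
  \sum_{ij} q_i q_j / f_{GB}$ with
  $f_{GB}=\sqrt{r^2 + R_iR_j e^{-r^2/4R_iR_j}}$, self terms included.

Effective Born radii use the Hawkins--Cramer--Truhlar pairwise
descreening form: the inverse effective radius is the inverse reduced
intrinsic radius (intrinsic minus a 0.09 Å dielectric offset) minus the
closed-form descreening integral over all neighbors with screened reduced
radii. HCT radii can fall below the intrinsic radius; what the package
guarantees is positivity -- a non-positive inverse radius (pathological
overlap) is clamped to the reduced intrinsic radius with a warning and a
flag. The test suite checks the radii against a direct numerical
integration of the descreened Coulomb-field volume, and the energy
against the analytic Born limit (single ion) and the
Born-plus-screened-Coulomb limit (two distant ions).

Parameters unavoidably left open by the method's description -- solvent
dielectric 78.5, $k_e = 332.06$ kcal Å/mol/e², offset 0.09 Å -- default
to the standard values for this GB flavor and are all configurable
(`gb_params()`); per-atom intrinsic radii and screening factors come from
the topology file, so a different radii set is a data change, not a code
change.

$E^{ASA} = \gamma \cdot SASA + b$ with $\gamma = 0.005$ kcal/mol/Å² and
$b = 0$ by default. SASA is Shrake--Rupley with a probe of 1.4 Å and a
deterministic golden-angle spiral of 960 points per atom (no RNG). Two
design details matter here. First, the points are oriented per bonded
molecule by a covariant principal-axes frame of that molecule's atoms:
the frame rotates with the molecule, so the sampled area is *exactly*
invariant under rigid motions and *exactly* additive over identical
non-interacting copies, rather than only to point-sampling resolution.
Second, with 960 points the sampled area of one or two overlapping
spheres is within a fraction of a percent of the analytic value, which
the tests assert across a grid of separations.

## The entropy term: per-torsion dihedral histograms

The conformational entropy treats torsion angles as the relevant degrees
of freedom -- bond lengths and angles are effectively fixed in typical
constrained dynamics, while torsions rotate freely -- and treats torsions
as independent:

$$S = \sum_{i=1}^{N_d} S_i, \qquad
  S_i = -\sum_{b} P_i(b)\, \ln \frac{P_i(b)}{(w)},$$

where $P_i(b)$ is the normalized occupancy of bin $b$ of torsion $i$'s
histogram over the ensemble. Bins are half-open, anchored at $-180°$,
with $+180°$ identified with $-180°$; $0 \ln 0 = 0$. Two readings of the
histogram entropy are first-class:

* **discrete** ($w$ absent): $S_i \in [0, \ln(360/w)]$, zero for a
  delta distribution -- the natural reading for "how many rotamer wells";
* **differential** ($w$ = bin width in radians): the Riemann
  approximation of the continuous circular entropy, maximal at
  $\ln 2\pi$ for a uniform torsion and *bin-width independent* in that
  case. This is the default, because the observed near-invariance of
  $TS$ across moderate bin widths (12°--60°) with deviation only at very
  coarse ones (120°) is exactly the behavior of the differential reading;
  the discrete reading shifts by the log-ratio of bin counts under
  near-uniform occupancy.

`bin_sensitivity()` reports $TS$ across widths. The leading-order bias of
the differential estimator for a smooth density $p$ is
$\tfrac{w^2}{24}\int p'^2/p \,d\theta$ (binning smooths, so the histogram
entropy overshoots). For a von Mises torsion this integral is
$\kappa^2\,\mathbb{E}[\sin^2\theta]$, which motivates the default width
of 30° for typical, moderately concentrated torsions and a finer 12°
width when validating against highly concentrated distributions
($\kappa = 8$: bias $\approx 0.085$ nats/torsion at 30° but $0.014$ at
12°). No smoothing or bias correction is applied by default; a
Miller--Madow correction flag exists but is off, since at the ensemble
sizes used here ($n \ge 10^4$ per torsion) the multinomial bias
$(k-1)/2n$ is negligible.

$TS$ uses $k_B = 0.0019872041$ kcal/mol/K, default $T = 300$ K, entropy
in nats throughout.

Which torsions enter $N_d$? The default policy (`enumerate_torsions()`)
emits one torsion per non-terminal heavy-atom bond, flanking atoms chosen
by lowest index (a deterministic tie-break); backbone-only and
force-field-term policies are available. Since the torsion count directly
scales $S$, $N_d$ is reported on every entropy result.

## Replicates, comparisons, tables

Independent replicate runs (different seeds) are aggregated by
`summarize_replicates()` into mean and deviation of $G_1$, $G_2$, $TS$.
The deviation defaults to the **population** (n-denominator) standard
deviation: that is the convention under which the package reproduces the
sigma row of the published A3Gctd replicate table exactly (the sample
estimator is available via `sd_method = "sample"`). `compare_states()`
reports B-minus-A differences with quadrature-propagated deviations and a
deliberately loose significance flag -- `|Δ|` exceeding the larger single
-state sigma -- mirroring the one-standard-deviation criterion such
replicate tables use; it is not a formal test. The replicate CSV layout
prints a `minus_ts` column (so $G_1 = G_2 + (-TS)$ row-wise), matching
the sign convention of the published table while the in-memory records
keep $TS \ge 0$ and $G_1 = G_2 - TS$ literal.

The shipped reference tables (`reference_tables()`) are the published
per-run values for A3Gctd: ten-run main-chain RMSD and zinc-coordinated
water counts after 10 and 20 ns, arginine RMSDs, and the per-run
$G_2 / -TS / G_1$ free-energy table for the NMR and crystal forms. They
are *inputs* for arithmetic validation (recombination, column means,
deviations), since regenerating the underlying 20-ns explicit-solvent
trajectories of the real protein is out of scope at desk scale.

## Geometry conventions

* Superposition is least-squares (Kabsch), reflections excluded; the
  quaternion method serves as an independent oracle in tests.
* `rmsd(fit, measure)` separates the superposition set from the measured
  set. Region tables (loops, individual arginines) superpose globally on
  all main-chain atoms (N, CA, C, O) and then measure the region without
  a local re-fit -- the convention under which a mobile loop's RMSD can
  exceed the global value, as the published arginine table requires.
* Dihedrals follow the IUPAC sign convention (cis 0°, trans 180°), range
  $(-180°, 180°]$, verified against an independent projection oracle and
  against `bio3d::torsion.xyz`.
* Metal--water contacts count partner atoms within a cutoff of any
  center atom, averaged over frames. The cutoff default is 3.0 Å
  (typical Zn²⁺--O first-shell distance); the underlying study states no
  cutoff, so it is exposed as a parameter.

## Pathways: PCA, waypoints, morphing

Ensembles are aligned (`align_ensemble()`: to-first or iterative-mean
with a 1e-6 Å tolerance), then analyzed by PCA of the 3N coordinates of a
selection (default main-chain). The mean structure is the origin of the
component axes; eigenvector signs follow a deterministic
largest-component-positive convention, which also breaks eigenvalue ties
reproducibly. Waypoints along a projected path are selected at equal
cumulative arc length in (PC1, PC2) -- chosen over equal frame-index
spacing because path point density varies -- always including both
endpoints, with a nearest-unchosen, smaller-index tie-break.

The transition path itself is produced by `morph()`: linear Cartesian
interpolation after superposition. This is an explicit geometric stand-in
for a biased transition simulation; it makes no physical claim (frames
are tagged "interpolated") and is used to exercise the profile machinery
on a continuous path. Per-waypoint ensembles are regenerated by
small-amplitude torsion resampling (von Mises jitter about the waypoint's
torsions) standing in for a restrained simulation at each waypoint.
Because a Cartesian interpolation can momentarily pass through a
geometrically degenerate frame (collinear bond), waypoint torsions fall
back to the nearest non-degenerate neighbor frame when needed, and the
event is logged.

## The synthetic-data generator and what passing tests mean

Every pipeline input can be generated with known ground truth:

* `make_toy_topology()` -- a peptide-like chain (N, CA, C, O per
  residue; 3 residues = 12 atoms, 11 bonds) with harmonic terms
  parameterized at the construction geometry, alternating charges
  summing to zero, and standard heavy-atom radii;
* `make_chain_topology()` -- a linear chain with an exact torsion count
  ($N_d = N_{atoms} - 3$), non-interacting by default (zero charges and
  LJ epsilon) so two ensembles differing only in torsion distributions
  have identical enthalpy *by construction*;
* `build_coordinates_from_torsions()` -- internal-to-Cartesian chain
  building with fixed bond lengths/angles; re-measuring returns the
  input torsions to numerical precision;
* `sample_ensemble()` -- i.i.d. frames with per-torsion fixed, uniform,
  or von Mises distributions, whose differential entropies have closed
  forms ($\ln 2\pi$; $\ln(2\pi I_0(\kappa)) - \kappa I_1(\kappa)/I_0(\kappa)$),
  verified at construction against direct quadrature of $-\int p\ln p$;
* `make_metal_site()` -- a Zn particle with waters placed so the
  expected within-cutoff count equals a requested mean exactly;
* `make_two_state_system()` -- two ensembles differing only in torsion
  concentration, with analytic $\Delta S$ and an optional constant
  enthalpy offset carried by the topology. A constant (rather than a
  harmonic) offset was chosen so $\Delta G_2$ is set exactly, free of
  sampling noise; it appears as its own component of the energy
  decomposition. The two-state validation also sets $\gamma = 0$: on an
  interacting chain the surface-area term would add a small
  conformation-dependent enthalpy difference between a compact and an
  extended state (a few kcal/mol at these sizes) -- real model behavior,
  but noise for the question "is the constructed $\Delta H$/$\Delta TS$
  contrast recovered?".

What these ensembles deliberately do *not* emulate: real protein
energetics, water structure, correlated torsions, or kinetics. A passing
validation therefore shows that the estimators recover known ground
truth under the model's own assumptions (independent torsions, i.i.d.
frames), not that the GBSA + histogram-entropy model is accurate for any
particular real protein.

Problem sizes used by the validation suite and the acceptance script --
chosen as the package's standard validation conditions: $10^5$ frames
for entropy recovery and the two-state system (50 torsions,
$\kappa_B = 8$, enthalpy offset $-20$ kcal/mol opposing the entropy
penalty), $2 \times 10^4$ frames for bin-width studies, 100 random
instances per oracle-equivalence check, and strided subsets of ~100
frames for energy averages (snapshot energies are i.i.d. means and
converge far faster than the histograms; the frames used are recorded on
every result).

## Numerical choices and degenerate inputs

* Binning: half-open bins anchored at $-180°$; exact $+180°$ wraps to
  the first bin; widths must divide 360.
* Superposition requires three non-collinear fit atoms; collinear sets
  are rejected, as are dihedrals with a collinear central bond.
* Ensembles with NaN coordinates, empty selections, mixed bin widths,
  mismatched MODEL atom counts, and missing topology sections are all
  rejected with specific errors (line numbers for PDB parse errors,
  section names for topology files, character positions for selection
  syntax errors).
* Alternate locations keep the highest-occupancy conformer; insertion
  codes are preserved as part of the residue key; residue numbers are
  taken verbatim from the input (author numbering), and all indices are
  1-based, the R convention.
* All generators are deterministic per seed; pipeline reruns with an
  identical configuration are byte-identical, and run logs record every
  seed and every default actually used.

## Known limitations

No forces, minimization, or dynamics; no salt dependence in GB; no
mutual-information correction between torsions (the entropy is a sum of
marginals, an upper bound for correlated torsions); no mmCIF or binary
trajectory input; the linear morph is not a physical transition path.
The free energies are for *relative* comparisons between forms of the
same system -- the model is not calibrated for absolute stabilities or
quantitative population ratios.

## A worked example

```{r example, eval = FALSE}
library(confree)

# two-state comparison on synthetic ensembles with a known answer
sys <- make_two_state_system(kappaA = 0, kappaB = 8, n_torsions = 50,
                             n_frames = 2e4, seed = 1, delta_h = -20)
recA <- free_energy_of_ensemble(sys$ensembleA, sa = sasa_params(gamma = 0),
                                bin_width = 12, energy_frames = 100,
                                label = "loose")
recB <- free_energy_of_ensemble(sys$ensembleB, sa = sasa_params(gamma = 0),
                                bin_width = 12, energy_frames = 100,
                                label = "tight")
c(dTS = recB$ts - recA$ts, analytic = sys$truth$dts,
  dG1 = recB$g1 - recA$g1, dG2 = recB$g2 - recA$g2)

# published replicate-table arithmetic
tb <- reference_tables()$free_energy_runs
summarize_replicates(records_from_table(tb, "nmr"))
```
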