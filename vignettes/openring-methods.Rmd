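---
title: "Determining open-ring solution structures by rigid-body SAXS refinement"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Determining open-ring solution structures by rigid-body SAXS refinement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6, fig.height = 4)
library(openring)
```

## The problem

Some homo-oligomeric proteins assemble not into closed rings but into a
single *open* helical turn: the lateral interfaces between subunits define a
rotation and a small rise, the rise per turn is too low for the assembly to
climb into a second turn, and the residual gap after the last subunit is too
tight to admit another one. The assembly therefore terminates at a defined
stoichiometry — an open ring — even though no subunit "counts" its
neighbours. Crystal lattices of such proteins typically show continuous
helices (the crystal environment extends the helix indefinitely), so the
*solution* oligomer must be established independently, and small-angle X-ray
scattering (SAXS) is the natural probe: it measures the orientationally
averaged intensity $I(q)$ of the particle in solution.

`openring` implements the complete computational chain for this problem:

1. build candidate assemblies (closed rings of $n$ units at scanned radii,
   and helical segments generated by repeated application of a single
   inter-unit rigid transform);
2. compute each candidate's theoretical profile with the Debye formula;
3. score it against the measured profile by reduced $\chi^2$ with an
   analytic scale factor;
4. refine the six parameters of the inter-unit transform (three Euler
   angles, three translation components) on a 1°/1 Å grid around a starting
   geometry, with steric-clash filtering;
5. analyse the winning model's rigid-body geometry: screw parameters
   (rotation per unit, rise, units per turn), superposition RMSDs,
   twist–swing decomposition of inter-dimer orientation differences,
   clash-based termination (`can_extend`), and buried interface areas.

A companion module reproduces the consensus-design workflow used to
engineer stabilized variants of such proteins: redundancy filtering of a
sequence alignment to a maximum pairwise identity, followed by a
majority-rule consensus with a per-column conservation profile.

Because experimental scattering data for this problem class are often not
deposited, the package treats synthetic data generation as a first-class
module: bead protomers, ground-truth assemblies with known generators,
noisy profiles with a known error model, and alignments with a known
consensus. Every stage of the pipeline is tested against these ground
truths.

## The scattering model

The Debye formula gives the exact orientational average for a rigid
particle of point scatterers:

$$ I(q) \;=\; \sum_i \sum_j f_i f_j \,\frac{\sin(q r_{ij})}{q r_{ij}}. $$

`debye_profile()` evaluates it either exactly (`bin_width = 0`) or through
a weighted pair-distance histogram. The histogram stores, per distance bin,
the weight sum $\sum w$, $\sum w d$ and $\sum w d^2$, and the kernel is
expanded to second order about each bin's weighted mean distance, so the
binned sum tracks the exact double sum to better than $10^{-7}$ relative at
the default 0.1 Å bin — the binning error is irrelevant against any
realistic noise level. For an assembly with a recorded generator the
cross-distance set between copies $i$ and $j$ depends only on $j - i$, so
one cross-histogram per offset (weighted by its multiplicity) replaces the
all-pairs computation; this is verified against the flat computation in the
tests.

**Form factors.** The default scattering model assigns each element a
*constant* reduced scattering length (vacuum electrons minus displaced
solvent electrons at 0.334 e/Å$^3$), and coarse-grained beads a single
effective per-residue value. Because every fit optimizes a free
multiplicative scale $c$, only relative amplitudes matter for model
ranking. The $q$-dependence of atomic form factors and the adjustable
excluded-volume/hydration terms of full-featured profile calculators are
deliberately out of scope: the package's claims are about *relative* model
selection and parameter recovery on calibrated synthetic data, not about
absolute-intensity matching of experimental profiles. This is the one
declared simplification relative to standard profile-fitting programs.

**Fitting.** `chi_square_fit()` interpolates the model onto the
experiment's grid (linear in $(q, \log I)$; extrapolation refused),
computes the analytic minimizer
$c = \sum I_e I_m/\sigma^2 \big/ \sum I_m^2/\sigma^2$ and reports
$\chi^2 = \frac{1}{N-1}\sum \big[(I_e - c I_m)/\sigma\big]^2$. With noise
simulated as $\varepsilon \sim \mathcal N(0, \sigma(q))$ and the same
$\sigma$ written into the data file, the reduced $\chi^2$ of the generating
model is calibrated to expectation 1, which the acceptance suite checks
over 200 replicates.

## The refinement procedure

The inter-unit transform is parameterized by intrinsic Z–Y–Z Euler angles
(degrees) and a translation (Å); the convention is a single package
constant and is embedded in every serialized transform. The canonical scan
varies these six parameters in 1° / 1 Å steps around a starting geometry
(for crystal-derived starts, `extract_step_transform()` between consecutive
units provides the center).

The $\chi^2$ landscape over this parameterization has a characteristic
pathology: nearly congruent assemblies have multiple representations along
curved valleys (small rotations of the screw axis compensated by correlated
changes in the other parameters), so axis-aligned 1-D sweeps strand on the
valley walls at lattice points several steps from the optimum.
`refine_against_saxs(mode = "sweep")` therefore combines three
deterministic stages:

1. axis-aligned 1-D sweeps through the grid (the classical scan; all
   evaluations enter the ranked results);
2. a *steepest lattice descent* from the center: at each move the entire
   ±1 cube of 728 neighbours is scored in compiled code and the best one is
   taken. Guidance uses the same $\chi^2$ on a coarser 0.5 Å histogram
   (relative error $\sim 10^{-5}$); full-cube moves are what track the
   valley floor, including its 3+-parameter diagonal directions;
3. final axis sweeps at full fidelity from the descent endpoint.

Models with inter-unit steric clashes are excluded from ranking but
recorded with their clash counts, so the exclusion is auditable. Default
clash cutoffs sit at the short end of nonbonded contact distances (2.5 Å
between heavy atoms, 3.5 Å between residue beads) so that only genuine
overlap disqualifies a model. `local_refine()` polishes the six parameters
continuously with a restarted Nelder–Mead simplex plus a 0.01-step
coordinate polish; pure coordinate descent with shrinking steps was
evaluated first and stalls in the curved valley (on noiseless data it stops
about 0.7° from the optimum where the simplex reaches it to better than
0.01°), which is why the simplex design was adopted.

`model_selection()` compares model classes the way the scientific question
demands: closed 6-rings over a radius scan in 1 Å intervals (per-unit
rotation 60°), closed 7-rings over the same scan (360/7 = 51.43°), and
open helical segments refined as above. Classes are ranked by their best
reduced $\chi^2$.

## The synthetic ground truth

The generator module emulates the study system at a realistic scale:

* **Protomer** (`make_bead_protomer`): 230 beads sampled uniformly inside a
  hard-edged triaxial ellipsoid (axis ratios 1 : 0.71 : 0.79 of a 28 Å
  extent) — the proportions of a proteasome-like subunit at one bead per
  residue. The hard boundary matters: units whose surfaces are separated
  carry exactly zero clash pairs. Random bead clouds are generically
  chiral, so mirror images scatter identically but are distinguishable by
  superposition, which the tests assert.
* **Dimer** (`make_bead_dimer`): two copies of the protomer stacked
  antiparallel along z, touching at the interface — a rigid two-chain unit
  mimicking a tight dimer of opposing protomers.
* **Assembly** (`make_ground_truth_assembly`): the dimer placed at a 36 Å
  radius and propagated by a screw transform, by default 55° per unit with
  a 3 Å rise for 6 units. These defaults realize the open-ring regime: the
  construction is clash-free, while the would-be seventh unit collides
  with the first (the 30° end gap is too tight), so `can_extend()` is
  `FALSE` — assembly terminates at a defined oligomer. The whole
  construction is expressed in a fixed generic lab orientation
  (Euler 25°, 40°, 15°), as for an arbitrarily oriented crystal frame;
  this keeps the generator's Euler parameterization away from its gimbal
  degeneracy (a rotation purely about the lab z axis would sit exactly at
  the $\beta = 0$ singularity, where per-parameter recovery is
  ill-defined). Scattering is unaffected — the Debye average is
  orientation-invariant.
* **Profiles** (`simulate_profile`): Gaussian noise with
  $\sigma(q) = a\,I(q) + b$ (default $a = 0.02$, $b = 0$), the true
  $\sigma$ written into the third column. Gaussian-with-known-$\sigma$
  rather than Poisson keeps the $\chi^2$ calibration analytic and matches
  how uncertainty columns behave in standard 3-column SAXS files. The
  default grid (`default_q_grid()`: 691 points, 0.005–0.35 Å$^{-1}$ in
  0.0005 steps) emulates the radial binning of a modern SEC-SAXS
  measurement on a photon-counting detector; with a sparse grid
  (~100 points) nearly congruent lattice models become statistically
  unresolvable at 2% noise, which misrepresents what such an experiment
  can distinguish.
* **Alignments** (`make_synthetic_msa`): i.i.d. per-column substitutions
  (uniform over the 19 alternatives) and optional gaps, from a known
  consensus. For substitution rate $p$ and $n$ sequences the per-column
  recovery failure probability is bounded by
  $\exp\!\big(-2n(1/2 - p)^2\big)$; at the test conditions
  ($n = 50$, $p = 0.1$) exact recovery of a 240-column consensus is
  essentially certain, and the tests assert it across seeds.

What the generator does *not* emulate: interparticle interference and
concentration effects, hydration-shell contrast, instrument smearing,
Poisson counting statistics, correlated residuals from buffer subtraction,
and any internal flexibility of the units. Passing tests therefore
demonstrate the correctness and statistical calibration of the pipeline on
rigid particles with well-specified noise — not that every experimental
profile of this kind is automatically fittable to $\chi^2 \approx 1$.

## Numerical choices and degenerate inputs

* Euler convention: intrinsic Z–Y–Z, degrees. At gimbal lock
  ($\beta$ within $10^{-6}$° of 0 or 180) the degeneracy is resolved by
  reporting $\gamma = 0$ and folding the free angle into $\alpha$.
* Screw axes: from the antisymmetric part of the rotation away from 180°,
  from the $+1$ eigenvector (sign fixed by the first non-zero component)
  at 180°; rotations below 0.1° are rejected as axis-degenerate. Rises are
  signed projections of the translation on the axis.
* Superpositions: proper rotations only (SVD determinant correction);
  collinear sets are rejected; default atom selection for published-RMSD
  style comparisons is CA, configurable. Residue correspondence between
  unit copies uses (chain order, residue number, insertion code, atom
  name); identity mismatches beyond 2% abort.
* Alternate conformers: highest occupancy kept. Waters/heteroatoms dropped
  by default; selenomethionine is renamed MET with its Se retained for
  scattering.
* Consensus ties are broken by a fixed residue order
  (`ARNDCQEGHILKMFPSTWYV`) and flagged, so designed sequences are
  auditable; columns with an absolute majority of gaps are dropped under
  the default rule.
* Dimer pairing uses greedy descending-weight matching on inter-chain
  contact counts. For assemblies of tightly coupled dimers the intra-dimer
  weight dominates every lateral contact, so the greedy matching attains
  the maximum-weight matching; this is verified on synthetic ground truth.
* `interface_area()` reports the full buried area
  $\mathrm{SASA}(a) + \mathrm{SASA}(b) - \mathrm{SASA}(ab)$, not halved;
  area *ratios* between corresponding interfaces are independent of that
  convention.

## Worked example

```{r example, eval = FALSE}
# ground truth: open ring of 6 dimers, 55 deg / 3 A rise, 2% noise
truth <- make_ground_truth_assembly(seed = 1)
profile <- simulate_profile(truth$assembly, rel_noise = 0.02, seed = 42)

# refine the inter-unit transform on a 1 deg / 1 A grid around a start
# two steps off the truth
start <- params_to_transform(transform_to_params(truth$generator) +
                               c(2, -1, 1, -2, 1, -1))
fit <- refine_against_saxs(truth$assembly$seed, start,
                           grid_spec(angle_half = 5, trans_half = 3),
                           profile)
glance(fit)
screw_parameters(fit$best_transform)
can_extend(fit$best_assembly)     # FALSE: the ring terminates
autoplot(fit)

# compare model classes
sel <- model_selection(truth$assembly$seed, profile,
                       ring_radii = seq(20, 60, 1),
                       helix_center = truth$generator)
tidy(sel)
```

The problem sizes used throughout the tests and the acceptance script are
the package defaults above (460-bead dimers, 6-unit assemblies, 691-point
profiles, 200 calibration replicates, 20 recovery seeds in the test suite
and 8 in the acceptance script); they were chosen as the smallest scale
that is faithful to the study system.

## Known limitations

* Constant form factors mean absolute intensities are not comparable to
  experimental data without the free scale; descriptors that depend on the
  high-$q$ contrast decay (e.g. Porod constants, volumes) are not
  computed.
* The refinement explores a single-generator (fully symmetric) model
  space; asymmetric multi-body refinement with contact restraints is out
  of scope.
* The lattice descent is deterministic but heuristic: it is guaranteed to
  return a model no worse than the scan center and in measured practice
  recovers the generating lattice point (or a one-step neighbour) at 2%
  noise, but no global-optimality certificate is implied.
* `pair_dimers()`'s greedy matching can be suboptimal for chains whose
  largest contact is not with their true partner — not the regime of
  tightly coupled dimers it is designed for.
* The accession-tier regression (`accession_checks()`) requires deposited
  coordinate files that cannot be shipped with the package; it runs only
  where a local cache or network access provides them.
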