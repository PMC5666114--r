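# openring

Rigid-body SAXS refinement of helical segments and closed rings, for
establishing the solution geometry of symmetric protein oligomers — in
particular *open rings*: single helical turns whose rise is too low to
continue into a second turn and whose end gap is too tight for another
subunit, so that assembly terminates at a defined stoichiometry.

Crystal lattices of such proteins typically contain continuous helices, so
the solution oligomer has to be determined against small-angle X-ray
scattering (SAXS) data. `openring` implements the full chain:

* **Assembly construction** — `build_helix()` places `n` copies of a rigid
  seed unit by repeated application of one rigid transform (the
  *generator*); `build_closed_ring()` builds n-fold symmetric rings over a
  radius scan (a 7-ring uses the 360/7 = 51.43° rotation).
* **Scattering** — `debye_profile()` evaluates
  `I(q) = ΣᵢΣⱼ fᵢfⱼ sin(q rᵢⱼ)/(q rᵢⱼ)` exactly or through a
  second-order-corrected pair-distance histogram;
  `chi_square_fit()` scores a model against data by reduced χ² with the
  analytic scale factor `c = Σ IₑIₘ/σ² / Σ Iₘ²/σ²`;
  `guinier_fit()` and `kratky_porod()` give Rg, the Kratky curve and the
  Porod exponent.
* **Refinement** — `refine_against_saxs()` scans the six parameters of the
  generator (Z–Y–Z Euler angles, translation) in 1°/1 Å steps around a
  start, excludes sterically clashing models, and ranks the rest;
  `local_refine()` polishes continuously; `model_selection()` compares
  closed 6-rings, closed 7-rings and open helical segments by best χ².
* **Rigid-body geometry** — Kabsch superposition, step-transform
  extraction between unit copies, screw parameters (angle per unit, rise,
  units per turn), twist–swing (shear/hinge) decomposition of orientation
  differences, clash counting, `can_extend()` termination analysis, and
  Shrake–Rupley buried interface areas.
* **Consensus design** — `filter_max_identity()` (greedy redundancy
  filtering of an alignment to a maximum pairwise identity) and
  `consensus_sequence()` (majority-rule consensus with per-column support
  and auditable tie-breaks).
* **Synthetic ground truth** — bead protomers/dimers, assemblies with a
  known generator, noisy profiles with σ(q) = a·I(q) + b, and alignments
  from a known consensus, so every stage is testable end to end without
  downloads.

Structures are plain tibbles (one row per atom), profiles are tibbles
(`q`, `I`, `sigma`), fitted objects have `tidy()`/`glance()`/`autoplot()`
methods, and everything composes with the pipe.

## Worked example

```r
library(openring)

truth   <- make_ground_truth_assembly(seed = 1)   # open ring: 6 dimers, 55 deg, 3 A rise
profile <- simulate_profile(truth$assembly, rel_noise = 0.02, seed = 42)

start <- params_to_transform(transform_to_params(truth$generator) +
                               c(2, -1, 1, -2, 1, -1))   # two steps off truth
fit <- refine_against_saxs(truth$assembly$seed, start,
                           grid_spec(angle_half = 5, trans_half = 3), profile)
fit
#> <saxs_refinement> sweep scan: 194 models scored, 0 clash-excluded
#> best chi2 = 0.9686 at (alpha=-43.26, beta=34.53, gamma=86.74, tx=1.75, ty=0.81, tz=2.30)

screw_parameters(fit$best_transform)
#> <helical_params> 55.000 deg/unit (6.545 units/turn), rise 3.000 A, pitch 19.636 A

can_extend(fit$best_assembly)
#> $can_extend  FALSE        (a seventh unit would clash with the first)
#> $clashes     25
```

The refinement recovered the generating transform exactly: 55° per unit
and a 3 Å rise (6.5 units per turn — an open single-turn ring), with χ²
close to 1, and the recovered model terminates: one more unit collides
with the first. Model-class comparison on the same data ranks the open
helix far ahead of any closed ring:

```r
tidy(model_selection(truth$assembly$seed, profile,
                     ring_radii = seq(20, 60, 1),
                     helix_center = truth$generator))
#> # A tibble: 3 x 5
#>   class best_chi2 best_parameter                        n_models n_clash_excluded
#> 1 helix     0.969 alpha=-43.26, beta=34.53, gamma=86.7…       49                0
#> 2 ring7    49.4   radius=38 A, rotation=51.43 deg             41               14
#> 3 ring6    85.2   radius=35 A, rotation=60.00 deg             41               10
```

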