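---
title: "Committee potentials from CSP landscapes: models, design choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Committee potentials from CSP landscapes: models, design choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(cspal)
```

## The problem

Crystal structure prediction (CSP) produces landscapes of thousands of
locally minimized candidate crystal structures ranked by lattice energy. The
energies that generate these landscapes come from cheap baseline methods
(empirical force fields, tight-binding), because first-principles energies
for a whole landscape are prohibitively expensive; yet polymorph energy
differences are only a few kJ/mol, so the cheap ranking is often wrong where
it matters. `cspal` implements a workflow to close this gap at a small
fraction of the reference-method cost:

1. learn the **correction** between the baseline and the target method
   (delta-learning) rather than the total energy;
2. train a **committee** of atomic neural-network potentials and use the
   spread of member predictions (query-by-committee, QBC) as an uncertainty;
3. select training structures by **active learning** — label only candidates
   the committee is uncertain about;
4. re-rank the full landscape with the final committee, evaluating the few
   remaining high-uncertainty structures directly with the reference method;
5. extend the potential beyond lattice-energy minima with **threshold Monte
   Carlo** and **on-the-fly training**, adding reference calculations only
   when the uncertainty exceeds a trigger.

Everything runs at desk scale against a built-in surrogate oracle pair, so
the complete method — not a stub of it — is exercised by the tests.

## Models

### Committee neural-network potential

The energy of a structure with atoms $a$ and $Z$ molecules per cell is

$$E(\mathbf{x}) = \frac{1}{Z}\sum_a f_{e(a)}(\mathbf{x}_a),$$

where $f_e$ is a feed-forward subnet for element $e$ (two hidden layers of
16 tanh units by default) and $\mathbf{x}_a$ is the atom's descriptor
vector. A committee of $n$ members (default 6 during active learning;
an 18-member committee can be retrained on the final set) predicts

$$\bar E = \frac{1}{n}\sum_{i=1}^n E_i, \qquad
  \sigma = \sqrt{\tfrac{1}{n-1}\sum_i (E_i - \bar E)^2},$$

and $\sigma$ is the QBC uncertainty. All energies are kJ/mol **per
molecule** throughout the package, the natural unit for comparing polymorphs
of different $Z$.

Members differ by their seeded weight initialization and by a bootstrap
resample of the training structures; the out-of-bag structures of each
member form its validation set for early stopping. Bootstrap resampling was
chosen over a fixed 90/10 split because members trained on near-identical
data produce an overconfident (collapsed) spread — small committees are
known to underestimate $\sigma$, and resampling counteracts that without
any extra cost. Optimization is L-BFGS on the full batch, run in chunks
with the best-validation parameters retained; the convergence tolerance is
set very tight (`factr = 1e3`) because each chunk restart discards
curvature information and the default relative-reduction test would
otherwise fire long before an actual minimum.

In `"delta"` mode the labels are $\Delta E = E_\text{target} -
E_\text{baseline}$ and predictions are corrections; `corrected_energy()`
adds the deterministic baseline back, leaving $\sigma$ unchanged. In
`"total"` mode labels are first centered by least-squares per-element
atomic reference energies. Labels are standardized internally for
optimization and predictions are returned on the original scale.

### Descriptors

Atomic environments are encoded as atom-centered symmetry functions (ACSFs)
with the Behler cosine cutoff $f_c(r) = \tfrac12(\cos(\pi r/r_c)+1)$ at
$r_c = 8$ Å: radial G2 functions per neighbor element (a centered family
with geometrically spaced widths and a shifted family with equally spaced
centers) and angular G4 functions over element pairs
($\zeta \in \{1,2,4,16\}$, $\lambda = \pm 1$, a small set of widths). All
periodic images within the cutoff are included; the image search replicates
cells as needed, so thin cells are handled exactly.

From this deterministic pool (128 functions for a two-element system with
the defaults) an informative subset — 64 per element by default — is chosen
by iterative CUR selection: leverage scores from the top right-singular
vector, greedy pick, orthogonalization of the remainder against the pick.
Ties break toward the lowest column index so selection is reproducible.
Features are standardized over the current training set before entering the
networks and constant columns are dropped with a warning.

Structure-level descriptors (for farthest point sampling, FPS) are the
per-element means of the atomic rows, concatenated in fixed element order
— an intensive quantity, so supercell replicas coincide. FPS uses plain
Euclidean distance on standardized structure descriptors, greedy max-min,
ties toward the lowest index.

### Active learning

The loop: seed a first batch (random by default, FPS optional) → label with
the oracle → train the committee → predict all remaining candidates → stop
if the fraction of remaining candidates with $\sigma$ at or above the
threshold has dropped below the target — otherwise select a batch, label,
retrain. Defaults follow the configuration found to balance cost and
accuracy for landscape correction: delta-learning, committee of 6,
uncertainty threshold 1.0 kJ/mol, batch 30, 5% uncertain target, selection
by highest uncertainty. Three query strategies are provided: `random` (each
candidate evaluated once in a seeded random order, uncertain ones kept),
`highest_uncertainty` (all remaining candidates scored each round) and
`highest_uncertainty_fps` (FPS restricted to the uncertain set, seeded at
the most uncertain candidate). An optional energy window above the global
minimum focuses the candidate pool on the low-energy region, and an
optional cap bounds the training-set size.

Design notes on ambiguities the loop had to resolve: the initial seed size
equals the batch size; the "% uncertain" stopping fraction is computed over
the *remaining* (unselected) pool after each retrain, since selected
candidates are no longer uncertain by construction; ties everywhere break
by ascending candidate id; each retrain uses fresh member seeds derived
from `(master_seed, iteration)` so uncertainties stay calibrated across
iterations; the final committee is retrained on the identical selected set.

Reranking predicts every landscape entry (baseline-corrected in delta
mode), flags entries with $\sigma$ above 6 kJ/mol, and evaluates flagged
entries directly with the oracle — the standard treatment for the handful
of structures the model cannot be trusted on.

### Threshold Monte Carlo and on-the-fly training

Threshold MC accepts a move iff the new energy lies below a fixed lid,
$E_\text{start} + 20$ kJ/mol by default; the downhill variant accepts only
strictly decreasing energies. The rigid-molecule moveset draws uniformly
from: rotate one molecule about its centroid, translate one molecule,
perturb one cell length, perturb one cell angle, scale the volume
isotropically (defaults: 0.3 rad, 0.3 Å, 0.3 Å, 3°, volume factor in
[0.97, 1.03]). Cell moves rescale molecular centroids fractionally while
keeping every molecule rigid in Cartesian space; proposals that bring atoms
of different molecules below the 0.7 Å hard core are rejected without an
energy call. The lid is fixed for the whole run.

With on-the-fly training enabled, every step is first evaluated by the
committee; when $\sigma$ exceeds the trigger (2.0 kJ/mol default) the
target oracle evaluates the configuration, the configuration joins the
training set with its oracle label, the oracle energy supersedes the model
energy for the acceptance decision (the more truthful number is available,
so it decides), and the committee is retrained every 5 additions from a
warm start. With on-the-fly training off, a model-backed trajectory aborts
once $\sigma$ exceeds 50 kJ/mol — the level at which a prediction carries
no usable information.

## The synthetic benchmark

The surrogate oracle pair stands in for a force field (baseline) and a
first-principles method (target) so the workflow is testable without
electronic-structure codes. The baseline is an intermolecular 12-6
repulsion–dispersion plus damped point-charge Coulomb potential on rigid
4-site molecules (two elements, neutral), plus a short-wavelength
oscillatory pair term (amplitude 1.5 kJ/mol, wavelength 0.7 Å) that gives
the baseline landscape the short-length-scale structure of a multipolar
force field — without it, learning total energies would be no harder than
learning the correction, and the central advantage of delta-learning would
be invisible by construction. The oscillation is present identically in
baseline and target, so it cancels exactly in the correction. The target
additionally differs by two things the baseline lacks:

* narrow per-element-pair Gaussian wells (width 0.15 Å, amplitudes of a few
  kJ/mol) — a short-correlation-length radial correction. The width is
  deliberately below the resolution of the shifted-G2 descriptor grid
  (~0.5 Å), so the correction is *hard but learnable*: hundreds of minima
  suffice for ~1 kJ/mol accuracy on minima, while the model's behaviour
  between and beyond training geometries is genuinely imperfect —
  the regime in which uncertainty-driven selection earns its keep;
* an Axilrod–Teller-style triple-dipole three-body term (target only), the
  classic many-body dispersion contribution that pairwise force fields
  miss. Purely intramolecular triangles are excluded as rigid-body
  constants; distances are clamped at 2 Å so the term stays bounded.

The landscape generator quasi-randomly samples rigid-molecule packings in
P1 — Halton sequences with a seeded Cranley–Patterson shift over cell
parameters (lengths 5.5–9 Å, angles 75–105°), molecular positions, and
Shoemake-uniform orientations — rejects overlaps, relaxes each packing to a
baseline local minimum (bounded L-BFGS over cell and rigid-body degrees of
freedom, with the objective and its finite-difference gradient evaluated in
compiled code), and de-duplicates by (energy, density). The default study
conditions are 300 structures with Z = 2; generation takes on the order of
three minutes on one CPU, and each entry withstands a perturbation-probe
audit (random 0.01 Å / 0.01 rad rigid-body pokes raise the energy).

What the surrogate does *not* emulate: real chemistry (no physical
parametrization is claimed), space-group symmetry (P1 only), conformational
flexibility, and — importantly — the full ruggedness of a force-field→DFT
correction. The committee's disagreement on this surrogate saturates near
the correction's own standard deviation (a few kJ/mol), so the 50 kJ/mol
abort level is effectively never reached here; passing tests demonstrate
the mechanics and direction of the method's claims (fewer selections in
delta mode, fewer additions at a higher trigger, improved off-minima
accuracy after on-the-fly training), not DFT-scale error magnitudes.

## Numerical choices and degenerate inputs

* Lattices are stored as row-vector matrices (`cart = frac %*% lattice`);
  construction rejects left-handed cells and cells whose angles give
  non-positive volume. Fractional coordinates wrap into [0, 1).
* After wrapping, "same molecule, zero image offset" no longer identifies
  bonded pairs, so intramolecular exclusion uses the minimum-image
  convention; molecules are assumed smaller than half the cell.
* Overlapping molecules below the 0.7 Å hard core refuse to construct by
  default; energy kernels clamp distances at 0.5 Å and return large finite
  flagged energies instead of infinities.
* Zero-variance descriptor columns are dropped with a warning; constant
  labels train against an exactly centered zero target.
* CUR stops early with a warning on rank deficiency; FPS resolves
  zero-distance ties toward the lowest index and never re-picks a point.
* All randomness flows from one master seed through named substreams
  (`substream_seed`), so every stage is independently reproducible and
  checkpoints restore bitwise-identical predictions (floating-point
  metadata round-trips through C99 hex-float strings).

## Problem sizes used by the tests and the acceptance script

The shipped benchmark uses the 300-structure default landscape, a 50
structure held-out split, active learning on the remaining 250 candidates
in both delta and total mode, on-the-fly training from FPS-selected
starts (10 in the acceptance script, 6 in the cached test benchmark) with
150-step downhill trajectories, paired plain-downhill runs from 20 held-out
minima, and an off-minima test set of ~100 configurations
sampled from threshold-MC trajectories under a 20 kJ/mol lid. These sizes
are the package's chosen study conditions; the vignette states them so that
reported numbers are interpretable.

## Known limitations

* Energy-only training: atomic forces are neither predicted nor trained on,
  so the model is not suitable for force-based relaxation or dynamics.
* The committee spread is an uncalibrated uncertainty; thresholds are set
  in energy units by the user, not derived from a calibration.
* Rigid molecules only; conformational moves are not implemented.
* The lid is fixed per trajectory; lid schedules are out of scope.
* P1 landscapes only; no space-group machinery.
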