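# cspal

Active learning of committee neural-network potentials from crystal
structure prediction (CSP) landscapes.

## The problem

CSP generates thousands of locally minimized candidate crystal structures,
ranked by lattice energies from a cheap baseline method (an empirical force
field or tight binding). Polymorph energy gaps are only a few kJ/mol, so
those rankings often need correcting with a far more expensive reference
method — too expensive to apply to a whole landscape. `cspal` is for
computational chemists and method developers who want that correction at a
small fraction of the reference cost, and a desk-scale testbed for the
machinery that delivers it.

The core model is a **committee neural-network potential**: per-element
feed-forward subnets map atom-centered symmetry function (ACSF) descriptors
**x** to atomic energies, summed and normalized per molecule. A committee of
*n* independently initialized, bootstrap-resampled members predicts

    E(x)  = (1/n) Σᵢ Eᵢ(x)          (committee mean)
    σ(x)  = sd({Eᵢ(x)})             (query-by-committee uncertainty)

Instead of total energies the committee learns the **Δ-learning correction**
ΔE = E_target − E_baseline, a much smaller function that needs far fewer
training structures. **Active learning** selects which candidates to label:
structures whose σ exceeds a threshold (1.0 kJ/mol by default) are added in
batches of 30 until fewer than 5% of the remaining pool is uncertain. The
trained committee re-ranks the landscape, flags entries with σ > 6 kJ/mol,
and evaluates those directly with the reference oracle. Beyond the minima,
**threshold Monte Carlo** (moves accepted iff the energy stays below a fixed
lid, or strictly decreases in downhill mode) explores each basin, with
**on-the-fly training**: any configuration with σ above a trigger is labeled
by the oracle and added to the training set, keeping trajectories reliable.

A built-in surrogate oracle pair (repulsion–dispersion + electrostatics
baseline with multipole-like short-range structure; the target adds
short-length-scale pair corrections and a triple-dipole many-body term) plus
a quasi-random rigid-molecule landscape
generator make the entire workflow runnable and testable without any
electronic-structure code. A real backend attaches as a shell command that
reads an extended-XYZ file and prints one energy.

## Worked example

```r
library(cspal)

## a synthetic CSP landscape: 300 quasi-random packings of a rigid 4-site
## molecule, relaxed to baseline local minima, labeled with the target oracle
pair <- surrogate_pair()
ls <- generate_landscape(n = 300, z = 2, seed = 1)
ls <- label_with_target(ls, pair)
print(ls)
#> <landscape> 300 entries (energies in kJ/mol/molecule)
#>   e_baseline: [-26.651, -4.125]   targets known: 300

## descriptors: deterministic ACSF pool, CUR-selected 64 functions/element
params <- acsf_param_pool(c("C", "O"))
params <- select_descriptors(ls$structures[seq(1, 300, 3)], params, k = 64)

## delta-learning active learning, Table-style defaults:
## threshold 1.0 kJ/mol, committee 6, batch 30, 5% uncertain target
res <- run_active_learning(ls, pair$target, al_config(master_seed = 1),
                           params = params)
print(res$state)
#> <al_state> 8 iterations, 208 training / 92 remaining / 0 excluded; stop: pct_target

## rerank the full landscape; flagged entries go to the oracle directly
rr <- rerank_landscape(res$model, ls, oracle = pair$target)
head(rr[order(rr$mean), c("id", "e_baseline", "mean", "sigma")], 3)
#>        id e_baseline      mean      sigma
#> 107 s0107  -25.77504 -39.42207 0.03306812
#> 6   s0006  -26.65134 -37.82003 4.45871381
#> 39  s0039  -24.00805 -34.19644 2.22303072
```

The run converges once fewer than 5% of the unselected candidates are
uncertain: 208 of the 300 structures end up labeled, and the corrected
ranking reorders the landscape (the baseline global minimum, `s0006`, drops
to second place with a large committee uncertainty, while `s0107` becomes
the confident corrected minimum).

The active-learning state records, per iteration, the ids added, their σ at
selection time and the percentage of uncertain candidates — so the run can
be audited (`audit_al_state`) and reproduced exactly from its master seed.

Command-line wrappers over the same functions live in `inst/cli/cspal.R`
(subcommands `make-landscape`, `select-descriptors`, `al-run`, `rerank`,
`mc-run`, one YAML config, `--seed`/`--out` overrides).

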