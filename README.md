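# dnfba — constraint-based modeling of a dopaminergic nerve cell

`dnfba` is an R package for flux balance analysis (FBA) of a dopaminergic
neuron, the cell type whose death in the *substantia nigra* causes
Parkinson's disease. It is written for systems-biology researchers who
want to probe how dopamine metabolism, oxidative stress, α-synuclein
aggregation, protein/organelle degradation and apoptosis initiation trade
off against each other at steady state.

The cell is represented as a process network: metabolites connected by
irreversible reactions with flux bounds in µM·h⁻¹. A steady state is a
flux vector *v* with

```
S v = 0,        lb ≤ v ≤ ub
```

where *S* is the stoichiometric matrix, and the analyses optimize linear
target functions *cᵀv* over that polytope — canonically the minimization
or maximization of the summed apoptosis-initiation fluxes (`minApo`,
`maxApo`) or of the summed degradation fluxes over lysosome, proteasome
and mitophagy (`minDeg`, `maxDeg`).

The package provides:

* **Network containers and bound policy** — metabolites, irreversible
  bounded reactions, boundary inputs/outputs, currency metabolites,
  18 canonical functional flux groups; bound tags `default` (0–100),
  `slow` (0–30) and `best_et_al` (kinetic reference ± 10 %) with the four
  named zero-lower-bound overrides.
* **A curated skeleton model** (`make_skeleton_model()`): a 63-reaction
  reconstruction of the dopaminergic cell covering dopamine
  synthesis/metabolism/transport, MPTP import, ROS production and damage,
  DJ-1, α-synuclein aggregation and export, all degradation routes, and
  both apoptosis triggers. For the full deposited 139-reaction network,
  download BioModels entry `MODEL1302200000` yourself and load it with
  `read_sbml_model()` — the package performs no network access.
* **A deterministic FBA engine** — a bounded-variable two-phase simplex
  with Bland's rule, parsimonious (minimum-total-flux) tie-breaking,
  flux variability analysis with per-reaction uniqueness flags, and a
  brute-force vertex-enumeration oracle for models of ≤ 12 reactions.
* **The experiment suite** — the four-objective basic characterization
  plus pinned input-flux scans (O₂, ATP, MPTP, α-synuclein, tyrosine)
  with feasibility-window and onset-threshold extraction; experiment
  parameterizations ship as JSON presets.
* **Model exchange** — SBML (read L2/L3, write L3V1 with fbc-style
  bounds), a TSV reaction-table dialect, TSV/JSON result tables.
* **Seeded synthetic generators** — random networks with exactly balanced
  planted fluxes, a neuron-like fixture with a constructed feasibility
  window, and micro fixtures with closed-form optima.
* **Command-style entry points** — `cmd_validate()`, `cmd_run()`,
  `cmd_simulate()` and the thin wrapper script `inst/cli/dnfba`.

## Worked example

```r
library(dnfba)

model  <- make_skeleton_model()
groups <- model_groups(model)
model
#> cell_model (curated-skeleton): 34 metabolites, 63 reactions (11 in / 11 out)

# basic characterization under the four target functions
suite <- run_objective_suite(model, groups)
head(suite$table[suite$table$group %in%
                   c("Apoptosis (LBs)", "Apoptosis (mitochondria)",
                     "Degradation (lysosome)"), ])
#>                       group maxApo minApo maxDeg minDeg
#> 2           Apoptosis (LBs)     50      0      0      0
#> 3  Apoptosis (mitochondria)     85      0      0      0
#> 12   Degradation (lysosome)      0      0     85      0
```

A healthy cell minimizing apoptosis reaches a steady state with zero
apoptosis-initiation flux; forcing apoptosis maximal (`maxApo`) drives
135 µM·h⁻¹ through the two initiation routes; maximal degradation is
capped at 85 µM·h⁻¹ by the cell's ATP budget.

```r
# neurotoxin scan: pin the MPTP input at 0..100 uM/h under maxDeg
mptp <- run_scan(model, scan_spec("MPTPin", 0:100, "maxDeg"), groups)
find_onset(mptp, "Apoptosis (LBs)", "appears")$threshold
#> [1] 86

# energy requirement: pinned ATP input is feasible only inside a window
atp <- run_scan(model, scan_spec("ATPin", 0:1000, "maxDeg"), groups)
unlist(find_feasibility_window(atp)[c("min_feasible", "max_feasible")])
#> min_feasible max_feasible
#>           15          200
```

Below an ATP input of 15 µM·h⁻¹ the skeleton's basal ATP demand cannot be
met even with respiration at its cap; above 200 µM·h⁻¹ the cell can no
longer absorb or export the surplus. MPTP exposure above 86 µM·h⁻¹
saturates the ATP-backed detoxification routes and apoptosis becomes
unavoidable. (These thresholds characterize the packaged skeleton
reconstruction; the deposited whole-cell network has its own, larger
values.)

Every reported flux vector satisfies `|S v|∞ ≤ 1e-6` and its bounds, and
repeated runs are bit-identical: alternate optima are resolved by a
parsimonious tie-break, with flux-variability flags
(`solve_fba(..., with_fva = TRUE)`) marking any reaction whose flux is
not unique at the optimum.

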