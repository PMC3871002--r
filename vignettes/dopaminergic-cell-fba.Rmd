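---
title: "Constraint-based analysis of a dopaminergic nerve cell"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constraint-based analysis of a dopaminergic nerve cell}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dnfba)
```

## The model and its assumptions

`dnfba` models a dopaminergic neuron as a process network: a set of
metabolites (species and coarse-grained pools such as "damaged protein" or
"defective mitochondrion") connected by irreversible reactions with finite
flux bounds in µM·h⁻¹. The biology covered is the one relevant to
Parkinson's disease: dopamine (DA) synthesis from tyrosine via L-DOPA, DA
metabolism to homovanillic acid (monoamine oxidase and
catechol-O-methyl-transferase routes), vesicular storage, release and
re-uptake through the dopamine transporter (DAT); reactive oxygen species
(ROS) production by DA chemistry, by complex I and III of the respiratory
chain and by iron (Fenton) chemistry; ROS damage to proteins, mitochondria
and DNA; α-synuclein (αSYN) input, aggregation (enhanced by DA and ROS),
inhibition of aggregation by the chaperone DJ-1, Lewy-body formation and
ATP-dependent export of αSYN to the extracellular space; degradation by the
lysosome, the ubiquitin–proteasome system and mitophagy; mitochondrial
biogenesis and repair; MPTP import via DAT with complex-I poisoning by
MPP⁺; and two apoptosis-initiation routes, one triggered by Lewy bodies and
one by cytochrome-C release from defective mitochondria. Apoptosis itself
is not resolved mechanistically — the model only carries its *initiation*
fluxes, which is what the analysis optimizes.

The analysis is flux balance analysis (FBA). With stoichiometric matrix
$S$ (metabolites × reactions) and flux vector $v$, a steady state satisfies

$$S\,v = 0,\qquad \mathrm{lb} \le v \le \mathrm{ub},$$

and the cell's behavior is probed by optimizing linear "target functions"
$c^\top v$ over that polytope. Four canonical objectives are used
throughout, built from functional reaction groups: minimize or maximize
the summed apoptosis-initiation flux (`minApo`, `maxApo`) and minimize or
maximize the summed degradation flux over lysosome, proteasome and
mitophagy (`minDeg`, `maxDeg`).

Key assumptions, inherited from the modeling tradition this network comes
from:

* **Irreversibility.** Every reaction runs forward with
  $0 \le \mathrm{lb} \le v \le \mathrm{ub}$; reversible chemistry would be
  split into paired forward/backward reactions. All reported flux ranges
  are therefore one-sided.
* **Process network, not atom balance.** Stoichiometric coefficients
  express process coupling (one unit of damaged protein consumes one unit
  of ATP to degrade), not elemental balance. No charge or mass checking is
  done, by design.
* **Compartments are metadata.** Cytosol, mitochondrion, vesicle,
  extracellular space and lysosome tag the species but do not enter the
  mathematics; FBA here is purely stoichiometric, with no volume scaling.
* **Currency metabolites** (O₂, H₂O, NAD⁺/NADH, Fe³⁺/Fe²⁺, ADP+Pi, ATP)
  may flow in and out of the cell through boundary reactions within their
  bound ranges.

## The bound policy

Flux bounds are set by a three-tag policy (`bounds_policy()`,
`apply_bounds_policy()`):

| tag          | bounds (µM·h⁻¹)             | meaning                          |
|--------------|-----------------------------|----------------------------------|
| `default`    | (0, 100)                    | no specific knowledge            |
| `slow`       | (0, 30)                     | known to proceed slowly / rarely |
| `best_et_al` | reference $f$ ± 10 %        | taken from the kinetic DA-terminal model |

After tag-based assignment, the lower bounds of `OMSynthesis1`,
`OMSynthesis2`, `HVASynthesis3` and `HVASynthesis4` are forced to 0: the
whole-cell network contains more consumers of cytosolic dopamine than the
kinetic model these reference values come from, and keeping their positive
lower bounds would make the steady-state system infeasible. The policy is
idempotent and never produces a crossed bound pair.

## The curated skeleton versus the deposited network

The full deposited whole-cell model (BioModels identifier
`MODEL1302200000`, 139 reactions and 111 metabolites) is not bundled: the
package never accesses the network, and the deposited file is third-party
data that users fetch themselves and load with `read_sbml_model()`. What
ships instead is a curated **skeleton reconstruction**
(`make_skeleton_model()`, 63 reactions and 34 metabolites) assembled from
the published sub-model descriptions. It covers every sub-model area and
populates all 18 canonical flux groups, but it makes *no claim of
reaction-count parity* with the deposited network, and its scan thresholds
are its own, not the published ones. The `provenance` field of every model
records which network an analysis ran on (`deposited`, `curated-skeleton`,
`synthetic`).

Reference fluxes in the skeleton are curation choices at the magnitudes the
published basic-model table suggests: the vesicular transport/release pair
carries a reference of 0.8 µM·h⁻¹ (the extracellular-DA scale), the four
O-methylation/HVA reactions 1.0 µM·h⁻¹, and a basal ATPase 50 µM·h⁻¹. The
basal ATPase, together with the 30 µM·h⁻¹ respiration cap, is what gives
the skeleton a two-sided ATP feasibility window (pinned ATP input feasible
only between 15 and 200 µM·h⁻¹) analogous in shape to the published
window; the window edges themselves are emergent, not fitted.

## Solver, tie-break and numerical choices

No linear-programming backend is assumed: the engine is a two-phase
primal simplex for bounded variables written for this package
(`lp_solve_bounded()`), with Bland's rule for both the entering and the
leaving variable. Bland's rule cannot cycle and makes the pivot sequence a
pure function of the input, so identical inputs give bit-identical
solutions — determinism is part of the contract, not an accident of the
backend. Unboundedness and infeasibility are reported as statuses, never
clamped.

FBA optima are generally degenerate: the optimal face can contain many
flux vectors, and a single printed flux per reaction would otherwise be
solver lottery. Two mechanisms address this:

* **Parsimonious tie-break.** After the primary solve, the objective is
  fixed at its optimum and the total flux $\sum_j v_j$ is minimized. The
  reported vector is therefore canonical and reproducible.
* **Flux variability analysis** (`flux_variability()`): per reaction, the
  min and max flux at the fixed optimum. Reactions with range ≤ 1e-6 are
  flagged unique; any non-unique reported flux is visibly marked
  (`uniqueness_flags` on `solve_fba(..., with_fva = TRUE)`).

Tolerances (defaulted, configurable where exposed): steady state
$|Sv|_\infty \le 10^{-6}$, bound containment $10^{-9}$, FVA uniqueness
$10^{-6}$, simplex pivot tolerance $10^{-9}$, phase-1 feasibility
$10^{-7}$. Degenerate pivots are taken (ratio clipped at 0); basis systems
are re-solved densely each iteration, which at this problem size
(≤ ~150 columns) costs milliseconds and avoids accumulated update error.

As an independent check, `enumerate_vertices()` exhaustively enumerates
basic feasible solutions for models of at most 12 reactions (every
full-rank basic column set × every lower/upper assignment of the nonbasic
variables) and refuses larger inputs rather than approximating. The test
suite drives both routes over 100 seeded networks and requires agreement
to 1e-6; a general-purpose LP routine from another package provides a
third opinion on a subset.

## Experiments

`run_objective_suite()` reproduces the basic-model characterization: the
four canonical objectives, each reported as summed flux per functional
group (the wide table's column order is maxApo, minApo, maxDeg, minDeg).
`run_scan()` implements the input-flux experiments: a boundary input
reaction is swept over a range and the model re-solved at each value.
Decisions that the original description leaves open, fixed here once:

* **Pinning, not relaxing.** By default the swept input is pinned
  (`lb = ub = value`). A pinned ATP input is the only reading under which
  a *two-sided* feasibility requirement and a forced ATP surplus export
  can occur; `relax_ub` mode (upper bound only) is available and is the
  natural mode for monotonicity properties.
* **Step 1 µM·h⁻¹.** Every published threshold is an integer; the step is
  not stated. The presets use step 1 over 0–100 (ATP: 0–1000).
* **Oxygen objective augmentation.** The oxygen experiment includes the O₂
  input reaction in the optimization function; sense and weight are not
  stated, so the preset records weight +1 in the primary sense explicitly
  in its JSON config (`inst/extdata/presets/o2.json`).
* **Infeasible scan points are data.** They are recorded with status
  `infeasible`, never skipped, so `find_feasibility_window()` can locate
  the feasible interval (for a pinned input this is exactly the projection
  of the flux polytope, hence contiguous).
* **Onset persistence.** `find_onset(direction = "vanishes")` requires the
  group flux to stay below tolerance for *all* larger scanned values.
  Narrow DA-synthesis bounds are known to cause isolated flux fluctuations
  at high inputs; persistence keeps such artifacts from faking an
  extinction threshold.
* **minDeg is a pure minimization**, symmetric with the other three
  objectives; no composite objective is used.

## Synthetic data: what it emulates and what it does not

`generate_random_network()` builds test instances whose feasibility is
guaranteed by construction: internal stoichiometry (integer coefficients)
and a planted non-negative flux $v^\*$ on a dyadic grid are sampled first,
then boundary reactions are added whose planted fluxes absorb each
metabolite's net imbalance exactly — so $S v^\* = 0$ holds *bitwise*, not
just to rounding, and bounds derived as $v^\* \pm$ slack always contain
$v^\*$. With slack 0 the planted vector is the unique feasible point and
any maximization optimum equals $c^\top v^\*$ exactly; with positive slack
it is a certified lower bound. Generation is a pure function of spec and
seed (the global RNG stream is saved and restored).

`generate_neuronlike_network()` is a fixed mid-size topology with currency
exchange, tagged apoptosis/degradation sinks, a degradation bypass (so a
zero-apoptosis steady state exists under `minApo`), and one designated
input whose sole consumer carries bounds $(a, b) = (7, 19)$: a step-1
pinned scan must recover exactly that window. The seed only jitters
non-critical wide upper bounds.

These generators emulate the *structural* features the analysis relies on
— bounded irreversible fluxes, boundary exchange, currency species, group
tags, guaranteed steady states. They do not emulate biological kinetics,
realistic degree distributions, or the curated coupling structure of the
real network; passing tests on them validates the machinery (solver,
oracles, scans, I/O round trips), not any biological claim.

## Problem sizes used in the checked analyses

The packaged checks run the oracle comparison on 100 seeded networks of 8
reactions, planted-recovery on 25 networks of 9 reactions, the window
recovery on a 31-point step-1 scan, and the full skeleton experiments with
step-1 scans (101 points; 1001 for ATP). These sizes keep each property
statistically meaningful while the whole suite stays fast enough to run
routinely.

## Known limitations

* The skeleton is a reduced reconstruction: its absolute flux values and
  scan thresholds (e.g. ATP window 15–200 µM·h⁻¹, apoptosis onset at an
  MPTP input of 86 µM·h⁻¹) characterize the skeleton, not the deposited
  139-reaction network. Analyses of the deposited model require the
  BioModels file as a local path.
* In the skeleton, MPTP-driven apoptosis overflow exits through the
  Lewy-body route (the mitochondrial route requires ATP-dependent
  mitochondrial turnover, which is saturated at onset); in the full
  network the mitochondria-initiated route carries it.
* Non-objective group fluxes can be non-unique at an optimum even after
  the parsimonious tie-break; always consult the FVA flags before reading
  a single number as "the" flux.
* The SBML writer emits Level 3 Version 1 with fbc-style bound parameters
  plus a small package-namespace annotation for fields core SBML cannot
  carry; readers of other toolchains will see a valid constrained model
  but will ignore the group/speed metadata.
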