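---
title: "Local assembly rules and RNA packaging on the T=1 capsid lattice"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Local assembly rules and RNA packaging on the T=1 capsid lattice}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(capsidpath)
```

## The model

Small plus-sense ssRNA viruses such as satellite tobacco necrosis virus
(STNV) package their genome while the protein shell assembles around it.
In the packaging-signal-mediated picture, roughly 30 stem-loops
(packaging signals, PSs) spread along the genome bind coat protein (CP)
with heterogeneous affinities, and shell growth proceeds by incorporating
CP:PS complexes one after another. `capsidpath` implements a
local-rule version of this process on the T=1 lattice:

* **Lattice.** The 60 CP binding sites are the orbit of a generic point
  under the 60 proper rotations of the icosahedral group. Each position
  is flanked by one five-fold, two three-fold and one two-fold symmetry
  axis, and the nine *moves* an RNA can make between consecutive PSs are
  rotations about those axes: move 1 is 180° about the closest two-fold;
  moves 2/5 and 6/7 are ±120° about the two flanking three-folds; moves
  3/4 (±72°) and 8/9 (±144°) wind around the five-fold. A *move set* is
  an inverse-closed subset of the nine moves; it defines the local
  assembly rules.
* **Mutual exclusion.** Each two-fold axis supports two sterically
  clashing hairpin orientations, so the 60 sites split into 30 mutually
  exclusive pairs; at most one member of a pair can ever hold RNA. The
  pairing is the composite of move 4 followed by move 2 (equivalently 5
  then 3), a fixed-point-free involution.
* **RNA paths.** A fully packaged RNA traces a *pseudo-Hamiltonian
  path*: 30 distinct positions, consecutive ones related by a move of
  the set, exactly one member of each exclusion pair visited.

## Frame conventions and the counting convention

The move definitions leave three conventions free: the handedness of the
five-fold and three-fold rotations, and which flanking three-fold is
"closest". Requiring the exclusion composite to be a fixed-point-free
involution eliminates half the sign combinations; the remaining
ambiguity (which three-fold serves moves 2/5) is fixed by the exhaustive
path counts, which are extremely sensitive to it: the validated frame
gives 64 paths for move set {2,3,4,5} and 826 for {3,4,6,7}, while the
swapped assignment exchanges qualitative behaviour entirely. The choice
is recorded in `lattice_frame()` and validated by `validate_lattice()`.

Paths are counted as directed 5'→3' move sequences from a fixed start
position. Because the rotation group acts simply transitively on
positions and commutes with every move, a directed path class is
identified exactly by its move sequence, so the fixed-start count is the
number of distinct RNA organisations; a path and its reversal are
counted separately. Under this convention the enumerator reproduces the
full reference series (64; 826; 1,342; 7,242; 12,582; 120,086;
2,240,200), which `scripts/acceptance.R` recomputes from scratch.
Counts for 8- and 9-move sets are combinatorially out of reach and are
only attempted under an explicit node budget.

## The stochastic assembly engine

`run_assembly()` is an exact Gillespie simulation over an ensemble of
RNAs sharing a CP pool. Reactions and default propensities
(`kinetic_params()`):

| reaction | propensity | default scale |
|---|---|---|
| CP binds a free PS | `k_bind * free_cp / cp_ref` per PS | `cp_ref = 7500 * cp_total` |
| CP:PS unbinds | `k_bind * exp(dG_ps / rt)` | detailed balance |
| nucleation (adjacent CP:PS pair placed via a contact move 1/3/4) | `k_nuc` per pair | `1e-5` |
| elongation (next PS placed at a move image of the interval end) | `k_attach * exp(-phi * dG_cs * c / rt)` per eligible target | `k_attach = 3e-3`, `phi = 0.9` |
| detachment (terminal in-shell unit, breaking `c` contacts) | `k_attach * exp((1 - phi) * dG_cs * c / rt)` | — |

with `dG_cs = -4` kcal/mol, `rt = 0.593` kcal/mol (25&nbsp;°C) and time in
arbitrary units. Three design choices matter and were made on mechanistic
grounds before any benchmarking of reported values:

* **Occupancy scale.** The bound fraction of a PS is
  `b / (b + k_bind exp(dG_ps/rt))` with `b = k_bind * free_cp / cp_ref`.
  `cp_ref` is chosen so that occupancy spans ~0.1 at −4 kcal/mol to
  ~1 at −9 and below. If binding is made fast relative to unbinding
  (for instance, a propensity proportional to the raw CP copy number),
  every PS saturates regardless of affinity and the entire
  packaging-signal landscape flattens out.
* **Slow nucleation.** `k_nuc` is far below the fastest unbinding rate,
  so nucleation samples the *equilibrium* occupancies rather than the
  initial binding transient. Without this separation the first adjacent
  pair to bind — usually a weak one — nucleates, and nucleation becomes
  affinity-blind.
* **Transition-state split `phi`.** The contact energy of a placement is
  split across the attachment/detachment barrier; the equilibrium ratio
  `exp(-dG_cs * c / rt)` is independent of `phi`. At the default
  `phi = 0.9` attachment strongly prefers contact-forming placements.
  This matters because the exhaustive analysis of the 64-path census
  shows that, once a five-fold pentagon has nucleated, the unique
  completing continuation is at every step either the only eligible
  placement or the only one that touches the shell; contact-biased
  attachment therefore funnels growth down the completable spiral while
  zero-contact missteps stay transient. `phi = 0` recovers the plain
  contact-Boltzmann detachment rule.

Two further engine options are off by default but retained:
`fill_contacts` counts contacts against the exclusion partners of placed
units as well (a quasi-static image of the 30 non-path CPs of the full
shell) and `require_contact` gates elongation on touching the shell.
Measured on the census geometry, both mis-guide growth — partner-filled
contacts reward locally tucked-in placements that are globally
un-completable — so the default kinetics use path-CP contacts only and
leave eligibility to the move set and the exclusion rule.

Detachment is restricted to the 5'/3' terminal in-shell units, keeping
the in-shell interval contiguous; completed capsids are inert. A run
ends at `t_max`, or once no shell-composition change has occurred for
`q_window` (quiescence), or when total propensity vanishes. Every
simulation takes an explicit seed and is bit-reproducible.

## Genetic algorithm and landscape

`evolve()` follows the standard elitist scheme: evaluate all variants
(stochastic fitness, fresh derived seed each generation), keep the top
`survivors` unchanged, fill the population with round-robin copies
mutated per-PS with probability 0.05 (uniform redraw within
[−12, −4] kcal/mol), and stop at the generation cap or when the top-20
spread falls below the tolerance. `ga_profile("full")` is the
published-scale configuration (1024 variants × 2000 copies × 30
generations); `"desk"` and `"mini"` are reduced profiles sized for a
workstation and for test suites. The test suite runs a 48-variant,
150-copy, 14-generation optimisation and evaluates the winner at 2000
copies; `landscape_histogram()` maps random variants to yields for the
one-dimensional landscape picture.

`nucleation_site()` reports the longest run of strong-band PSs
(≤ −9 kcal/mol, the strong band of `affinity_bands()`); `knockout()` and
`nucleation_only()` build the matched perturbations used in the
profile-comparison table (`make_table2()`).

## What the synthetic profiles emulate

The generators cover the study conditions: `uniform_variant()` for the
uniform −4/−8/−9/−10 ensembles, `random_variant()` for i.i.d. uniform
affinities in [−12, −4] (each position equally likely to be strong, the
initial GA population), and knockout / nucleation-only perturbations of
an optimised variant. They do not emulate sequence-level features of
real genomes: PS spacing irregularity, secondary-structure context, or
affinity correlations along the genome. Passing tests therefore support
the local-rule model's internal behaviour, not quantitative predictions
for any particular viral sequence.

## Numerical choices and degenerate inputs

* Group closure and orbit identification use an 1e-8 coordinate
  tolerance; positions are ordered lexicographically on rounded
  coordinates for stable serialisation.
* A representative point equidistant from two candidate axes, or lying
  on an axis (orbit smaller than 60), is rejected with instructions to
  perturb the frame weights.
* DFS explores moves in ascending label order — determinism of
  enumeration order only; counts are order-independent.
* Ties among eligible attachment targets carry equal propensity at
  equal contact count.
* The engine's Fenwick trees are rebuilt every 2e6 events to cap
  floating-point drift.
* Simulation sizes in the tests (ensembles of 25–2000 RNAs, a
  48-variant GA) were chosen so the full suite exercises every claim at
  workstation scale; the acceptance script's combinatorial targets are
  exact at any scale.

## Known limitations

* Exact equilibrium capsid counts for uniform ensembles (and the exact
  optimised percentages) depend on kinetic rate constants that the
  local-rule description does not pin down; the package treats them as
  qualitative ordering targets only, and its defaults were calibrated to
  reproduce the orderings, not the percentages.
* Under the default kinetics the optimised-variant yield for
  {2,3,4,5} improves severalfold over the uniform baselines but falls
  short of the >90% headline figure. The bottleneck is identifiable and
  structural: shortly after nucleation the growing end faces forks where
  a completable continuation and an un-completable "corner" placement
  form the same number of CP–CP contacts, so no local propensity rule
  distinguishes them, and the reinforcement-to-erosion ratio
  (`occupancy * exp(-dG_cs/rt)`) makes a wrong sticky choice effectively
  irreversible at any occupancy that still permits growth. Resolving
  such forks requires kinetic detail beyond the local rules (or much
  deeper annealing than a workstation-scale horizon affords), so the
  90% bound is reported honestly as unmet by this implementation.
* The 30 non-path CPs of the complete shell are not explicit agents;
  their only trace is the optional `fill_contacts` accounting.
* Hamiltonian-cycle analysis, T>1 lattices and sequence-level PS design
  are out of scope.

## Reproducing the reference quantities

```r
lat <- build_lattice()
count_paths(lat, move_set(c(2, 3, 4, 5)))$n_path   # 64
run_assembly(lat, uniform_variant(-9), move_set(c(2, 5, 6, 7)),
             seed = 1, n_rna = 2000)$n_cap          # 0
```

`scripts/acceptance.R` recomputes the seven exact path counts and the
structural-zero simulation and writes them as JSON.
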