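---
title: "Simulating tumor growth and intratumor heterogeneity on a lattice"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating tumor growth and intratumor heterogeneity on a lattice}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tumorlat)
```

## The model

`tumorlat` simulates a tumor as a population of cells, each occupying a
single node of an unbounded lattice, growing from one cancer stem cell at
the origin. Normal tissue and extracellular matrix are not modeled, and
the environment is unaffected by the tumor — the simplifications shared
by the classical single-node cellular-automaton models of tumor growth
that this framework generalizes.

Three kinds of events compete: cell division, cell death, and migration.
Each live cell carries at most one pending waiting time per event class,
and the simulation repeatedly executes the globally earliest event
(an event-driven, Gillespie-like loop with per-cell non-exponential
clocks). Event waiting times follow gamma distributions parameterized by
a shape $k$ and a rate: for division,

$$w_b \sim \mathrm{gamma}(k_b,\ \beta_i), \qquad
  E[w_b] = 1/\beta_i, \qquad \mathrm{Var}[w_b] = 1/(k_b \beta_i^2),$$

where $\beta_i$ is the cell's *potential* birth rate. The shape
interpolates between two idealizations:

* $k_b = 1$: exponential, memoryless division — the assumption of most
  earlier simulators. Cells can re-divide arbitrarily soon after a
  division.
* $k_b = \infty$: a delta function — every division takes exactly
  $1/\beta_i$, so an undisturbed tumor divides in synchronous cohorts
  and $N_t = 2^t$ when $\beta = 1$.

Intermediate $k_b$ (say 8–100) mimics the cell cycle: a newborn daughter
must pass through interphase before it can divide again. Because the
gamma clock is not memoryless, a cell that last divided $\tau$ ago draws
its *residual* waiting time from the gamma tail conditioned on exceeding
$\tau$, renormalized — sampled exactly by inverse CDF on the upper tail.
With $k = 1$ the conditioning cancels (memorylessness), which is also why
death and migration clocks, exponential by default ($k_d = k_m = 1$),
never need re-drawing when circumstances change around a cell.

### Rate composition

A cell's potential birth rate is a product of five factors,
$\beta_i = \beta_0\,\beta_{C1}\,\beta_{C2}\,\beta_{E1}\,\beta_{E2}$:

* $\beta_0$ — base rate shared by all cells (default 1 per unit time;
  time is measured in mean cell-cycle units).
* $\beta_{C1}$ — cell type. Stem cells (CSC) divide symmetrically with
  probability `p_s` (two CSC daughters) and otherwise asymmetrically
  (the resident daughter stays a CSC, the displaced daughter is a
  transient amplifying cell, TAC, with division budget `omega_max`).
  A TAC division decrements the budget of both daughters; at zero they
  are terminally differentiated (TDC) and $\beta_{C1} = 0$ — a TDC never
  divides but still dies and migrates. `p_s = 1` (default) recovers the
  all-CSC models of earlier studies.
* $\beta_{C2}$ — driver mutations. Each division, each daughter
  independently acquires a driver of each class with probability `mu_*`;
  effects are Gaussian $s \sim N(\bar{s}, \sigma)$ and act additively on
  the rate scale, $\beta_{C2} = \prod_j (1 + s_j)$. Each factor is
  clamped below at 0 so a drawn $s \le -1$ is lethal-equivalent rather
  than producing a negative rate.
* $\beta_{E1}$ — global environment: a piecewise-constant multiplier
  schedule (`env_schedule`), the hook for modeling treatment pulses.
  The framework's positional environment function is reduced to this
  single global multiplier because the model assumes a uniform
  environment across the tumor; when it changes, every pending waiting
  time is re-evaluated (division clocks via the conditioned tail at the
  cell's current cycle age).
* $\beta_{E2}$ — local density, a function of $\phi_i$, the fraction of
  empty sites among the cell's neighbors: `constant`
  ($\beta_{E2} = 1$), `step` ($\beta_{E2} = \mathbb{1}[\phi_i > 0]$), or
  `linear` ($\beta_{E2} = \phi_i$).

Death and migration compose analogously
($\delta_i = \delta_0 \delta_{C2}$, $\rho_i = \rho_0 \rho_{C2}$; their
type and density factors are fixed at 1). Death may alternatively be
*coupled* to division: one clock fires and the outcome is death with
probability `alpha` — the failed-mitosis model used by some earlier
simulators.

### Lattices and neighborhoods

Regular (square/cubic) lattices support the Moore neighborhood
($3^d - 1$ = 8 or 26 directions) and the von Neumann neighborhood ($2d$ =
4 or 6); hexagonal lattices have a single neighborhood — 6 neighbors in
2D (axial integer coordinates) and 12 in 3D. The 3D close-packed lattice
is represented as face-centered cubic: integer triples with even
coordinate sum and the twelve offsets $(\pm1,\pm1,0)$ and permutations;
the Cartesian embedding divides by $\sqrt2$ so all nearest neighbors sit
at unit distance, as they do under the hex-2D basis
$(x + y/2,\ y\sqrt3/2)$. The hexagonal-close-packed variant is not
implemented. The lattice is unbounded — occupancy lives in a dense grid
that doubles in extent whenever the tumor approaches its edge — and
there are no boundary conditions.

### Placing the second daughter: push methods

Division keeps one daughter at the parent's site and must place the
other. The statistic $l_{\min}(d)$ — the number of consecutive occupied
sites from the adjacent site in direction $d$ to the nearest empty site —
drives the four placement rules (see `?place_daughter`): random-direction
ray pushing (method 1), $1/l_{\min}$-weighted pushing (2), iterative
steepest-descent pushing (3), and single-direction minimal pushing (4);
methods 2–4 first fill a uniformly chosen empty neighbor site when one
exists. Under the step/linear models a division only ever fires with
$\phi > 0$, so methods 2–4 coincide with the empty-site fill there —
verified in the tests by seed-identical trajectories — while method 1
retains its pushing semantics in every model. Displaced cells keep their
identity, clocks, and cycle age: a push is passive mechanics, not a
division.

### The event loop

After every event the engine re-schedules exactly the cells whose
composed rates may have changed: the cells directly involved always; and
under the step/linear models also every cell whose $\phi$ was altered —
the occupancy pattern changes only at a handful of sites per event (the
newly filled chain tail, a freed site, a migration's two sites; a swap
changes nothing), so the affected set is the occupied neighborhood of
those sites plus any pushed cells. Re-drawn division clocks use the
conditioned gamma tail at the cell's current age; death/migration clocks
are exponential and exact under reuse. Unchanged clocks are reused with
the elapsed time implicitly subtracted (they are stored as absolute
firing times).

Simultaneous firing times arise systematically at $k_b = \infty$, where
whole cohorts divide at one instant. Tied events are executed in
uniformly shuffled order, and each placement sees the partially updated
occupancy — division is synchronous in time but necessarily sequential
on the lattice. With a shared $\beta$ the tied times are exactly equal in
floating point (each is the same sum $t + 1/\beta$), so tie detection by
equality is reliable. A cell whose deterministic clock becomes *overdue*
after a rate increase (possible after an environment change) fires after
a minimal positive `eps_overdue` instead of a nonpositive wait.

Runs stop at `max_cells` (default $2^{14}$), at `max_time`, on
extinction, or when no event is pending ("stalled") — the latter occurs
with `p_s < 1`, no death and no migration under the step/linear models,
when immortal TDCs encase the tumor and every interior division rate is
zero.

## Genealogy statistics

Every cell entity spans one generation: a division retires the parent
record and creates two daughter records, so the genealogy is a strictly
binary tree whose edges are divisions. A cell's $\nu$ — the number of
division events in its ancestry — is its depth in this tree; under
synchronous neutral growth to $2^{14}$ cells every live cell has
$\nu = 14$, while memoryless division produces wide variation in $\nu$.

*Founder-lineage fractions* label each live cell by which of the first
`n_founders` cells (the population at the first instant it reached that
size, recovered exactly by replaying the genealogy in execution order)
contains it; under synchronous neutral growth the four founder fractions
are exactly 25% each.

*F\_ST between subregions* quantifies spatial genetic structure without
simulating markers: with branch lengths measured on the genealogy, the
infinite-marker expectation of differentiation between two disjoint cell
sets is taken in the Hudson/Slatkin form
$F_{ST} = 1 - \pi_w/\pi_b$, where $\pi_w$ is the unweighted mean of the
two within-region mean pairwise genealogical distances and $\pi_b$ the
between-region mean. The estimator form and the branch-length units are
deliberate choices (the quantity is only defined up to them): units are
configurable between division counts and time, with division counts the
default since genealogies are naturally drawn in division generations.
Distances use the most recent common ancestor
($\nu_a + \nu_b - 2\nu_{\mathrm{MRCA}}$, or twice the time back to the
MRCA's division with live branches extended to the snapshot). A
"subregion" emulates a multiregional biopsy: a uniformly chosen focal
cell plus its `size - 1` nearest live cells by Cartesian distance
(default 20 cells, ties broken at random) — compact regions, one of
several reasonable readings of sampling "random subregions". The F_ST
profile pairs disjoint subregions and reports Euclidean distance between
their central cells alongside F_ST, plus their Pearson correlation — the
isolation-by-distance signal, which is weaker for constant-rate growth
with random pushing (lineages intermix) than for surface growth with
empty-site filling (lineages stay clustered).

## What the defaults represent

| Parameter | Default | Meaning |
|---|---|---|
| `beta0` | 1 | time unit = one mean cell cycle |
| `k_b` | `Inf` | synchronous division (the analytically checkable baseline) |
| `k_d`, `k_m` | 1 | memoryless death/migration |
| `delta0`, `rho0` | 0 | neutral growth baseline ignores turnover |
| `e2_model`, `push` | `constant`, 2 | the baseline of the growth-curve analyses |
| `p_s` | 1 | all-CSC (no differentiation) |
| `omega_max` | 5 | TAC budget used in the differentiation analyses |
| `max_cells` | 16384 | $2^{14}$, the standard stopping size |
| `n_founders` | 4 | four-lineage coloring of the tumor |

## Numerical and design choices

* **Residual sampling.** `qgamma(u * S(tau), lower.tail = FALSE)` is
  exact and O(1) at any age; ages so large that the tail mass underflows
  raise an error rather than returning garbage.
* **Determinism.** One seeded random stream drives every draw in a
  documented event order; equal seeds give byte-identical output files.
  Offset tables are in fixed lexicographic order, and all ties (argmin
  directions, simultaneous events, equidistant subregion members) are
  resolved by draws from the same stream.
* **Whether both TAC daughters decrement the budget** is ambiguous in
  the differentiation model as usually stated; both-decrement is
  implemented (the budget is a property of lineage depth). A
  split-budget variant would differentiate faster.
* **Migration targets** are uniform over all neighbors (swapping when
  occupied); `migration_prefer_empty` switches to filling empty
  neighbors preferentially.
* **Mutation timing.** Drivers are drawn independently per daughter at
  each division, keeping daughters exchangeable under "rate per cell
  division".
* **Dense occupancy grid.** Coordinates are keyed into a centered dense
  integer grid (initial half-width 64 in 3D, 256 in 2D) that doubles
  when the tumor nears its edge; ray walks peek at most one site past
  the occupied hull, so a 2-site margin suffices.
* **In-place state updates.** The simulation state is an environment of
  parallel vectors; indexed writes are evaluated with the AST
  interpreter inside that environment (see `R/state.R`) because
  byte-compiled indexed assignment into environment fields copies the
  full vector, which would make every event O(population).

## Scale of the shipped analyses

The test-suite analyses run at reduced sizes chosen to keep the full
suite in minutes while leaving the qualitative contrasts unambiguous:
growth-curve and migration orderings at 1024 cells over 10 seeds,
differentiation stalls at up to 1024 cells, the isolation-by-distance
contrast at 4096 cells with 50 region pairs over 10 seeds (records
pooled across seeds before correlating, as one would pool replicate
tumors), and the exponential-growth calibration over 100 seeds to
$t = 6$. The synchronous $2^{14}$ benchmark runs at full size.

## What the generator does and does not emulate

Simulated tumors reproduce the *mechanisms* of the lattice framework:
density-limited growth, pushing mechanics, differentiation barriers,
driver sweeps, and the genealogical consequences of each. They do not
emulate normal-tissue interaction, nutrient fields or vasculature
(the global environment multiplier is spatially uniform), cell-size
variation, or sequence-level mutation processes (F_ST is an
infinite-marker expectation, not a property of simulated genomes).
Passing tests therefore demonstrate internal consistency of the model
and its statistics, not calibration to any particular cancer.

## Session example

```{r, eval = FALSE}
cfg <- sim_config(k_b = 8, e2_model = "linear", push = 2,
                  max_cells = 4096, seed = 1)
st <- sim_run(cfg)
growth_curve(st)               # (t, N) after every event
lineage_fractions(genealogy(st), 4)
fst_distance_profile(st, n_pairs = 50, size = 20)
write_outputs(st, "out/run1", newick = TRUE)
```
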