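---
title: "Modelling signal-coupled microbial consortia with quorumCA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling signal-coupled microbial consortia with quorumCA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quorumCA)
```

## The model

quorumCA simulates engineered bacterial communities on a 2D lattice in which
strain growth rates are coupled through diffusible signals. The model has
three interacting layers.

**Agents.** Each lattice square (area 10 mm², side ΔL = √10 ≈ 3.162 mm)
is empty or holds one *cell-block*, a patch of ~10⁸ cells of a single strain
treated as one replicating agent. The block abstraction makes a plate-scale
community (hundreds of mm²) tractable: the block size is chosen so that a
block can plausibly double within one time step, and sub-block heterogeneity
is deliberately ignored. Blocks never die, move, or change strain; the only
transition is division into an empty von Neumann (4-) neighbour.

**Fields.** Every signalling molecule has a concentration field in nM,
co-registered with the grid. Per step (Δt = 10 min, the default throughout):

1. *Secretion* — each square occupied by a producer of molecule *m* gains
   `rate · Δt` nM. Secretion deposits into the producer's own square only;
   the rate is a per-cell-block volumetric rate with no spatial kernel.
2. *Diffusion* — one explicit Forward-Time Central-Space (FTCS) step,
   `U += s·(ΣU_neighbours − 4U)` with `s = D·Δt/ΔL²`.
3. *Decay* — first-order, forward-Euler: `U ·= (1 − k·Δt)`.

**Division.** After the field update, every square occupied *at the start of
the division phase* is visited in a freshly shuffled order and divides with
probability equal to its current fitness into an empty neighbour chosen
uniformly at its turn. Fitness is a Boolean threshold gate on the
concentration of the strain's *sensed* molecule at its own square:
`base_fitness` at or below the threshold, `base_fitness + fitness_gain`
(clamped to 1) strictly above it. There is no graded dose–response: the gate
models strong, switch-like promoter activation.

Two coupling chemistries share this machinery. In the quorum-sensing model
(QSMM) each strain constitutively secretes an acyl homoserine lactone and
gains fitness when its partner's AHL exceeds the threshold; base fitness is
positive (a reduced-growth knockout background) and a strain never senses its
own product. In the metabolite-mediated model (MMM) strains are auxotrophs:
base fitness is 0 and a block can only divide where the partner-secreted
essential metabolite is above threshold. Sensing consumes nothing in either
model; for metabolites this is a simplification (uptake would deplete the
field) chosen for symmetry between the two chemistries.

Coupling topologies are fixed-point-free permutations: mutual for two
strains, the ring 1→3, 2→1, 3→2 for three (the arrow meaning "is sensed
by"), and the cyclic shift for larger consortia.

## Parameters, units, defaults

| parameter | default | unit | note |
|---|---|---|---|
| Δt | 10 | min | one FTCS + decay + division round |
| block area | 10 | mm² | ΔL = √10 mm |
| cells per block | 10⁸ | cells | sets per-block secretion |
| D (AHL) | 8×10⁻¹⁰ | m²/s | = 0.048 mm²/min in agar |
| D (metabolite) | 5×10⁻¹⁰ | m²/s | maltose-like small metabolite |
| decay k | 4.6×10⁻⁴ | /min | AHL lactonolysis scale |
| secretion | 1.6×10⁻² | nM·block⁻¹·min⁻¹ | = 1.6×10⁻¹⁰ nM·cell⁻¹·min⁻¹ × 10⁸ |
| threshold | 5 | nM | modular QS receiver sensitivity scale |
| fitness gain | 0.05 | probability | additive above threshold |
| base fitness | 0.25 | probability/step | Δt/generation-time × growth ratio |
| band-pass window | 10–200 | nM | = 0.01–0.2 µM, boundaries inclusive |

Experimentally tractable ranges, used by the sweeps: secretion 10⁻⁴–10⁻¹
nM/block/min (promoter strength), threshold 10⁻¹–10⁴ nM (receiver module
choice), fitness gain 0.01–0.1 (knockout choice via the FBA screen).

All diffusivities are supplied in m²/s (the unit of tabulated measurements)
and converted once, by `convert_diffusivity()`, to mm²/min (×6×10⁷); fields
are always nM, lengths mm, times min. Keeping a single conversion routine,
with unit-suffixed configuration keys (`dt_min`, `D_m2_per_s`, ...), is a
deliberate guard against silent unit bugs.

The default base fitness 0.25 follows the strain-design formula
`base_fitness(dt, generation_time, ratio) = (dt/generation_time)·ratio` with
a 20-min *E. coli* generation time and a growth ratio of 0.5, the midpoint of
the 0.30–0.90 screening window. When a genome-scale model is supplied, the
generation time can instead be derived from the wild-type FBA optimum as
`ln(2)/µ` (`generation_time_from_growth()`); it is a plain configuration
parameter otherwise.

## Numerical choices

**Stability.** The 2D von Neumann criterion for explicit FTCS is
`s = D·Δt/ΔL² ≤ 1/4`. The AHL defaults give `s = 0.048`; `check_stability()`
reports `s` per molecule and every configuration constructor rejects unstable
parameter sets rather than warning. With `s ≤ 1/4` the update is a convex
combination of neighbour values, so non-negativity is preserved exactly.

**Boundaries.** Zero-flux (reflective) by default: a plate rim neither
absorbs nor leaks signal, and conservation of ΣU to machine precision gives
the test suite a crisp invariant. An absorbing alternative is available per
molecule (`boundary = "absorbing"`).

**Decay discretisation.** Forward-Euler `(1 − kΔt)` rather than the exact
exponential, consistent with the explicit diffusion step; at `kΔt = 0.0046`
the per-step relative error against `exp(−kΔt)` is below 2×10⁻⁵, far
smaller than any biological uncertainty in k.

**Operation order.** Secretion → diffusion → decay, then division. Sources
feed the field before transport, decay acts on the transported field, and
fitness reads the freshest concentrations. Within-step order matters at the
per-mille level only, but fixing it makes trajectories reproducible.

**Division scheduling.** Asynchronous by default: occupied squares are
processed in a freshly shuffled order and each division takes effect
immediately, so later blocks see updated occupancy and two parents can never
claim one square — no conflict rule is needed. A synchronous-lottery
alternative (`update_order = "synchronous_lottery"`: all parents draw
against start-of-step occupancy, contested squares resolved by lottery) is
provided as a behavioural switch; newly created blocks never divide within
their birth step under either mode, preserving "one division per generation
time on average". The division probability draw and the neighbour choice are
separate uniform draws; a block whose draw succeeds but which has no empty
neighbour simply does not divide.

**Reproducibility.** One root integer seed determines everything: the
shuffle order, the division draws, the target choices, and (for random
seeding) the initial placement. Batch experiments derive one seed per run
from the root seed and the run index (a fixed linear-congruential mix kept
below 2³¹); re-running any assay with the same root seed is bit-identical,
and `run_manifest()` records the resolved configuration plus output
checksums so a run can be replayed byte-for-byte.

**Conventions.** Coordinates are 0-based with x = column and y = row,
including in snapshot files (row y, column x). Threshold comparison is
strict (`conc > threshold` gains fitness) because the gate is described as
activation *above* a threshold; the band-pass window is inclusive on both
boundaries so that its printed endpoints fluoresce. Degenerate inputs —
empty grids, zero steps, zero-rate producers, all-occupied lattices — are
exercised in the test suite and return the obvious fixed points rather than
errors.

## The assays

**Band-pass patterning.** Sender blocks at the grid centre (2×2 cluster by
default; a single-sender layout is a flag) secrete into a static lawn of
receivers filling every other square; receivers fluoresce while their local
concentration is inside the window. Nothing grows, so the assay is fully
deterministic. The pattern is called stable at the first step of a run of 6
consecutive identical fluorescence masks (one hour) — short against the
multi-day horizon, long against step-to-step transients. Ring extents are
Euclidean distances from receiver centres to the nearest sender centre,
floored to whole blocks, reported both in blocks and on the model's nominal
3-mm resolution scale. On a closed lattice a bounded source with decay
drives the field toward a fixed profile, which is what makes a stable mask
possible at all.

**Preferential growth.** Two coupled strains are seeded in parallel lines
and every division is classified by the sign of its child-minus-parent
displacement along the line-joining axis: toward the partner, away, or
neutral (lateral). The default geometry places the lines at rows 5 and 15 of
a 21×21 grid (separation 10) and runs 14 steps. That specific combination is
a capacity argument: the fastest possible front advances at most
`max fitness = 0.30` rows/step, i.e. 4.2 rows in 14 steps, which is less
than the 5 rows to either rim and less than the 4.5 rows each strain can
claim between the lines. No front can hit a wall or the opposing front
inside the assay window, so toward/away counts measure *growth rates*, not
space exhaustion, and are symmetric in distribution when coupling is absent
— the control the assay is judged against. (With the lines 4 rows apart on
the same grid, the middle saturates within a few steps and away-counts
dominate for purely geometric reasons, which would confound the direction
statistic; that configuration remains available through
`seed_parallel_lines()` for pattern work.) Summaries report per-strain mean
toward/away/neutral counts, the pooled toward/away ratio, and a one-sided
Welch test of toward > away across runs — the test is over replicate runs,
not pooled events, so between-run variability is respected.

**Sweeps and grid search.** `single_parameter_sweep()` varies one Strain-1
parameter (secretion, threshold, or gain) with partners at defaults, 4
blocks per strain seeded randomly, 100 steps and 100 replicate runs per
value by default; `grid_search()` crosses all three axes (secretion and
threshold log-spaced, gain linear, 4 points each) at 50 steps. Every
(point, run) pair gets its own derived seed, so points are statistically
independent; comparisons between points therefore carry seeding noise as
well as parameter effect, which the summary's per-point dispersion columns
make visible.

## Strain design by FBA

The framework assumes strains whose base growth is deliberately reduced —
single-gene knockouts whose lost function is restored by signal-driven
re-expression. The `strain_design` tools compute wild-type and knockout
growth by flux balance analysis (maximise the biomass flux subject to
steady-state mass balance and bounds), evaluate gene–reaction boolean rules
(`and`/`or`/parentheses) to disable reactions orphaned by a knockout, and
shortlist candidates whose growth ratio falls in [0.30, 0.90] — below it the
strain is crippled or dead (ratios < 10⁻⁶ are called lethal), above it the
signal has nothing to restore. The linear programmes are solved by an
in-package dense two-phase simplex with Bland's anti-cycling rule: knockout
LPs are routinely degenerate, and exactness on small problems matters more
here than large-scale speed. SBML Level-3/FBC models can be imported for
realistic screens; unit tests run on generated toy networks.

`make_toy_gsmm(target_ratios)` builds those networks with knockout ratios
that are *exact by construction*: lethal genes gate serial chain steps,
neutral genes gate one copy of a duplicated step, and partially deleterious
genes gate parallel capacity shares into the biomass precursor. This gives
the screen an oracle that is independent of the LP path being tested. The
construction requires the (1 − ratio) shares of partial genes to sum to at
most 1; richer ratio sets need a different network family and are rejected
explicitly.

## What the defaults can and cannot show

The default parameter set is internally consistent as a transport model but
operates in a *weak-field regime*, and honest use of the package requires
knowing this. A 2×2 cluster of blocks secreting at the default
1.6×10⁻² nM/block/min against the default decay saturates near 3.4 nM at the
source (the continuum estimate `U(r) = (Q/2πD)·K₀(r/λ)` with decay length
λ = √(D/k) ≈ 10.2 mm ≈ 3.2 blocks agrees with the lattice simulation,
which the test suite computes). That peak sits below both the
5 nM default induction threshold and, by an order of magnitude, the
10–200 nM band-pass window. Consequences, all of which the test suite and
acceptance script compute rather than assume:

* the default band-pass assay reports an empty, trivially stable mask — the
  documented ring geometry (tested with a source two orders of magnitude
  stronger) needs sources or windows matched to the achievable amplitude;
* in growth assays, threshold crossings first occur where blocks are already
  densely packed, because the field accumulates in proportion to local
  colony mass — and enclosed blocks cannot divide, so the fitness boost
  often cannot express demographically; at default rates the secretion knob
  leaves trajectories literally unchanged over 100 steps;
* MMM auxotrophs, with base fitness 0, never start growing at default
  amplitudes.

Users studying coupling phenomenology should therefore either raise
secretion rates, lower thresholds (the 10⁻¹ nM end of the studied range
engages within a few steps), or shrink the arena — and treat the defaults as
a faithful record of the weak-field operating point rather than a
demonstration regime. The mechanism tests in the suite exercise coupling at
such reachable points (e.g. threshold 0.1 nM beside a 0.1 nM/block/min
producer), where partner presence demonstrably raises growth.

## Problem sizes

The shipped tests and the acceptance script run at desk scale by choice:
21×21 lattices (the band-pass ring never approaches the rim on it), 100
replicate runs for directional statistics, 25 runs per sweep point, 10⁴
single-step trials for the division-probability calibration, and toy
metabolic networks of a handful of genes. All of these are plain function
arguments; plate-scale lattices and genome-scale screens change nothing but
wall-clock time, except that the dense simplex is not meant for
genome-scale LPs.

## Known limitations

No cell death, dormancy or motility; no nutrient limitation beyond lattice
exhaustion; no advective flow; no intracellular gene-expression dynamics
(the Boolean gate jumps instantaneously with local concentration); no AHL
cross-talk between channels (molecules are opaque orthogonal labels); no
consumption of sensed molecules; single occupancy per square with a fixed
block size. The coupling range is bounded by the signal decay length
(~10 mm for the AHL defaults), so coordinated behaviour across larger
distances would require relay or feedback mechanisms outside this model.
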