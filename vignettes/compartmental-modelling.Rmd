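---
title: "Compartmental modelling with cabletree: models, numerics, design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Compartmental modelling with cabletree: models, numerics, design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cabletree)
```

## The problem and the architecture

`cabletree` simulates the electrical behaviour of single neurons with the
classic compartmental approach: a dendritic morphology is cut into
*segments* (the biological description), each segment becomes a
*compartment* (an RC node coupled axially to its parent), and the branched
cable equation is integrated implicitly over the resulting tree. The
package is deliberately organised as a federation of small, separately
testable components, mirroring how mature simulators in this field
structure themselves:

* a **model container** holding the biological model as a slash-addressed
  tree (`/cell/soma`, `/Purkinje/segments/b1s06[182]`) and translating
  biological quantities to mathematical ones,
* a **channel library** (Hodgkin–Huxley gate kinetics) shipped in a
  declarative model file,
* a **solver** that compiles the tree to flat arrays and integrates it,
* an **experiment layer** (fixed-step scheduler, text output sinks,
  event-driven synapses),
* readers for a declarative model dialect (**NDF**) and a small legacy
  **SLI** command subset,
* an interactive **shell**, and an **EM contour importer**.

The container, not the solver, owns the biology: solvers see only
compartments, conductances and currents. That separation is what the tests
exploit — every numerical claim is checked against an oracle that bypasses
the implementation (dense linear algebra, closed forms, brute-force graph
walks).

## Specific versus actual parameters

Membrane properties are stored as *specific* values as reported in the
literature: `RM` (Ω·m²), `CM` (F/m²), `RA` (Ω·m), plus the geometry `DIA`
and `LENGTH` (m). `specific_to_actual()` scales them to one compartment:

* cylinder (`LENGTH > 0`): area `a = π·DIA·LENGTH`, `Cm = CM·a`,
  `Rm = RM/a`, `Ra = 4·RA·LENGTH/(π·DIA²)`;
* sphere (`LENGTH = 0`): `a = π·DIA²`, `Ra = RA/(π·DIA/2)`.

These formulas are the package's normative convention, tested for
dimensional consistency (`Rm·a = RM`, `Cm/a = CM` to machine precision).
Legacy SLI scripts specify *actual* values directly; segments created by
`sli_load()` are flagged accordingly and their `Cm`, `Em`, `InitVm`,
`Inject`, `Ra`, `Rm` pass to the solver bit-exactly, bypassing the scaling
path entirely. The two parameterisations therefore never mix within one
segment.

```{r}
con <- model_container()
create_cell(con, "/cell")
create_segment(con, "/cell/soma")
set_parameters(con, "/cell/soma", list(
  Vm_init = -0.068, RM = 1.0, RA = 2.5, CM = 0.0164,
  ELEAK = -0.08, DIA = 2e-5, LENGTH = 4.47e-5, INJECT = 1e-9))
specific_to_actual(con, "/cell/soma")
```

All quantities are SI throughout (V, s, m, Ω, F, S, A); nothing is ever
stored in mV or µm.

## The cable equation and its discretisation

Each compartment obeys

$$C_m \frac{dV_i}{dt} = \frac{E_m - V_i}{R_m} + I_{inj}
  + \sum_{j \sim i} g_{ij}(V_j - V_i)
  - \sum_c g_c (V_i - E_c) - g_s (V_i - E_s),$$

with axial coupling between child `c` and parent `p` given by the half-Ra
convention `g = 2/(Ra_c + Ra_p)` (each compartment contributes half of its
axial resistance to the link). A single compartment has no axial term.

Integration is Crank–Nicolson with staggered gate updates, the scheme
inherited from the fast implicit solvers this package emulates:

1. **Gates.** Each Hodgkin–Huxley gating particle `x` follows
   `dx/dt = α(V)(1-x) − β(V)x`. Per step the rates are frozen at the
   current membrane potential — which is the gate's half-step midpoint in
   the staggered arrangement — and the update is the exact exponential
   `x ← x_∞ + (x − x_∞)e^{−dt/τ}`, clamped to `[0, 1]`.
2. **Membrane.** The linear system for `V^{n+1}` uses the trapezoidal
   average of the passive, axial and channel terms, with channel
   conductances held at their half-step values and synaptic conductance
   evaluated at both step ends. The matrix is symmetric with nonzeros only
   on the diagonal and parent links.
3. **Hines elimination.** Compartments are numbered canonically: parents
   before children, siblings sorted lexicographically by path, soma first.
   The ordering is therefore a function of the tree alone, making
   trajectories independent of model-construction order (tested). One
   elimination sweep from the last compartment toward the root and one
   back-substitution solve the system exactly with no fill-in;
   `hines_solve()` is exported and verified against dense `solve()` on
   random trees to below `1e-10` relative error.

The scheme is unconditionally stable (tested at `dt = 10·R_mC_m`) and
second order: the acceptance run measures a maximum deviation of order
`1e-9` V from the closed-form RC charging curve at `dt = 1e-5` s, and an
error ratio of 4.00 when `dt` halves.

**Numerical guards.** A step that produces a non-finite potential, or any
`|V| > 1` V, aborts with the offending compartment named — a biophysical
model that leaves ±1 V has diverged, not depolarised. `advance()` refuses
to run backwards in time. The default `dt = 1e-5` s suits membrane time
constants of ~10 ms and squid-speed gates; halve it when checking
convergence of spike counts.

## Channel kinetics and the shipped library

Rate functions come in the three classic shapes — `linoid`
(`A·(offset−V)/(e^{(offset−V)/scale}−1)`), `exponential`, `sigmoid` — with
absolute-voltage offsets. The linoid pole is removable; within `1e-9·scale`
of it the limit `A·scale` is returned, and the two branches agree to
`1e-6` relative at the boundary (tested from both sides).

`channels/hodgkin-huxley.ndf` ships squid-axon `/na` (m³h, `GBAR` 1200
S/m², `EREV` +45 mV) and `/k` (n⁴, 360 S/m², −82 mV) prototypes with the
standard kinetics at 6.3 °C, rest at −70 mV. With these channels on the
worked-example soma and 1 nA of sustained injection the model fires
repetitively (10 spikes in 0.1 s at both `dt = 1e-5` and `5e-6` s in the
acceptance run). Temperature scaling (Q10) and tabulated rates are out of
scope. Gates are initialised to steady state at `InitVm` on reset, so a
model at its resting potential starts in equilibrium rather than with a
start-up transient.

## Synapses and event delivery

A synapse is a dual-exponential conductance normalised so that a single
event peaks at exactly `GMAX` (peak rather than unit-area normalisation —
the convention had to be chosen, and peak normalisation makes `GMAX`
directly interpretable as the observed peak conductance). Defaults:
`TAU1 = 1` ms, `TAU2 = 2` ms, `EREV = 0` V. When the two time constants
coincide the kinetics degenerate to the alpha function
`g = GMAX·(t/τ)·e^{1−t/τ}`, handled as an explicit special case.

Implementation is a two-accumulator exponential recursion: superposition
of arbitrarily many events costs O(1) per step, and each event is injected
at its *exact* offset inside the step rather than snapped to the grid —
this is why the recursion matches the closed form to ~`1e-13` relative
instead of the ~1 % a grid-snapped update would give at `dt/τ = 0.01`.
Event trains are YAML sequences of seconds (`load_events()`), sorted on
load with a warning if out of order. Delivery is serial and in-process;
parallel event transport between processes is explicitly out of scope.

## Scheduler and outputs

`run_simulation()` compiles the cell, builds the schedulee list (solver,
output sinks) and advances every participant in lock step: the loop runs a
step counter, sets `currentTime = k·dt` (avoiding accumulated float
drift), and advances each schedulee to it until `currentTime ≥ duration` —
`ceiling(duration/dt)` steps, so a half-second run at `dt = 1e-5` s yields
exactly 50,000 rows. Sinks write headerless whitespace-separated text,
time first, `%.10g`, one row per advance; labels stay with the sink object.
A sink with no outputs records a time-only column; a sink never advanced
leaves an empty file.

## File formats

**NDF dialect.** The declarative model format is line-oriented: header
`#!ndf`; blocks `CELL`/`SEGMENT`/`CHANNEL`/`SYNAPSE` … `END`;
`PARAMETER <name> <value>` (strings double-quoted); `CHILD
<file>::<proto>` library imports; `#` comments; indentation ignored. One
keyword was added beyond the minimal set: `GATE <name> <power> <alpha>
<beta>`, each rate as `<form A offset scale>`, because channel kinetics
must be expressible for the shipped library to be self-contained. The
grammar is a documented local dialect — it does not aim to parse the
original simulator's native files. Rendering is canonical (document order,
parameters alphabetical, numbers `%.17g` so doubles round-trip exactly):
equal documents render byte-identically, and `export_ndf()` followed by
`read_ndf()` is the identity on the model tree (tested on 100 random
fixtures). Exports inline imported prototypes rather than emitting `CHILD`
references, since an imported copy may have diverged from its library
source.

**SLI subset.** Exactly four verbs (`create`, `setfield`, `reset`,
`step`); anything else is an explicit unsupported-command error naming the
verb. Typeset-glued forms (`setfield/cell/soma Cm …`) are accepted by
greedy token parsing, which also lets `reset step 0.5 -time` share a line.
`reset`/`step` are recorded as pending directives, executed only when the
shell user later issues `run`; `step T -time` means `T` seconds, a bare
`step T` counts steps, and `T/dt` is rounded half-up to a step count.

**Contour stacks.** Plain text: `section <idx> <thickness>` then `x y`
vertex lines. The equivalent-cylinder reduction preserves total thickness
(`LENGTH = Σh_i`) and lateral membrane area
(`DIA = Σ p_i h_i / (π·LENGTH)`), the quantity that matters for passive
cable loading; a volume-preserving alternative was considered and not
implemented. Area conservation holds to machine precision and the
reduction is covariant under uniform scaling (both tested). Only
unbranched stacks are supported: branching inside a traced series is
ambiguous without an explicit topology, so it is left to the modeller to
split stacks at branch points.

## Morphology queries

`segment_tips()` lists segments with no segment children in depth-first
pre-order. `morphology_summarize()` annotates every segment with
`SOMATOPETAL_BRANCHPOINTS`: the number of *strictly intermediate* nodes on
the walk from the segment toward the soma that carry ≥ 2 segment children
— "between the segment and the soma" is read as excluding both endpoints,
so the soma itself never counts, and a tip directly below a branching node
counts that node. The annotation is only readable after the summarise pass;
before it, `show_parameter()` raises an unknown-parameter error rather than
silently returning 0. Both operations are validated against brute-force
traversals on 100 random trees, and the count is monotone non-decreasing
along any root-to-tip path by construction.

Structural conventions: a segment's electrical parent is its nearest
*segment* ancestor by path — cells are namespaces, not electrical nodes —
and a cell's soma is its first root segment. Unknown parameter names are
stored with a logged warning instead of rejected, so library files can
carry annotations that future versions interpret.

## What the fixtures emulate — and what they do not

`fx_random_tree(n, seed)` grows a tree by uniform attachment with specific
parameters drawn around typical somatic values (`DIA` ∈ [10, 30] µm,
`LENGTH` ∈ [20, 80] µm, `RM` ∈ [0.7, 1.3] Ω·m², `RA` ∈ [1.5, 3.5] Ω·m,
`CM` ∈ [0.01, 0.025] F/m²; `ELEAK` −80 mV, `Vm_init` −68 mV). These are
deliberate exercisers of the *algorithms* — path handling, ordering,
elimination, round-trips — not statistical models of real arbours: they
have no tapering, no realistic branch-order statistics, no spines, and
their diameters are somatic-scale throughout. Passing tests therefore
establish correctness of the machinery, not biological realism of any
particular model. `fx_poisson_train(rate, T, seed)` produces homogeneous
Poisson spike times; `fx_circle_stack(r, h, N)` produces regular-polygon
contour stacks whose analytic cylinder is known. Every fixture seeds a
private RNG stream and restores the caller's, so identical arguments give
byte-identical fixtures.

Problem sizes in the shipped tests and the acceptance script — trees of up
to 200 segments, 100-fold round-trip repetitions, half-second
single-compartment runs at `dt = 1e-5` s — were chosen as the smallest
sizes at which each property is genuinely exercised (several membrane time
constants, multiple spikes, deep and wide trees) while keeping the whole
suite comfortably interactive.

## The shell

`cable_shell()` wires the components behind the printed command surface:
`list components`, `ndf_load`, `sli_load`, `morphology_summarize`,
`show_parameter`, `set_runtime_parameter`, `add_output`, `run`, `explore`,
`quit`, accepting both spaced and typeset-glued spellings. It is a pure
router — every command has byte-identical effect to the corresponding API
call (tested) — and `explore` prints an indented text tree with
per-segment parameters in place of a graphical inspector. Errors from a
bad load are echoed and noted on the component's registry entry; the
component itself stays loaded, since a failed file load is a per-file
condition. `show_parameter` prints `<path> <name> = <value>`, a format
chosen here since none is prescribed.

## Known limitations

Single cells only (no network matrices, no parallel execution); fixed
`dt`; `Vm` is the only addressable state variable so far; no calcium
dynamics or kinetic pathways; the NDF dialect is local; the SLI loader
covers exactly the four-verb subset; contour import handles unbranched
stacks in the package's own text format, not the microscope tool's native
XML.
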