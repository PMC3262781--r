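# cabletree

Compartmental modelling of single neurons in R: a model container for
biological morphologies, an implicit branched-cable solver with
Hodgkin–Huxley channels, an event-driven synapse and scheduler layer, a
declarative model file format with a shipped channel library, a legacy SLI
script loader, an interactive shell, and an importer that turns
serial-section EM contour stacks into equivalent cylinders.

It is written for computational neuroscientists who want a small,
fully-inspectable simulator — every component is an ordinary R object, and
every numerical claim in the test suite is checked against an independent
oracle (closed forms, dense linear algebra, brute-force traversal).

## The model

A dendritic morphology is stored as a tree of *segments* addressed by
slash paths (`/cell/soma`, `/Purkinje/segments/b1s06[182]`). Segments carry
*specific* membrane parameters as reported in the literature — `RM` (Ω·m²),
`CM` (F/m²), `RA` (Ω·m), geometry `DIA`, `LENGTH` (m) — which the container
scales to the *actual* values of one compartment:

    area = π·DIA·LENGTH        (cylinder; sphere formulas for LENGTH = 0)
    Cm = CM·area    Rm = RM/area    Ra = 4·RA·LENGTH/(π·DIA²)

Each compartment then obeys the cable equation

    Cm dV/dt = (Em − V)/Rm + I_inj + Σ g_axial (V_parent/child − V)
               − Σ g_chan (V − E_chan) − g_syn (V − E_syn)

with axial coupling `g = 2/(Ra_child + Ra_parent)`. The system is
integrated by Crank–Nicolson with staggered exponential gate updates and
solved per step by Hines tree elimination — one sweep to the root, one
back-substitution, no fill-in — which is exact for the tree-structured
matrix and unconditionally stable. Channels follow Hodgkin–Huxley kinetics
(`α`, `β` in linoid / exponential / sigmoid form); the shipped library
`channels/hodgkin-huxley.ndf` provides squid-axon `/na` (m³h) and `/k`
(n⁴) prototypes in SI units. Synapses are dual-exponential conductances
normalised to peak `GMAX`, driven by YAML spike-event files with events
applied at their exact times inside a step.

## A worked example

Build the classic single-compartment demonstration — a cylindrical soma
with squid Na/K channels and 1 nA of sustained current — and run it for
100 ms:

```r
library(cabletree)

con <- model_container()
create_cell(con, "/cell")
create_segment(con, "/cell/soma")
set_parameters(con, "/cell/soma", list(
  Vm_init = -0.068, RM = 1.0, RA = 2.5, CM = 0.0164,
  ELEAK = -0.08, DIA = 2e-5, LENGTH = 4.47e-5, INJECT = 1e-9))

specific_to_actual(con, "/cell/soma")
#> compartment: Cm 4.60608e-11 F  Rm 3.56051e+08 Ohm  Ra 355711 Ohm
#>              Em -0.08 V  InitVm -0.068 V  Inject 1e-09 A

import_child(con, "/cell/soma", "channels/hodgkin-huxley.ndf::/k")
import_child(con, "/cell/soma", "channels/hodgkin-huxley.ndf::/na")

res <- run_simulation(con, "/cell", duration = 0.1, dt = 1e-5)
v <- as.matrix(read.table(res$file))
nrow(v)                                        # 10000 rows: t and Vm
sum(v[-1, 2] > 0 & v[-nrow(v), 2] <= 0)        # 10 upward 0 V crossings
range(v[, 2])                                  # -0.0776  0.0328 V
```

The scaled values are the soma's actual capacitance (46 pF), input
resistance (356 MΩ) and axial resistance; the run writes a headerless
two-column text file (time, somatic `Vm`, SI units) and the cell fires ten
action potentials in the 100 ms window, peaking near +33 mV.

The same session is available interactively:

```r
sh <- cable_shell()
shell_batch(sh, lines = c(
  "ndf_load cells/toy/ball-and-stick.ndf",
  "morphology_summarize /toy",
  "show_parameter /toy/soma/d1/d2 SOMATOPETAL_BRANCHPOINTS",
  "add_output /toy/soma Vm",
  "run /toy 0.001",
  "explore /toy"))
```

or from a legacy script: `sli_load()` imports the four-verb
`create`/`setfield`/`reset`/`step` subset, storing solver-scale fields
bit-exactly and recording `reset`/`step` as pending directives for a later
`run`.

## Layout

    R/                  implementation (container, channels, solver,
                        experiment, ndf, sli, shell, contours, fixtures)
    inst/library/       shipped model library (channels/, cells/toy/)
    inst/extdata/       small text fixtures (legacy SLI listing)
    tests/testthat/     unit, property and acceptance tests
    scripts/            acceptance script
    vignettes/          methods vignette (model, numerics, design choices)
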