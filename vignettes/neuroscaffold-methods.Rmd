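---
title: "neuroscaffold: the meta-model, interpreters and reference simulator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{neuroscaffold: the meta-model, interpreters and reference simulator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neuroscaffold)
```

Neuroscience tools constantly juggle heterogeneous artifacts — segmented
morphology reconstructions, surface meshes, network models, recorded traces —
each in its own format. `neuroscaffold` is the headless core of a middleware
layer for such tools: a small, domain-agnostic meta-model into which any of
these artifacts can be mapped, plus the machinery around it (interpreters for
domain formats, an instantiation engine with lazy loading, a reference
simulator with an experiment lifecycle, deterministic fixture generators and
a CLI). This vignette explains the design: the model and its assumptions, the
parameters that matter, the numerical choices, and what the package's tests
do and do not demonstrate.

## The meta-model

Three concepts from object-oriented programming carry everything:

* **Types** are schema elements. Concrete kinds: `composite` (contains
  variables of other types), `array` (a fixed-size population of one element
  type), `import` (a placeholder for data not yet loaded), `state_variable`
  and `parameter` (simulation quantities with units), `primitive`, and
  `visual_group` (a bag of geometry).
* **Variables** are named slots of a given type.
* **Values** fill slots: scalars with units, spheres/tapered
  cylinders/meshes (coordinates in µm), recorded time series, and pointers
  (path strings).

A model bundles libraries of types, root variables, data-source declarations
and queries. Because nothing in the meta-model is specific to neuroscience,
one library can describe a compartmental neuron while another describes a
collection of microscopy images; the rest of the machinery treats both
identically.

### Inheritance and composition

Types support **single** inheritance: lineage is a list, and the field-merge
rule stays unambiguous. The merge (`effective_fields()`) works root-down with
nearest-descendant override, checked name-wise — the convention of mainstream
object systems. A deliberate restriction: a subtype may override an inherited
variable's *values* but not redeclare its *type*; redeclaration is reported
by validation. Allowing covariant type overrides would make instantiation
dependent on resolution order, and nothing in the intended use cases needs
it.

### Addressing and validation

Instances and model nodes are addressed with dot-separated paths; array
elements use zero-based bracket indices (`net.excitatory[2].v`), matching
the zero-based array semantics of the JavaScript front-ends this layer is
designed to feed. Failed resolution names the deepest valid prefix, which in
practice is the difference between a usable and a frustrating error message.

`validate_model()` returns findings (severity, rule, path, message) as data
rather than raising on the first problem, so a CLI or UI can report every
defect at once; ordering is deterministic (path, then rule). Exceptions are
reserved for operations whose contract is already violated, e.g. resolving a
path that does not exist.

### Queries

Query semantics are fixed to the simplest composition that covers the
intended "interrogate a connected data source" use: an ordered conjunction
of `(field, predicate, operand)` filters with stable result order. An empty
filter list is the identity. Only an in-memory backend ships with the
package; remote backends would register behind the same declaration surface.

## Serialization

Documents are JSON (UTF-8) with a top-level `"schemaVersion": "1"`. Two
properties are load-bearing:

* **Canonical output.** Object keys are sorted and floats are printed with
  17 significant digits — enough to reproduce any double exactly (15 digits
  is the shortest form that *displays* faithfully, but loses the last bit on
  re-parse). Equal structures therefore serialize to byte-identical text,
  which makes "did anything change?" a file comparison.
* **Absence over null.** Optional fields (a missing supertype, parameter
  bounds, an unresolved import's future content) are omitted, never written
  as `null`; the reader treats absence as the default. Required keys are
  checked explicitly so a truncated document fails loudly, with the missing
  key named.

Projects persist an opaque `viewState` map verbatim: what an embedding
application considers "the current state" is its business, not the
middleware's. Results export is CSV (RFC 4180 quoting, `.` decimal
separator), one time column plus one column per watched variable, headers
carrying full paths and units, numbers again at full round-trip precision.

## Interpreters

### SWC morphologies

The SWC dialect read here is the 7-column form: id, structure code, x, y, z,
radius, parent (µm assumed for coordinates and radii — the format itself
declares no units). Geometry is derived per node:

* a **sphere** for every soma node (structure code 1), radius = node radius;
* a **tapered cylinder** (frustum) for every non-root node, spanning parent
  position → node position with `r1` = parent radius, `r2` = node radius —
  a linear taper;
* **no cylinder between two soma nodes**: multi-node somas render as
  spheres only. SWC has several dialects for soma encoding; this choice
  keeps value counts predictable (`#cylinders = #nodes − #roots` whenever no
  soma–soma edges exist, which holds for all generated fixtures).

Children must appear after their parent; forward references are rejected as
dangling parents rather than buffered — a simpler contract surfaced as a
clear error. Unknown structure codes are preserved and rendered as
cylinders.

### OBJ meshes

Only `v` and `f` records are honored; normals, texture coordinates and
materials are ignored silently because only geometry reaches the mesh value.
Indices are 1-based per the OBJ standard and converted to 0-based. Polygons
fan-triangulate into `n − 2` triangles, which conserves area exactly for
planar convex faces (the tests verify this against a shoelace oracle to
1e-9 relative).

### The network dialect

A deliberately small stand-in for full network description languages: named
cell definitions (morphology source + membrane dynamics parameters +
optional per-parameter bounds), populations (cell definition × size) and
weighted cell-to-cell connections. Interpretation produces one array type
per population, one composite cell type per definition — containing the
state variable `v` (mV) and one parameter per dynamics entry — and pointer
pairs for connections. `connectivity_matrix()` reduces connections to a
population-indexed count (or weight-sum) matrix whose total equals the
number of connection records.

## Instantiation, capabilities and lazy loading

`instantiate()` expands a validated model into an instance tree in
declaration order, so two runs produce identical path sets. Capabilities are
injected by type kind: state variables expose unit, initial value and the
recorded series (an explicit *no data* indicator before any simulation —
not an error, because "not simulated yet" is a normal state); parameters
expose unit, current value and bounds-checked assignment; instances holding
geometry expose their values.

Import types yield first-class placeholder instances: they are addressable
and listable before resolution, so a UI or CLI can show what *could* be
loaded. `resolve_import()` runs the registered interpreter on the import's
source and swaps the result in; the update is functional (the function
returns a new tree) rather than mutating in place, which is the natural
contract in R's copy-on-modify semantics and makes idempotence trivial to
state: resolving an already-resolved path returns the tree unchanged. One
level resolves per call; imports nested inside interpreted content remain
placeholders until asked for. The load-bearing property, checked on every
fixture, is that eager interpretation at build time and deferred resolution
produce `identical()` trees.

## The reference simulator

The package substitutes a bespoke leaky integrate-and-fire (LIF) simulator
for the external simulation engines a full deployment would wrap, so the
simulator contract is exercisable offline; the registry
(`register_simulator()`) is written so a wrapper around an external process
could be added without touching the experiment layer. The membrane model:

$$\tau_m \frac{dv}{dt} = -(v - v_\mathrm{rest}) + R_m I_\mathrm{ext}$$

with threshold-and-reset spiking and an optional absolute refractory clamp.
Parameters, with units and fixture defaults: `v_rest` −65 mV, `v_thr`
−50 mV, `v_reset` −65 mV (reset at rest, so the closed-form interspike
interval below applies directly), `r_m` 10 MΩ, `tau_m` 10 ms, `i_ext` in nA,
`t_ref` 0 ms. No unit conversion is performed; units are declared metadata.

Numerical choices:

* **Integrator:** classical fixed-step RK4 from `v(0) = v_rest`. The
  experiment default is `dt` = 0.025 ms; the subthreshold equation is linear,
  so the integrator's fourth-order convergence is directly observable
  (halving `dt` reduces the maximum error ≈ 16×) until rounding noise
  (~1e-13 mV) is reached.
* **Threshold detection:** checked after each full step, spike time recorded
  as the step's end time — no sub-step interpolation. This is a documented,
  deterministic O(dt) bias; at `dt` = 0.01 ms it shifts each interspike
  interval by less than one step.
* **Oracles:** subthreshold, `v(t) = v_rest + R_m I_{ext}(1 − e^{−t/\tau_m})`;
  suprathreshold with reset at rest, the interspike interval is
  `T = t_ref + τ_m ln(R_m I_{ext} / (R_m I_{ext} − (v_thr − v_rest)))`.
  With the defaults and `i_ext` = 2 nA, `T = 10\,\ln 4 ≈ 13.86` ms, i.e. 72
  spikes in a one-second run — the tests require agreement within ±1 spike
  and observe exact agreement.

## Experiments

The experiment lifecycle is a five-state machine, `DESIGN → QUEUED →
RUNNING → {COMPLETED, ERROR}`. The states are artifact-defined: upstream
platforms describe experiment running as asynchronous without enumerating
states, so the machine here is the minimal one that distinguishes "being
configured", "accepted", "executing" and the two terminal outcomes. It
executes synchronously in-process; queue/worker infrastructure is out of
scope, but the state machine is the part such infrastructure would need.
`run_experiment()` never throws: failures (bad `dt`, unknown watched path,
out-of-bounds override) land the experiment in `ERROR` with a message and
empty results — results are non-empty only in `COMPLETED`. Parameter sweeps
are atomic: one out-of-bounds value voids the whole batch, so a half-created
sweep can never exist. `watch_all()` implements "record every membrane
potential in one action" with set semantics.

## Synthetic fixtures: what they emulate, and what they do not

All tests run against generated fixtures; one seed drives all randomness
through a single generator stream, so every fixture is byte-reproducible.

* `generate_swc()` grows a random tree: node 1 is the root soma; each later
  node extends the current tip or, with probability `branching_prob`
  (default 0.3), branches off a uniformly chosen earlier node; radii are
  uniform in (0.1, 5] µm and positions take Gaussian steps (σ = 3 µm) from
  the parent. This emulates the *structure* of segmented reconstructions —
  ids, parent links, branching, tapers — not their biology: no realistic
  branch-angle or diameter statistics, a single soma node, one structure
  code for all neurites.
* `generate_project()` writes a complete project: populations of LIF cells
  (defaults above, drive 2 nA — a regularly spiking regime; `i_ext` bounded
  in [0, 10] nA so bounds checking is exercised), morphologies attached as
  lazy imports, uniformly random connections, and one experiment watching
  every membrane potential (duration 100 ms, `dt` 0.1 ms).

Passing tests therefore demonstrate the machinery's contracts — parsing,
conservation laws, round-trips, determinism, numerical correctness of the
reference simulator — on structurally realistic inputs. They do not
demonstrate robustness to the full variety of real-world SWC/OBJ dialects
(negative-radius sentinels, multi-contour somas, gigantic meshes) or
biological realism of the simulated dynamics.

Problem sizes used by the default test run and the acceptance script: 50
random models for serialization, 20 morphologies of 50–1000 nodes,
population grids up to 10 cells per population, 10 lazy/eager fixture
comparisons, subthreshold traces of 10⁴ samples and a suprathreshold run of
10⁵ steps, and 1000 randomized lifecycle sequences — sizes at which every
property is checked exhaustively in seconds.

## Known limitations

* Single inheritance only; no user-defined capabilities; no reflection over
  host-language objects.
* Only the in-memory data-source backend; conjunctive-only query
  composition.
* One import level resolves per call; recursive resolution is the caller's
  loop (`resolve_all_imports()`).
* The CLI, serialization and instance tree are single-threaded by contract;
  concurrent mutation is out of scope.
* No XMI/EMF compatibility, no transport layer, no rendering — this package
  is the headless core such layers would sit on.
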