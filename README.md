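# neuroscaffold

Neuroscience applications juggle heterogeneous artifacts — segmented
neuronal morphologies, surface meshes, network models, simulation
recordings — each in its own domain format. `neuroscaffold` is a headless
middleware core for building such applications in R: it maps all of these
onto one small, domain-agnostic **meta-model** (Types, Variables, Values,
with single inheritance and composition), and provides the machinery around
it:

* **Model interpreters** for SWC neuronal morphologies (spheres for soma
  nodes, tapered cylinders for segments), Wavefront OBJ meshes
  (fan-triangulated), and a compact network dialect (populations of
  leaky integrate-and-fire cells plus weighted connections).
* **Canonical JSON serialization** of models and projects: sorted keys,
  full-precision floats, byte-stable output, exact round-trips — including
  unresolved imports.
* An **instantiation engine** expanding a model into an addressable
  instance tree (`net.pop1[2].v`, zero-based indices) with capabilities
  injected by type kind, and **lazy loading**: imported types stay
  addressable placeholders until resolved on demand, with eager and
  deferred resolution guaranteed to produce identical trees.
* A **reference simulator and experiment lifecycle**: a leaky
  integrate-and-fire neuron — τₘ dv/dt = −(v − v_rest) + Rₘ I_ext with
  threshold-and-reset spiking — integrated with fixed-step RK4, plus
  experiments (`DESIGN → QUEUED → RUNNING → {COMPLETED, ERROR}`) with
  parameter sweeps, watched variables and CSV export.
* **Deterministic fixture generators** and a small CLI
  (`inst/cli/neuroscaffold.R`).

It is aimed at tool builders who need a tested, offline backbone —
validation, addressing, persistence, lazy loading, simulation bookkeeping —
rather than another visualization front-end.

## Worked example

```r
library(neuroscaffold)

dir <- file.path(tempdir(), "demo")
generate_project(fixture_spec(seed = 1, population_sizes = c(2, 3),
                              n_connections = 4), dir)
project <- read_project_file(file.path(dir, "project.json"))

tree <- instantiate(project$model)
tree
#> <nsc_instance_tree> model 'fixture_model_1': 53 instances

resolve_path(tree, "net.pop1[0].morphology")
#> <nsc_instance import> net.pop1[0].morphology (cells.cd1_morphology) [unresolved import]

tree <- resolve_all_imports(tree)   # lazy loading: morphology subtrees swap in
tree
#> <nsc_instance_tree> model 'fixture_model_1': 203 instances

get_capability_view(resolve_path(tree, "net.pop1[0].v"), "StateVariableCapability")
#> $unit          "mV"
#> $initial_value -65
#> $series        <no data>   (nothing recorded yet)

connectivity_matrix(project$model)
#>      pop1 pop2
#> pop1    1    1
#> pop2    2    0

exp <- run_experiment(project, "exp1")  # watches all 5 membrane potentials
exp$state
#> [1] "COMPLETED"
length(exp$results[["net.pop1[0].v"]]$times)
#> [1] 1001        # floor(100 ms / 0.1 ms) + 1 samples
```

The 53 instances are the network skeleton (2 + 3 cells, each with a membrane
potential, seven dynamics parameters and a morphology placeholder); resolving
the imports adds the 150 geometric values of the two 30-node morphologies.
The connectivity matrix counts the 4 generated connections by (pre, post)
population.

The reference simulator agrees with the closed-form leaky
integrate-and-fire solution: with the defaults (rest −65 mV, threshold
−50 mV, reset at rest, Rₘ = 10 MΩ, τₘ = 10 ms) and a 2 nA drive, the
interspike interval is 10·ln 4 ≈ 13.86 ms:

```r
out <- simulate_lif(neuron_dynamics(i_ext = 2), duration = 1000, dt = 0.01)
length(out$spikes)
#> [1] 72
head(round(out$spikes, 2), 4)
#> [1] 13.87 27.74 41.61 55.48
```

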