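#' Leaky integrate-and-fire neuron parameters
#'
#' Parameter set for the reference single-compartment neuron model
#' integrated by [simulate_lif()]: a leaky membrane
#' \deqn{\tau_m \frac{dv}{dt} = -(v - v_{rest}) + R_m I_{ext}}
#' with threshold-and-reset spiking. When `v` reaches `v_thr` a spike is
#' recorded, `v` is clamped to `v_reset` for the refractory period `t_ref`,
#' and integration resumes.
#'
#' @param v_rest Resting potential (mV).
#' @param v_thr Spike threshold (mV); must exceed `v_rest`.
#' @param v_reset Post-spike reset potential (mV); at most `v_rest`.
#' @param r_m Membrane resistance (MOhm, > 0).
#' @param tau_m Membrane time constant (ms, > 0).
#' @param i_ext External current (nA).
#' @param t_ref Absolute refractory period (ms, default 0).
#' @return An object of class `nsc_neuron_dynamics`.
#' @examples
#' d <- neuron_dynamics(v_rest = -65, v_thr = -50, v_reset = -65,
#'                      r_m = 10, tau_m = 10, i_ext = 2)
#' length(simulate_lif(d, duration = 1000, dt = 0.01)$spikes)
#' @export
neuron_dynamics <- function(v_rest = -65, v_thr = -50, v_reset = -65,
                            r_m = 10, tau_m = 10, i_ext = 0, t_ref = 0) {
  if (tau_m <= 0) nsc_abort("tau_m must be > 0", "nsc_invalid_argument")
  if (r_m <= 0) nsc_abort("r_m must be > 0", "nsc_invalid_argument")
  if (!(v_reset <= v_rest && v_rest < v_thr)) {
    nsc_abort("dynamics require v_reset <= v_rest < v_thr", "nsc_invalid_argument")
  }
  if (t_ref < 0) nsc_abort("t_ref must be >= 0", "nsc_invalid_argument")
  structure(list(v_rest = v_rest, v_thr = v_thr, v_reset = v_reset,
                 r_m = r_m, tau_m = tau_m, i_ext = i_ext, t_ref = t_ref),
            class = "nsc_neuron_dynamics")
}

#' Reference leaky integrate-and-fire simulator
#'
#' Integrates the membrane equation of [neuron_dynamics()] with classical
#' fixed-step fourth-order Runge-Kutta from `v(0) = v_rest`. Threshold
#' crossing is detected after each full step; the spike time is recorded as
#' the step's end time (a deterministic O(dt) bias, no sub-step
#' interpolation), the membrane is reset and held at `v_reset` for `t_ref`
#' ms. The returned series has `floor(duration/dt) + 1` samples starting at
#' time 0. In the subthreshold regime the closed form
#' `v(t) = v_rest + r_m * i_ext * (1 - exp(-t/tau_m))` applies and the RK4
#' trace converges to it at fourth order.
#'
#' @param d A [neuron_dynamics()] parameter set.
#' @param duration Simulated time (ms, >= 0).
#' @param dt Integration step (ms, > 0).
#' @return List with `series` (a [time_series_value()] of the membrane
#'   potential in mV) and `spikes` (numeric vector of spike times in ms).
#' @export
simulate_lif <- function(d, duration, dt) {
  stopifnot(inherits(d, "nsc_neuron_dynamics"))
  if (!is.numeric(dt) || length(dt) != 1L || is.na(dt) || dt <= 0) {
    nsc_abort("dt must be a single number > 0", "nsc_invalid_argument")
  }
  if (!is.numeric(duration) || length(duration) != 1L || is.na(duration) || duration < 0) {
    nsc_abort("duration must be a single number >= 0", "nsc_invalid_argument")
  }
  n <- floor(duration / dt) + 1L
  times <- (seq_len(n) - 1) * dt
  v <- numeric(n)
  v[1] <- d$v_rest
  spikes <- numeric(0)
  drive <- d$v_rest + d$r_m * d$i_ext   # attractor of the linear membrane
  tau <- d$tau_m
  ref_until <- -Inf
  half <- dt / 2
  sixth <- dt / 6
  for (i in seq_len(n)[-1]) {
    t_i <- times[i]
    if (t_i <= ref_until) {            # clamped during the refractory period
      v[i] <- d$v_reset
      next
    }
    v0 <- v[i - 1L]
    k1 <- (drive - v0) / tau
    k2 <- (drive - (v0 + half * k1)) / tau
    k3 <- (drive - (v0 + half * k2)) / tau
    k4 <- (drive - (v0 + dt * k3)) / tau
    vn <- v0 + sixth * (k1 + 2 * k2 + 2 * k3 + k4)
    if (vn >= d$v_thr) {
      spikes[length(spikes) + 1L] <- t_i
      vn <- d$v_reset
      ref_until <- t_i + d$t_ref
    }
    v[i] <- vn
  }
  list(series = time_series_value(times, v, unit = "mV"), spikes = spikes)
}

# ---- experiments --------------------------------------------------------

EXPERIMENT_STATES <- c("DESIGN", "QUEUED", "RUNNING", "COMPLETED", "ERROR")

# legal lifecycle transitions
LEGAL_TRANSITIONS <- list(
  DESIGN = "QUEUED",
  QUEUED = "RUNNING",
  RUNNING = c("COMPLETED", "ERROR"),
  COMPLETED = character(0),
  ERROR = character(0))

#' Create an experiment
#'
#' An experiment is a configured simulation run: parameter overrides applied
#' through the parameter capability, a set of watched state-variable paths,
#' a duration and integration step, and a lifecycle state. The legal state
#' machine is `DESIGN -> QUEUED -> RUNNING -> {COMPLETED, ERROR}`; recorded
#' results are non-empty only in `COMPLETED`. Experiments are executed with
#' [run_experiment()].
#'
#' @param id Experiment id.
#' @param name Human-readable name.
#' @param duration Simulated time (ms).
#' @param dt Integration step (ms).
#' @param watched Character vector of state-variable instance paths to
#'   record.
#' @param parameter_overrides Named list mapping parameter instance paths to
#'   values.
#' @return An object of class `nsc_experiment` in state `"DESIGN"`.
#' @export
new_experiment <- function(id, name = id, duration = 100, dt = 0.025,
                           watched = character(0),
                           parameter_overrides = list()) {
  assert_identifier(id, "experiment id")
  structure(list(id = id, name = name, state = "DESIGN",
                 parameter_overrides = parameter_overrides,
                 watched = unique(as.character(watched)),
                 duration = as.numeric(duration), dt = as.numeric(dt),
                 results = named_list(), error_message = NULL),
            class = "nsc_experiment")
}

#' Transition an experiment's lifecycle state
#'
#' Enforces the lifecycle state machine; an illegal transition raises an
#' illegal-state error and leaves the experiment unchanged.
#'
#' @param exp An [new_experiment()].
#' @param to Target state.
#' @return The updated experiment.
#' @export
experiment_transition <- function(exp, to) {
  stopifnot(inherits(exp, "nsc_experiment"))
  if (!to %in% EXPERIMENT_STATES) {
    nsc_abort(sprintf("unknown experiment state '%s'", to), "nsc_illegal_state")
  }
  if (!to %in% LEGAL_TRANSITIONS[[exp$state]]) {
    nsc_abort(sprintf("illegal experiment transition %s -> %s", exp$state, to),
              "nsc_illegal_transition")
  }
  exp$state <- to
  exp
}

find_experiment <- function(project, experiment_id) {
  for (i in seq_along(project$experiments)) {
    if (project$experiments[[i]]$id == experiment_id) return(i)
  }
  nsc_abort(sprintf("project '%s' has no experiment '%s'", project$id, experiment_id),
            "nsc_unknown_experiment")
}

#' Replace an experiment inside a project
#'
#' @param project A [new_project()].
#' @param exp The updated experiment (matched by id).
#' @return The updated project.
#' @export
set_experiment <- function(project, exp) {
  i <- find_experiment(project, exp$id)
  project$experiments[[i]] <- exp
  project
}

#' Run an experiment
#'
#' Executes an experiment against the project's instantiated model:
#' transitions it through `QUEUED` and `RUNNING`, applies the parameter
#' overrides through the parameter capability (bounds-checked), runs the
#' registered simulator once per watched cell, attaches one recorded time
#' series per watched path and lands in `COMPLETED`. Any failure —
#' invalid step size, unknown path, out-of-bounds override — lands the
#' experiment in `ERROR` with a message and empty results; no condition is
#' thrown (the asynchronous-style contract of the lifecycle).
#'
#' @param project A [new_project()] whose model validates cleanly.
#' @param experiment_id Id of an experiment in state `DESIGN` or `QUEUED`.
#' @param simulator_id Id of a registered simulator (default `"lif"`).
#' @return The updated experiment (`COMPLETED` or `ERROR`). Use
#'   [set_experiment()] to store it back into the project.
#' @export
run_experiment <- function(project, experiment_id, simulator_id = "lif") {
  stopifnot(inherits(project, "nsc_project"))
  exp <- project$experiments[[find_experiment(project, experiment_id)]]
  if (!exp$state %in% c("DESIGN", "QUEUED")) {
    nsc_abort(sprintf("experiment '%s' cannot run from state %s", exp$id, exp$state),
              "nsc_illegal_state")
  }
  if (exp$state == "DESIGN") exp <- experiment_transition(exp, "QUEUED")
  exp <- experiment_transition(exp, "RUNNING")
  result <- tryCatch({
    if (!is.numeric(exp$dt) || length(exp$dt) != 1L || is.na(exp$dt) || exp$dt <= 0) {
      nsc_abort(sprintf("invalid integration step dt = %s; dt must be > 0", exp$dt),
                "nsc_invalid_argument")
    }
    if (exp$duration < 0) {
      nsc_abort("duration must be >= 0", "nsc_invalid_argument")
    }
    simulator <- get_simulator(simulator_id)
    tree <- instantiate(project$model)
    for (p in names(exp$parameter_overrides)) {
      tree <- set_parameter_value(tree, p, exp$parameter_overrides[[p]])
    }
    results <- named_list()
    for (wp in exp$watched) {
      inst <- resolve_path(tree, wp)
      if (!"StateVariableCapability" %in% inst$capabilities) {
        nsc_abort(sprintf("watched path '%s' does not address a state variable", wp),
                  "nsc_capability_not_supported")
      }
      cell_path <- sub("\\.[A-Za-z_][A-Za-z0-9_]*$", "", wp)
      dynamics <- cell_dynamics(tree, cell_path)
      sim <- simulator(dynamics, exp$duration, exp$dt)
      results[[wp]] <- sim$series
    }
    results
  }, error = function(e) e)
  if (inherits(result, "error")) {
    exp <- experiment_transition(exp, "ERROR")
    exp$error_message <- conditionMessage(result)
    exp$results <- named_list()
  } else {
    exp <- experiment_transition(exp, "COMPLETED")
    exp$results <- result
  }
  exp
}

# Assemble neuron dynamics from the parameter children of a cell instance;
# overrides applied earlier through the parameter capability are visible as
# the children's current values.
cell_dynamics <- function(tree, cell_path) {
  cell <- resolve_path(tree, cell_path)
  params <- list()
  for (ch in cell$children %||% list()) {
    if ("ParameterCapability" %in% ch$capabilities) {
      params[[ch$name]] <- ch$current_value
    }
  }
  required <- c("v_rest", "v_thr", "v_reset", "r_m", "tau_m", "i_ext", "t_ref")
  missing <- setdiff(required, names(params))
  if (length(missing) > 0L) {
    nsc_abort(sprintf("cell '%s' lacks dynamics parameters: %s",
                      cell_path, paste(missing, collapse = ", ")),
              "nsc_invalid_argument")
  }
  do.call(neuron_dynamics, params[required])
}

#' Create a parameter sweep
#'
#' Produces one new `DESIGN` experiment per value, each a copy of the
#' template with the override `parameter_path = value` set and its id/name
#' suffixed deterministically. The sweep is atomic: if any value falls
#' outside the parameter's declared bounds, no experiment is created.
#'
#' @param project A [new_project()].
#' @param template_experiment_id Id of the template experiment.
#' @param parameter_path Instance path of a parameter (carries the parameter
#'   capability).
#' @param values Numeric values to sweep over.
#' @return List of new experiments (possibly empty).
#' @export
sweep_experiments <- function(project, template_experiment_id, parameter_path, values) {
  stopifnot(inherits(project, "nsc_project"), is.numeric(values))
  template <- project$experiments[[find_experiment(project, template_experiment_id)]]
  tree <- instantiate(project$model)
  inst <- resolve_path(tree, parameter_path)
  if (!"ParameterCapability" %in% inst$capabilities) {
    nsc_abort(sprintf("path '%s' does not address a parameter", parameter_path),
              "nsc_capability_not_supported")
  }
  if (!is.null(inst$bounds)) {
    out <- values < inst$bounds[1] | values > inst$bounds[2]
    if (any(out)) {
      nsc_abort(sprintf("sweep rejected: value(s) %s outside bounds [%g, %g] of '%s'",
                        paste(values[out], collapse = ", "),
                        inst$bounds[1], inst$bounds[2], parameter_path),
                "nsc_bounds_error")
    }
  }
  lapply(seq_along(values), function(i) {
    e <- new_experiment(sprintf("%s_sweep%d", template$id, i),
                        name = sprintf("%s [%s=%g]", template$name,
                                       parameter_path, values[i]),
                        duration = template$duration, dt = template$dt,
                        watched = template$watched,
                        parameter_overrides = template$parameter_overrides)
    e$parameter_overrides[[parameter_path]] <- values[i]
    e
  })
}

#' Watch every state variable of a project's model
#'
#' Sets the experiment's watched set to all instance paths carrying the
#' state-variable capability ("record all membrane potentials with one
#' action"). Set semantics: already-watched paths are not duplicated. Only
#' legal while the experiment is in `DESIGN`.
#'
#' @param project A [new_project()].
#' @param experiment_id Id of an experiment in state `DESIGN`.
#' @return The updated experiment.
#' @export
watch_all <- function(project, experiment_id) {
  stopifnot(inherits(project, "nsc_project"))
  exp <- project$experiments[[find_experiment(project, experiment_id)]]
  if (exp$state != "DESIGN") {
    nsc_abort(sprintf("watch_all requires state DESIGN, experiment '%s' is %s",
                      exp$id, exp$state),
              "nsc_illegal_state")
  }
  tree <- instantiate(project$model)
  paths <- instance_paths(tree, capability = "StateVariableCapability")
  exp$watched <- unique(c(exp$watched, paths))
  exp
}
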