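# Service registries: model interpreters (domain format -> meta-model
# types), simulators, and data-source backends. Ids are looked up at
# resolve/run time so applications can plug in their own services.

the <- new.env(parent = emptyenv())
the$interpreters <- list()
the$simulators <- list()
the$backends <- character(0)

#' Register a model interpreter
#'
#' A model interpreter converts a description in a domain language (a file
#' addressed by an import type's `source_ref`) into meta-model types. The
#' function is called as `fn(source)` with the resolved source path and must
#' return a type object (typically a composite). The interpreters `"swc"`
#' and `"obj"` are registered when the package loads.
#'
#' @param id Interpreter id.
#' @param fn Interpreter function.
#' @export
register_interpreter <- function(id, fn) {
  assert_identifier(id, "interpreter id")
  stopifnot(is.function(fn))
  the$interpreters[[id]] <- fn
  invisible(id)
}

get_interpreter <- function(id) {
  fn <- the$interpreters[[id]]
  if (is.null(fn)) {
    nsc_abort(sprintf("no interpreter registered under id '%s'", id),
              "nsc_unknown_interpreter")
  }
  fn
}

#' Register a simulator service
#'
#' A simulator is called as `fn(dynamics, duration, dt)` where `dynamics`
#' is a [neuron_dynamics()] parameter set and must return a list with
#' elements `series` (a [time_series_value()]) and `spikes` (numeric spike
#' times). The reference simulator `"lif"` ([simulate_lif()]) is registered
#' when the package loads; a wrapper around an external simulator process
#' would register here the same way.
#'
#' @param id Simulator id.
#' @param fn Simulator function.
#' @export
register_simulator <- function(id, fn) {
  assert_identifier(id, "simulator id")
  stopifnot(is.function(fn))
  the$simulators[[id]] <- fn
  invisible(id)
}

get_simulator <- function(id) {
  fn <- the$simulators[[id]]
  if (is.null(fn)) {
    nsc_abort(sprintf("no simulator registered under id '%s'", id),
              "nsc_unknown_simulator")
  }
  fn
}

register_backend <- function(id) {
  the$backends <- union(the$backends, id)
  invisible(id)
}

registered_backends <- function() the$backends

.onLoad <- function(libname, pkgname) {
  register_interpreter("swc", function(source) interpret_swc(source))
  register_interpreter("obj", function(source) {
    composite_type("mesh", variables = list(
      new_variable("surface", "common.Visual",
                   initial_values = list(interpret_obj(source)))))
  })
  register_simulator("lif", function(dynamics, duration, dt)
    simulate_lif(dynamics, duration, dt))
  register_backend("memory")
}
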