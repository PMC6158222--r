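#' Instantiate a model into a runtime instance tree
#'
#' Expands a validated model into an addressable tree of instances: every
#' root variable yields one root instance, array types expand into their
#' declared number of children (named `name[0] .. name[size-1]`, zero-based)
#' and import types yield first-class placeholder instances that can be
#' listed and addressed before resolution (see [resolve_import()]).
#' Traversal order is declaration order, so instantiation is deterministic.
#' Capabilities are injected by type kind: state variables receive the
#' state-variable capability, parameters the parameter capability and
#' instances holding geometric values the visual capability
#' (see [get_capability_view()]).
#'
#' @param m A [new_model()]; refused (with the attached report) if
#'   [validate_model()] finds errors.
#' @return An object of class `nsc_instance_tree`.
#' @examples
#' m <- interpret_network(network_doc(
#'   cell_defs = list(cd = list(dynamics = list(i_ext = 1))),
#'   populations = list(list(name = "pop", cell_def = "cd", size = 3))))
#' tree <- instantiate(m)
#' resolve_path(tree, "net.pop[2].v")$capabilities
#' @export
instantiate <- function(m) {
  stopifnot(inherits(m, "nsc_model"))
  report <- validate_model(m)
  errors <- report[report$severity == "error", , drop = FALSE]
  if (nrow(errors) > 0L) {
    nsc_abort(sprintf("model '%s' fails validation with %d error(s); first: %s",
                      m$id, nrow(errors), errors$message[1]),
              "nsc_validation_error", report = report)
  }
  roots <- lapply(m$variables, build_variable_instance, prefix = "", m = m)
  structure(list(roots = roots, model = m,
                 base_dir = attr(m, "base_dir") %||% "."),
            class = "nsc_instance_tree")
}

new_instance <- function(name, path, kind, type, children = list(),
                         capabilities = character(0), ...) {
  structure(c(list(name = name, path = path, kind = kind, type = type,
                   children = children, capabilities = capabilities,
                   resolved = TRUE),
              list(...)),
            class = "nsc_instance")
}

build_variable_instance <- function(v, prefix, m) {
  tinfo <- lookup_type(m, v$type)
  if (is.null(tinfo)) {
    nsc_abort(sprintf("variable '%s' references unknown type '%s'", v$name, v$type),
              "nsc_unknown_type")
  }
  path <- if (nzchar(prefix)) paste0(prefix, ".", v$name) else v$name
  build_type_instance(tinfo$type, tinfo$qualified, v$name, path, m, var = v)
}

build_type_instance <- function(t, qualified, name, path, m, var = NULL) {
  eff <- effective_fields(t, m)
  switch(t$kind,
    composite = {
      children <- lapply(unname(eff), build_variable_instance, prefix = path, m = m)
      new_instance(name, path, "composite", qualified, children = children)
    },
    array = {
      el <- lookup_type(m, eff$element_type)
      if (is.null(el)) {
        nsc_abort(sprintf("array '%s' references unknown element type '%s'",
                          t$name, eff$element_type),
                  "nsc_unknown_type")
      }
      children <- lapply(seq_len(eff$size), function(i) {
        seg <- sprintf("%s[%d]", name, i - 1L)
        build_type_instance(el$type, el$qualified, seg,
                            sprintf("%s[%d]", path, i - 1L), m)
      })
      new_instance(name, path, "array", qualified, children = children,
                   size = eff$size)
    },
    import = {
      inst <- new_instance(name, path, "import", qualified,
                           interpreter_id = t$interpreter_id,
                           source_ref = t$source_ref)
      inst$resolved <- FALSE
      inst
    },
    state_variable = {
      initial <- eff$initial_value %||% 0
      for (iv in (var$initial_values %||% list())) {
        if (iv$value_type == "Scalar") initial <- iv$value
      }
      new_instance(name, path, "state_variable", qualified,
                   capabilities = "StateVariableCapability",
                   unit = eff$unit, initial_value = initial, recorded = NULL)
    },
    parameter = {
      new_instance(name, path, "parameter", qualified,
                   capabilities = "ParameterCapability",
                   unit = eff$unit, default_value = eff$default_value,
                   current_value = eff$default_value, bounds = eff$bounds)
    },
    primitive = {
      vals <- Filter(is_visual_value, var$initial_values %||% list())
      new_instance(name, path, "primitive", qualified,
                   capabilities = if (length(vals)) "VisualCapability" else character(0),
                   values = vals)
    },
    visual_group = {
      new_instance(name, path, "visual_group", qualified,
                   capabilities = "VisualCapability",
                   values = eff$values %||% list())
    },
    nsc_abort(sprintf("cannot instantiate type kind '%s'", t$kind), "nsc_invalid_argument"))
}

# depth-first walk in declaration order
walk_instances <- function(tree, fn) {
  recurse <- function(inst) {
    fn(inst)
    for (ch in inst$children) recurse(ch)
  }
  for (r in tree$roots) recurse(r)
  invisible(NULL)
}

#' Enumerate instance paths
#'
#' Lists the paths of all reachable instances in deterministic (declaration,
#' depth-first) order, optionally restricted to instances carrying a given
#' capability or to leaves.
#'
#' @param tree An [instantiate()]d tree.
#' @param capability Optional capability name filter (e.g.
#'   `"StateVariableCapability"`).
#' @param leaves_only Keep only instances without children?
#' @return Character vector of paths.
#' @export
instance_paths <- function(tree, capability = NULL, leaves_only = FALSE) {
  stopifnot(inherits(tree, "nsc_instance_tree"))
  out <- character(0)
  walk_instances(tree, function(inst) {
    if (!is.null(capability) && !capability %in% inst$capabilities) return()
    if (leaves_only && length(inst$children) > 0L) return()
    out[[length(out) + 1L]] <<- inst$path
  })
  out
}

count_instances <- function(tree) length(instance_paths(tree))

# replace the instance at `path` (must exist) with `value`
replace_instance <- function(tree, path, value) {
  segs <- parse_path(path)
  stopifnot(length(segs) > 0L)
  tree$roots <- replace_in(tree$roots, segs, value)
  tree
}

replace_in <- function(children, segs, value) {
  seg <- segs[[1]]
  for (i in seq_along(children)) {
    if (children[[i]]$name != seg$name) next
    if (!is.na(seg$index)) {
      arr <- children[[i]]
      if (length(segs) == 1L) {
        arr$children[[seg$index + 1L]] <- value
      } else {
        el <- arr$children[[seg$index + 1L]]
        el$children <- replace_in(el$children, segs[-1L], value)
        arr$children[[seg$index + 1L]] <- el
      }
      children[[i]] <- arr
    } else if (length(segs) == 1L) {
      children[[i]] <- value
    } else {
      node <- children[[i]]
      node$children <- replace_in(node$children, segs[-1L], value)
      children[[i]] <- node
    }
    return(children)
  }
  nsc_abort(sprintf("internal: segment '%s' not found during replacement", seg$name),
            "nsc_path_not_found")
}

#' Resolve an import placeholder on demand
#'
#' Lazy loading: the placeholder instance at `path` is replaced by the
#' subtree obtained by running the registered interpreter on the import's
#' source (relative sources resolve against the directory the model was
#' loaded from). All other paths are unchanged, and calling the function
#' again on the same path is a no-op, so eager interpretation at build time
#' and deferred resolution yield structurally identical trees. On failure
#' (unregistered interpreter, unreadable source) the tree is left intact.
#' One level is resolved per call; imports nested in the interpreted subtree
#' remain placeholders.
#'
#' @param tree An [instantiate()]d tree.
#' @param path Path of an unresolved import placeholder.
#' @return The updated tree.
#' @seealso [resolve_all_imports()] to resolve every placeholder.
#' @export
resolve_import <- function(tree, path) {
  stopifnot(inherits(tree, "nsc_instance_tree"))
  inst <- resolve_path(tree, path)
  if (inst$kind != "import" || isTRUE(inst$resolved)) {
    return(tree)  # already resolved (or never an import): no-op
  }
  fn <- get_interpreter(inst$interpreter_id)
  src <- inst$source_ref
  if (!file.exists(src)) {
    candidate <- file.path(tree$base_dir, src)
    if (!file.exists(candidate)) {
      nsc_abort(sprintf("import source '%s' is unreadable (tried '%s')", src, candidate),
                "nsc_io_error")
    }
    src <- candidate
  }
  newtype <- fn(src)
  replacement <- build_type_instance(newtype, inst$type, inst$name, inst$path,
                                     tree$model)
  replace_instance(tree, path, replacement)
}

#' @rdname resolve_import
#' @export
resolve_all_imports <- function(tree) {
  repeat {
    pending <- character(0)
    walk_instances(tree, function(inst) {
      if (inst$kind == "import" && !isTRUE(inst$resolved)) {
        pending[[length(pending) + 1L]] <<- inst$path
      }
    })
    if (length(pending) == 0L) return(tree)
    for (p in pending) tree <- resolve_import(tree, p)
  }
}

# ---- capabilities -------------------------------------------------------

#' Indicator for "no recorded data yet"
#'
#' Querying a recorded series before any simulation has run returns this
#' explicit indicator rather than raising an error.
#'
#' @return An object of class `nsc_no_data`.
#' @export
no_data <- function() structure(list(), class = "nsc_no_data")

#' @rdname no_data
#' @param x Object to test.
#' @export
is_no_data <- function(x) inherits(x, "nsc_no_data")

#' Obtain a capability view of an instance
#'
#' Capabilities are API contracts injected into instances according to their
#' type kind. The view is a plain list of the contract's data:
#' \describe{
#'   \item{StateVariableCapability}{`unit`, `initial_value` (reflecting the
#'     inheritance-merged effective type) and `series` — the recorded time
#'     series, or the [no_data()] indicator before any simulation.}
#'   \item{ParameterCapability}{`unit`, `value` (current), `bounds`; values
#'     are changed with [set_parameter_value()], which enforces bounds.}
#'   \item{VisualCapability}{`values` — the instance's geometric values.}
#' }
#'
#' @param instance An instance (from [resolve_path()] on a tree).
#' @param capability Capability name.
#' @return A list as described above.
#' @export
get_capability_view <- function(instance, capability) {
  stopifnot(inherits(instance, "nsc_instance"))
  if (!capability %in% instance$capabilities) {
    nsc_abort(sprintf("instance '%s' does not carry capability '%s'",
                      instance$path, capability),
              "nsc_capability_not_supported")
  }
  switch(capability,
    StateVariableCapability = list(
      unit = instance$unit,
      initial_value = instance$initial_value,
      series = instance$recorded %||% no_data()),
    ParameterCapability = list(
      unit = instance$unit,
      value = instance$current_value,
      bounds = instance$bounds),
    VisualCapability = list(values = instance$values),
    nsc_abort(sprintf("unknown capability '%s'", capability),
              "nsc_capability_not_supported"))
}

#' Set a parameter instance's value
#'
#' Applies a new value through the parameter capability. Values outside the
#' parameter's declared bounds are rejected with a bounds error and the tree
#' is unchanged.
#'
#' @param tree An [instantiate()]d tree.
#' @param path Path of a parameter instance.
#' @param value New value.
#' @return The updated tree.
#' @export
set_parameter_value <- function(tree, path, value) {
  inst <- resolve_path(tree, path)
  if (!"ParameterCapability" %in% inst$capabilities) {
    nsc_abort(sprintf("instance '%s' does not carry the parameter capability", path),
              "nsc_capability_not_supported")
  }
  value <- assert_scalar_number(value, "parameter value")
  if (!is.null(inst$bounds) && (value < inst$bounds[1] || value > inst$bounds[2])) {
    nsc_abort(sprintf("value %g for '%s' outside bounds [%g, %g]",
                      value, path, inst$bounds[1], inst$bounds[2]),
              "nsc_bounds_error")
  }
  inst$current_value <- value
  replace_instance(tree, path, inst)
}

#' Attach recorded experiment results to the instance tree
#'
#' Copies the time series recorded by a completed experiment onto the
#' watched state-variable instances, so their capability views expose the
#' data.
#'
#' @param tree An [instantiate()]d tree.
#' @param exp A completed experiment.
#' @return The updated tree.
#' @export
attach_results <- function(tree, exp) {
  stopifnot(inherits(exp, "nsc_experiment"))
  for (p in names(exp$results)) {
    inst <- resolve_path(tree, p)
    inst$recorded <- exp$results[[p]]
    tree <- replace_instance(tree, p, inst)
  }
  tree
}

#' @export
print.nsc_instance_tree <- function(x, ...) {
  cat(sprintf("<nsc_instance_tree> model '%s': %d instances\n",
              x$model$id, count_instances(x)))
  invisible(x)
}

#' @export
print.nsc_instance <- function(x, ...) {
  cat(sprintf("<nsc_instance %s> %s (%s)%s\n", x$kind, x$path, x$type,
              if (x$kind == "import" && !isTRUE(x$resolved)) " [unresolved import]" else ""))
  invisible(x)
}
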