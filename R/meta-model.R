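#' The meta-model: types, variables and models
#'
#' The package represents neuroscience models and data through a small,
#' domain-agnostic meta-model built from three concepts borrowed from
#' object-oriented programming: \emph{Types} (schema elements, supporting
#' single inheritance and composition), \emph{Variables} (named slots of a
#' given type) and \emph{Values} (concrete data filling a slot). A
#' \code{\link{new_model}} bundles libraries of types together with root
#' variables, data-source declarations and queries; instantiating it (see
#' \code{\link{instantiate}}) expands it into an addressable runtime tree.
#'
#' @name meta-model
#' @keywords internal
NULL

TYPE_KINDS <- c("composite", "array", "import", "state_variable",
                "parameter", "primitive", "visual_group")

new_type <- function(kind, name, supertype = NULL, ...) {
  assert_identifier(name, "type name")
  stopifnot(kind %in% TYPE_KINDS)
  if (!is.null(supertype)) stopifnot(is.character(supertype), length(supertype) == 1L)
  structure(
    c(list(kind = kind, name = name, supertype = supertype), list(...)),
    class = c(paste0("nsc_", kind, "_type"), "nsc_type")
  )
}

#' Type constructors
#'
#' Construct the concrete type kinds of the meta-model. All types have a
#' `name` and an optional `supertype` reference (single inheritance); the
#' reference is either a plain type name or a qualified `"library.Type"`
#' string.
#'
#' @param name Type name (identifier).
#' @param supertype Optional reference to the supertype.
#' @param variables For [composite_type()], an ordered list of
#'   [new_variable()] objects; contained variable names must be unique.
#' @param element_type For [array_type()], reference to the element type.
#' @param size For [array_type()], non-negative population size.
#' @param interpreter_id For [import_type()], id of a registered model
#'   interpreter (see [register_interpreter()]).
#' @param source_ref For [import_type()], a locator (e.g. a relative file
#'   path) understood by the interpreter.
#' @param unit Unit string, e.g. `"mV"`; must be non-empty for state
#'   variables.
#' @param initial_value Initial value of a state variable.
#' @param default_value Default value of a parameter.
#' @param bounds Optional closed interval `c(lo, hi)` constraining a
#'   parameter; must contain `default_value`.
#' @param values For [visual_group_type()], a list of visual values
#'   (spheres, cylinders, meshes).
#' @return A type object (class `nsc_type`).
#' @examples
#' v <- state_variable_type("MembranePotential", unit = "mV", initial_value = -65)
#' cell <- composite_type("Cell", variables = list(new_variable("v", "MembranePotential")))
#' @export
composite_type <- function(name, variables = list(), supertype = NULL) {
  stopifnot(is.list(variables))
  new_type("composite", name, supertype, variables = variables)
}

#' @rdname composite_type
#' @export
array_type <- function(name, element_type, size, supertype = NULL) {
  size <- assert_scalar_number(size, "size")
  if (size < 0 || size != trunc(size)) {
    nsc_abort("array size must be a non-negative integer", "nsc_invalid_argument")
  }
  new_type("array", name, supertype, element_type = element_type, size = as.integer(size))
}

#' @rdname composite_type
#' @export
import_type <- function(name, interpreter_id, source_ref, supertype = NULL) {
  assert_identifier(interpreter_id, "interpreter_id")
  new_type("import", name, supertype, interpreter_id = interpreter_id,
           source_ref = source_ref, resolved = FALSE)
}

#' @rdname composite_type
#' @export
state_variable_type <- function(name, unit, initial_value = 0, supertype = NULL) {
  # an empty unit is representable but flagged by validate_model, so a
  # document with the defect loads and reports rather than failing to parse
  stopifnot(is.character(unit), length(unit) == 1L)
  new_type("state_variable", name, supertype, unit = unit,
           initial_value = if (is.null(initial_value)) NULL else as.numeric(initial_value))
}

#' @rdname composite_type
#' @export
parameter_type <- function(name, unit, default_value = 0, bounds = NULL, supertype = NULL) {
  if (!is.null(bounds)) {
    stopifnot(is.numeric(bounds), length(bounds) == 2L)
    if (!(bounds[1] <= default_value && default_value <= bounds[2])) {
      nsc_abort(sprintf("parameter %s: default value %g outside bounds [%g, %g]",
                        name, default_value, bounds[1], bounds[2]),
                "nsc_bounds_error")
    }
    bounds <- as.numeric(bounds)
  }
  new_type("parameter", name, supertype, unit = unit,
           default_value = as.numeric(default_value), bounds = bounds)
}

#' @rdname composite_type
#' @export
primitive_type <- function(name, supertype = NULL) {
  new_type("primitive", name, supertype)
}

#' @rdname composite_type
#' @export
visual_group_type <- function(name, values = list(), supertype = NULL) {
  new_type("visual_group", name, supertype, values = values)
}

#' Create a variable
#'
#' A variable is a named slot of a given type. `initial_values` may carry
#' concrete [values] (e.g. a scalar overriding the type-level initial value
#' of a state variable, or geometric values for visual slots).
#'
#' @param name Variable name (identifier grammar: letters, digits,
#'   underscore, not starting with a digit).
#' @param type Reference to the variable's type (plain or `"lib.Type"`).
#' @param initial_values Optional list of value objects.
#' @return An object of class `nsc_variable`.
#' @export
new_variable <- function(name, type, initial_values = list()) {
  assert_identifier(name, "variable name")
  stopifnot(is.character(type), length(type) == 1L, is.list(initial_values))
  structure(list(name = name, type = type, initial_values = initial_values),
            class = "nsc_variable")
}

#' Create a type library
#'
#' @param id Library id (identifier). Type names must be unique within a
#'   library; the qualified name of a type is `"<library id>.<type name>"`.
#' @param types Ordered list of type objects.
#' @return An object of class `nsc_library`.
#' @export
new_library <- function(id, types = list()) {
  assert_identifier(id, "library id")
  stopifnot(is.list(types))
  structure(list(id = id, types = types), class = "nsc_library")
}

#' Create a model
#'
#' The root container of the meta-model: an ordered set of type libraries,
#' the model's root variables, declarations of data sources and the queries
#' available to interrogate them. Use [validate_model()] to check all
#' invariants and [instantiate()] to expand the model into a runtime
#' instance tree.
#'
#' @param id Model id (identifier).
#' @param libraries List of [new_library()] objects.
#' @param variables List of root [new_variable()] objects.
#' @param datasources List of [data_source_decl()] objects.
#' @param queries List of [query_decl()] objects.
#' @param network Optional network metadata as produced by
#'   [interpret_network()] (population order and connection records).
#' @param schema_version Serialization schema version (currently `"1"`).
#' @return An object of class `nsc_model`.
#' @export
new_model <- function(id, libraries = list(), variables = list(),
                      datasources = list(), queries = list(),
                      network = NULL, schema_version = "1") {
  assert_identifier(id, "model id")
  structure(list(id = id, libraries = libraries, variables = variables,
                 datasources = datasources, queries = queries,
                 network = network, schema_version = schema_version),
            class = "nsc_model")
}

#' Declare a query
#'
#' A query is an ordered conjunction of `(field, predicate, operand)`
#' filters evaluated by [run_query()]. An empty filter list matches every
#' record.
#'
#' @param id Query id.
#' @param filters List of filters created with [query_filter()].
#' @return An object of class `nsc_query_decl`.
#' @export
query_decl <- function(id, filters = list()) {
  assert_identifier(id, "query id")
  structure(list(id = id, filters = filters), class = "nsc_query_decl")
}

#' @rdname query_decl
#' @param field Record field the filter applies to.
#' @param predicate One of `"eq"`, `"ne"`, `"lt"`, `"le"`, `"gt"`, `"ge"`,
#'   `"contains"`.
#' @param operand Comparison operand.
#' @export
query_filter <- function(field, predicate, operand) {
  predicate <- match.arg(predicate, c("eq", "ne", "lt", "le", "gt", "ge", "contains"))
  structure(list(field = field, predicate = predicate, operand = operand),
            class = "nsc_query_filter")
}

#' Declare a data source
#'
#' Declares that a model draws records from a data-source backend. Only the
#' in-memory backend ships with the package; see [in_memory_data_source()].
#'
#' @param id Declaration id.
#' @param backend_id Id of a registered backend (e.g. `"memory"`).
#' @param config Named list of backend configuration values.
#' @return An object of class `nsc_data_source_decl`.
#' @export
data_source_decl <- function(id, backend_id, config = named_list()) {
  assert_identifier(id, "data source id")
  assert_identifier(backend_id, "backend id")
  structure(list(id = id, backend_id = backend_id, config = config),
            class = "nsc_data_source_decl")
}

#' @export
print.nsc_model <- function(x, ...) {
  n_types <- sum(vapply(x$libraries, function(l) length(l$types), integer(1)))
  cat(sprintf("<nsc_model> %s: %d libraries (%d types), %d root variables\n",
              x$id, length(x$libraries), n_types, length(x$variables)))
  invisible(x)
}

#' @export
print.nsc_type <- function(x, ...) {
  cat(sprintf("<nsc_type %s> %s%s\n", x$kind, x$name,
              if (is.null(x$supertype)) "" else paste0(" extends ", x$supertype)))
  invisible(x)
}

# ---- type lookup --------------------------------------------------------

qualified_name <- function(lib_id, type_name) paste0(lib_id, ".", type_name)

# Find a type by reference. `ref` is "Type" (searched across libraries,
# must be unambiguous) or "lib.Type". Returns list(library_id, type,
# qualified) or NULL when absent; ambiguous plain references raise.
lookup_type <- function(model, ref) {
  if (grepl(".", ref, fixed = TRUE)) {
    parts <- strsplit(ref, ".", fixed = TRUE)[[1]]
    if (length(parts) != 2L) return(NULL)
    for (lib in model$libraries) {
      if (lib$id == parts[1]) {
        for (t in lib$types) {
          if (t$name == parts[2]) {
            return(list(library_id = lib$id, type = t,
                        qualified = qualified_name(lib$id, t$name)))
          }
        }
      }
    }
    return(NULL)
  }
  hits <- list()
  for (lib in model$libraries) {
    for (t in lib$types) {
      if (t$name == ref) hits[[length(hits) + 1L]] <- list(
        library_id = lib$id, type = t, qualified = qualified_name(lib$id, t$name))
    }
  }
  if (length(hits) == 0L) return(NULL)
  if (length(hits) > 1L) {
    nsc_abort(sprintf("type reference '%s' is ambiguous: found in libraries %s",
                      ref, paste(vapply(hits, `[[`, "", "library_id"), collapse = ", ")),
              "nsc_ambiguous_type")
  }
  hits[[1]]
}

# ---- inheritance --------------------------------------------------------

#' Resolve the supertype lineage of a type
#'
#' Walks the single-inheritance chain of `t` within model `m`, returning the
#' ordered lineage with `t` first and the inheritance root last. Lineages
#' are finite and acyclic in a valid model.
#'
#' @param t A type object belonging to `m` (or a reference string).
#' @param m A [new_model()].
#' @return List of type objects, self first, root last.
#' @seealso [effective_fields()] for the inherited field merge.
#' @export
resolve_supertypes <- function(t, m) {
  if (is.character(t)) {
    hit <- lookup_type(m, t)
    if (is.null(hit)) nsc_abort(sprintf("unknown type '%s'", t), "nsc_unknown_type")
    t <- hit$type
  }
  lineage <- list(t)
  seen <- t$name
  cur <- t
  while (!is.null(cur$supertype)) {
    hit <- lookup_type(m, cur$supertype)
    if (is.null(hit)) {
      nsc_abort(sprintf("type '%s' extends unknown type '%s'", cur$name, cur$supertype),
                "nsc_unknown_type")
    }
    cur <- hit$type
    if (cur$name %in% seen) {
      nsc_abort(sprintf("inheritance cycle involving types: %s",
                        paste(c(seen, cur$name), collapse = " -> ")),
                "nsc_inheritance_cycle", members = seen)
    }
    seen <- c(seen, cur$name)
    lineage[[length(lineage) + 1L]] <- cur
  }
  lineage
}

#' Merged (effective) fields of a type under inheritance
#'
#' Merges fields along the supertype lineage root-down: an ancestor's fields
#' are taken first and a descendant's field of the same name overrides them
#' (nearest-descendant wins). For composite types the fields are the
#' contained variables; for state-variable and parameter types they are the
#' scalar attributes (`unit`, `initial_value`, `default_value`, `bounds`),
#' where `NULL` in a descendant means "inherit".
#'
#' @inheritParams resolve_supertypes
#' @return For composites, a named list of variables in merged declaration
#'   order; for leaf kinds, a named list of scalar attributes.
#' @export
effective_fields <- function(t, m) {
  lineage <- rev(resolve_supertypes(t, m))  # root first
  kind <- lineage[[length(lineage)]]$kind
  if (kind == "composite") {
    merged <- list()
    for (anc in lineage) {
      for (v in anc$variables %||% list()) merged[[v$name]] <- v
    }
    merged
  } else {
    merged <- list()
    keys <- c("unit", "initial_value", "default_value", "bounds",
              "element_type", "size", "values")
    for (anc in lineage) {
      for (k in keys) if (!is.null(anc[[k]])) merged[[k]] <- anc[[k]]
    }
    merged
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
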