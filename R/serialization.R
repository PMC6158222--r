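#' @name serialization
#' @title Canonical JSON serialization
#' @description
#' Models and projects are persisted as UTF-8 JSON with a top-level
#' `"schemaVersion": "1"`. Output is canonical — object keys are sorted and
#' floats are written at full round-trip precision — so writing equal
#' structures yields byte-identical text and `read(write(x))` is the
#' identity, including unresolved import types. Optional fields are omitted
#' rather than written as null; the reader treats absence as the default.
#' @keywords internal
NULL

SUPPORTED_SCHEMA_VERSIONS <- "1"

# ---- writing ------------------------------------------------------------

# Recursively sort object keys so serialization is canonical.
canonicalize <- function(x) {
  if (is.list(x)) {
    nm <- names(x)
    if (!is.null(nm)) x <- x[order(nm, method = "radix")]
    lapply(x, canonicalize)
  } else {
    x
  }
}

to_json_text <- function(doc) {
  # digits = I(17): decimal significant digits, enough for exact double
  # round-trips (shortest 15-digit form loses the last bit)
  txt <- jsonlite::toJSON(canonicalize(doc), auto_unbox = TRUE, digits = I(17),
                          always_decimal = FALSE)
  as.character(txt)
}

# numeric vector that must serialize as a JSON array even at length 1
arr <- function(x) I(as.numeric(x))

value_to_doc <- function(v) {
  switch(v$value_type,
    Scalar = list(valueType = "Scalar", value = v$value, unit = v$unit),
    Sphere = list(valueType = "Sphere", center = arr(v$center), radius = v$radius),
    Cylinder = list(valueType = "Cylinder", p1 = arr(v$p1), p2 = arr(v$p2),
                    r1 = v$r1, r2 = v$r2),
    Mesh = list(valueType = "Mesh",
                vertices = lapply(v$vertices, arr),
                faces = lapply(v$faces, function(f) I(as.integer(f)))),
    TimeSeries = list(valueType = "TimeSeries", times = arr(v$times),
                      values = arr(v$values), unit = v$unit),
    Pointer = list(valueType = "Pointer", path = v$path),
    nsc_abort(sprintf("unknown value type '%s'", v$value_type), "nsc_parse_error"))
}

variable_to_doc <- function(v) {
  doc <- list(name = v$name, type = v$type)
  if (length(v$initial_values) > 0L) {
    doc$initialValues <- lapply(v$initial_values, value_to_doc)
  }
  doc
}

type_to_doc <- function(t) {
  doc <- list(kind = t$kind, name = t$name)
  if (!is.null(t$supertype)) doc$supertype <- t$supertype
  switch(t$kind,
    composite = { doc$variables <- lapply(t$variables, variable_to_doc) },
    array = { doc$elementType <- t$element_type; doc$size <- t$size },
    import = { doc$interpreterId <- t$interpreter_id
               doc$sourceRef <- t$source_ref
               doc$resolved <- t$resolved },
    state_variable = { doc$unit <- t$unit
                       if (!is.null(t$initial_value)) doc$initialValue <- t$initial_value },
    parameter = { doc$unit <- t$unit
                  doc$defaultValue <- t$default_value
                  if (!is.null(t$bounds)) doc$bounds <- arr(t$bounds) },
    primitive = NULL,
    visual_group = { doc$values <- lapply(t$values, value_to_doc) })
  doc
}

network_to_doc <- function(net) {
  list(
    populations = lapply(net$populations, function(p)
      list(name = p$name, cellDef = p$cell_def, size = p$size)),
    connections = lapply(net$connections, function(con)
      list(pre = con$pre$path, post = con$post$path, weight = con$weight)))
}

model_to_doc <- function(m) {
  doc <- list(
    schemaVersion = m$schema_version,
    id = m$id,
    libraries = lapply(m$libraries, function(lib)
      list(id = lib$id, types = lapply(lib$types, type_to_doc))),
    variables = lapply(m$variables, variable_to_doc),
    datasources = lapply(m$datasources, function(ds)
      list(id = ds$id, backendId = ds$backend_id, config = ds$config)),
    queries = lapply(m$queries, function(q)
      list(id = q$id, filters = lapply(q$filters, function(flt)
        list(field = flt$field, predicate = flt$predicate, operand = flt$operand)))))
  if (!is.null(m$network)) doc$network <- network_to_doc(m$network)
  doc
}

#' Write and read models
#'
#' `write_model()` serializes a model to canonical JSON text;
#' `read_model()` parses it back. The pair is a structural identity:
#' `read_model(write_model(m))` equals `m`, including unresolved import
#' types, and writing the same model twice yields byte-identical text.
#' `write_model_file()`/`read_model_file()` wrap the pair with file I/O;
#' the reader records the file's directory so relative import sources
#' resolve later.
#'
#' @param m A [new_model()] that passes [validate_model()].
#' @param text JSON document text.
#' @param path File path.
#' @return `write_model()` returns the document text; `read_model()` and
#'   `read_model_file()` return the model.
#' @export
write_model <- function(m) {
  stopifnot(inherits(m, "nsc_model"))
  to_json_text(model_to_doc(m))
}

#' @rdname write_model
#' @export
read_model <- function(text) {
  doc <- parse_json_doc(text)
  model_from_doc(doc)
}

#' @rdname write_model
#' @export
write_model_file <- function(m, path) {
  writeLines(write_model(m), path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model_file <- function(path) {
  if (!file.exists(path)) {
    nsc_abort(sprintf("cannot read model file '%s': no such file", path),
              "nsc_io_error")
  }
  m <- read_model(paste(readLines(path, warn = FALSE), collapse = "\n"))
  attr(m, "base_dir") <- dirname(path)
  m
}

# ---- reading ------------------------------------------------------------

parse_json_doc <- function(text) {
  tryCatch(
    jsonlite::fromJSON(text, simplifyVector = FALSE),
    error = function(e) {
      nsc_abort(sprintf("malformed document: %s", conditionMessage(e)),
                "nsc_parse_error")
    })
}

need <- function(doc, key, ctx) {
  if (!key %in% names(doc)) {
    nsc_abort(sprintf("%s: required key '%s' is missing", ctx, key),
              "nsc_missing_key")
  }
  doc[[key]]
}

check_schema_version <- function(doc, ctx) {
  v <- need(doc, "schemaVersion", ctx)
  if (!v %in% SUPPORTED_SCHEMA_VERSIONS) {
    nsc_abort(sprintf("%s: unsupported schema version '%s' (supported: %s)",
                      ctx, v, paste(SUPPORTED_SCHEMA_VERSIONS, collapse = ", ")),
              "nsc_unsupported_version")
  }
  v
}

num_vec <- function(x) vapply(x, as.numeric, 0)

value_from_doc <- function(doc) {
  vt <- need(doc, "valueType", "value")
  switch(vt,
    Scalar = scalar_value(doc$value, doc$unit %||% ""),
    Sphere = sphere_value(num_vec(doc$center), doc$radius),
    Cylinder = cylinder_value(num_vec(doc$p1), num_vec(doc$p2), doc$r1, doc$r2),
    Mesh = mesh_value(lapply(doc$vertices, num_vec), lapply(doc$faces, num_vec)),
    TimeSeries = time_series_value(num_vec(doc$times), num_vec(doc$values),
                                   doc$unit %||% ""),
    Pointer = pointer_value(doc$path),
    nsc_abort(sprintf("unknown value type '%s'", vt), "nsc_parse_error"))
}

variable_from_doc <- function(doc) {
  new_variable(need(doc, "name", "variable"), need(doc, "type", "variable"),
               lapply(doc$initialValues %||% list(), value_from_doc))
}

type_from_doc <- function(doc) {
  kind <- need(doc, "kind", "type")
  name <- need(doc, "name", "type")
  st <- doc$supertype
  switch(kind,
    composite = composite_type(name, lapply(doc$variables %||% list(),
                                            variable_from_doc), st),
    array = array_type(name, need(doc, "elementType", name), need(doc, "size", name), st),
    import = {
      t <- import_type(name, need(doc, "interpreterId", name),
                       need(doc, "sourceRef", name), st)
      t$resolved <- isTRUE(doc$resolved)
      t
    },
    state_variable = state_variable_type(name, need(doc, "unit", name),
                                         doc$initialValue, st),
    parameter = parameter_type(name, need(doc, "unit", name),
                               need(doc, "defaultValue", name),
                               if (!is.null(doc$bounds)) num_vec(doc$bounds), st),
    primitive = primitive_type(name, st),
    visual_group = visual_group_type(name, lapply(doc$values %||% list(),
                                                  value_from_doc), st),
    nsc_abort(sprintf("unknown type kind '%s'", kind), "nsc_parse_error"))
}

network_from_doc <- function(doc) {
  list(
    populations = lapply(need(doc, "populations", "network"), function(p)
      list(name = p$name, cell_def = p$cellDef, size = as.integer(p$size))),
    connections = lapply(doc$connections %||% list(), function(con)
      list(pre = pointer_value(con$pre), post = pointer_value(con$post),
           weight = as.numeric(con$weight))))
}

as_config <- function(x) {
  if (length(x) == 0L) return(named_list())
  x
}

model_from_doc <- function(doc) {
  check_schema_version(doc, "model")
  new_model(
    id = need(doc, "id", "model"),
    libraries = lapply(need(doc, "libraries", "model"), function(ld)
      new_library(need(ld, "id", "library"),
                  lapply(need(ld, "types", "library"), type_from_doc))),
    variables = lapply(need(doc, "variables", "model"), variable_from_doc),
    datasources = lapply(need(doc, "datasources", "model"), function(dd)
      data_source_decl(need(dd, "id", "datasource"),
                       need(dd, "backendId", "datasource"),
                       as_config(dd$config))),
    queries = lapply(need(doc, "queries", "model"), function(qd)
      query_decl(need(qd, "id", "query"),
                 lapply(qd$filters %||% list(), function(fd)
                   query_filter(fd$field, fd$predicate, fd$operand)))),
    network = if (!is.null(doc$network)) network_from_doc(doc$network))
}

# ---- projects -----------------------------------------------------------

#' Create a project
#'
#' A project holds exactly one model (inline, or by relative path to a
#' model document), an ordered set of experiments, and an opaque view-state
#' map that is persisted verbatim for the embedding application.
#'
#' @param id Project id; experiment ids must be unique within a project.
#' @param name Human-readable name.
#' @param model A [new_model()], or `NULL` when `model_ref` is given.
#' @param model_ref Relative path to a model document.
#' @param experiments List of [new_experiment()] objects.
#' @param view_state Named list persisted verbatim.
#' @return An object of class `nsc_project`.
#' @export
new_project <- function(id, name = id, model = NULL, model_ref = NULL,
                        experiments = list(), view_state = named_list()) {
  assert_identifier(id, "project id")
  if (is.null(model) && is.null(model_ref)) {
    nsc_abort("a project must reference exactly one model (inline or by path)",
              "nsc_invalid_argument")
  }
  ids <- vapply(experiments, `[[`, "", "id")
  if (anyDuplicated(ids)) {
    nsc_abort("experiment ids must be unique within a project", "nsc_invalid_argument")
  }
  structure(list(id = id, name = name, model = model, model_ref = model_ref,
                 experiments = experiments, view_state = view_state),
            class = "nsc_project")
}

experiment_to_doc <- function(e) {
  doc <- list(id = e$id, name = e$name, state = e$state,
              duration = e$duration, dt = e$dt,
              watched = as.list(e$watched),
              parameterOverrides = if (length(e$parameter_overrides))
                e$parameter_overrides else named_list(),
              results = if (length(e$results))
                lapply(e$results, value_to_doc) else named_list())
  if (!is.null(e$error_message)) doc$errorMessage <- e$error_message
  doc
}

experiment_from_doc <- function(doc) {
  e <- new_experiment(need(doc, "id", "experiment"),
                      name = need(doc, "name", "experiment"),
                      duration = need(doc, "duration", "experiment"),
                      dt = need(doc, "dt", "experiment"),
                      watched = vapply(need(doc, "watched", "experiment"), as.character, ""),
                      parameter_overrides = lapply(
                        need(doc, "parameterOverrides", "experiment"), as.numeric))
  e$state <- need(doc, "state", "experiment")
  if (!e$state %in% EXPERIMENT_STATES) {
    nsc_abort(sprintf("unknown experiment state '%s'", e$state), "nsc_parse_error")
  }
  e$results <- lapply(need(doc, "results", "experiment"), value_from_doc)
  if (length(e$results) == 0L) e$results <- named_list()
  e$error_message <- doc$errorMessage
  e
}

project_to_doc <- function(p) {
  doc <- list(schemaVersion = "1", id = p$id, name = p$name,
              experiments = lapply(p$experiments, experiment_to_doc),
              viewState = if (length(p$view_state)) p$view_state else named_list())
  if (!is.null(p$model_ref)) doc$modelRef <- p$model_ref
  else doc$model <- model_to_doc(p$model)
  doc
}

#' Write and read projects
#'
#' Canonical JSON persistence for projects, mirroring [write_model()]. A
#' project whose model is referenced by relative path is reattached on read:
#' `read_project_file()` loads the referenced model document relative to the
#' project file. The view-state map round-trips verbatim.
#'
#' @param p A [new_project()].
#' @param text Project document text.
#' @param base_dir Directory against which a relative model reference is
#'   resolved; `NULL` leaves the model unattached.
#' @param path File path.
#' @return `write_project()` returns text; readers return the project.
#' @export
write_project <- function(p) {
  stopifnot(inherits(p, "nsc_project"))
  to_json_text(project_to_doc(p))
}

#' @rdname write_project
#' @export
read_project <- function(text, base_dir = NULL) {
  doc <- parse_json_doc(text)
  check_schema_version(doc, "project")
  model <- NULL
  model_ref <- doc$modelRef
  if (is.null(model_ref)) {
    model <- model_from_doc(need(doc, "model", "project"))
  } else if (!is.null(base_dir)) {
    model <- read_model_file(file.path(base_dir, model_ref))
  }
  p <- new_project(need(doc, "id", "project"),
                   name = need(doc, "name", "project"),
                   model = model, model_ref = model_ref,
                   experiments = lapply(need(doc, "experiments", "project"),
                                        experiment_from_doc),
                   view_state = as_config(need(doc, "viewState", "project")))
  p
}

#' @rdname write_project
#' @export
write_project_file <- function(p, path) {
  writeLines(write_project(p), path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_project
#' @export
read_project_file <- function(path) {
  if (!file.exists(path)) {
    nsc_abort(sprintf("cannot read project file '%s': no such file", path),
              "nsc_io_error")
  }
  p <- read_project(paste(readLines(path, warn = FALSE), collapse = "\n"),
                    base_dir = dirname(path))
  attr(p, "base_dir") <- dirname(path)
  p
}

# ---- results export -----------------------------------------------------

#' Export recorded experiment results as CSV
#'
#' Writes the recorded time series of a completed experiment as tabular
#' text: one time column plus one column per watched variable, with a header
#' row carrying the full variable paths and units (RFC 4180 quoting, `.`
#' decimal separator). Numbers are printed at full round-trip precision so
#' the table parses back to the in-memory series exactly.
#'
#' @param exp A completed experiment (state `"COMPLETED"`).
#' @param path Optional file to write; when `NULL` the CSV text is returned.
#' @return The CSV text (invisibly when written to a file).
#' @export
export_results <- function(exp, path = NULL) {
  stopifnot(inherits(exp, "nsc_experiment"))
  if (exp$state != "COMPLETED") {
    nsc_abort(sprintf("experiment '%s' is in state %s; results can only be exported from COMPLETED",
                      exp$id, exp$state),
              "nsc_illegal_state")
  }
  paths <- names(exp$results)
  if (length(paths) > 0L) {
    times <- exp$results[[1]]$times
    cols <- lapply(exp$results, function(ts) ts$values)
    units <- vapply(exp$results, function(ts) ts$unit, "")
  } else {
    n <- floor(exp$duration / exp$dt) + 1L
    times <- seq(0, by = exp$dt, length.out = n)
    cols <- list()
    units <- character(0)
  }
  header <- c("time [ms]",
              if (length(paths)) sprintf("%s [%s]", paths, units))
  lines <- c(paste(vapply(header, csv_quote, ""), collapse = ","),
             do.call(paste, c(lapply(c(list(times), cols), fmt_num), sep = ",")))
  text <- paste0(paste(lines, collapse = "\n"), "\n")
  if (is.null(path)) return(text)
  writeLines(text, path, sep = "", useBytes = TRUE)
  invisible(text)
}

csv_quote <- function(x) {
  if (grepl('[",\n]', x)) paste0('"', gsub('"', '""', x), '"') else x
}

# shortest representation that round-trips a double exactly
fmt_num <- function(x) {
  s <- sprintf("%.15g", x)
  bad <- as.numeric(s) != x
  if (any(bad)) s[bad] <- sprintf("%.17g", x[bad])
  s
}
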