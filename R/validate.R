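#' Validate a model
#'
#' Checks every structural invariant of the meta-model and returns the
#' problems as data rather than raising: a data frame of findings, each with
#' a severity (`"error"`, `"warning"`), a rule id, the path of the offending
#' node and a message. An empty report means the model is valid. Findings
#' are ordered deterministically by path, then rule id.
#'
#' Checked rules include: uniqueness of library ids, of type names within a
#' library and of fully-qualified type names; existence and unambiguity of
#' every type reference (variables, supertypes, array element types);
#' acyclicity of supertype chains; identifier grammar of variable names;
#' uniqueness of variable names within a composite; non-empty state-variable
#' units; parameter defaults within bounds; rejection of inherited-variable
#' type redefinition (a subtype may override an inherited variable's values,
#' not its type); registration of data-source backends; and, for network
#' models, connection pointers staying within population bounds.
#'
#' @param m A [new_model()].
#' @return A data frame with columns `severity`, `rule`, `path`, `message`;
#'   zero rows iff the model passes.
#' @examples
#' m <- new_model("m", libraries = list(new_library("lib", list(primitive_type("Txt")))))
#' nrow(validate_model(m)) == 0
#' @export
validate_model <- function(m) {
  stopifnot(inherits(m, "nsc_model"))
  f <- list()
  add <- function(severity, rule, path, message) {
    f[[length(f) + 1L]] <<- data.frame(severity = severity, rule = rule,
                                       path = path, message = message,
                                       stringsAsFactors = FALSE)
  }

  lib_ids <- vapply(m$libraries, `[[`, "", "id")
  for (i in seq_along(lib_ids)) {
    if (lib_ids[i] %in% lib_ids[seq_len(i - 1L)]) {
      add("error", "library-id-unique", paste0("libraries.", lib_ids[i]),
          sprintf("duplicate library id '%s'", lib_ids[i]))
    }
  }

  check_ref <- function(ref, where) {
    hit <- tryCatch(lookup_type(m, ref), nsc_ambiguous_type = function(e) {
      add("error", "type-ref-ambiguous", where, conditionMessage(e)); NA
    })
    if (is.null(hit)) {
      add("error", "type-ref-exists", where, sprintf("reference to unknown type '%s'", ref))
      return(NULL)
    }
    if (identical(hit, NA)) return(NULL)
    hit
  }

  # per-library checks
  for (lib in m$libraries) {
    seen <- character(0)
    for (t in lib$types) {
      tpath <- paste0("libraries.", lib$id, ".", t$name)
      if (t$name %in% seen) {
        add("error", "type-name-unique", tpath,
            sprintf("duplicate type name '%s' in library '%s'", t$name, lib$id))
      }
      seen <- c(seen, t$name)
      if (!is.null(t$supertype)) {
        if (!is.null(check_ref(t$supertype, tpath))) {
          tryCatch(resolve_supertypes(t, m),
                   nsc_inheritance_cycle = function(e)
                     add("error", "supertype-acyclic", tpath, conditionMessage(e)),
                   nsc_error = function(e) NULL)
        }
      }
      if (t$kind == "composite") {
        vseen <- character(0)
        for (v in t$variables) {
          vpath <- paste0(tpath, ".", v$name)
          if (v$name %in% vseen) {
            add("error", "composite-variable-unique", vpath,
                sprintf("duplicate variable name '%s' in composite '%s'", v$name, t$name))
          }
          vseen <- c(vseen, v$name)
          validate_variable(v, vpath, add, check_ref)
        }
        check_type_redefinition(t, m, tpath, add)
      } else if (t$kind == "array") {
        check_ref(t$element_type, tpath)
        if (t$size < 0) add("error", "array-size", tpath, "array size must be >= 0")
      } else if (t$kind == "state_variable") {
        eff <- tryCatch(effective_fields(t, m), nsc_error = function(e) NULL)
        unit <- if (is.null(eff)) t$unit else eff$unit
        if (is.null(unit) || !nzchar(unit)) {
          add("error", "unit-nonempty", tpath, "state variable unit must be non-empty")
        }
      } else if (t$kind == "parameter") {
        if (!is.null(t$bounds) &&
            !(t$bounds[1] <= t$default_value && t$default_value <= t$bounds[2])) {
          add("error", "parameter-bounds", tpath,
              sprintf("default %g outside bounds [%g, %g]",
                      t$default_value, t$bounds[1], t$bounds[2]))
        }
      }
    }
  }

  for (v in m$variables) validate_variable(v, paste0("variables.", v$name), add, check_ref)

  for (ds in m$datasources) {
    if (!ds$backend_id %in% registered_backends()) {
      add("warning", "datasource-backend", paste0("datasources.", ds$id),
          sprintf("data source backend '%s' is not registered", ds$backend_id))
    }
  }

  if (!is.null(m$network)) validate_network(m, add)

  if (length(f) == 0L) {
    return(data.frame(severity = character(0), rule = character(0),
                      path = character(0), message = character(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, f)
  out <- out[order(out$path, out$rule), , drop = FALSE]
  rownames(out) <- NULL
  out
}

validate_variable <- function(v, vpath, add, check_ref) {
  if (!is_identifier(v$name)) {
    add("error", "variable-name-grammar", vpath,
        sprintf("variable name '%s' violates the identifier grammar", v$name))
  }
  check_ref(v$type, vpath)
}

# A composite may override an inherited variable's initial values but never
# redeclare it with a different type.
check_type_redefinition <- function(t, m, tpath, add) {
  lineage <- tryCatch(resolve_supertypes(t, m), nsc_error = function(e) NULL)
  if (is.null(lineage) || length(lineage) < 2L) return(invisible())
  inherited <- list()
  for (anc in rev(lineage[-1L])) {
    for (v in anc$variables %||% list()) inherited[[v$name]] <- v$type
  }
  for (v in t$variables) {
    it <- inherited[[v$name]]
    if (!is.null(it) && !identical(it, v$type)) {
      add("error", "inherited-type-redefinition", paste0(tpath, ".", v$name),
          sprintf("variable '%s' inherited with type '%s' cannot be redeclared with type '%s'",
                  v$name, it, v$type))
    }
  }
}

validate_network <- function(m, add) {
  net <- m$network
  sizes <- stats::setNames(
    vapply(net$populations, `[[`, 0, "size"),
    vapply(net$populations, `[[`, "", "name"))
  for (i in seq_along(net$connections)) {
    con <- net$connections[[i]]
    cpath <- sprintf("network.connections[%d]", i - 1L)
    for (endp in c("pre", "post")) {
      p <- con[[endp]]$path
      seg <- tryCatch(parse_path(p), nsc_error = function(e) NULL)
      if (is.null(seg) || length(seg) == 0L) {
        add("error", "connection-path", cpath, sprintf("unparseable %s path '%s'", endp, p))
        next
      }
      last <- seg[[length(seg)]]
      if (!last$name %in% names(sizes)) {
        add("error", "connection-population", cpath,
            sprintf("%s path '%s' references undeclared population '%s'", endp, p, last$name))
      } else if (!is.na(last$index) && last$index >= sizes[[last$name]]) {
        add("error", "connection-index", cpath,
            sprintf("%s path '%s' indexes population '%s' of size %d out of range",
                    endp, p, last$name, sizes[[last$name]]))
      }
    }
  }
}
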