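#' Path-based addressing
#'
#' Model and instance nodes are addressed with dot-separated paths; array
#' elements use zero-based bracket indices, e.g. `"net.excitatory[2].v"`.
#' The empty path addresses the root. [resolve_path()] returns the unique
#' node a path addresses; unknown segments raise a path-not-found error
#' naming the deepest valid prefix, and an index at or beyond the array size
#' raises an index-out-of-range error.
#'
#' @param root A [new_model()] or an instance tree from [instantiate()].
#' @param path Path string.
#' @return For a model: the addressed variable or type object. For an
#'   instance tree: the addressed instance (class `nsc_instance`).
#' @export
resolve_path <- function(root, path) UseMethod("resolve_path")

# "net.excitatory[2].v" -> list of list(name, index) segments (index NA when
# the segment carries no bracket access).
parse_path <- function(path) {
  stopifnot(is.character(path), length(path) == 1L)
  if (!nzchar(path)) return(list())
  segs <- strsplit(path, ".", fixed = TRUE)[[1]]
  lapply(segs, function(s) {
    mm <- regmatches(s, regexec("^([A-Za-z_][A-Za-z0-9_]*)(\\[([0-9]+)\\])?$", s))[[1]]
    if (length(mm) == 0L) {
      nsc_abort(sprintf("path segment '%s' violates the path grammar", s),
                "nsc_path_grammar")
    }
    list(name = mm[2], index = if (nzchar(mm[3])) as.integer(mm[4]) else NA_integer_)
  })
}

path_not_found <- function(path, prefix) {
  nsc_abort(sprintf("path '%s' not found (deepest valid prefix: '%s')", path, prefix),
            "nsc_path_not_found", deepest_valid_prefix = prefix)
}

#' @export
resolve_path.nsc_model <- function(root, path) {
  segs <- parse_path(path)
  if (length(segs) == 0L) return(root)
  node <- NULL          # current variable or type object
  vars <- root$variables
  prefix <- ""
  for (seg in segs) {
    hit <- NULL
    for (v in vars) if (v$name == seg$name) { hit <- v; break }
    if (is.null(hit)) path_not_found(path, prefix)
    prefix <- if (nzchar(prefix)) paste0(prefix, ".", seg$name) else seg$name
    tinfo <- lookup_type(root, hit$type)
    if (is.null(tinfo)) path_not_found(path, prefix)
    t <- tinfo$type
    node <- hit
    if (!is.na(seg$index)) {
      if (t$kind != "array") path_not_found(path, prefix)
      if (seg$index >= t$size) {
        nsc_abort(sprintf("index %d out of range for array '%s' of size %d",
                          seg$index, seg$name, t$size),
                  "nsc_index_out_of_range")
      }
      tinfo <- lookup_type(root, t$element_type)
      if (is.null(tinfo)) path_not_found(path, prefix)
      t <- tinfo$type
      node <- t
      prefix <- sprintf("%s[%d]", prefix, seg$index)
    }
    vars <- if (t$kind == "composite") {
      eff <- tryCatch(effective_fields(t, root), nsc_error = function(e) t$variables)
      unname(eff)
    } else {
      list()
    }
  }
  node
}

#' @export
resolve_path.nsc_instance_tree <- function(root, path) {
  segs <- parse_path(path)
  if (length(segs) == 0L) return(root)
  children <- root$roots
  prefix <- ""
  node <- NULL
  for (seg in segs) {
    hit <- NULL
    for (ch in children) if (ch$name == seg$name) { hit <- ch; break }
    if (is.null(hit)) path_not_found(path, prefix)
    prefix <- if (nzchar(prefix)) paste0(prefix, ".", seg$name) else seg$name
    if (!is.na(seg$index)) {
      if (hit$kind != "array") path_not_found(path, prefix)
      if (seg$index >= length(hit$children)) {
        nsc_abort(sprintf("index %d out of range for array '%s' of size %d",
                          seg$index, seg$name, length(hit$children)),
                  "nsc_index_out_of_range")
      }
      hit <- hit$children[[seg$index + 1L]]
      prefix <- sprintf("%s[%d]", prefix, seg$index)
    }
    node <- hit
    children <- hit$children %||% list()
  }
  node
}
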