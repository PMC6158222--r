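#' @name interpreters
#' @title Model interpreters
#' @description
#' Model interpreters convert descriptions in a domain language into
#' meta-model types: [interpret_swc()] for segmented neuronal morphology
#' reconstructions, [interpret_obj()] for Wavefront OBJ surface meshes and
#' [interpret_network()] for a small network dialect. Interpreters are pure:
#' the same input stream always yields a structurally identical result.
#' @keywords internal
NULL

read_source_lines <- function(source, text) {
  if (!is.null(text)) {
    strsplit(text, "\n", fixed = TRUE)[[1]]
  } else {
    if (!file.exists(source)) {
      nsc_abort(sprintf("cannot read '%s': no such file", source), "nsc_io_error")
    }
    readLines(source, warn = FALSE)
  }
}

#' Interpret an SWC neuronal morphology
#'
#' Parses the 7-column SWC format (id, structure code, x, y, z, radius,
#' parent id; `#` comment lines ignored; coordinates and radii taken as
#' micrometres) into a composite type holding geometric values: one sphere
#' per soma node (structure code 1, radius = node radius) and one tapered
#' cylinder (frustum) per non-root node spanning the parent position to the
#' node position with `r1` = parent radius and `r2` = node radius. No
#' cylinder is emitted between two soma nodes, so multi-node somas render as
#' spheres only; for single-soma morphologies the counts satisfy
#' `#cylinders = #nodes - #roots`. Unknown structure codes are preserved and
#' rendered as cylinders. Children must be declared after their parent;
#' forward references are rejected as dangling parents.
#'
#' @param source Path to an SWC file (ignored when `text` is given).
#' @param text Optional SWC document text.
#' @param name Name of the returned composite type.
#' @return A [composite_type()] with one variable per geometric value.
#' @examples
#' ct <- interpret_swc(text = "1 1 0 0 0 5 -1", name = "soma_only")
#' collect_visual_values(ct)[[1]]$value_type  # "Sphere"
#' @export
interpret_swc <- function(source = NULL, text = NULL, name = "morphology") {
  lines <- read_source_lines(source, text)
  nodes <- new.env(hash = TRUE, parent = emptyenv())  # id -> node record
  vars <- vector("list", length(lines))
  nv <- 0L
  for (ln in seq_along(lines)) {
    s <- trimws(lines[ln])
    if (!nzchar(s) || startsWith(s, "#")) next
    fields <- strsplit(s, "[ \t]+")[[1]]
    if (length(fields) != 7L) {
      nsc_abort(sprintf("SWC parse error at line %d: expected 7 fields, found %d",
                        ln, length(fields)),
                "nsc_parse_error", line = ln)
    }
    num <- suppressWarnings(as.numeric(fields))
    if (anyNA(num)) {
      nsc_abort(sprintf("SWC parse error at line %d: non-numeric field", ln),
                "nsc_parse_error", line = ln)
    }
    id <- as.integer(num[1]); code <- as.integer(num[2])
    pos <- num[3:5]; radius <- num[6]; parent <- as.integer(num[7])
    key <- as.character(id)
    if (!is.null(nodes[[key]])) {
      nsc_abort(sprintf("SWC parse error at line %d: duplicate node id %d", ln, id),
                "nsc_parse_error", line = ln)
    }
    if (radius <= 0) {
      nsc_abort(sprintf("SWC node %d has non-positive radius %g", id, radius),
                "nsc_invalid_radius", node_id = id)
    }
    if (parent != -1L && is.null(nodes[[as.character(parent)]])) {
      nsc_abort(sprintf("SWC node %d references parent %d which has not been declared",
                        id, parent),
                "nsc_dangling_parent", node_id = id)
    }
    nodes[[key]] <- list(code = code, pos = pos, radius = radius, parent = parent)
    if (code == 1L) {
      nv <- nv + 1L
      vars[[nv]] <- new_variable(
        sprintf("node%d_soma", id), "common.Visual",
        initial_values = list(sphere_value(pos, radius)))
    }
    if (parent != -1L) {
      pn <- nodes[[as.character(parent)]]
      if (!(code == 1L && pn$code == 1L)) {
        nv <- nv + 1L
        vars[[nv]] <- new_variable(
          sprintf("node%d_seg", id), "common.Visual",
          initial_values = list(cylinder_value(pn$pos, pos, pn$radius, radius)))
      }
    }
  }
  composite_type(name, variables = vars[seq_len(nv)])
}

#' Interpret a Wavefront OBJ mesh
#'
#' Honors only `v` (vertex) and `f` (face) records; all other record types
#' (normals, texture coordinates, materials, groups) are ignored silently.
#' Face indices are 1-based per the OBJ convention and converted to 0-based;
#' `v/vt/vn` slash forms keep only the vertex index. Polygon faces with more
#' than three vertices are fan-triangulated into `n - 2` triangles, which
#' conserves the area of planar convex faces.
#'
#' @inheritParams interpret_swc
#' @return A [mesh_value()].
#' @export
interpret_obj <- function(source = NULL, text = NULL) {
  lines <- read_source_lines(source, text)
  vertices <- list()
  faces <- list()
  saw_geometry <- FALSE
  for (ln in seq_along(lines)) {
    s <- trimws(lines[ln])
    if (!nzchar(s)) next
    fields <- strsplit(s, "[ \t]+")[[1]]
    rec <- fields[1]
    if (rec == "v") {
      if (length(fields) < 4L) {
        nsc_abort(sprintf("OBJ parse error at line %d: vertex needs 3 coordinates", ln),
                  "nsc_parse_error", line = ln)
      }
      vertices[[length(vertices) + 1L]] <- as.numeric(fields[2:4])
      saw_geometry <- TRUE
    } else if (rec == "f") {
      idx <- vapply(fields[-1], function(tok)
        as.integer(strsplit(tok, "/", fixed = TRUE)[[1]][1]), integer(1))
      if (length(idx) < 3L || anyNA(idx)) {
        nsc_abort(sprintf("OBJ parse error at line %d: face needs >= 3 vertex indices", ln),
                  "nsc_parse_error", line = ln)
      }
      if (any(idx < 1L) || any(idx > length(vertices))) {
        nsc_abort(sprintf("OBJ face at line %d references vertex outside range [1, %d]",
                          ln, length(vertices)),
                  "nsc_index_error", line = ln)
      }
      idx <- idx - 1L                        # to 0-based
      for (k in seq_len(length(idx) - 2L)) { # fan triangulation
        faces[[length(faces) + 1L]] <- c(idx[1], idx[k + 1L], idx[k + 2L])
      }
      saw_geometry <- TRUE
    }
  }
  if (!saw_geometry) {
    nsc_abort("OBJ stream contains no geometry records (no 'v' or 'f' lines)",
              "nsc_empty_geometry")
  }
  mesh_value(vertices, faces)
}

#' Describe a toy network
#'
#' Input document for [interpret_network()]: named cell definitions (a
#' morphology source plus leaky integrate-and-fire dynamics parameters and
#' optional per-parameter bounds), populations instantiating a cell
#' definition a fixed number of times, and weighted cell-to-cell
#' connections.
#'
#' @param cell_defs Named list; each entry a list with elements `morphology`
#'   (SWC path or `NULL`), `dynamics` (named list of [neuron_dynamics()]
#'   parameters) and optionally `bounds` (named list of `c(lo, hi)`).
#' @param populations List of `list(name, cell_def, size)`.
#' @param connections List of `list(pre, post, weight)` with cell paths like
#'   `"net.pop1[0]"`.
#' @return An object of class `nsc_network_doc`.
#' @export
network_doc <- function(cell_defs = list(), populations = list(),
                        connections = list()) {
  stopifnot(is.list(cell_defs), is.list(populations), is.list(connections))
  for (p in populations) {
    if (!p$cell_def %in% names(cell_defs)) {
      nsc_abort(sprintf("population '%s' references undeclared cell definition '%s'",
                        p$name, p$cell_def),
                "nsc_invalid_argument")
    }
    if (p$size < 0) nsc_abort("population sizes must be >= 0", "nsc_invalid_argument")
  }
  structure(list(cell_defs = cell_defs, populations = populations,
                 connections = connections),
            class = "nsc_network_doc")
}

PARAM_UNITS <- c(v_rest = "mV", v_thr = "mV", v_reset = "mV",
                 r_m = "MOhm", tau_m = "ms", i_ext = "nA", t_ref = "ms")

#' Interpret a network document into a model
#'
#' Builds a full model from a [network_doc()]: one array type per population
#' (declared size), one composite cell type per cell definition containing a
#' state variable `v` (unit mV, initial value at the resting potential) and
#' one parameter per dynamics entry, and a root variable `net`. Morphologies
#' are attached as import types resolved lazily through the `"swc"`
#' interpreter by default (`lazy = TRUE`); with `lazy = FALSE` they are
#' interpreted eagerly at build time, which fails immediately if a
#' morphology file is missing. Connections are stored as pointer pairs plus
#' weight in the model's network metadata; see [connectivity_matrix()].
#'
#' @param doc A [network_doc()].
#' @param base_dir Directory against which morphology paths resolve.
#' @param lazy Defer morphology interpretation to [resolve_import()]?
#' @param model_id Id of the resulting model.
#' @return A [new_model()].
#' @export
interpret_network <- function(doc, base_dir = ".", lazy = TRUE,
                              model_id = "network_model") {
  stopifnot(inherits(doc, "nsc_network_doc"))
  cell_types <- list()
  defaults <- list(v_rest = -65, v_thr = -50, v_reset = -65,
                   r_m = 10, tau_m = 10, i_ext = 0, t_ref = 0)
  for (cd in names(doc$cell_defs)) {
    def <- doc$cell_defs[[cd]]
    dyn <- def$dynamics %||% list()
    bounds <- def$bounds %||% list()
    members <- list()
    for (p in names(PARAM_UNITS)) {
      value <- as.numeric(dyn[[p]] %||% defaults[[p]])
      cell_types[[length(cell_types) + 1L]] <- parameter_type(
        paste0(cd, "_", p), unit = PARAM_UNITS[[p]], default_value = value,
        bounds = bounds[[p]])
      members[[length(members) + 1L]] <- new_variable(p, paste0("cells.", cd, "_", p))
    }
    v_rest <- as.numeric(dyn$v_rest %||% defaults$v_rest)
    cell_types[[length(cell_types) + 1L]] <- state_variable_type(
      paste0(cd, "_V"), unit = "mV", initial_value = v_rest)
    members <- c(list(new_variable("v", paste0("cells.", cd, "_V"))), members)
    if (!is.null(def$morphology)) {
      morph_name <- paste0(cd, "_morphology")
      cell_types[[length(cell_types) + 1L]] <- if (lazy) {
        import_type(morph_name, "swc", def$morphology)
      } else {
        interpret_swc(file.path(base_dir, def$morphology), name = morph_name)
      }
      members[[length(members) + 1L]] <- new_variable(
        "morphology", paste0("cells.", morph_name))
    }
    cell_types[[length(cell_types) + 1L]] <- composite_type(
      paste0(cd, "_cell"), variables = members)
  }

  net_types <- list()
  net_members <- list()
  for (p in doc$populations) {
    net_types[[length(net_types) + 1L]] <- array_type(
      paste0(p$name, "_array"),
      element_type = paste0("cells.", p$cell_def, "_cell"),
      size = p$size)
    net_members[[length(net_members) + 1L]] <- new_variable(
      p$name, paste0("network.", p$name, "_array"))
  }
  net_types[[length(net_types) + 1L]] <- composite_type("Network",
                                                        variables = net_members)

  new_model(
    model_id,
    libraries = list(
      new_library("common", list(primitive_type("Visual"))),
      new_library("cells", cell_types),
      new_library("network", net_types)),
    variables = list(new_variable("net", "network.Network")),
    network = list(
      populations = doc$populations,
      connections = lapply(doc$connections, function(con)
        list(pre = pointer_value(con$pre), post = pointer_value(con$post),
             weight = as.numeric(con$weight %||% 1)))))
}

#' Population-level connectivity matrix
#'
#' Summarizes a network model's connections as a square matrix indexed by
#' population declaration order: entry `(i, j)` counts the connections with
#' presynaptic cell in population `i` and postsynaptic cell in population
#' `j` (`weights = TRUE` sums connection weights instead). The matrix total
#' equals the number (or total weight) of connection records. This is the
#' quantity behind population connectivity displays such as chord diagrams.
#'
#' @param model A model produced by [interpret_network()].
#' @param weights Sum weights instead of counting?
#' @return A square numeric matrix with population names as dimnames.
#' @export
connectivity_matrix <- function(model, weights = FALSE) {
  stopifnot(inherits(model, "nsc_model"))
  if (is.null(model$network)) {
    nsc_abort("model carries no network metadata", "nsc_invalid_argument")
  }
  pops <- vapply(model$network$populations, `[[`, "", "name")
  mat <- matrix(0, length(pops), length(pops), dimnames = list(pops, pops))
  pop_of <- function(path) {
    segs <- parse_path(path)
    segs[[length(segs)]]$name
  }
  for (con in model$network$connections) {
    i <- pop_of(con$pre$path); j <- pop_of(con$post$path)
    mat[i, j] <- mat[i, j] + if (weights) con$weight else 1
  }
  mat
}

#' Collect the geometric values of a composite type
#'
#' Flattens the sphere/cylinder/mesh values held in a composite's variables
#' (e.g. the output of [interpret_swc()]) into one list, in declaration
#' order.
#'
#' @param t A [composite_type()].
#' @return List of visual value objects.
#' @export
collect_visual_values <- function(t) {
  stopifnot(inherits(t, "nsc_type"))
  out <- list()
  for (v in t$variables %||% list()) {
    for (val in v$initial_values) {
      if (is_visual_value(val)) out[[length(out) + 1L]] <- val
    }
  }
  out
}
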