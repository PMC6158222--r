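#' Values
#'
#' Concrete data filling a variable slot. A value is a tagged union over:
#' scalars with a unit, visual primitives (sphere, tapered cylinder, mesh)
#' with coordinates in micrometres, recorded time series, and pointers
#' (path strings addressing other nodes).
#'
#' @param value,unit Scalar magnitude and unit string.
#' @param center,radius Sphere centre (3-vector, um) and radius (um, > 0).
#' @param p1,p2 Cylinder end points (3-vectors, um); must differ.
#' @param r1,r2 Cylinder radii at `p1` and `p2` (um, > 0); unequal radii
#'   describe a frustum (tapered cylinder).
#' @param vertices List of 3-vectors (um).
#' @param faces List of integer triples (zero-based vertex indices).
#' @param times,values Strictly increasing sample times (seconds) and the
#'   recorded values, equal length.
#' @param path Pointer target path (see [resolve_path()]).
#' @return A value object (class `nsc_value`).
#' @name values
NULL

# leading dot avoids partial matching against field names like `value`
new_value <- function(.value_type, ...) {
  structure(c(list(value_type = .value_type), list(...)),
            class = c(paste0("nsc_value_", tolower(.value_type)), "nsc_value"))
}

#' @rdname values
#' @export
scalar_value <- function(value, unit = "") {
  new_value("Scalar", value = assert_scalar_number(value, "value"), unit = unit)
}

#' @rdname values
#' @export
sphere_value <- function(center, radius) {
  stopifnot(is.numeric(center), length(center) == 3L)
  radius <- assert_scalar_number(radius, "radius")
  if (radius <= 0) nsc_abort("sphere radius must be > 0", "nsc_invalid_value")
  new_value("Sphere", center = as.numeric(center), radius = radius)
}

#' @rdname values
#' @export
cylinder_value <- function(p1, p2, r1, r2) {
  stopifnot(is.numeric(p1), length(p1) == 3L, is.numeric(p2), length(p2) == 3L)
  r1 <- assert_scalar_number(r1, "r1"); r2 <- assert_scalar_number(r2, "r2")
  if (r1 <= 0 || r2 <= 0) nsc_abort("cylinder radii must be > 0", "nsc_invalid_value")
  if (all(p1 == p2)) nsc_abort("cylinder end points must differ", "nsc_invalid_value")
  new_value("Cylinder", p1 = as.numeric(p1), p2 = as.numeric(p2), r1 = r1, r2 = r2)
}

#' @rdname values
#' @export
mesh_value <- function(vertices, faces) {
  stopifnot(is.list(vertices), is.list(faces))
  nv <- length(vertices)
  for (v in vertices) stopifnot(is.numeric(v), length(v) == 3L)
  for (f in faces) {
    stopifnot(is.numeric(f), length(f) == 3L)
    if (any(f < 0) || any(f >= nv)) {
      nsc_abort(sprintf("mesh face references vertex outside range [0, %d)", nv),
                "nsc_index_error")
    }
  }
  new_value("Mesh",
            vertices = lapply(vertices, as.numeric),
            faces = lapply(faces, as.integer))
}

#' @rdname values
#' @export
time_series_value <- function(times, values, unit = "") {
  stopifnot(is.numeric(times), is.numeric(values))
  if (length(times) != length(values)) {
    nsc_abort("time series: times and values must have equal length", "nsc_invalid_value")
  }
  if (length(times) > 1L && any(diff(times) <= 0)) {
    nsc_abort("time series: times must be strictly increasing", "nsc_invalid_value")
  }
  new_value("TimeSeries", times = as.numeric(times), values = as.numeric(values),
            unit = unit)
}

#' @rdname values
#' @export
pointer_value <- function(path) {
  stopifnot(is.character(path), length(path) == 1L)
  new_value("Pointer", path = path)
}

is_visual_value <- function(v) {
  inherits(v, "nsc_value") && v$value_type %in% c("Sphere", "Cylinder", "Mesh")
}

#' @export
print.nsc_value <- function(x, ...) {
  cat(sprintf("<nsc_value %s>\n", x$value_type))
  invisible(x)
}
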