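# Shared fixture builders and independent oracles.

# Three-level state-variable inheritance chain A <- B <- C plus a composite
# hierarchy for field-merge tests.
make_inheritance_model <- function() {
  new_model("inh", libraries = list(new_library("lib", list(
    state_variable_type("A", unit = "mV", initial_value = -70),
    state_variable_type("B", unit = "mV", initial_value = NULL, supertype = "lib.A"),
    state_variable_type("C", unit = "mV", initial_value = -60, supertype = "lib.B"),
    composite_type("Base", variables = list(new_variable("v", "lib.A"))),
    composite_type("Child", supertype = "lib.Base", variables = list(
      new_variable("g", "lib.A"),
      new_variable("v", "lib.A", initial_values = list(scalar_value(-55, "mV")))))))))
}

# write a small self-contained network project to dir and return its paths
tiny_project <- function(dir, seed = 1, sizes = c(2, 3), n_connections = 4,
                         n_nodes = 5) {
  generate_project(fixture_spec(seed = seed, n_nodes = n_nodes,
                                population_sizes = sizes,
                                n_connections = n_connections),
                   dir)
}

# pull the raw type object of a qualified name out of a model
lookup_child <- function(m, ref) {
  for (lib in m$libraries) for (t in lib$types) {
    if (paste0(lib$id, ".", t$name) == ref) return(t)
  }
  stop("type not found: ", ref)
}

# closed-form subthreshold membrane trajectory from rest
lif_closed_form <- function(d, t) {
  d$v_rest + d$r_m * d$i_ext * (1 - exp(-t / d$tau_m))
}

# closed-form interspike interval (threshold crossing from v_reset)
lif_isi <- function(d) {
  drive <- d$r_m * d$i_ext
  d$t_ref + d$tau_m * log((drive - (d$v_reset - d$v_rest)) /
                          (drive - (d$v_thr - d$v_rest)))
}

# independent SWC table parse (oracle for interpreter tests)
swc_table <- function(text) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  tab <- utils::read.table(text = paste(lines, collapse = "\n"))
  names(tab) <- c("id", "code", "x", "y", "z", "radius", "parent")
  tab
}

# area of a planar polygon embedded in 3-space (shoelace in its own plane)
planar_polygon_area <- function(pts) {
  n <- nrow(pts)
  total <- c(0, 0, 0)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    a <- pts[i, ]; b <- pts[j, ]
    total <- total + c(a[2] * b[3] - a[3] * b[2],
                       a[3] * b[1] - a[1] * b[3],
                       a[1] * b[2] - a[2] * b[1])
  }
  sqrt(sum(total^2)) / 2
}

triangle_area <- function(a, b, c) {
  u <- b - a; v <- c - a
  cr <- c(u[2] * v[3] - u[3] * v[2],
          u[3] * v[1] - u[1] * v[3],
          u[1] * v[2] - u[2] * v[1])
  sqrt(sum(cr^2)) / 2
}
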