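count_kind <- function(ct, kind) {
  sum(vapply(collect_visual_values(ct), function(v) v$value_type == kind, TRUE))
}

test_that("SWC interpretation follows the sphere/cylinder rules", {
  # single root soma: one sphere of the node's radius, no cylinders
  ct <- interpret_swc(text = "1 1 0 0 0 5 -1")
  vv <- collect_visual_values(ct)
  expect_length(vv, 1)
  expect_identical(vv[[1]]$value_type, "Sphere")
  expect_equal(vv[[1]]$radius, 5)

  # unbranched 3-node chain rooted at a soma: 1 sphere + 2 cylinders
  chain <- paste("1 1 0 0 0 5 -1",
                 "2 3 0 0 10 2 1",
                 "3 3 0 0 20 1 2", sep = "\n")
  ct <- interpret_swc(text = chain)
  expect_equal(count_kind(ct, "Sphere"), 1)
  expect_equal(count_kind(ct, "Cylinder"), 2)
  # frustum taper: r1 from the parent node, r2 from the child
  cyl <- collect_visual_values(ct)[[2]]
  expect_equal(cyl$r1, 5)
  expect_equal(cyl$r2, 2)
  expect_equal(cyl$p1, c(0, 0, 0))
  expect_equal(cyl$p2, c(0, 0, 10))

  # multi-node soma: spheres per node, no soma-soma cylinder
  soma2 <- paste("1 1 0 0 0 5 -1",
                 "2 1 0 0 5 4 1",
                 "3 3 0 0 10 1 2", sep = "\n")
  ct <- interpret_swc(text = soma2)
  expect_equal(count_kind(ct, "Sphere"), 2)
  expect_equal(count_kind(ct, "Cylinder"), 1)
})

test_that("SWC errors carry the offending node or line", {
  expect_error(interpret_swc(text = "1 1 0 0 0 5 7"),
               class = "nsc_dangling_parent")
  err <- expect_error(interpret_swc(text = "2 3 0 0 0 1 7"),
                      class = "nsc_dangling_parent")
  expect_match(conditionMessage(err), "7")
  expect_error(interpret_swc(text = "1 1 0 0 0 0 -1"),
               class = "nsc_invalid_radius")
  err <- expect_error(interpret_swc(text = "1 1 0 0 0 5 -1\n2 3 0 0"),
                      class = "nsc_parse_error")
  expect_identical(err$line, 2L)
  # children must come after their parent (no forward-reference buffering)
  expect_error(interpret_swc(text = "1 1 0 0 0 5 2\n2 3 0 0 1 1 -1"),
               class = "nsc_dangling_parent")
})

test_that("SWC value counts and cylinder endpoints match the input table", {
  for (seed in c(2, 9, 13)) {
    swc <- generate_swc(120, branching_prob = 0.25, seed = seed)
    ct <- interpret_swc(text = swc)
    tab <- swc_table(swc)
    roots <- sum(tab$parent == -1)
    somas <- sum(tab$code == 1)
    expect_equal(count_kind(ct, "Sphere"), somas)
    expect_equal(count_kind(ct, "Cylinder"), nrow(tab) - roots)

    # every cylinder spans a parent->child position pair of the input
    pos <- as.matrix(tab[, c("x", "y", "z")])
    pair_key <- function(p1, p2) paste(c(p1, p2), collapse = "|")
    expected <- vapply(which(tab$parent != -1), function(i)
      pair_key(pos[tab$parent[i], ], pos[i, ]), "")
    got <- vapply(Filter(function(v) v$value_type == "Cylinder",
                         collect_visual_values(ct)),
                  function(v) pair_key(v$p1, v$p2), "")
    expect_setequal(got, expected)
  }
})

test_that("interpreters are pure: identical input yields identical output", {
  swc <- generate_swc(40, seed = 5)
  expect_identical(interpret_swc(text = swc), interpret_swc(text = swc))
  obj <- "v 0 0 0\nv 1 0 0\nv 1 1 0\nf 1 2 3\n"
  expect_identical(interpret_obj(text = obj), interpret_obj(text = obj))
})

test_that("OBJ meshes honor v/f records and fan-triangulate polygons", {
  # unit cube written as 12 explicit triangles
  tri_cube <- paste(
    "# cube", "v 0 0 0", "v 1 0 0", "v 1 1 0", "v 0 1 0",
    "v 0 0 1", "v 1 0 1", "v 1 1 1", "v 0 1 1",
    "f 1 2 3", "f 1 3 4", "f 5 7 6", "f 5 8 7",
    "f 1 5 6", "f 1 6 2", "f 2 6 7", "f 2 7 3",
    "f 3 7 8", "f 3 8 4", "f 4 8 5", "f 4 5 1", sep = "\n")
  mesh <- interpret_obj(text = tri_cube)
  expect_length(mesh$vertices, 8)
  expect_length(mesh$faces, 12)

  # a quad fans into 2 triangles; slash forms keep only the vertex index
  quad <- "v 0 0 0\nv 1 0 0\nv 1 1 0\nv 0 1 0\nf 1/1/1 2/2/2 3/3/3 4/4/4\n"
  mesh <- interpret_obj(text = quad)
  expect_length(mesh$faces, 2)

  # non-geometry records are ignored silently
  with_noise <- paste("mtllib x.mtl", "vn 0 0 1", "vt 0 0", "usemtl m", quad, sep = "\n")
  expect_identical(interpret_obj(text = with_noise), interpret_obj(text = quad))

  expect_error(interpret_obj(text = "# only comments\n"),
               class = "nsc_empty_geometry")
  expect_error(interpret_obj(text = "v 0 0 0\nf 1 2 9\n"),
               class = "nsc_index_error")
})

test_that("fan triangulation conserves the area of planar convex faces", {
  withr::with_seed(31, {
    for (rep in 1:5) {
      n <- sample(4:8, 1)
      angles <- sort(stats::runif(n, 0, 2 * pi))
      r <- stats::runif(1, 1, 4)
      # planar convex polygon embedded in a random 3D plane
      u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
      w <- stats::rnorm(3); w <- w - sum(w * u) * u; w <- w / sqrt(sum(w^2))
      pts <- t(vapply(angles, function(a) r * cos(a) * u + r * sin(a) * w,
                      numeric(3)))
      obj <- paste(c(sprintf("v %.12f %.12f %.12f", pts[, 1], pts[, 2], pts[, 3]),
                     paste("f", paste(seq_len(n), collapse = " "))),
                   collapse = "\n")
      mesh <- interpret_obj(text = obj)
      expect_length(mesh$faces, n - 2)
      tri_total <- sum(vapply(mesh$faces, function(f)
        triangle_area(mesh$vertices[[f[1] + 1]],
                      mesh$vertices[[f[2] + 1]],
                      mesh$vertices[[f[3] + 1]]), 0))
      expect_equal(tri_total, planar_polygon_area(pts), tolerance = 1e-9)
    }
  })
})

test_that("network interpretation expands populations and flags bad connections", {
  cd <- list(dynamics = list(i_ext = 1))
  doc <- network_doc(
    cell_defs = list(exc = cd, inh = cd),
    populations = list(list(name = "e", cell_def = "exc", size = 2),
                       list(name = "i", cell_def = "inh", size = 3)))
  m <- interpret_network(doc)
  expect_identical(nrow(validate_model(m)), 0L)
  tree <- instantiate(m)
  cells <- instance_paths(tree, capability = "StateVariableCapability")
  expect_length(cells, 5)

  # size-0 population still yields a valid model
  doc0 <- network_doc(cell_defs = list(exc = cd),
                      populations = list(list(name = "e", cell_def = "exc", size = 0)))
  expect_identical(nrow(validate_model(interpret_network(doc0))), 0L)

  # undeclared cell definition is rejected at document construction
  expect_error(network_doc(cell_defs = list(exc = cd),
                           populations = list(list(name = "e", cell_def = "nope", size = 1))),
               class = "nsc_invalid_argument")

  # out-of-range connection index becomes a validation finding
  bad <- network_doc(
    cell_defs = list(exc = cd),
    populations = list(list(name = "e", cell_def = "exc", size = 3)),
    connections = list(list(pre = "net.e[5]", post = "net.e[0]", weight = 1)))
  rep <- validate_model(interpret_network(bad))
  expect_true("connection-index" %in% rep$rule)
})

test_that("connectivity matrices count and conserve connections", {
  cd <- list(dynamics = list())
  mk <- function(cons) interpret_network(network_doc(
    cell_defs = list(a = cd, b = cd),
    populations = list(list(name = "A", cell_def = "a", size = 3),
                       list(name = "B", cell_def = "b", size = 3)),
    connections = cons))

  expect_equal(connectivity_matrix(mk(list())),
               matrix(0, 2, 2, dimnames = list(c("A", "B"), c("A", "B"))))

  cons <- lapply(0:2, function(i)
    list(pre = sprintf("net.A[%d]", i), post = sprintf("net.B[%d]", i), weight = 0.5))
  expect_equal(unname(connectivity_matrix(mk(cons))),
               matrix(c(0, 0, 3, 0), 2, 2))
  expect_equal(sum(connectivity_matrix(mk(cons), weights = TRUE)), 1.5)

  withr::with_seed(17, {
    cells <- c(sprintf("net.A[%d]", 0:2), sprintf("net.B[%d]", 0:2))
    cons <- lapply(1:50, function(k)
      list(pre = sample(cells, 1), post = sample(cells, 1), weight = stats::runif(1)))
    expect_equal(sum(connectivity_matrix(mk(cons))), 50)
  })
})
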