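test_that("supertype lineage resolution handles base, chain and cycle cases", {
  m <- make_inheritance_model()
  a <- lookup_a <- resolve_supertypes("lib.A", m)
  expect_length(a, 1)
  expect_equal(a[[1]]$name, "A")

  lineage <- resolve_supertypes("lib.C", m)
  expect_equal(vapply(lineage, `[[`, "", "name"), c("C", "B", "A"))

  cyc <- new_model("cyc", libraries = list(new_library("lib", list(
    state_variable_type("A", unit = "mV", supertype = "lib.B"),
    state_variable_type("B", unit = "mV", supertype = "lib.A")))))
  err <- expect_error(resolve_supertypes("lib.A", cyc), class = "nsc_inheritance_cycle")
  expect_match(conditionMessage(err), "A")
  expect_match(conditionMessage(err), "B")

  dangling <- new_model("d", libraries = list(new_library("lib", list(
    state_variable_type("A", unit = "mV", supertype = "lib.Gone")))))
  expect_error(resolve_supertypes("lib.A", dangling), class = "nsc_unknown_type")
})

test_that("effective fields merge root-down with nearest-descendant override", {
  m <- make_inheritance_model()

  # child adds a field, parent's remains
  eff <- effective_fields(lookup_child(m, "lib.Child"), m)
  expect_setequal(names(eff), c("v", "g"))

  # child's redefinition of the inherited initial value wins
  expect_equal(eff$v$initial_values[[1]]$value, -55)

  # scalar-attribute merge: B inherits A's initial value, C overrides it
  effB <- effective_fields(lookup_child(m, "lib.B"), m)
  expect_equal(effB$initial_value, -70)
  effC <- effective_fields(lookup_child(m, "lib.C"), m)
  expect_equal(effC$initial_value, -60)

  # lineage of one: fields unchanged
  effA <- effective_fields(lookup_child(m, "lib.A"), m)
  expect_equal(effA$unit, "mV")
  expect_equal(effA$initial_value, -70)

  # idempotence: a synthetic type built from the merged fields is a no-op
  merged <- composite_type("Merged", variables = unname(eff))
  expect_equal(effective_fields(merged, m), eff)
})

test_that("validation returns findings as data with deterministic ordering", {
  clean <- new_model("ok", libraries = list(new_library("lib", list(
    primitive_type("Txt")))))
  expect_identical(nrow(validate_model(clean)), 0L)

  unknown <- new_model("bad", libraries = list(new_library("lib", list())),
                       variables = list(new_variable("x", "Foo")))
  rep <- validate_model(unknown)
  expect_identical(nrow(rep), 1L)
  expect_equal(rep$severity, "error")
  expect_match(rep$message, "Foo")

  # three same-named types: one finding per duplicate beyond the first
  dup <- new_model("dup", libraries = list(new_library("lib", list(
    primitive_type("T"), primitive_type("T"), primitive_type("T")))))
  rep <- validate_model(dup)
  expect_identical(nrow(rep), 2L)
  expect_true(all(rep$rule == "type-name-unique"))

  # ordering is by path then rule, independent of construction order
  messy <- new_model("messy", libraries = list(
    new_library("zlib", list(primitive_type("Z"), primitive_type("Z"))),
    new_library("alib", list(state_variable_type("S", unit = "")))))
  rep <- validate_model(messy)
  expect_identical(rep$path, sort(rep$path, method = "radix"))
})

test_that("a subtype may not redeclare an inherited variable's type", {
  m <- new_model("redef", libraries = list(new_library("lib", list(
    state_variable_type("V", unit = "mV"),
    parameter_type("P", unit = "nA", default_value = 1),
    composite_type("Base", variables = list(new_variable("x", "lib.V"))),
    composite_type("Child", supertype = "lib.Base",
                   variables = list(new_variable("x", "lib.P")))))))
  rep <- validate_model(m)
  expect_true("inherited-type-redefinition" %in% rep$rule)
})

test_that("path resolution addresses model and instance nodes", {
  m <- make_inheritance_model()
  expect_identical(resolve_path(m, ""), m)

  withr::with_tempdir({
    p <- tiny_project(".", seed = 11, sizes = c(3))
    proj <- read_project_file(p$project_path)
    tree <- instantiate(proj$model)

    inst <- resolve_path(tree, "net.pop1[2].v")
    expect_s3_class(inst, "nsc_instance")
    expect_identical(inst$path, "net.pop1[2].v")
    expect_true("StateVariableCapability" %in% inst$capabilities)

    expect_error(resolve_path(tree, "net.pop1[99]"),
                 class = "nsc_index_out_of_range")
    err <- expect_error(resolve_path(tree, "net.pop1[0].nope"),
                        class = "nsc_path_not_found")
    expect_identical(err$deepest_valid_prefix, "net.pop1[0]")
    expect_error(resolve_path(tree, "net..v"), class = "nsc_path_grammar")
  })
})

test_that("every enumerated instance path resolves to itself; near-miss paths fail", {
  withr::with_tempdir({
    p <- tiny_project(".", seed = 4, sizes = c(2, 2))
    proj <- read_project_file(p$project_path)
    tree <- resolve_all_imports(instantiate(proj$model))
    paths <- instance_paths(tree)
    expect_gt(length(paths), 10)
    for (pa in paths) {
      expect_identical(resolve_path(tree, pa)$path, pa)
    }
    # single-character mutations that keep the grammar intact must fail
    mutated <- c("nat", "net.pop1[0].w", "net.pop3[0]", "net.pop1[0].v_rest7")
    for (bad in mutated) {
      expect_error(resolve_path(tree, bad), class = "nsc_error")
    }
  })
})

test_that("queries filter conjunctively with stable order", {
  labels <- c("RMEL", "RMER", "AVAL", "AVAR", "PVCL", "PVCR",
              "DVA", "AIYL", "AIYR", "SMDD")
  records <- data.frame(label = labels, n = 1:10, side = rep(c("L", "R"), 5),
                        stringsAsFactors = FALSE)
  ds <- in_memory_data_source(records)

  # empty source
  empty <- in_memory_data_source(records[0, , drop = FALSE])
  expect_identical(run_query(empty, query_decl("q"))$count, 0L)

  # label-contains with exactly two matches
  q <- query_decl("rme", list(query_filter("label", "contains", "RME")))
  res <- run_query(ds, q)
  expect_identical(res$count, 2L)
  expect_identical(res$records$label, c("RMEL", "RMER"))

  # empty filter list is the identity
  all_res <- run_query(ds, query_decl("all"))
  expect_identical(all_res$records, records)

  # unknown field raises a schema error
  expect_error(run_query(ds, query_decl("bad", list(query_filter("nope", "eq", 1)))),
               class = "nsc_query_schema")
})

test_that("chained filters equal the intersection of single-filter results", {
  set.seed(99)
  records <- data.frame(label = sample(c("RME", "AVA", "PVC"), 20, TRUE),
                        n = sample(1:5, 20, TRUE), stringsAsFactors = FALSE)
  ds <- in_memory_data_source(records)
  f1 <- query_filter("label", "eq", "RME")
  f2 <- query_filter("n", "ge", 3)
  both <- run_query(ds, query_decl("b", list(f1, f2)))
  # brute-force oracle: row-index intersection of the single-filter results
  idx1 <- which(records$label == "RME")
  idx2 <- which(records$n >= 3)
  expect_identical(both$count, length(intersect(idx1, idx2)))
  expect_identical(both$records, {
    out <- records[intersect(idx1, idx2), , drop = FALSE]
    rownames(out) <- NULL
    out
  })
  # conjunction bound
  n1 <- run_query(ds, query_decl("f1", list(f1)))$count
  n2 <- run_query(ds, query_decl("f2", list(f2)))$count
  expect_lte(both$count, min(n1, n2))
})
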