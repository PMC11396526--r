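test_that("corannulene fixture has the expected structure", {
  g <- fixture_corannulene()
  expect_equal(g$n, 20L)
  expect_equal(nrow(g$edges), 25L)
  deg <- lengths(g$rotation)
  expect_equal(sum(deg == 2L), 10L)  # CH rim positions
  expect_equal(sum(g$face_kind == "pentagon"), 1L)
  expect_equal(sum(g$face_kind == "hexagon"), 5L)
  expect_equal(sum(g$face_kind == "outer"), 1L)
  v <- validate_fullerene(g)
  expect_false(v$valid)  # degree-2 vertices, outer face
})

test_that("platonic cage fixtures validate as fullerenes", {
  d <- fixture_dodecahedron()
  expect_s3_class(d, "fullerene_graph")
  vd <- validate_fullerene(d)
  expect_true(vd$valid)
  expect_equal(vd$pentagons, 12L)
  expect_equal(vd$hexagons, 0L)
  expect_equal(igraph::girth(ig_of(d))$girth, 5)
  expect_equal(pentagon_adjacency_count(d), 30L)  # every edge

  ti <- fixture_truncated_icosahedron()
  vt <- validate_fullerene(ti)
  expect_true(vt$valid)
  expect_equal(vt$hexagons, 20L)
  expect_equal(nrow(ti$edges), 90L)
  expect_equal(pentagon_adjacency_count(ti), 0L)  # the canonical IPR cage
})

test_that("building from adjacency recovers faces and obeys Euler's relation", {
  d <- fixture_dodecahedron()
  rebuilt <- build_from_adjacency(lapply(d$rotation, sort))
  expect_equal(length(rebuilt$faces), 12L)
  expect_equal(rebuilt$n - nrow(rebuilt$edges) + length(rebuilt$faces), 2L)
  expect_true(graphs_isomorphic(d, rebuilt))

  ti <- fixture_truncated_icosahedron()
  rb <- build_from_adjacency(lapply(ti$rotation, sort))
  expect_equal(sum(rb$face_kind == "pentagon"), 12L)
  expect_equal(sum(rb$face_kind == "hexagon"), 20L)
})

test_that("non pentagon/hexagon inputs are rejected", {
  k4 <- lapply(1:4, function(v) setdiff(1:4, v))  # triangular faces only
  expect_error(build_from_adjacency(k4), "pentagon|hexagon")
  expect_error(build_from_adjacency(list(2L, 1L, 4L, 3L)), "disconnected")
  k4_plus <- matrix(1, 5, 5) - diag(5)            # degree 4
  expect_error(build_from_adjacency(k4_plus), "degree")
  asym <- matrix(0, 6, 6); asym[1, 2] <- 1
  expect_error(build_from_adjacency(asym), "symmetric")
})

test_that("degenerate acyclic molecules get a trivial embedding", {
  k2 <- single_edge_graph()
  expect_equal(nrow(k2$edges), 1L)
  expect_equal(length(k2$faces), 1L)
  p3 <- path3_graph()
  expect_equal(p3$n - nrow(p3$edges) + length(p3$faces), 2L)
})

test_that("face tracing uses each directed edge once and each edge twice", {
  for (g in list(fixture_corannulene(), fixture_dodecahedron(),
                 hexagon_ring(), fixture_truncated_icosahedron())) {
    faces <- trace_faces(g)
    sizes <- vapply(faces, `[[`, 0L, "size")
    expect_equal(sum(sizes), 2L * nrow(g$edges))  # directed edges partitioned
    ek <- unlist(lapply(faces, function(f) {
      v <- f$vertices; k <- length(v)
      paste(pmin(v, v[c(2:k, 1)]), pmax(v, v[c(2:k, 1)]))
    }))
    expect_true(all(table(ek) == 2L))             # involution consistency
    expect_equal(g$n - nrow(g$edges) + length(faces), 2L)
  }
})

test_that("a single hexagon ring traces to an inner and an outer face", {
  h <- hexagon_ring()
  expect_equal(length(h$faces), 2L)
  expect_setequal(h$face_kind, c("hexagon", "outer"))
})

test_that("graph files round-trip with identical labels", {
  for (g in list(fixture_corannulene(), fixture_dodecahedron(),
                 fixture_truncated_icosahedron())) {
    f <- withr::local_tempfile(fileext = ".adj")
    write_graph(g, f)
    h <- read_graph(f)
    expect_equal(h$edges, g$edges)
  }
})

test_that("malformed graph files are rejected", {
  f <- withr::local_tempfile(fileext = ".adj")
  writeLines(c("not a header", "1 2"), f)
  expect_error(read_graph(f), "malformed")
  writeLines(c("n 5", "2"), f)
  expect_error(read_graph(f), "malformed")
})

test_that("XYZ round trip reproduces spiral-cage adjacency (C20, C24)", {
  for (n in c(20L, 24L)) {
    g <- isomer(n, 1)
    g$coords <- spherical_layout(g)
    f <- withr::local_tempfile(fileext = ".xyz")
    write_xyz(g, f)
    h <- read_xyz(f)
    expect_equal(h$n, n)
    expect_equal(h$edges, g$edges)
  }
})

test_that("XYZ bond perception honours the cutoff", {
  f <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("2", "two carbons", "C 0 0 0", "C 1.4 0 0"), f)
  g <- read_xyz(f)
  expect_equal(nrow(g$edges), 1L)               # a lone bond
  expect_error(read_xyz(f, bond_cutoff = 0.5), "cutoff")
  writeLines(c("3", "CH2 fragment", "C 0 0 0", "H 0 1.1 0", "C 1.4 0 0"), f)
  g2 <- read_xyz(f)
  expect_equal(g2$n, 2L)                        # hydrogens are ignored
  writeLines(c("banana", "?", "C 0 0 0"), f)
  expect_error(read_xyz(f), "unparsable")
})

test_that("hydrogen-free XYZ export of the truncated icosahedron keeps bonds", {
  ti <- fixture_truncated_icosahedron()
  f <- withr::local_tempfile(fileext = ".xyz")
  write_xyz(ti, f)
  h <- read_xyz(f)
  expect_equal(nrow(h$edges), 90L)
  expect_s3_class(h, "fullerene_graph")
})
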