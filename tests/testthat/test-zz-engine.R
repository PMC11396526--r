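test_that("corannulene reproduces the textbook ZZ polynomial", {
  g <- fixture_corannulene()
  p <- zz(g)
  expect_equal(p$coeffs, c(11, 15, 5))
  expect_equal(kekule_count(p), 11)
  expect_equal(clar_count(p), 31)
  expect_equal(clar_number(p), 2L)
  expect_equal(clar_formula_count(p), 5)
  expect_match(format(p), "11 \\+ 15 x \\+ 5 x\\^2")
})

test_that("small closed-form cases: hexagon, lone bond, dodecahedron", {
  expect_equal(zz(hexagon_ring())$coeffs, c(2, 1))     # 2 Kekule + 1 sextet
  expect_equal(clar_count(hexagon_ring()), 3)
  expect_equal(clar_formula_count(hexagon_ring()), 1)

  expect_equal(zz(single_edge_graph())$coeffs, 1)      # one perfect matching

  d <- fixture_dodecahedron()
  pd <- zz(d)
  expect_equal(clar_number(pd), 0L)                    # girth-5 solid: no sextets
  expect_equal(kekule_count(pd), matching_count_oracle(d))
  expect_equal(clar_count(pd), kekule_count(pd))       # Cl = 0 forces C = K
})

test_that("odd-vertex graphs have the zero polynomial and no-cover status", {
  p3 <- path3_graph()
  p <- zz(p3)
  expect_length(p$coeffs, 0L)
  expect_equal(clar_number(p), -1L)
  expect_equal(kekule_count(p), 0)
  expect_equal(clar_count(p), 0)
  expect_length(enumerate_clar_covers(p3), 0L)
})

test_that("sextet candidates are exactly the hexagonal faces of cages", {
  expect_length(sextet_candidates(fixture_dodecahedron()), 0L)
  expect_length(sextet_candidates(fixture_truncated_icosahedron()), 20L)
  expect_length(sextet_candidates(fixture_corannulene()), 5L)
  for (n in c(26L, 36L)) {
    for (g in all_isomer_graphs(n)) {
      expect_length(sextet_candidates(g), n / 2L - 10L)
    }
  }
})

test_that("recursive ZZ equals exhaustive enumeration on all small graphs", {
  small <- c(list(fixture_corannulene(), hexagon_ring(),
                  fixture_dodecahedron()),
             all_isomer_graphs(24), all_isomer_graphs(26),
             all_isomer_graphs(28))
  for (g in small) {
    expect_equal(zz(g)$coeffs, zz_via_enumeration(g)$coeffs,
                 info = paste("graph:", g$name))
  }
})

test_that("corannulene's 31 covers split 11 / 15 / 5 by order", {
  covers <- enumerate_clar_covers(fixture_corannulene())
  expect_length(covers, 31L)
  orders <- vapply(covers, function(cv) length(cv$sextets), integer(1))
  expect_equal(unname(table(orders)), array(c(11L, 15L, 5L)))
  # each cover spans all 20 vertices exactly once
  for (cv in covers[c(1, 15, 31)]) {
    spanned <- c(as.vector(cv$edges), unlist(cv$sextets))
    expect_setequal(spanned, 1:20)
    expect_equal(anyDuplicated(spanned), 0L)
  }
})

test_that("ZZ(0) matches the independent matching oracle on C20-C36", {
  for (n in seq(20L, 36L, by = 4L)) {
    for (g in all_isomer_graphs(n)) {
      expect_equal(kekule_count(g), matching_count_oracle(g),
                   info = g$name)
    }
  }
})

test_that("ZZ polynomials are invariant under vertex permutation", {
  for (g in list(fixture_corannulene(), isomer(24, 1))) {
    ref <- zz(g)$coeffs
    set.seed(7)
    for (k in 1:20) {
      p <- sample(g$n)
      h <- build_from_adjacency(relabelled_adjacency(g, p))
      expect_equal(zz(h)$coeffs, ref)
    }
  }
})

test_that("the size guard rejects oversized graphs", {
  expect_error(zz(fixture_truncated_icosahedron(), size_limit = 50),
               "size limit")
  expect_error(enumerate_clar_covers(fixture_truncated_icosahedron()),
               "guard")
})

test_that("invariant records and their TSV form round-trip", {
  inv <- isomer_invariants(28)
  expect_equal(nrow(inv), 2L)
  expect_equal(inv$K, inv$C - (inv$C - inv$K))  # columns numeric
  expect_true(all(inv$C >= inv$K))
  expect_equal(inv$m, 1:2)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_invariants_tsv(inv, f)
  back <- read_invariants_tsv(f)
  expect_equal(back$K, inv$K)
  expect_equal(back$coeffs, inv$coeffs)
  # record carries K = c0, C = sum, Cl = degree
  g <- isomer(28, 1)
  p <- zz(g)
  expect_equal(inv$K[1], p$coeffs[1])
  expect_equal(inv$C[1], sum(p$coeffs))
  expect_equal(inv$Cl[1], p$degree)
})
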