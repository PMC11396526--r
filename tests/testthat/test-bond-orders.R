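test_that("edge-transitive dodecahedron gets pK = pC = 1/3 on every edge", {
  d <- fixture_dodecahedron()
  tk <- pauling_kekule_orders(d)
  expect_equal(nrow(tk), 30L)
  expect_true(all(tk$pK_num * 3 == tk$pK_den))  # exactly 1/3
  tc <- pauling_clar_orders(d)
  expect_equal(tc$pC, tk$pK)                    # no 6-cycles: pC == pK
})

test_that("a lone bond has full double-bond character", {
  tab <- pauling_kekule_orders(single_edge_graph())
  expect_equal(tab$pK, 1)
})

test_that("truncated icosahedron has two edge orbits with p66 + 2 p65 = 1", {
  ti <- fixture_truncated_icosahedron()
  tk <- pauling_kekule_orders(ti)
  nhex <- lengths(tk$hexagons)           # 2 for 6-6 edges, 1 for 6-5 edges
  expect_setequal(nhex, c(1L, 2L))
  p66 <- unique(tk$pK_num[nhex == 2L])
  p65 <- unique(tk$pK_num[nhex == 1L])
  expect_length(p66, 1L)                 # orbit constancy
  expect_length(p65, 1L)
  expect_equal(p66 + 2 * p65, tk$pK_den[1])   # vertex sum rule, exactly
  expect_gt(p66, p65)                    # 6-6 bonds are more double-bond like
})

test_that("vertex sum rules hold exactly on fixtures and all C20-C30 isomers", {
  gs <- c(list(fixture_corannulene(), fixture_dodecahedron(), hexagon_ring()),
          all_isomer_graphs(24), all_isomer_graphs(28), all_isomer_graphs(30))
  for (g in gs) {
    tk <- pauling_kekule_orders(g)
    expect_true(sum_rule_holds(g, tk, "pK_num", "pK_den"), info = g$name)
    expect_true(all(tk$pK >= 0 & tk$pK <= 1))
    tc <- pauling_clar_orders(g)
    expect_true(sum_rule_holds(g, tc, "pC_num2", "pC_den2"), info = g$name)
    expect_true(all(tc$pC >= 0 & tc$pC <= 1))
  }
})

test_that("corannulene Clar orders sum to half the vertex count", {
  g <- fixture_corannulene()
  tc <- pauling_clar_orders(g)
  expect_equal(sum(tc$pC_num2) / tc$pC_den2[1], 10)  # n/2 by the sum rule
  # the five hub-ring bonds share one value by 5-fold symmetry
  hub <- tc$u <= 5 & tc$v <= 5
  expect_equal(sum(hub), 5L)
  expect_length(unique(tc$pC_num2[hub]), 1L)
})

test_that("pK agrees edge-by-edge with the independent matching oracle", {
  g <- isomer(30, 1)
  tk <- pauling_kekule_orders(g)
  for (i in seq_len(nrow(tk))) {
    keep <- setdiff(seq_len(g$n), c(tk$u[i], tk$v[i]))
    relab <- match(seq_len(g$n), keep)  # NA for the deleted endpoints
    sub <- g$edges[g$edges[, 1] %in% keep & g$edges[, 2] %in% keep, ,
                   drop = FALSE]
    sub[] <- relab[sub]
    m <- fullerzz:::matching_count_cpp(length(keep), sub)
    expect_equal(tk$pK_num[i], m)       # numerator is K(G - u - v), exactly
  }
})

test_that("bond-length models reproduce the fitted constants", {
  expect_equal(predict_bond_lengths(0, "clar"), 1.5096)
  expect_equal(predict_bond_lengths(1, "kekule"), 1.5708 - 0.3851)
  expect_equal(predict_bond_lengths(1 / 3, "kekule"), 1.4424, tolerance = 1e-4)
  m <- bond_length_model("clar")
  expect_true(all(predict_bond_lengths(c(0, 0.5, 1), m) > 0))
  tab <- pauling_kekule_orders(fixture_dodecahedron())
  expect_equal(unique(predict_bond_lengths(tab, "kekule")), 1.5708 - 0.3851 / 3)
})

test_that("regression recovers an exact linear law", {
  x <- c(0, 0.25, 0.5, 1)
  fit <- regress_orders_vs_lengths(x, 1.5096 - 0.2016 * x)
  expect_equal(fit$slope, -0.2016)
  expect_equal(fit$intercept, 1.5096)
  expect_equal(fit$r_squared, 1)
  expect_error(regress_orders_vs_lengths(c(0, 1), c(1, 2)), "at least 3")
  expect_error(regress_orders_vs_lengths(rep(0.5, 5), 1:5), "identical")
})

test_that("regression slope is consistent under symmetric noise", {
  set.seed(1234)
  n <- 1e4
  x <- stats::runif(n)
  y <- 1.5096 - 0.2016 * x + stats::rnorm(n, sd = 0.02)
  fit <- regress_orders_vs_lengths(x, y)
  se <- 0.02 / (stats::sd(x) * sqrt(n))  # asymptotic slope standard error
  expect_lt(abs(fit$slope + 0.2016), 3 * se)
})

test_that("the combined bond-order report is well-formed", {
  g <- fixture_corannulene()
  f <- withr::local_tempfile(fileext = ".tsv")
  out <- bond_order_report(g, path = f)
  expect_named(out, c("u", "v", "pK", "pC", "len_pred_K", "len_pred_C"))
  expect_equal(nrow(out), 25L)
  expect_true(file.exists(f))
  expect_equal(out$len_pred_C, 1.5096 - 0.2016 * out$pC)
})
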