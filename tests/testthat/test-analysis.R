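test_that("Clar-number populations count and percentage correctly", {
  inv20 <- isomer_invariants(20)
  pop <- clar_population(inv20)
  expect_equal(pop$Cl, 0L)          # the dodecahedron has no hexagons
  expect_equal(pop$count, 1L)
  expect_equal(pop$percent, 100L)

  inv36 <- isomer_invariants(36)
  pop36 <- clar_population(inv36)
  expect_equal(sum(pop36$count), 15L)
  expect_true(abs(sum(pop36$percent) - 100L) <= 2L)  # integer rounding
  expect_equal(pop36$count,
               as.integer(table(inv36$Cl)[as.character(pop36$Cl)]),
               ignore_attr = TRUE)

  empty <- clar_population(inv36[0, ])
  expect_equal(nrow(empty), 0L)
})

test_that("percentages round half away from zero as in printed tables", {
  recs <- data.frame(n = 40L, m = 1:8, K = 1, C = 1, Cl = c(rep(1L, 1), rep(2L, 7)),
                     cCl = 1, coeffs = as.character(1:8))
  pop <- clar_population(recs)
  expect_equal(pop$percent, c(13L, 88L))  # 12.5 -> 13, 87.5 -> 88
})

test_that("C >= K always, with equality exactly at Cl = 0", {
  inv <- rbind(isomer_invariants(20), isomer_invariants(32))
  expect_true(all(inv$C >= inv$K))
  expect_true(all((inv$C == inv$K) == (inv$Cl == 0L)))
  cks <- ck_statistics(inv)
  expect_true(cks$min_ratio >= 1)
  bad <- inv; bad$C[1] <- bad$K[1] - 1
  expect_error(ck_statistics(bad), "C < K")
})

test_that("records on an exact line give R^2 = 1", {
  recs <- data.frame(n = 60L, m = 1:6, K = c(10, 20, 30, 40, 50, 60),
                     C = 5 * c(10, 20, 30, 40, 50, 60),
                     Cl = 3L, cCl = 1, coeffs = as.character(1:6))
  cks <- ck_statistics(recs)
  expect_equal(cks$r_squared, 1)
  expect_equal(cks$min_ratio, 5)
  expect_equal(cks$max_ratio, 5)
})

test_that("the stability hypotheses report argmax/argmin and a verdict", {
  recs <- data.frame(n = 60L, m = 1:4,
                     K = c(100, 250, 200, 50),
                     C = c(500, 900, 1000, 300),
                     Cl = c(3L, 5L, 5L, 5L),
                     cCl = 1, coeffs = as.character(1:4))
  # energies rank isomer 2 most stable: K-hypothesis holds (max K among Cl=5)
  e1 <- toy_energy_table(recs, c(4, 1, 2, 3))
  zh <- zhang_hypothesis(recs, e1)
  expect_true(zh$holds)
  expect_equal(zh$candidates, "60:2")
  expect_equal(zh$candidate_count, 250)
  expect_equal(zh$max_Cl, 5L)
  # ... but the C-variant fails (isomer 3 maximizes C)
  mzh <- modified_zhang_hypothesis(recs, e1)
  expect_false(mzh$holds)
  expect_equal(mzh$candidates, "60:3")
  # constructed violation of the K-hypothesis
  e2 <- toy_energy_table(recs, c(1, 2, 3, 4))
  expect_false(zhang_hypothesis(recs, e2)$holds)
  # missing energies are an error
  expect_error(zhang_hypothesis(recs, e1[-2, ]), "missing")
  expect_error(zhang_hypothesis(recs, NULL), "required")
})

test_that("verdicts are invariant to units and affine energy rescaling", {
  recs <- data.frame(n = 60L, m = 1:3, K = c(5, 9, 7), C = c(50, 90, 70),
                     Cl = c(4L, 4L, 4L), cCl = 1, coeffs = as.character(1:3))
  kcal <- toy_energy_table(recs, c(30, 10, 20))
  hart <- toy_energy_table(recs, (c(30, 10, 20) + 1000) / 627.5094740631,
                           unit = "hartree")
  expect_equal(zhang_hypothesis(recs, kcal)$holds,
               zhang_hypothesis(recs, hart)$holds)
  expect_equal(rank_by_energy(recs, kcal)$labels,
               rank_by_energy(recs, hart)$labels)
})

test_that("energy tables are read, normalized and ranked stably", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("n\tm\tenergy\tunit",
               "36\t1\t-1370.5\thartree",
               "36\t2\t-860005.0\tkcal/mol",
               "36\t3\t-1370.6\thartree"), f)
  e <- read_energy_table(f)
  expect_equal(nrow(e), 3L)
  recs <- data.frame(n = 36L, m = 1:3, K = 1, C = 1, Cl = 1L, cCl = 1,
                     coeffs = as.character(1:3))
  rk <- rank_by_energy(recs, e)
  expect_equal(rk$labels, c("36:3", "36:2", "36:1"))  # -860005 kcal between
  writeLines(c("n\tm\tenergy\tunit", "36\t1\t1\teV"), f)
  expect_error(read_energy_table(f), "unit")
  writeLines(c("n\tm\tenergy\tunit", "36\t1\t1\thartree",
               "36\t1\t2\thartree"), f)
  expect_error(read_energy_table(f), "duplicate")
})

test_that("ties in the optima are reported as label sets", {
  recs <- data.frame(n = 40L, m = 1:3, K = c(8, 8, 2), C = c(80, 80, 20),
                     Cl = c(2L, 2L, 2L), cCl = 1, coeffs = as.character(1:3))
  e <- toy_energy_table(recs, c(5, 5, 9))
  zh <- zhang_hypothesis(recs, e)
  expect_setequal(zh$candidates, c("40:1", "40:2"))
  expect_setequal(zh$most_stable, c("40:1", "40:2"))
  expect_true(zh$holds)
})

test_that("ZZ vectors separate isomers and duplicates are detected", {
  inv <- rbind(isomer_invariants(32), isomer_invariants(34))
  uq <- uniqueness_check(inv)
  expect_true(uq$unique)
  dup <- rbind(inv, inv[3, ])
  uq2 <- uniqueness_check(dup)
  expect_false(uq2$unique)
  expect_length(uq2$collisions, 1L)
  expect_equal(length(uq2$collisions[[1]]), 2L)
  expect_true(uniqueness_check(inv[0, ])$unique)
})
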