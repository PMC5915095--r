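test_that("monoisotopic masses are exact and additive", {
  expect_identical(monoisotopicMass(1, 0, 0), 12)
  # hand sum: 9*12 + 10*1.0078250319 + 2*15.9949146221
  expect_equal(monoisotopicMass(9, 10, 2), 150.06808, tolerance = 1e-7)
  # linearity: mass(a) + mass(b) = mass(a + b), elementwise
  set.seed(11)
  a <- data.frame(c = sample(1:30, 20, TRUE), h = sample(0:40, 20, TRUE),
                  o = sample(0:15, 20, TRUE))
  b <- data.frame(c = sample(1:30, 20, TRUE), h = sample(0:40, 20, TRUE),
                  o = sample(0:15, 20, TRUE))
  expect_equal(monoisotopicMass(a) + monoisotopicMass(b),
               monoisotopicMass(a$c + b$c, a$h + b$h, a$o + b$o))
  expect_error(monoisotopicMass(-1, 0, 0), "non-negative")
})

test_that("neutral mass follows the deprotonation model", {
  expect_equal(neutralMass(149.060776, 1), 150.068052)
  expect_equal(neutralMass(374, 2), 750.014552)
  # algebraic consistency between charge states of one molecule
  M <- monoisotopicMass(20, 22, 8)
  expect_equal(neutralMass((M - 1.007276) / 1, 1),
               neutralMass((M - 2 * 1.007276) / 2, 2))
  expect_error(neutralMass(100, 3), "z must be 1 or 2")
  expect_error(neutralMass(-5, 1), "positive")
})

test_that("enumerator finds planted formulas and respects constraints", {
  hit <- enumerateFormulas(monoisotopicMass(9, 10, 2), tol_ppm = 1)
  expect_true("C9H10O2" %in% hit$formula)
  expect_lt(abs(hit$error_ppm[hit$formula == "C9H10O2"]), 1e-6)
  # below the lightest valid formula
  expect_identical(nrow(enumerateFormulas(11.0, 1)), 0L)
  # every candidate over random masses satisfies the constraint box
  set.seed(5)
  for (m in runif(25, 150, 900)) {
    cand <- enumerateFormulas(m, tol_ppm = 5)
    if (nrow(cand) == 0L) next
    expect_true(all(cand$o / cand$c <= 1))
    expect_true(all(cand$h / cand$c <= 2))
    expect_true(all(cand$c <= 120 & cand$h <= 200 & cand$o <= 60))
    expect_true(all(abs(cand$error_ppm) <= 5))
    expect_true(!is.unsorted(abs(cand$error_ppm)))
  }
  # H/C = 4 candidates can never appear
  expect_false(any(enumerateFormulas(monoisotopicMass(1, 4, 2), 10)$h >
                     2 * enumerateFormulas(monoisotopicMass(1, 4, 2), 10)$c))
})

test_that("enumerator agrees with the brute-force oracle", {
  set.seed(42)
  masses <- runif(30, 200, 800)
  for (m in masses) {
    mine <- enumerateFormulas(m, tol_ppm = 1)
    expect_identical(formulaKey(mine), formulaKey(oracleEnumerate(m, 1)))
  }
})

test_that("peak assignment recovers planted formulas and round-trips charge", {
  set.seed(7)
  planted <- simulateFormulaSet(50, seed = 7)
  pk <- simulatePeaklist(planted, ppm_sigma = 0.3, frac_doubly = 0.4, seed = 7)
  asg <- assignPeaklist(pk$peaks, tol_ppm = 1)
  recovered <- sum(asg$formula == pk$peak_map$formula, na.rm = TRUE)
  expect_gte(recovered, 49)
  # same molecule at z = 1 and z = 2 gets the same formula
  M <- monoisotopicMass(16, 18, 7)
  two <- data.frame(mz = c(M - 1.007276, (M - 2 * 1.007276) / 2),
                    intensity = 1, z = c(1L, 2L))
  asg2 <- assignPeaklist(two)
  expect_identical(asg2$formula[1], asg2$formula[2])
  # hopeless peak ends up unassigned but keeps its row
  mix <- rbind(two, data.frame(mz = 9, intensity = 1, z = 1L))
  asg3 <- assignPeaklist(mix)
  expect_identical(nrow(asg3), 3L)
  expect_false(asg3$assigned[3])
  expect_true(is.na(asg3$formula[3]))
})

test_that("round trip: any formula is recovered from its own m/z at both charges", {
  planted <- simulateFormulaSet(40, seed = 3)
  M <- monoisotopicMass(planted)
  for (z in c(1L, 2L)) {
    peaks <- data.frame(mz = (M - z * 1.007276) / z, intensity = 1, z = z)
    asg <- assignPeaklist(peaks, tol_ppm = 1)
    expect_identical(asg$formula, formulaString(planted))
  }
})

test_that("bulk atomic ratios reproduce the two-decimal convention", {
  expect_equal(nominalRatios(66.7, 4.82, 28.48), c(h_c = 0.87, o_c = 0.32))
  expect_equal(nominalRatios(65.7, 5.52, 28.77), c(h_c = 1.01, o_c = 0.33))
  expect_equal(nominalRatios(40.0, 6.67, 53.33), c(h_c = 2.00, o_c = 1.00))
  expect_error(nominalRatios(0, 5, 50))
})

test_that("oxygen by difference closes the ash-free balance", {
  expect_equal(oxygenByDifference(66.7, 4.82), 28.48)
  expect_equal(oxygenByDifference(100, 0), 0)
  expect_equal(oxygenByDifference(40, 10), 50)
  expect_error(oxygenByDifference(70, 40), "exceed 100")
})

test_that("number-averaged composition is an unweighted per-formula mean", {
  one <- numberAveragedComposition(data.frame(c = 1, h = 2, o = 1))
  expect_equal(one, c(c_pct = 40, h_pct = 20 / 3, o_pct = 160 / 3))
  # two formulas: mean of the two fraction vectors, by hand
  two <- data.frame(c = c(2, 1), h = c(2, 2), o = c(1, 1))
  m <- 12 * two$c + two$h + 16 * two$o
  byhand <- colMeans(cbind(100 * 12 * two$c / m, 100 * two$h / m,
                           100 * 16 * two$o / m))
  expect_equal(unname(numberAveragedComposition(two)), unname(byhand))
  # replication invariance and normalisation
  rep5 <- two[rep(1, 5), ]
  expect_equal(numberAveragedComposition(rep5),
               numberAveragedComposition(two[1, ]))
  set.seed(8)
  any <- simulateFormulaSet(30, seed = 8)
  expect_equal(sum(numberAveragedComposition(any)), 100, tolerance = 0.01)
  # intensity weighting degenerates to the plain mean under equal weights
  expect_equal(numberAveragedComposition(two, weights = c(2, 2)),
               numberAveragedComposition(two))
})

test_that("formula strings round-trip and reject foreign elements", {
  f <- data.frame(c = c(15L, 1L, 7L), h = c(10L, 0L, 14L), o = c(5L, 0L, 0L))
  expect_identical(formulaString(f), c("C15H10O5", "C1", "C7H14"))
  expect_identical(parseFormulaString(formulaString(f))$c, f$c)
  expect_identical(parseFormulaString(formulaString(f))$h, f$h)
  expect_identical(parseFormulaString(formulaString(f))$o, f$o)
  bad <- parseFormulaString(c("C6H5N", "H2O", "C2H6O"))
  expect_true(is.na(bad$c[1]))   # nitrogen-containing
  expect_true(is.na(bad$c[2]))   # carbon-free
  expect_identical(bad$c[3], 2L)
})

test_that("peak list IO round-trips through TSV", {
  pk <- data.frame(mz = c(150.1, 300.2), intensity = c(10, 20), z = c(1L, 2L))
  f <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(pk, f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_equal(readPeaklist(f), pk)
  f2 <- withr::local_tempfile(fileext = ".tsv")
  asg <- assignPeaklist(pk)
  writeAssignments(asg, f2)
  back <- utils::read.delim(f2)
  expect_identical(nrow(back), 2L)
})
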