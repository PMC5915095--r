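# profile: ADORA1 active, DRD4 active, OPRK1 inactive (see helper)

test_that("fit vectors encode match/mismatch/missing", {
  prof <- miniProfile()
  fp <- fpFromMatrix(matrix(c(1L, 0L, NA_integer_,
                              0L, NA_integer_, 0L),
                            nrow = 2, byrow = TRUE,
                            dimnames = list(c("A", "B"),
                                            c("ADORA1", "DRD4", "OPRK1"))))
  m <- fitVectors(fp, prof)
  expect_identical(m["A", ], c(ADORA1 = 1L, DRD4 = -1L, OPRK1 = 0L))
  expect_identical(m["B", ], c(ADORA1 = -1L, DRD4 = 0L, OPRK1 = 1L))
  # all-missing fingerprint scores zero everywhere
  fp0 <- fpFromMatrix(matrix(NA_integer_, 1, 3,
                             dimnames = list("Z", c("ADORA1", "DRD4", "OPRK1"))))
  expect_identical(unname(fitVectors(fp0, prof)["Z", ]), c(0L, 0L, 0L))
  # n(+1) + n(-1) + n(0) = panel size per compound
  expect_true(all(rowSums(m == 1L) + rowSums(m == -1L) + rowSums(m == 0L) == 3))
})

test_that("fit scores sum the vector; ideal compound scores the panel size", {
  prof <- miniProfile()
  ideal <- fpFromMatrix(matrix(c(1L, 1L, 0L), 1,
                               dimnames = list("I", c("ADORA1", "DRD4", "OPRK1"))))
  res <- scoreFingerprints(ideal, prof)
  expect_identical(unname(fitScores(res)), 3L)   # T = 3 scored targets
  # {+1,+1,+1,-1,-1} -> 1 on a five-target panel
  prof5 <- buildProfile(data.frame(
    target_symbol = paste0("T", 1:5), inhibition_pct = rep(60, 5),
    interference = 0L))
  fp5 <- fpFromMatrix(matrix(c(1L, 1L, 1L, 0L, 0L), 1,
                             dimnames = list("X", paste0("T", 1:5))))
  expect_identical(unname(fitScores(scoreFingerprints(fp5, prof5))), 1L)
})

test_that("excluded targets contribute zero and can be removed harmlessly", {
  rec <- data.frame(target_symbol = c("A1", "A2", "BAD"),
                    inhibition_pct = c(60, 30, 95),
                    interference = c(0L, 0L, 1L))
  prof <- buildProfile(rec)
  fp <- fpFromMatrix(matrix(c(1L, 1L, 1L), 1,
                            dimnames = list("X", c("A1", "A2", "BAD"))))
  res <- scoreFingerprints(fp, prof)
  expect_identical(unname(fitMatrix(res)[1, "BAD"]), 0L)
  expect_identical(unname(fitScores(res)), 0L)   # +1 (A1) -1 (A2) + 0
  # dropping a missing-valued target never changes any score
  prof2 <- buildProfile(rec[1:2, ])
  fp2 <- fpFromMatrix(matrix(c(1L, 1L), 1, dimnames = list("X", c("A1", "A2"))))
  expect_identical(unname(fitScores(scoreFingerprints(fp2, prof2))),
                   unname(fitScores(res)))
})

test_that("sign symmetry: inverting a fully defined fingerprint negates the score", {
  prof <- miniProfile()
  set.seed(31)
  for (i in 1:50) {
    v <- sample(0:1, 3, replace = TRUE)
    fp <- fpFromMatrix(matrix(as.integer(v), 1,
                              dimnames = list("X", panelTargets(prof))))
    inv <- fpFromMatrix(matrix(as.integer(1L - v), 1,
                               dimnames = list("X", panelTargets(prof))))
    expect_identical(fitScores(scoreFingerprints(fp, prof)) +
                       fitScores(scoreFingerprints(inv, prof)),
                     c(X = 0L))
  }
})

test_that("fit score equals a naive per-target loop on random fingerprints", {
  rec <- data.frame(target_symbol = paste0("T", 1:8),
                    inhibition_pct = c(60, 60, 60, 30, 30, 90, 20, 55),
                    interference = c(0L, 0L, 0L, 0L, 0L, 1L, 0L, 0L))
  prof <- buildProfile(rec)
  ref <- profileStates(prof)
  set.seed(17)
  m <- matrix(sample(c(0L, 1L, NA_integer_), 200 * 8, replace = TRUE), 200, 8,
              dimnames = list(sprintf("C%03d", 1:200), paste0("T", 1:8)))
  res <- scoreFingerprints(fpFromMatrix(m), prof)
  naive <- vapply(seq_len(nrow(m)), function(i) {
    s <- 0L
    for (t in colnames(m)) {
      if (ref[t] == "excluded" || is.na(m[i, t])) next
      want <- if (ref[t] == "active") 1L else 0L
      s <- s + (if (m[i, t] == want) 1L else -1L)
    }
    s
  }, integer(1))
  expect_identical(unname(fitScores(res)), naive)
})

test_that("well-fitted selection thresholds and orders deterministically", {
  prof <- miniProfile()
  m <- matrix(c(1L, 1L, 0L,   # +1 +1 +1 = 3 (0 matches the inactive OPRK1)
                1L, NA, NA,   # score 1
                NA, NA, NA,   # score 0
                0L, 0L, NA),  # -1 -1 = -2
              nrow = 4, byrow = TRUE,
              dimnames = list(c("d", "a", "b", "c"),
                              c("ADORA1", "DRD4", "OPRK1")))
  res <- scoreFingerprints(fpFromMatrix(m), prof)
  wf <- selectWellFitted(res)
  expect_identical(rownames(fitMatrix(wf)), c("d", "a"))
  expect_identical(unname(fitScores(wf)), c(3L, 1L))
  expect_identical(length(selectWellFitted(res, threshold = 4)), 0L)
  # ties broken by compound id
  m2 <- m[c(1, 1), ]; rownames(m2) <- c("zz", "aa")
  wf2 <- selectWellFitted(scoreFingerprints(fpFromMatrix(m2), prof))
  expect_identical(rownames(fitMatrix(wf2)), c("aa", "zz"))
})

test_that("per-target tallies mirror the n-of-m phrasing", {
  prof <- miniProfile()
  # plant 7 matching of 10 tested at ADORA1
  m <- matrix(NA_integer_, 10, 3,
              dimnames = list(sprintf("C%02d", 1:10),
                              c("ADORA1", "DRD4", "OPRK1")))
  m[, "ADORA1"] <- c(rep(1L, 7), rep(0L, 3))
  res <- scoreFingerprints(fpFromMatrix(m), prof)
  tal <- perTargetTally(res)
  expect_identical(tal$n_matching[tal$target == "ADORA1"], 7L)
  expect_identical(tal$n_tested[tal$target == "ADORA1"], 10L)
  expect_identical(tal$n_tested[tal$target == "DRD4"], 0L)
  # totals across the cohort
  expect_identical(matchMismatchTotals(res),
                   c(total_matching = 7L, total_mismatching = 3L))
  # single all-match compound over T targets gives (T, 0)
  all1 <- fpFromMatrix(matrix(c(1L, 1L, 0L), 1,
                              dimnames = list("I", c("ADORA1", "DRD4", "OPRK1"))))
  expect_identical(matchMismatchTotals(scoreFingerprints(all1, prof)),
                   c(total_matching = 3L, total_mismatching = 0L))
})

test_that("fit results serialise to a per-target CSV", {
  prof <- miniProfile()
  m <- matrix(c(1L, 0L, NA), 1, dimnames = list("A", panelTargets(prof)))
  f <- withr::local_tempfile(fileext = ".csv")
  writeFitResults(scoreFingerprints(fpFromMatrix(m), prof), f)
  back <- utils::read.csv(f, check.names = FALSE)
  expect_identical(back$compound_id, "A")
  expect_identical(back$fit_score, 0L)
  expect_identical(back$ADORA1, 1L)
  expect_identical(back$DRD4, -1L)
})
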