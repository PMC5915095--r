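test_that("formula matching is exact and preserves isomer multiplicity", {
  store <- miniStore()
  hit <- matchFormulas("C15H10O5", store$compounds)
  expect_identical(hit$compound_id, c("A", "B"))   # two isomers, both kept
  expect_identical(nrow(matchFormulas("C5H4O4", store$compounds)), 0L)
  # union property: match(A u B) = match(A) u match(B)
  a <- data.frame(c = 15L, h = 10L, o = 5L)
  b <- data.frame(c = 20L, h = 30L, o = 2L)
  both <- matchFormulas(rbind(a, b), store$compounds)
  expect_identical(sort(both$compound_id),
                   sort(union(matchFormulas(a, store$compounds)$compound_id,
                              matchFormulas(b, store$compounds)$compound_id)))
  # unparseable store formulas are skipped with a warning
  store$compounds$formula_string[3] <- "C6H5N"
  expect_warning(m <- matchFormulas("C15H10O5", store$compounds),
                 "not parseable")
  expect_identical(m$compound_id, c("A", "B"))
})

test_that("assay search is case-insensitive substring containment", {
  store <- miniStore()
  keys <- miniKeys()
  hits <- searchAssays(store$assays, keys)
  expect_true(all(hits$panel_target[hits$assay_id == "AS01"] == "ADORA1"))
  # "adenosine a1" must not hit an adenosine deaminase assay
  extra <- store$assays[1, ]
  extra$assay_id <- "AS99"; extra$target_name <- "Adenosine deaminase"
  extra$description <- "adenosine deaminase enzymatic assay"
  expect_false("AS99" %in% searchAssays(extra, keys)$assay_id)
  # case invariance of corpus and keys
  up <- store$assays
  up$description <- toupper(up$description); up$target_name <- toupper(up$target_name)
  keys_up <- keys; keys_up$key <- toupper(keys_up$key)
  expect_identical(nrow(searchAssays(up, keys)), nrow(hits))
  expect_identical(nrow(searchAssays(store$assays, keys_up)), nrow(hits))
  expect_identical(nrow(searchAssays(store$assays[0, ], keys)), 0L)
})

test_that("activity hashing applies potency and percent cutoffs", {
  flag <- standardizeActivity(
    activity_type = c("Ki", "IC50", "Inhibition", "Ki", "Ki", "EC50"),
    relation = c("=", "=", "=", ">", "<", "="),
    value = c(50, 100, 80, 50, 200000, 9.9),
    units = c("nM", "uM", "%", "nM", "nM", "uM"))
  expect_identical(flag, c(1L, 0L, 1L, NA_integer_, NA_integer_, 1L))
  # unknown units are undetermined, with a warning
  expect_warning(
    u <- standardizeActivity("Residence time", "=", 5, "s"),
    "unrecognised")
  expect_true(is.na(u))
  # boundary: exactly at the 10 uM cutoff counts active, just above inactive
  expect_identical(standardizeActivity(c("Ki", "Ki"), c("=", "="),
                                       c(10000, 10000.1), c("nM", "nM")),
                   c(1L, 0L))
  # percent boundary mirrors the >= 50 rule
  expect_identical(standardizeActivity(c("Inhibition", "Inhibition"),
                                       c("=", "="), c(50, 49.9), c("%", "%")),
                   c(1L, 0L))
})

test_that("fingerprints aggregate flags over the full panel universe", {
  hits <- data.frame(
    compound_id = c("A", "A", "A", "B", "B"),
    panel_target = c("ADORA1", "ADORA1", "DRD4", "OPRK1", "OPRK1"),
    flag = c(1L, 0L, NA_integer_, 0L, 0L))
  targets <- c("ADORA1", "DRD4", "OPRK1")
  fp <- fingerprintMatrix(buildFingerprints(hits, targets))
  expect_identical(fp["A", "ADORA1"], 1L)      # any-active beats a 0
  expect_true(is.na(fp["A", "DRD4"]))          # undetermined flags ignored
  expect_true(is.na(fp["A", "OPRK1"]))         # never assayed
  expect_identical(fp["B", "OPRK1"], 0L)
  # defined + missing = panel size, for every compound
  expect_true(all(rowSums(!is.na(fp)) + rowSums(is.na(fp)) == length(targets)))
  # majority vote flips the conflicting pair only when 0s outnumber 1s
  hits2 <- rbind(hits, data.frame(compound_id = "A", panel_target = "ADORA1",
                                  flag = 0L))
  fp_any <- fingerprintMatrix(buildFingerprints(hits2, targets))
  fp_maj <- fingerprintMatrix(buildFingerprints(hits2, targets, "majority"))
  expect_identical(fp_any["A", "ADORA1"], 1L)
  expect_identical(fp_maj["A", "ADORA1"], 0L)
  expect_error(buildFingerprints(hits, c("ADORA1", "DRD4")), "outside the panel")
})

test_that("mineActivities recovers the mini store's planted profile", {
  store <- miniStore()
  prof <- miniProfile()
  mined <- mineActivities("C15H10O5", store, miniKeys(),
                          panel_targets = panelTargets(prof))
  fp <- fingerprintMatrix(mined$fingerprints)
  # compound A: Ki 50 nM at ADORA1 (active), IC50 100 uM at DRD4 (inactive)
  expect_identical(fp["A", ], c(ADORA1 = 1L, DRD4 = 0L, OPRK1 = NA_integer_))
  # compound B: Ki 2 uM at ADORA1, Ki 500 nM at the kappa opioid site
  expect_identical(fp["B", ], c(ADORA1 = 1L, DRD4 = NA_integer_, OPRK1 = 1L))
  # decoy compound C never enters the fingerprint set
  expect_false("C" %in% rownames(fp))
})

test_that("readStore accepts canonical and genuine ChEMBL column names", {
  store <- miniStore()
  d <- withr::local_tempdir()
  # canonical names
  utils::write.csv(store$compounds, file.path(d, "compounds.csv"),
                   row.names = FALSE)
  utils::write.csv(store$assays, file.path(d, "assays.csv"), row.names = FALSE)
  s1 <- readStore(file.path(d, "compounds.csv"), file.path(d, "assays.csv"))
  expect_identical(s1$compounds$compound_id, c("A", "B", "C"))
  # ChEMBL-style names
  comp2 <- store$compounds
  names(comp2) <- c("molregno", "full_molformula", "canonical_smiles")
  ass2 <- store$assays
  names(ass2) <- c("assay_id", "molregno", "pref_name", "description",
                   "standard_type", "standard_relation", "standard_value",
                   "standard_units")
  utils::write.csv(comp2, file.path(d, "c2.csv"), row.names = FALSE)
  utils::write.csv(ass2, file.path(d, "a2.csv"), row.names = FALSE)
  s2 <- readStore(file.path(d, "c2.csv"), file.path(d, "a2.csv"))
  expect_identical(s2$compounds, s1$compounds)
  expect_identical(s2$assays, s1$assays)
})
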