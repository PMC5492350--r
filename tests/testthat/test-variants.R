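t3 <- loadVariantTable(variantFixturePath("table3_damaging"))
t4 <- loadVariantTable(variantFixturePath("table4_conserved_regions"))

test_that("SIFT classification follows the 0.05 convention", {
  expect_equal(classifySift(0.03), "damaging")
  expect_equal(classifySift(0.65), "tolerated")
  expect_equal(classifySift(0.05), "damaging")  # boundary is damaging
  expect_equal(classifySift(NA), "unknown")
  expect_error(classifySift(1.2), "out of")
  # monotone: severity never increases with the score
  s <- classifySift(seq(0, 1, by = 0.01))
  expect_true(all(diff(match(s, c("damaging", "tolerated"))) >= 0))
})

test_that("PolyPhen-2 bins follow the 0.453/0.957 convention", {
  expect_equal(classifyPolyphen(0.993), "probably_damaging")
  expect_equal(classifyPolyphen(0.262), "benign")
  expect_equal(classifyPolyphen(0.497), "possibly_damaging")
  expect_equal(classifyPolyphen(NA), "unknown")
  expect_error(classifyPolyphen(-0.1), "out of")
  p <- classifyPolyphen(seq(0, 1, by = 0.001))
  sev <- match(p, c("benign", "possibly_damaging", "probably_damaging"))
  expect_true(all(diff(sev) >= 0))
})

test_that("packaged fixtures parse with the documented row counts", {
  expect_equal(nrow(t3), 12L)
  expect_equal(nrow(t4), 33L)
  t5 <- read.delim(variantFixturePath("table5_occupancy"))
  expect_equal(nrow(t5), 11L)
  expect_equal(t5$occupancy_percent[t5$structure_label == "WT"],
               c(24.5, 65.9, 1.5))
  # termination and deletion notation parses
  expect_true("R388Ter" %in% t4$protein_change)
  expect_true(all(isTruncatingChange(c("R388Ter", "Y233*", "M387delM"))))
  expect_false(any(isTruncatingChange(c("R277L", "D152G"))))
  # truncating variants without predictions carry unknown classes
  ter <- t4[t4$protein_change == "R388Ter", ]
  expect_equal(classifySift(ter$sift_score), "unknown")
})

test_that("malformed protein changes are parse errors with a row number", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("snp_id\tprotein_change\tregion",
               "rs1\tR277L\tSRS1",
               "rs2\t277L\tSRS1"), f)
  expect_error(loadVariantTable(f), "row 2")
})

test_that("damaging-by-both filtering retains and excludes correctly", {
  expect_equal(nrow(filterDamagingBoth(t3)), 12L)  # all of table 3
  rec <- t4[t4$protein_change == "R139H", ]        # sift 0.65: excluded
  expect_equal(nrow(filterDamagingBoth(rec)), 0L)
  empty <- t4[0, ]
  expect_equal(nrow(filterDamagingBoth(empty)), 0L)
  f4 <- filterDamagingBoth(t4)
  expect_true(all(f4$protein_change %in% t4$protein_change))
  expect_true(all(f4$sift_score <= 0.05 & f4$polyphen_score >= 0.453))
})

test_that("region counts reproduce the documented tallies", {
  cnt <- countByRegion(t4)
  expect_equal(cnt[["SRS1"]], 8L)
  expect_equal(cnt[["SRS3"]], 3L)
  expect_equal(cnt[["POR interaction"]], 3L)
  expect_equal(cnt[["SRS6"]], 2L)
  expect_equal(sum(cnt), sum(!is.na(t4$region)))
})

test_that("the label/threshold QC flags known internal inconsistencies", {
  cc <- consistencyCheck(t4)
  # R258H: printed Benign at score 0.93, which the bins call possibly damaging
  r258h <- cc[cc$protein_change == "R258H", ]
  expect_equal(nrow(r258h), 1L)
  expect_equal(r258h$computed_class, "possibly_damaging")
  # a fully consistent record is not reported
  cc3 <- consistencyCheck(t3[t3$snp_id == "rs372875744", ])
  expect_equal(nrow(cc3), 0L)
  # records with absent scores are skipped
  ccTer <- consistencyCheck(t4[t4$protein_change == "Y233*", ])
  expect_equal(nrow(ccTer), 0L)
})

test_that("fixture writing is deterministic", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  p1 <- writeFixtures(d1)
  p2 <- writeFixtures(d2)
  for (k in seq_along(p1))
    expect_identical(readBin(p1[k], "raw", file.size(p1[k])),
                     readBin(p2[k], "raw", file.size(p2[k])))
})
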