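test_that("GMT lines parse into categorized, name-normalized sets", {
  path <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c(
    "Coregulate MTOR\tregulator\thsa-mir-99a\thsa-mir-100\thsa-mir-182\thsa-mir-199b",
    "Mixed case\tfunction\thsa-miR-182\thsa-mir-182\tmiR-214"), path)
  coll <- readGmt(path)
  expect_identical(length(coll), 2L)
  expect_identical(length(coll[["Coregulate MTOR"]]), 4L)
  expect_identical(category(coll[["Coregulate MTOR"]]), "regulator")
  # hsa-miR-182 and hsa-mir-182 collapse; miR-214 gains the species prefix
  expect_setequal(members(coll[["Mixed case"]]),
                  c("hsa-mir-182", "hsa-mir-214"))
})

test_that("GMT writing round-trips member-identically", {
  coll <- readGmt(system.file("extdata", "misea_sets.gmt",
                              package = "qpcrSEA"))
  path <- withr::local_tempfile(fileext = ".gmt")
  writeGmt(coll, path)
  coll2 <- readGmt(path)
  expect_identical(names(coll2), names(coll))
  expect_identical(members(coll2), members(coll))
  expect_identical(category(coll2), category(coll))
})

test_that("malformed lines are reported, empty and duplicated input is
           an error", {
  path <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("ok\tfunction\thsa-mir-1\thsa-mir-2",
               "too-short\tfunction",
               "bad-category\tnonsense\thsa-mir-3\thsa-mir-4"), path)
  expect_warning(coll <- readGmt(path), "2, 3")
  expect_identical(length(coll), 1L)
  writeLines(character(), path)
  expect_error(readGmt(path), "empty GMT")
  writeLines(c("dup\tfunction\thsa-mir-1\thsa-mir-2",
               "dup\tfunction\thsa-mir-3\thsa-mir-4"), path)
  expect_error(readGmt(path), "duplicate set name")
})

test_that("tissue-specificity filter is inclusive at the threshold and
           scoped to the tissue category", {
  coll <- MirnaSetCollection(list(
    MirnaSet("t-hi", "tissue", c("hsa-mir-1", "hsa-mir-2"), tsi = 0.7),
    MirnaSet("t-lo", "tissue", c("hsa-mir-3", "hsa-mir-4"), tsi = 0.69),
    MirnaSet("fn", "function", c("hsa-mir-5", "hsa-mir-6"))))
  kept <- filterTissueSets(coll, 0.7)
  expect_setequal(names(kept), c("t-hi", "fn"))
  noIdx <- MirnaSetCollection(list(
    MirnaSet("t-none", "tissue", c("hsa-mir-1", "hsa-mir-2"))))
  expect_error(filterTissueSets(noIdx), "no tissue-specificity index")
})

test_that("universe restriction intersects members and drops small
           sets", {
  rl <- toyRanked(10)
  coll <- MirnaSetCollection(list(
    MirnaSet("inside", "function", c("hsa-mir-1", "hsa-mir-2")),
    MirnaSet("partial", "function",
             c("hsa-mir-3", "hsa-mir-4", "hsa-mir-99x")),
    MirnaSet("outside", "function", c("hsa-mir-77x", "hsa-mir-88x")),
    MirnaSet("shrunk", "function", c("hsa-mir-5", "hsa-mir-66x"))))
  expect_message(res <- restrictToUniverse(coll, rl, 2),
                 "dropped 2 set")
  expect_setequal(names(res), c("inside", "partial"))
  expect_identical(members(res[["inside"]]), c("hsa-mir-1", "hsa-mir-2"))
  expect_setequal(members(res[["partial"]]), c("hsa-mir-3", "hsa-mir-4"))
})

test_that("the packaged set collection loads with its categories", {
  coll <- readGmt(system.file("extdata", "misea_sets.gmt",
                              package = "qpcrSEA"))
  expect_identical(length(coll), 10L)
  expect_true(all(category(coll) %in% setCategories()))
  expect_identical(sum(category(coll) == "function"), 5L)
  expect_true("hsa-mir-182" %in% members(coll[["Coregulate MTOR"]]))
})

test_that("miRNA name normalization and base names behave as
           documented", {
  expect_identical(normalizeMirnaNames(c("hsa-miR-182", "miR-182-5p",
                                         "LET-7d")),
                   c("hsa-mir-182", "hsa-mir-182-5p", "hsa-let-7d"))
  expect_identical(mirnaBaseName(c("miR-182-5p", "hsa-mir-449c-5p",
                                   "hsa-let-7d", "hsa-mir-214")),
                   c("hsa-mir-182", "hsa-mir-449", "hsa-let-7",
                     "hsa-mir-214"))
})
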