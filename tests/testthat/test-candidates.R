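evidenceFixture <- function() {
  readPredictionEvidence(system.file("extdata", "wwox_predictions.tsv",
                                     package = "qpcrSEA"))
}

reportedReport <- function() {
  enr <- readEnrichmentReport(system.file(
    "extdata", "enriched_sets_reported.tsv", package = "qpcrSEA"))
  fun <- readEnrichmentReport(system.file(
    "extdata", "functional_sets_reported.tsv", package = "qpcrSEA"))
  methods::new("EnrichmentReport",
               results = rbind(enrichmentResults(enr),
                               enrichmentResults(fun)),
               params = list())
}

test_that("two-tool consensus retains the packaged WWOX predictions and
           is monotone in minTools", {
  ev <- evidenceFixture()
  c2 <- consensusTargets(ev, "WWOX", minTools = 2)
  expect_identical(length(c2), 17L)
  expect_setequal(c2[["hsa-mir-182-5p"]],
                  c("TargetScanMouse", "microRNA.org"))
  c1 <- consensusTargets(ev, "WWOX", minTools = 1)
  expect_identical(length(c1), 17L)
  c3 <- consensusTargets(ev, "WWOX", minTools = 3)
  expect_identical(length(c3), 0L)
  expect_true(all(names(c3) %in% names(c2)))
  expect_true(all(names(c2) %in% names(c1)))
})

test_that("single-tool predictions are excluded at the default
           threshold", {
  ev <- data.frame(mirna = c("miR-1-5p", "miR-2-5p", "miR-2-5p"),
                   target_gene = "WWOX",
                   tool = c("toolA", "toolA", "toolB"))
  cons <- consensusTargets(ev, "WWOX")
  expect_identical(names(cons), "hsa-mir-2-5p")
  # duplicated (mirna, gene, tool) rows do not inflate the tool count
  expect_identical(names(consensusTargets(readPredictionEvidence(
    withr::local_tempfile(fileext = ".tsv", lines = c(
      "mirna\ttarget_gene\ttool",
      "miR-1-5p\tWWOX\ttoolA",
      "miR-1-5p\tWWOX\ttoolA"))), "WWOX", minTools = 2)),
    character(0))
})

test_that("candidate annotation joins enriched-set membership with the
           prediction consensus at base-name level", {
  filtered <- applyReportFilters(reportedReport(), pCut = 0.05,
                                 absEsCut = 0.25)
  cons <- consensusTargets(evidenceFixture(), "WWOX", minTools = 2)
  ann <- annotateCandidates(filtered, cons, baseNameMatch = TRUE)
  m182 <- ann[ann$mirna == "hsa-mir-182", ]
  sets182 <- strsplit(m182$enriched_sets, ";")[[1]]
  expect_true(all(c("Coregulate MTOR", "Apoptosis") %in% sets182))
  expect_true(m182$predicted_regulator)   # via miR-182-5p base-name match
  expect_match(m182$supporting_tools, "TargetScanMouse")
  m214 <- ann[ann$mirna == "hsa-mir-214", ]
  expect_true("Regulated by TWIST1" %in%
                strsplit(m214$enriched_sets, ";")[[1]])
  expect_false(m214$predicted_regulator)
  expect_identical(m214$supporting_tools, "")
})

test_that("without base-name matching the mature-arm predictions no
           longer reach panel-level names", {
  filtered <- applyReportFilters(reportedReport(), pCut = 0.05,
                                 absEsCut = 0.25)
  cons <- consensusTargets(evidenceFixture(), "WWOX", minTools = 2)
  ann <- annotateCandidates(filtered, cons, baseNameMatch = FALSE)
  expect_false(ann$predicted_regulator[ann$mirna == "hsa-mir-182"])
})

test_that("annotations cover exactly the miRNAs of retained sets and
           rank predicted regulators first", {
  filtered <- applyReportFilters(reportedReport(), pCut = 0.05,
                                 absEsCut = 0.25)
  cons <- consensusTargets(evidenceFixture(), "WWOX", minTools = 2)
  ann <- annotateCandidates(filtered, cons)
  inSets <- unique(unlist(as.list(enrichmentResults(filtered)$members)))
  expect_setequal(ann$mirna, inSets)
  retained <- enrichmentResults(filtered)$set_name
  expect_true(all(unlist(strsplit(ann$enriched_sets, ";")) %in% retained))
  expect_true(all(diff(ann$predicted_regulator) <= 0))
  # supporting tools non-empty exactly when flagged
  expect_identical(nzchar(ann$supporting_tools), ann$predicted_regulator)
})

test_that("an empty report yields an empty annotation table", {
  empty <- applyReportFilters(reportedReport(), pCut = 0, absEsCut = 1)
  ann <- annotateCandidates(empty, consensusTargets(evidenceFixture()))
  expect_identical(nrow(ann), 0L)
})
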