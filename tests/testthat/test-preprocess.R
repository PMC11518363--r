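test_that("SDM Cq calling matches the logistic closed form", {
  # closed form: SDM cycle = m - ln(2 + sqrt(3)) / k
  for (k in c(0.5, 1, 2)) {
    for (m in c(16, 25, 35)) {
      trueCq <- m - log(2 + sqrt(3)) / k
      cv <- simulateCurve(trueCq, noiselessParams(k))
      expect_equal(callCqSdm(cv$fluorescence, cv$cycle), trueCq,
                   tolerance = 0.05 / trueCq,
                   label = sprintf("k=%g m=%g", k, m))
    }
  }
})

test_that("Cq calling is translation-equivariant", {
  cv <- simulateCurve(23, noiselessParams())
  cv2 <- simulateCurve(25, noiselessParams())
  d <- callCqSdm(cv2$fluorescence, cv2$cycle) -
    callCqSdm(cv$fluorescence, cv$cycle)
  expect_equal(d, 2, tolerance = 1e-6)
})

test_that("flat and noise-only traces are undetermined", {
  expect_true(is.na(callCqSdm(rep(1, 45))))
  set.seed(9)
  expect_true(is.na(callCqSdm(rnorm(45, 1, 0.1))))
})

test_that("Cq calling validates its input contract", {
  expect_error(callCqSdm(rnorm(5)), "at least 10 cycles")
  expect_error(callCqSdm(rnorm(20), cycles = c(1:10, 10:1)),
               "strictly increasing")
  expect_error(callCqSdm(rnorm(20), smoothingWindow = 4), "odd")
})

test_that("noisy curves are still called within a small tolerance", {
  set.seed(21)
  p <- defaultCurveParams()   # noiseSd = 0.1
  err <- replicate(50, {
    cv <- simulateCurve(24.5, p)
    callCqSdm(cv$fluorescence, cv$cycle) - 24.5
  })
  expect_lt(stats::quantile(abs(err), 0.9), 0.2)
  expect_lt(abs(mean(err)), 0.05)
})

test_that("interplate calibration removes between-plate offsets and is
           idempotent", {
  cq <- rbind(
    cqRec("s1", "cal", 20, "interplate_calibrator", "p1"),
    cqRec("s1", "m1", 25, "mirna_assay", "p1"),
    cqRec("s2", "cal", 21, "interplate_calibrator", "p2"),
    cqRec("s2", "m1", 26, "mirna_assay", "p2"))
  cal <- interplateCalibrate(cq)
  # plate means 20 / 21, global 20.5: plate 2 shifted by -0.5, plate 1 +0.5
  expect_equal(cal$cq[cal$sample_id == "s2" & cal$assay_name == "m1"], 25.5)
  expect_equal(cal$cq[cal$sample_id == "s1" & cal$assay_name == "m1"], 25.5)
  calMeans <- tapply(cal$cq[cal$well_class == "interplate_calibrator"],
                     cal$plate_id[cal$well_class == "interplate_calibrator"],
                     mean)
  expect_equal(diff(range(calMeans)), 0)
  cal2 <- interplateCalibrate(cal)
  expect_equal(cal2$cq, cal$cq)
})

test_that("single-plate calibration is a no-op and undefined calibrators
           fail QC", {
  cq <- rbind(cqRec("s1", "cal", 20, "interplate_calibrator"),
              cqRec("s1", "m1", 25, "mirna_assay"))
  expect_equal(interplateCalibrate(cq)$cq, cq$cq)
  bad <- rbind(cqRec("s1", "cal", NA_real_, "interplate_calibrator"),
               cqRec("s1", "m1", 25, "mirna_assay"))
  expect_error(interplateCalibrate(bad), "QC failure")
})

test_that("spike-in QC flags only deviant samples and ignores other
           well classes", {
  mk <- function(s, cqv) rbind(cqRec(s, "sp1", cqv, "spike_in"),
                               cqRec(s, "sp2", cqv + 1, "spike_in"))
  cq <- rbind(mk("s1", 22), mk("s2", 22), mk("s3", 22),
              cqRec("s1", NA, NA_real_, "blank"))
  rep1 <- qcSpikeIns(cq)
  expect_true(all(rep1$pass))
  # shift one sample far out
  cq2 <- rbind(mk("s1", 22), mk("s2", 22.01), mk("s3", 22.02),
               mk("s4", 32))
  rep2 <- qcSpikeIns(cq2, toleranceSd = 3)
  expect_false(rep2$pass[rep2$sample_id == "s4"])
  expect_true(all(rep2$pass[rep2$sample_id != "s4"]))
  expect_identical(nrow(qcSpikeIns(cqRec("s1", "m1", 25, "mirna_assay"))),
                   0L)
})

test_that("delta-Cq normalization follows the 2^(-dCq) contract", {
  cq <- rbind(cqRec("s1", "ref1", 20, "reference_gene"),
              cqRec("s1", "m1", 25, "mirna_assay"),
              cqRec("s1", "m2", 20, "mirna_assay"),
              cqRec("s1", "m3", NA_real_, "mirna_assay"),
              cqRec("s2", "ref1", 20, "reference_gene"),
              cqRec("s2", "m1", 20, "mirna_assay"),
              cqRec("s2", "m2", 20, "mirna_assay"),
              cqRec("s2", "m3", 20, "mirna_assay"))
  se <- normalizeDeltaCq(cq, c(s1 = "a", s2 = "b"))
  mat <- SummarizedExperiment::assay(se, "relexpr")
  expect_equal(mat["m1", "s1"], 0.03125)   # dCq = 5
  expect_equal(mat["m2", "s1"], 1.0)       # dCq = 0
  expect_true(is.na(mat["m3", "s1"]))      # undetermined -> missing, not 0
  expect_false(any(mat == 0, na.rm = TRUE))
})

test_that("delta-Cq normalization is invariant to a per-sample constant
           shift and fails without reference genes", {
  cq <- rbind(cqRec("s1", "ref1", 19, "reference_gene"),
              cqRec("s1", "ref2", 21, "reference_gene"),
              cqRec("s1", "m1", 24, "mirna_assay"),
              cqRec("s2", "ref1", 20, "reference_gene"),
              cqRec("s2", "ref2", 20, "reference_gene"),
              cqRec("s2", "m1", 26, "mirna_assay"))
  se1 <- normalizeDeltaCq(cq, c(s1 = "a", s2 = "b"))
  shifted <- cq
  shifted$cq[shifted$sample_id == "s1"] <- shifted$cq[shifted$sample_id == "s1"] + 3
  se2 <- normalizeDeltaCq(shifted, c(s1 = "a", s2 = "b"))
  expect_equal(SummarizedExperiment::assay(se1, "relexpr"),
               SummarizedExperiment::assay(se2, "relexpr"))
  noref <- cq[cq$well_class != "reference_gene" | cq$sample_id != "s1", ]
  expect_error(normalizeDeltaCq(noref, c(s1 = "a", s2 = "b")), "QC failure")
  expect_error(normalizeDeltaCq(cq, c(s1 = "a", s2 = "a")),
               "two distinct condition labels")
})

test_that("detectability filter drops miRNAs missing in over half of a
           condition", {
  mat <- rbind(keep = c(1, NA, 1, 1),
               dropA = c(NA, NA, 1, 1),
               dropB = c(1, 1, NA, NA))
  se <- makeSe(mat, c("a", "a", "b", "b"))
  kept <- rownames(filterDetected(se, 0.5))
  expect_identical(kept, "keep")
})
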