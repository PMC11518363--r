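test_that("running-sum enrichment score reproduces hand-computable
           cases", {
  rl <- toyRanked(10)
  nm <- rankedNames(rl)
  top <- enrichmentScore(rl, nm[c(1, 2)])
  expect_equal(top$es, 1.0)
  expect_identical(top$peakRank, 2L)
  expect_identical(top$leadingMembers, nm[c(1, 2)])
  bottom <- enrichmentScore(rl, nm[c(9, 10)])
  expect_equal(bottom$es, -1.0)
  expect_identical(bottom$leadingMembers, nm[c(9, 10)])
  spread <- enrichmentScore(rl, nm[c(1, 9)])
  expect_equal(spread$es, 0.5)
  expect_identical(spread$peakRank, 1L)
})

test_that("the running sum terminates at zero and ES stays in [-1, 1]", {
  set.seed(6)
  for (i in 1:25) {
    n <- sample(5:40, 1)
    g <- sample(seq_len(n - 1), 1)
    rl <- toyRanked(n)
    sc <- enrichmentScore(rl, sample(rankedNames(rl), g))
    expect_lt(abs(sc$runningSum[n]), 1e-9)
    expect_lte(abs(sc$es), 1)
  }
})

test_that("enrichment score matches the brute-force oracle and the
           position-arithmetic fast path on exhaustive small cases", {
  for (n in c(5, 8)) {
    rl <- toyRanked(n)
    nm <- rankedNames(rl)
    for (mask in seq_len(2^n - 2)) {
      hits <- as.logical(bitwAnd(mask, 2^(seq_len(n) - 1)))
      sc <- enrichmentScore(rl, nm[hits])
      br <- bruteEs(hits)
      expect_equal(sc$es, br$es, tolerance = 1e-12)
      expect_identical(sc$peakRank, br$peakRank)
      fast <- qpcrSEA:::.esFromPositions(matrix(which(hits), ncol = 1),
                                         n, sum(hits))
      expect_equal(fast, br$es, tolerance = 1e-12)
    }
  }
})

test_that("degenerate sets are an undefined-statistic error", {
  rl <- toyRanked(6)
  expect_error(enrichmentScore(rl, "hsa-mir-none"), "undefined")
  expect_error(enrichmentScore(rl, rankedNames(rl)), "undefined")
})

test_that("the permutation null is seeded, exhaustive when small, and
           sign-balanced", {
  rl <- toyRanked(4)
  ne <- permutationNull(rl, 2)
  expect_true(attr(ne, "exhaustive"))
  expect_identical(length(ne), 6L)   # all C(4,2) subsets
  expect_setequal(round(ne, 10),
                  round(vapply(utils::combn(4, 2, simplify = FALSE),
                               function(p) bruteEs(1:4 %in% p)$es,
                               numeric(1)), 10))
  big <- toyRanked(300)
  n1 <- withr::with_seed(8, permutationNull(big, 5, permutations = 50))
  n2 <- withr::with_seed(8, permutationNull(big, 5, permutations = 50))
  expect_identical(n1, n2)
  expect_false(attr(n1, "exhaustive"))
})

test_that("NES and nominal p follow the same-sign permutation
           convention", {
  # all null magnitudes equal to the observed, same sign
  expect_equal(normalizeAndTest(0.5, rep(0.5, 10)),
               list(nes = 1, p = 1))
  expect_equal(normalizeAndTest(-0.5, rep(-0.5, 10)),
               list(nes = -1, p = 1))
  # observed exceeding every same-sign null with B = 19: add-one floor
  nt <- normalizeAndTest(0.9, seq(0.1, 0.5, length.out = 19))
  expect_equal(nt$p, 1 / 20)
  # p never zero, floored at 1/(B+1)
  expect_gte(nt$p, 1 / 20)
  expect_warning(normalizeAndTest(0.5, rep(-0.4, 5)), "no same-sign")
})

test_that("the statistic is rank-based: rescaling scores changes
           nothing", {
  rl1 <- RankedList(paste0("hsa-mir-", 1:30), 30:1)
  rl2 <- RankedList(paste0("hsa-mir-", 1:30), 2 * (30:1))
  mem <- paste0("hsa-mir-", c(2, 5, 11))
  s1 <- enrichmentScore(rl1, mem)
  s2 <- enrichmentScore(rl2, mem)
  expect_identical(s1, s2)
  coll <- MirnaSetCollection(list(MirnaSet("s", "function", mem)))
  r1 <- mirnaSEA(rl1, coll, permutations = 100, seed = 3)
  r2 <- mirnaSEA(rl2, coll, permutations = 100, seed = 3)
  expect_equal(enrichmentResults(r1)$nes, enrichmentResults(r2)$nes)
  expect_equal(enrichmentResults(r1)$p_nominal,
               enrichmentResults(r2)$p_nominal)
})

test_that("FDR q-values hit their boundary cases and are monotone in
           |NES| within a sign class", {
  expect_equal(computeFdr(2.5, c(0.5, 1, 1.5)), 0)  # null never reaches
  expect_equal(computeFdr(c(1, 1, 1), c(1, 1)), c(1, 1, 1))
  set.seed(10)
  rl <- toyRanked(60)
  nm <- rankedNames(rl)
  coll <- MirnaSetCollection(lapply(1:5, function(i)
    MirnaSet(paste0("s", i), "function", sample(nm, 6))))
  rep_ <- mirnaSEA(rl, coll, permutations = 300, seed = 11)
  df <- enrichmentResults(rep_)
  for (s in c(1, -1)) {
    idx <- which(sign(df$nes) == s)
    if (length(idx) > 1) {
      o <- order(-abs(df$nes[idx]))
      expect_true(all(diff(df$fdr_q[idx][o]) >= -1e-12))
      expect_true(all(diff(df$p_nominal[idx][o]) >= -1e-12))
    }
  }
  expect_true(all(df$fdr_q >= 0 & df$fdr_q <= 1))
})

test_that("reports are grouped by category and ordered by decreasing
           |NES| with deterministic ties", {
  set.seed(12)
  rl <- toyRanked(50)
  nm <- rankedNames(rl)
  coll <- MirnaSetCollection(list(
    MirnaSet("f1", "function", nm[c(1, 2, 3)]),
    MirnaSet("f2", "function", sample(nm, 5)),
    MirnaSet("r1", "regulator", nm[c(48, 49, 50)]),
    MirnaSet("r2", "regulator", sample(nm, 4))))
  rep_ <- mirnaSEA(rl, coll, permutations = 200, seed = 13)
  df <- enrichmentResults(rep_)
  expect_identical(unique(df$category), c("regulator", "function"))
  for (cat in unique(df$category)) {
    v <- abs(df$nes[df$category == cat])
    expect_true(all(diff(v) <= 1e-12))
  }
  expect_equal(sign(df$nes), sign(df$es))
})

test_that("report filters apply inclusive thresholds on the packaged
           reported-set tables", {
  enr <- readEnrichmentReport(system.file(
    "extdata", "enriched_sets_reported.tsv", package = "qpcrSEA"))
  expect_identical(length(applyReportFilters(enr, pCut = 0.05,
                                             absEsCut = 0)), 6L)
  expect_identical(length(applyReportFilters(enr, pCut = 0.02,
                                             absEsCut = 0)), 0L)
  fun <- readEnrichmentReport(system.file(
    "extdata", "functional_sets_reported.tsv", package = "qpcrSEA"))
  # |ES| = 0.25 is retained: the threshold is inclusive
  expect_identical(length(applyReportFilters(fun, pCut = 1,
                                             absEsCut = 0.25)), 4L)
  expect_identical(length(applyReportFilters(fun, pCut = 1,
                                             absEsCut = 0.26)), 3L)
})

test_that("a zero p-value cut excludes everything: p is floored above
           zero", {
  rl <- toyRanked(20)
  coll <- MirnaSetCollection(list(
    MirnaSet("top", "function", rankedNames(rl)[1:3])))
  rep_ <- mirnaSEA(rl, coll, permutations = 100, seed = 14)
  expect_gt(enrichmentResults(rep_)$p_nominal, 0)
  expect_identical(length(applyReportFilters(rep_, pCut = 0,
                                             absEsCut = 0)), 0L)
})

test_that("plot-data tables expose the NES/p/FDR and ES/rank axes", {
  set.seed(15)
  rl <- toyRanked(40)
  coll <- MirnaSetCollection(lapply(1:4, function(i)
    MirnaSet(paste0("s", i), "function", sample(rankedNames(rl), 5))))
  rep_ <- mirnaSEA(rl, coll, permutations = 100, seed = 16)
  sig <- significancePlotData(rep_, "function")
  expect_identical(names(sig),
                   c("category", "set_name", "nes", "p_nominal", "fdr_q"))
  expect_identical(nrow(sig), 4L)
  esr <- esPlotData(rep_, "function")
  expect_identical(esr$rank, 1:4)
  expect_true(all(diff(esr$es) <= 0))   # positive to negative correlation
})

test_that("enrichment reports round-trip through their file format", {
  set.seed(17)
  rl <- toyRanked(30)
  coll <- MirnaSetCollection(list(
    MirnaSet("a", "function", rankedNames(rl)[c(1, 4, 7)]),
    MirnaSet("b", "target", rankedNames(rl)[c(20, 25)])))
  rep_ <- mirnaSEA(rl, coll, permutations = 100, seed = 18)
  path <- withr::local_tempfile(fileext = ".tsv")
  writeEnrichmentReport(rep_, path)
  back <- readEnrichmentReport(path)
  expect_equal(as.data.frame(back), as.data.frame(rep_))
})
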