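#' Rank miRNAs by differential expression between two conditions
#'
#' Computes a per-miRNA differential score between the two conditions of a
#' normalized expression matrix and returns the descending ranked list that
#' feeds the set enrichment statistic.  Rank 1 is the miRNA most
#' up-regulated in the test condition.
#'
#' Metrics (computed on condition means of the `2^(-dCq)` relative
#' expression values, over defined values only):
#' \describe{
#'   \item{log2_fold_change}{`log2(mean(test) / mean(reference))`, the
#'     default; equivalent to minus the delta-delta-Cq.}
#'   \item{signal_to_noise}{`(mean(test) - mean(reference)) / (sd(test) +
#'     sd(reference))` with each standard deviation floored at 20% of the
#'     corresponding mean magnitude, the convention of the GSEA lineage.}
#' }
#'
#' A condition mean of zero would give an infinite log2 fold change; such
#' scores are clamped to `+-(max finite |score| + 1)` with a warning so the
#' list stays total and finite.  miRNAs without any defined value in one of
#' the conditions are dropped with a message.  Ties are broken
#' lexicographically by name, making the order deterministic.
#'
#' @param se SummarizedExperiment with assay `relexpr` and a two-level
#'   `condition` column (see [normalizeDeltaCq()]).
#' @param metric `"log2_fold_change"` or `"signal_to_noise"`.
#' @param ref the reference condition label; defaults to the condition of
#'   the first sample.  The other label is the test condition.
#' @return a [RankedList-class].
#' @export
#' @examples
#' mat <- rbind("hsa-mir-1" = c(1, 1, 2, 2), "hsa-mir-2" = c(2, 2, 1, 1))
#' se <- SummarizedExperiment::SummarizedExperiment(
#'   assays = list(relexpr = mat),
#'   colData = S4Vectors::DataFrame(condition = c("a", "a", "b", "b")))
#' rankDifferential(se)
rankDifferential <- function(se,
                             metric = c("log2_fold_change",
                                        "signal_to_noise"),
                             ref = NULL) {
  metric <- match.arg(metric)
  mat <- SummarizedExperiment::assay(se, "relexpr")
  cond <- as.character(SummarizedExperiment::colData(se)$condition)
  lev <- unique(cond)
  .assert(length(lev) == 2L, "exactly two conditions are required")
  if (is.null(ref)) ref <- lev[1]
  .assert(ref %in% lev, "ref must be one of the condition labels")
  test <- setdiff(lev, ref)
  .assert(sum(cond == ref) > 0 && sum(cond == test) > 0,
          "each condition needs at least one sample")

  m1v <- mat[, cond == ref, drop = FALSE]
  m2v <- mat[, cond == test, drop = FALSE]
  def <- rowSums(!is.na(m1v)) > 0 & rowSums(!is.na(m2v)) > 0
  if (any(!def)) {
    message(sum(!def), " miRNA(s) without a defined value in one ",
            "condition dropped before ranking")
    m1v <- m1v[def, , drop = FALSE]
    m2v <- m2v[def, , drop = FALSE]
  }
  m1 <- rowMeans(m1v, na.rm = TRUE)
  m2 <- rowMeans(m2v, na.rm = TRUE)

  if (metric == "log2_fold_change") {
    score <- log2(m2 / m1)
    if (any(!is.finite(score))) {
      warning("zero condition mean(s): clamping ", sum(!is.finite(score)),
              " score(s) beyond the finite range")
      cap <- if (any(is.finite(score))) max(abs(score[is.finite(score)])) else 0
      score[is.nan(score)] <- 0                      # 0/0
      score[score == Inf] <- cap + 1
      score[score == -Inf] <- -(cap + 1)
    }
  } else {
    rowSdNa <- function(x) apply(x, 1, stats::sd, na.rm = TRUE)
    s1 <- rowSdNa(m1v); s2 <- rowSdNa(m2v)
    s1[!is.finite(s1)] <- 0; s2[!is.finite(s2)] <- 0
    s1 <- pmax(s1, 0.2 * abs(m1), 1e-8)
    s2 <- pmax(s2, 0.2 * abs(m2), 1e-8)
    score <- (m2 - m1) / (s1 + s2)
  }
  RankedList(names(score), unname(score))
}

#' Write / read a ranked list
#'
#' Two-column tab-separated text (`mirna`, `score`), descending by score.
#'
#' @param ranked a [RankedList-class].
#' @param path file path.
#' @return `readRankedList()` returns a [RankedList-class];
#'   `writeRankedList()` returns `path` invisibly.
#' @export
writeRankedList <- function(ranked, path) {
  utils::write.table(
    data.frame(mirna = rankedNames(ranked), score = scores(ranked)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeRankedList
#' @export
readRankedList <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  RankedList(df$mirna, df$score)
}
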