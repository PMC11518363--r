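## ---------------------------------------------------------------------------
## Running-sum enrichment statistic (unweighted, Kolmogorov-Smirnov style),
## permutation null, NES / nominal p, GSEA-convention FDR q-values.
## ---------------------------------------------------------------------------

#' Running-sum enrichment score of a miRNA set
#'
#' Walks the ranked list from rank 1 to N, adding `+1/G` when the current
#' miRNA belongs to the set (a hit) and `-1/(N-G)` otherwise, where `G` is
#' the number of set members inside the universe.  The enrichment score
#' (ES) is the signed value of the running sum at its maximum absolute
#' deviation from zero; exact ties are broken toward the positive peak and
#' then toward the earlier rank.  The running sum always terminates at zero.
#'
#' The leading-edge members are the set members at or before the peak for a
#' positive ES, and strictly after the peak for a negative ES.
#'
#' @param ranked a [RankedList-class].
#' @param members character vector of set member names (normalized
#'   internally).
#' @return list with elements `es` (in \[-1, 1\]), `peakRank` (1-based),
#'   `runningSum` (length-N trace), `sizeG`, and `leadingMembers`.
#' @export
#' @examples
#' rl <- RankedList(paste0("hsa-mir-", 1:10), 10:1)
#' enrichmentScore(rl, c("hsa-mir-1", "hsa-mir-2"))$es   # +1
enrichmentScore <- function(ranked, members) {
  universe <- rankedNames(ranked)
  N <- length(universe)
  hits <- universe %in% normalizeMirnaNames(members)
  G <- sum(hits)
  if (G == 0L || G == N)
    stop("enrichment score undefined: set covers ", G, " of ", N,
         " ranked miRNAs", call. = FALSE)
  rs <- cumsum(ifelse(hits, 1 / G, -1 / (N - G)))
  maxDev <- max(abs(rs))
  tol <- 1e-12
  cand <- which(abs(rs) >= maxDev - tol)
  pos <- cand[rs[cand] > 0]
  peak <- if (length(pos)) pos[1] else cand[1]
  es <- rs[peak]
  lead <- if (es >= 0) universe[hits & seq_len(N) <= peak]
          else universe[hits & seq_len(N) > peak]
  list(es = es, peakRank = peak, runningSum = rs, sizeG = G,
       leadingMembers = lead)
}

## ES from sorted hit positions, vectorised over the columns of a G x B
## matrix.  The running sum attains its extrema only adjacent to hits:
## after hit i the sum is i/G - (p_i - i)/(N - G); before hit i it is one
## 1/G step lower.  Same tie-break as enrichmentScore (positive wins).
.esFromPositions <- function(pos, N, G) {
  if (is.null(dim(pos))) pos <- matrix(pos, ncol = 1)
  i <- seq_len(G)
  after <- i / G - (pos - i) / (N - G)
  before <- after - 1 / G
  maxPos <- apply(after, 2, max)
  maxNeg <- apply(-before, 2, max)
  ifelse(maxPos >= maxNeg - 1e-12, maxPos, -maxNeg)
}

#' Permutation null distribution of the enrichment score
#'
#' Null ES values for random size-`G` sets drawn uniformly without
#' replacement from the ranked universe (set-label permutation).  When the
#' number of distinct subsets `choose(N, G)` does not exceed
#' `exhaustiveLimit`, all subsets are enumerated instead of sampled and the
#' result carries `attr(, "exhaustive") = TRUE`.
#'
#' Sampling uses the caller's RNG state; seed upstream (e.g. via the
#' `seed` argument of [mirnaSEA()]) for reproducibility.
#'
#' @param ranked a [RankedList-class] (only its length and order matter:
#'   the ES is a rank statistic).
#' @param G set size, `1 <= G < N`.
#' @param permutations number of Monte-Carlo draws `B`.
#' @param exhaustiveLimit enumerate exhaustively when `choose(N, G)` is at
#'   most this.
#' @return numeric vector of null ES values.
#' @export
permutationNull <- function(ranked, G, permutations = 1000L,
                            exhaustiveLimit = 10000L) {
  N <- length(ranked)
  .assert(G >= 1 && G < N, "need 1 <= G < N")
  .assert(permutations >= 1, "need at least one permutation")
  if (choose(N, G) <= exhaustiveLimit) {
    pos <- utils::combn(N, G)
    out <- .esFromPositions(pos, N, G)
    attr(out, "exhaustive") <- TRUE
  } else {
    pos <- vapply(seq_len(permutations),
                  function(i) sort.int(sample.int(N, G)), numeric(G))
    out <- .esFromPositions(matrix(pos, nrow = G), N, G)
    attr(out, "exhaustive") <- FALSE
  }
  out
}

#' Normalize an enrichment score and test it against a permutation null
#'
#' The normalized enrichment score (NES) divides the observed ES by the
#' mean magnitude of the same-sign null ES values, making sets of different
#' sizes comparable.  The nominal p-value is the add-one permutation
#' estimate `(1 + #same-sign null at least as extreme) / (1 + #same-sign
#' null)`, so p is never zero and is floored at `1/(B+1)`.  When no null
#' value shares the observed sign, all null magnitudes are used with a
#' warning.
#'
#' @param es observed enrichment score.
#' @param nullEs numeric vector of null ES values from [permutationNull()].
#' @return list with elements `nes` and `p`.
#' @export
normalizeAndTest <- function(es, nullEs) {
  .assert(length(nullEs) > 0, "empty null sample")
  if (es == 0) return(list(nes = 0, p = 1))
  same <- nullEs[sign(nullEs) == sign(es)]
  if (length(same) == 0) {
    warning("no same-sign null ES values; falling back to all magnitudes")
    same <- abs(nullEs) * sign(es)
  }
  nes <- es / mean(abs(same))
  p <- (1 + sum(abs(same) >= abs(es))) / (1 + length(same))
  list(nes = nes, p = p)
}

#' Permutation-based FDR q-values (GSEA convention)
#'
#' For each observed NES, the q-value is the ratio of the fraction of
#' pooled null NES values at least as extreme (same sign) to the fraction
#' of observed NES values at least as extreme (same sign), clipped to
#' \[0, 1\] and made monotone within each sign class (a more extreme NES
#' never gets a larger q than a less extreme one).
#'
#' @param nes numeric vector of observed NES values.
#' @param nullNes numeric vector of pooled, normalized null NES values.
#' @return numeric vector of q-values, same length as `nes`.
#' @export
computeFdr <- function(nes, nullNes) {
  .assert(length(nes) >= 1, "need at least one observed NES")
  q <- rep(NA_real_, length(nes))
  for (s in c(1, -1)) {
    idx <- which(sign(nes) == s)
    if (!length(idx)) next
    nullS <- abs(nullNes[sign(nullNes) == s])
    obsS <- abs(nes[idx])
    qi <- vapply(obsS, function(v) {
      num <- if (length(nullS)) mean(nullS >= v) else 0
      den <- mean(obsS >= v)
      min(1, max(0, num / den))
    }, numeric(1))
    ## monotone correction: suffix-minimum along decreasing |NES|
    o <- order(-obsS)
    qi[o] <- rev(cummin(rev(qi[o])))
    q[idx] <- qi
  }
  q[sign(nes) == 0] <- 1
  q
}

#' miRNA set enrichment analysis
#'
#' Computes, for every set of a collection, the running-sum enrichment
#' score, the permutation-normalized enrichment score, the nominal p-value
#' and the FDR q-value against a set-label permutation null, and returns a
#' category-grouped report ordered by decreasing |NES| within each
#' category.
#'
#' The null is generated once per distinct set size `G` (the ES is a rank
#' statistic, so the null depends only on `N` and `G`) and enumerated
#' exhaustively when `choose(N, G) <= exhaustiveLimit`.  FDR q-values are
#' computed within each category by default, mirroring reports that
#' analyze one category at a time; `fdrScope = "global"` pools all sets.
#'
#' @param ranked a [RankedList-class].
#' @param collection a [MirnaSetCollection-class].
#' @param permutations permutation count `B` per set size.
#' @param seed optional integer; when given, the permutation RNG is seeded
#'   locally and the caller's RNG state is untouched.
#' @param minSize minimum set size after restriction to the universe.
#' @param fdrScope `"category"` or `"global"`.
#' @param exhaustiveLimit see [permutationNull()].
#' @return an [EnrichmentReport-class].
#' @export
#' @examples
#' rl <- RankedList(paste0("hsa-mir-", 1:20), 20:1)
#' coll <- MirnaSetCollection(list(
#'   MirnaSet("top", "function", paste0("hsa-mir-", 1:4)),
#'   MirnaSet("spread", "function", paste0("hsa-mir-", c(3, 9, 15)))))
#' mirnaSEA(rl, coll, permutations = 200, seed = 1)
mirnaSEA <- function(ranked, collection, permutations = 1000L, seed = NULL,
                     minSize = 2L, fdrScope = c("category", "global"),
                     exhaustiveLimit = 10000L) {
  fdrScope <- match.arg(fdrScope)
  restricted <- restrictToUniverse(collection, ranked, minSize)
  emptyReport <- function() new("EnrichmentReport",
    results = S4Vectors::DataFrame(
      category = character(), set_name = character(), size_G = integer(),
      es = numeric(), peak_rank = integer(), nes = numeric(),
      p_nominal = numeric(), fdr_q = numeric(),
      leading_members = IRanges::CharacterList(),
      members = IRanges::CharacterList()),
    params = list(permutations = permutations, seed = seed,
                  minSize = minSize, fdrScope = fdrScope))
  if (length(restricted) == 0L) return(emptyReport())

  run <- function() {
    sizes <- vapply(restricted@sets, length, integer(1))
    nulls <- list()
    for (G in unique(sizes))
      nulls[[as.character(G)]] <-
        permutationNull(ranked, G, permutations, exhaustiveLimit)
    ## normalized null per size: positives / mean(pos), negatives / mean(|neg|)
    nullNes <- lapply(nulls, function(ne) {
      out <- numeric(length(ne))
      posM <- mean(ne[ne > 0]); negM <- mean(abs(ne[ne < 0]))
      out[ne > 0] <- ne[ne > 0] / posM
      out[ne < 0] <- ne[ne < 0] / negM
      out
    })
    rows <- lapply(restricted@sets, function(s) {
      sc <- enrichmentScore(ranked, s@members)
      nt <- normalizeAndTest(sc$es, nulls[[as.character(sc$sizeG)]])
      list(category = s@category, set_name = s@name, size_G = sc$sizeG,
           es = sc$es, peak_rank = sc$peakRank, nes = nt$nes,
           p_nominal = nt$p, lead = sc$leadingMembers, members = s@members)
    })
    list(rows = rows, nullNes = nullNes)
  }
  res <- if (is.null(seed)) run() else withSeed(seed, run())
  rows <- res$rows

  df <- S4Vectors::DataFrame(
    category = vapply(rows, `[[`, character(1), "category"),
    set_name = vapply(rows, `[[`, character(1), "set_name"),
    size_G = vapply(rows, `[[`, integer(1), "size_G"),
    es = vapply(rows, `[[`, numeric(1), "es"),
    peak_rank = vapply(rows, `[[`, integer(1), "peak_rank"),
    nes = vapply(rows, `[[`, numeric(1), "nes"),
    p_nominal = vapply(rows, `[[`, numeric(1), "p_nominal"),
    fdr_q = NA_real_,
    leading_members = IRanges::CharacterList(lapply(rows, `[[`, "lead")),
    members = IRanges::CharacterList(lapply(rows, `[[`, "members")))

  pooledNull <- function(idx) {
    unlist(res$nullNes[as.character(df$size_G[idx])], use.names = FALSE)
  }
  if (fdrScope == "global") {
    df$fdr_q <- computeFdr(df$nes, pooledNull(seq_len(nrow(df))))
  } else {
    for (cat in unique(df$category)) {
      idx <- which(df$category == cat)
      df$fdr_q[idx] <- computeFdr(df$nes[idx], pooledNull(idx))
    }
  }

  ## category-grouped, |NES|-descending order, ties by set name
  catOrder <- c(intersect(.SET_CATEGORIES, unique(df$category)),
                setdiff(unique(df$category), .SET_CATEGORIES))
  o <- order(match(df$category, catOrder), -abs(df$nes), df$set_name)
  new("EnrichmentReport", results = df[o, ],
      params = list(permutations = permutations, seed = seed,
                    minSize = minSize, fdrScope = fdrScope,
                    N = length(ranked)))
}

#' Filter an enrichment report by significance and effect size
#'
#' Keeps sets with nominal p-value at most `pCut` and |ES| at least
#' `absEsCut`; both bounds are inclusive.  Pass `pCut = 1` or
#' `absEsCut = 0` to disable one of the filters.  Rows with an undefined
#' value of a filtered statistic are dropped.
#'
#' @param report an [EnrichmentReport-class].
#' @param pCut nominal p-value threshold (inclusive).
#' @param absEsCut |ES| threshold (inclusive).
#' @return the filtered report; the thresholds are recorded in its params.
#' @export
applyReportFilters <- function(report, pCut = 0.05, absEsCut = 0.25) {
  df <- report@results
  keep <- !is.na(df$p_nominal) & df$p_nominal <= pCut &
    !is.na(df$es) & abs(df$es) >= absEsCut
  p <- report@params
  p$p_cut <- pCut
  p$abs_es_cut <- absEsCut
  new("EnrichmentReport", results = df[keep, ], params = p)
}

#' Plot-data tables behind the enrichment figures
#'
#' `significancePlotData()` returns, per set, the NES with its nominal
#' p-value and FDR q-value (the axes of the significance plot).
#' `esPlotData()` returns, per set, the unnormalized ES and the within-
#' category rank from the most positively to the most negatively
#' correlated set.
#'
#' @param report an [EnrichmentReport-class].
#' @param category optional category to restrict to.
#' @return a base data.frame.
#' @export
significancePlotData <- function(report, category = NULL) {
  df <- as.data.frame(report@results[, c("category", "set_name", "nes",
                                         "p_nominal", "fdr_q")])
  if (!is.null(category)) df <- df[df$category == category, ]
  rownames(df) <- NULL
  df
}

#' @rdname significancePlotData
#' @export
esPlotData <- function(report, category = NULL) {
  df <- as.data.frame(report@results[, c("category", "set_name", "es")])
  if (!is.null(category)) df <- df[df$category == category, ]
  parts <- split(df, df$category)
  out <- do.call(rbind, lapply(parts, function(d) {
    d <- d[order(-d$es, d$set_name), ]
    d$rank <- seq_len(nrow(d))
    d
  }))
  rownames(out) <- NULL
  out
}

#' Read / write an enrichment report as tabular text
#'
#' Tab-separated with one row per set; the `leading_members` and `members`
#' columns are comma-joined.  Reading reconstructs an
#' [EnrichmentReport-class] (with empty params), so externally supplied
#' report tables — e.g. published per-set ES and p values — can be pushed
#' through [applyReportFilters()] and the candidate-selection stage.
#'
#' @param report an [EnrichmentReport-class].
#' @param path file path.
#' @return `readEnrichmentReport()` returns an [EnrichmentReport-class];
#'   `writeEnrichmentReport()` returns `path` invisibly.
#' @export
writeEnrichmentReport <- function(report, path) {
  utils::write.table(as.data.frame(report), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeEnrichmentReport
#' @export
readEnrichmentReport <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, na.strings = "NA")
  splitCol <- function(x) IRanges::CharacterList(
    lapply(strsplit(ifelse(is.na(x), "", x), ",", fixed = TRUE),
           function(v) normalizeMirnaNames(v[nzchar(v)])))
  res <- S4Vectors::DataFrame(
    category = df$category, set_name = df$set_name,
    size_G = as.integer(df$size_G), es = as.numeric(df$es),
    peak_rank = as.integer(df$peak_rank), nes = as.numeric(df$nes),
    p_nominal = as.numeric(df$p_nominal), fdr_q = as.numeric(df$fdr_q),
    leading_members = splitCol(df$leading_members),
    members = splitCol(df$members))
  new("EnrichmentReport", results = res, params = list())
}
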