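#' @include AllGenerics.R
#' @importFrom methods setClass setGeneric setMethod setValidity new validObject is slot
#' @importFrom S4Vectors DataFrame
NULL

## valid well classes on a miRNome PCR panel
.WELL_CLASSES <- c("mirna_assay", "interplate_calibrator", "reference_gene",
                   "spike_in", "blank")

## the six miSEA set categories
.SET_CATEGORIES <- c("target", "regulator", "cluster", "family", "tissue",
                     "function")

#' Well classes and set categories
#'
#' Controlled vocabularies used throughout the package: the five well
#' classes of a miRNome PCR panel and the six miRNA set categories of the
#' set enrichment analysis.
#'
#' @return a character vector of valid values.
#' @export
#' @examples
#' wellClasses()
#' setCategories()
wellClasses <- function() .WELL_CLASSES

#' @rdname wellClasses
#' @export
setCategories <- function() .SET_CATEGORIES

# ---------------------------------------------------------------------------
# PanelLayout
# ---------------------------------------------------------------------------

#' PanelLayout: the well map of a qPCR miRNome panel plate
#'
#' One row per well with a well identifier, the assay measured in that well
#' (`NA` for the blank well) and the well class: `mirna_assay`,
#' `interplate_calibrator`, `reference_gene`, `spike_in` or `blank`.  The
#' default human miRNome panel layout carries 372 miRNA assays, 3 interplate
#' calibrators, 3 reference-gene assays, 5 RNA spike-in controls and 1 blank
#' well (384 wells in total).
#'
#' @slot wells data.frame with columns `well_id`, `assay_name`,
#'   `well_class`.
#' @slot plateId single plate identifier string.
#' @seealso [makeDefaultLayout()], [wells()], [plateId()]
#' @name PanelLayout-class
#' @exportClass PanelLayout
setClass("PanelLayout",
         slots = c(wells = "data.frame", plateId = "character"))

setValidity("PanelLayout", function(object) {
  w <- object@wells
  msg <- character()
  need <- c("well_id", "assay_name", "well_class")
  if (!all(need %in% names(w)))
    return(paste("wells must have columns", paste(need, collapse = ", ")))
  if (length(object@plateId) != 1L || is.na(object@plateId))
    msg <- c(msg, "plateId must be a single non-NA string")
  if (!all(w$well_class %in% .WELL_CLASSES))
    msg <- c(msg, paste("well_class values must be one of:",
                        paste(.WELL_CLASSES, collapse = ", ")))
  if (anyDuplicated(w$well_id))
    msg <- c(msg, "well_id values must be unique")
  an <- w$assay_name[w$well_class != "blank"]
  if (anyNA(an))
    msg <- c(msg, "non-blank wells must have an assay_name")
  if (anyDuplicated(an))
    msg <- c(msg, "assay_name must be unique per plate")
  if (!all(is.na(w$assay_name[w$well_class == "blank"])))
    msg <- c(msg, "blank wells must have no assay target (assay_name NA)")
  if (length(msg)) msg else TRUE
})

#' @rdname layout-accessors
setMethod("wells", "PanelLayout", function(x) x@wells)

#' @rdname layout-accessors
setMethod("plateId", "PanelLayout", function(x) x@plateId)

setMethod("show", "PanelLayout", function(object) {
  tab <- table(factor(object@wells$well_class, levels = .WELL_CLASSES))
  cat("PanelLayout '", object@plateId, "' with ",
      nrow(object@wells), " wells\n", sep = "")
  for (cl in names(tab))
    cat(sprintf("  %-22s %d\n", cl, tab[[cl]]))
})

# ---------------------------------------------------------------------------
# RankedList
# ---------------------------------------------------------------------------

#' RankedList: miRNAs ordered by a differential score
#'
#' The input of the set enrichment statistic: miRNA names sorted by a
#' differential-expression score, rank 1 being the most up-regulated in the
#' test condition.  Scores are non-increasing with rank and ties are broken
#' lexicographically by name so that the order is deterministic.
#'
#' @slot mirna character vector of unique, canonical miRNA names in rank
#'   order.
#' @slot score numeric vector of matching scores, non-increasing.
#' @seealso [rankDifferential()], [RankedList()]
#' @name RankedList-class
#' @exportClass RankedList
setClass("RankedList", slots = c(mirna = "character", score = "numeric"))

setValidity("RankedList", function(object) {
  msg <- character()
  n <- length(object@mirna)
  if (n < 2L) msg <- c(msg, "a ranked list needs at least 2 miRNAs")
  if (length(object@score) != n)
    msg <- c(msg, "mirna and score lengths differ")
  if (anyDuplicated(object@mirna))
    msg <- c(msg, "miRNA names must be unique")
  if (anyNA(object@score) || any(!is.finite(object@score)))
    msg <- c(msg, "scores must be finite")
  if (n >= 2L && any(diff(object@score) > 0))
    msg <- c(msg, "scores must be non-increasing with rank")
  if (length(msg)) msg else TRUE
})

#' Construct a RankedList
#'
#' Sorts (name, score) pairs by decreasing score, breaking ties
#' lexicographically by name, and validates the result.
#'
#' @param mirna character vector of miRNA names (normalized with
#'   [normalizeMirnaNames()]).
#' @param score numeric vector of differential scores, one per name.
#' @return a [RankedList-class] object.
#' @export
#' @examples
#' rl <- RankedList(c("hsa-mir-1", "hsa-mir-2", "hsa-mir-3"), c(0, 2, -1))
#' rankedNames(rl)
RankedList <- function(mirna, score) {
  mirna <- normalizeMirnaNames(mirna)
  o <- order(-score, mirna)
  new("RankedList", mirna = mirna[o], score = as.numeric(score[o]))
}

#' @rdname rankedlist-accessors
setMethod("rankedNames", "RankedList", function(x) x@mirna)

#' @rdname rankedlist-accessors
setMethod("scores", "RankedList", function(x) x@score)

#' @describeIn RankedList-class number of ranked miRNAs.
#' @param x a RankedList.
#' @export
setMethod("length", "RankedList", function(x) length(x@mirna))

setMethod("show", "RankedList", function(object) {
  n <- length(object@mirna)
  cat("RankedList of", n, "miRNAs\n")
  k <- min(3L, n)
  cat("  top:   ", paste(sprintf("%s (%.3g)", object@mirna[seq_len(k)],
                                 object@score[seq_len(k)]), collapse = ", "),
      "\n")
  cat("  bottom:", paste(sprintf("%s (%.3g)",
                                 object@mirna[seq(n - k + 1L, n)],
                                 object@score[seq(n - k + 1L, n)]),
                         collapse = ", "), "\n")
})

# ---------------------------------------------------------------------------
# MirnaSet / MirnaSetCollection
# ---------------------------------------------------------------------------

#' MirnaSet: a named set of miRNAs with a category
#'
#' A member set of the enrichment analysis, carrying one of the six
#' categories (target, regulator, cluster, family, tissue, function), a
#' free-text provenance tag, and — for tissue sets — the tissue-specificity
#' index in \[0, 1\] used by [filterTissueSets()].
#'
#' @slot name set name, unique within its category.
#' @slot category one of the six set categories.
#' @slot members non-empty character vector of canonical miRNA names.
#' @slot provenance free-text source tag.
#' @slot tsi tissue-specificity index; `NA` outside the tissue category.
#' @seealso [MirnaSet()], [readGmt()]
#' @name MirnaSet-class
#' @exportClass MirnaSet
setClass("MirnaSet",
         slots = c(name = "character", category = "character",
                   members = "character", provenance = "character",
                   tsi = "numeric"))

setValidity("MirnaSet", function(object) {
  msg <- character()
  if (length(object@name) != 1L || !nzchar(object@name))
    msg <- c(msg, "name must be a single non-empty string")
  if (length(object@category) != 1L ||
      !object@category %in% .SET_CATEGORIES)
    msg <- c(msg, paste("category must be one of:",
                        paste(.SET_CATEGORIES, collapse = ", ")))
  if (length(object@members) == 0L)
    msg <- c(msg, "members must be non-empty")
  if (anyDuplicated(object@members))
    msg <- c(msg, "members must be unique")
  if (length(object@tsi) != 1L)
    msg <- c(msg, "tsi must be a single value (NA when absent)")
  else if (!is.na(object@tsi) && (object@tsi < 0 || object@tsi > 1))
    msg <- c(msg, "tissue-specificity index must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Construct a MirnaSet
#'
#' Member names are normalized to canonical `hsa-mir-*` form and
#' de-duplicated.
#'
#' @param name set name.
#' @param category one of the six set categories (see [setCategories()]).
#' @param members character vector of member miRNA names.
#' @param provenance free-text source tag.
#' @param tsi tissue-specificity index in \[0, 1\] (tissue category only).
#' @return a [MirnaSet-class] object.
#' @export
#' @examples
#' MirnaSet("Coregulate MTOR", "function",
#'          c("hsa-mir-99a", "hsa-mir-100", "hsa-mir-182", "hsa-mir-199b"))
MirnaSet <- function(name, category, members, provenance = "",
                     tsi = NA_real_) {
  new("MirnaSet", name = as.character(name),
      category = as.character(category),
      members = unique(normalizeMirnaNames(members)),
      provenance = as.character(provenance), tsi = as.numeric(tsi))
}

#' @rdname set-accessors
setMethod("members", "MirnaSet", function(x) x@members)

#' @rdname set-accessors
setMethod("category", "MirnaSet", function(x) x@category)

#' @rdname set-accessors
setMethod("tissueSpecificityIndex", "MirnaSet", function(x) x@tsi)

#' @describeIn MirnaSet-class number of member miRNAs.
#' @param x a MirnaSet.
#' @export
setMethod("length", "MirnaSet", function(x) length(x@members))

setMethod("show", "MirnaSet", function(object) {
  cat("MirnaSet '", object@name, "' [", object@category, "], ",
      length(object@members), " members\n", sep = "")
  if (!is.na(object@tsi)) cat("  tissue-specificity index:", object@tsi, "\n")
  cat(" ", paste(utils::head(object@members, 8L), collapse = ", "),
      if (length(object@members) > 8L) "...\n" else "\n")
})

#' MirnaSetCollection: a list of MirnaSets
#'
#' An ordered list of [MirnaSet-class] objects; set names are unique within
#' each category.  Usually read from a GMT file with [readGmt()].
#'
#' @slot sets list of MirnaSet objects.
#' @seealso [readGmt()], [filterTissueSets()], [restrictToUniverse()]
#' @name MirnaSetCollection-class
#' @exportClass MirnaSetCollection
setClass("MirnaSetCollection", slots = c(sets = "list"))

setValidity("MirnaSetCollection", function(object) {
  msg <- character()
  if (!all(vapply(object@sets, is, logical(1), class2 = "MirnaSet")))
    return("all elements must be MirnaSet objects")
  nm <- vapply(object@sets, function(s) s@name, character(1))
  ct <- vapply(object@sets, function(s) s@category, character(1))
  if (anyDuplicated(paste(ct, nm, sep = "\r")))
    msg <- c(msg, "set names must be unique within a category")
  if (length(msg)) msg else TRUE
})

#' Construct a MirnaSetCollection
#'
#' @param sets list of [MirnaSet-class] objects.
#' @return a [MirnaSetCollection-class] object.
#' @export
MirnaSetCollection <- function(sets = list()) {
  new("MirnaSetCollection", sets = unname(sets))
}

#' @describeIn MirnaSetCollection-class number of sets.
#' @param x a MirnaSetCollection.
#' @export
setMethod("length", "MirnaSetCollection", function(x) length(x@sets))

#' @describeIn MirnaSetCollection-class set names.
#' @export
setMethod("names", "MirnaSetCollection",
          function(x) vapply(x@sets, function(s) s@name, character(1)))

#' @describeIn MirnaSetCollection-class extract one set by name or index.
#' @param i set name or index.
#' @export
setMethod("[[", "MirnaSetCollection", function(x, i) {
  if (is.character(i)) {
    j <- match(i, names(x))
    if (is.na(j)) stop("no set named '", i, "'")
    i <- j
  }
  x@sets[[i]]
})

#' @describeIn MirnaSetCollection-class subset the collection.
#' @export
setMethod("[", "MirnaSetCollection", function(x, i) {
  if (is.character(i)) i <- match(i, names(x))
  MirnaSetCollection(x@sets[i])
})

#' @rdname set-accessors
setMethod("members", "MirnaSetCollection", function(x) {
  out <- lapply(x@sets, function(s) s@members)
  names(out) <- names(x)
  out
})

#' @rdname set-accessors
setMethod("category", "MirnaSetCollection",
          function(x) vapply(x@sets, function(s) s@category, character(1)))

setMethod("show", "MirnaSetCollection", function(object) {
  cat("MirnaSetCollection with", length(object@sets), "sets\n")
  if (length(object@sets)) {
    tab <- table(category(object))
    for (cl in names(tab)) cat(sprintf("  %-10s %d\n", cl, tab[[cl]]))
  }
})

# ---------------------------------------------------------------------------
# EnrichmentReport
# ---------------------------------------------------------------------------

#' EnrichmentReport: per-set enrichment statistics
#'
#' The result of [mirnaSEA()]: one row per miRNA set with the running-sum
#' enrichment score (ES), permutation-normalized enrichment score (NES),
#' nominal p-value, FDR q-value, set size after restriction to the ranked
#' universe, the rank at which the running sum peaks, and the leading-edge
#' members.  Rows are grouped by category and ordered by decreasing |NES|
#' within each category (ties broken by set name).
#'
#' @slot results `S4Vectors::DataFrame` with columns `category`,
#'   `set_name`, `size_G`, `es`, `peak_rank`, `nes`, `p_nominal`, `fdr_q`,
#'   `leading_members` (CharacterList), `members` (CharacterList).
#' @slot params list of analysis parameters (permutations, seed, filters
#'   applied, ...).
#' @seealso [mirnaSEA()], [applyReportFilters()], [significancePlotData()],
#'   [esPlotData()]
#' @name EnrichmentReport-class
#' @exportClass EnrichmentReport
setClass("EnrichmentReport",
         slots = c(results = "DataFrame", params = "list"))

setValidity("EnrichmentReport", function(object) {
  need <- c("category", "set_name", "size_G", "es", "peak_rank", "nes",
            "p_nominal", "fdr_q", "leading_members", "members")
  if (!all(need %in% colnames(object@results)))
    return(paste("results must have columns:", paste(need, collapse = ", ")))
  es <- object@results$es
  if (any(abs(es[!is.na(es)]) > 1 + 1e-9))
    return("enrichment scores must lie in [-1, 1]")
  TRUE
})

#' @rdname report-accessors
setMethod("enrichmentResults", "EnrichmentReport", function(x) x@results)

#' @rdname report-accessors
setMethod("reportParams", "EnrichmentReport", function(x) x@params)

#' @describeIn EnrichmentReport-class number of reported sets.
#' @param x an EnrichmentReport.
#' @export
setMethod("length", "EnrichmentReport", function(x) nrow(x@results))

#' @describeIn EnrichmentReport-class result table as a base data.frame
#'   (list columns collapsed to comma-separated strings).
#' @param row.names,optional,... passed on conventions of the generic;
#'   ignored.
#' @export
setMethod("as.data.frame", "EnrichmentReport",
          function(x, row.names = NULL, optional = FALSE, ...) {
  df <- as.data.frame(x@results[, setdiff(colnames(x@results),
                                          c("leading_members", "members"))])
  df$leading_members <- vapply(as.list(x@results$leading_members),
                               paste, character(1), collapse = ",")
  df$members <- vapply(as.list(x@results$members),
                       paste, character(1), collapse = ",")
  rownames(df) <- row.names
  df
})

setMethod("show", "EnrichmentReport", function(object) {
  cat("EnrichmentReport with", nrow(object@results), "sets\n")
  if (nrow(object@results)) {
    tab <- table(object@results$category)
    cat("  categories:",
        paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "), "\n")
    sig <- sum(object@results$p_nominal <= 0.05, na.rm = TRUE)
    cat("  sets with nominal p <= 0.05:", sig, "\n")
  }
  if (!is.null(object@params$permutations))
    cat("  permutations:", object@params$permutations, "\n")
})
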