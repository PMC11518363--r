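#' Accessors for panel layouts
#'
#' @param x a [PanelLayout-class] object.
#' @return `wells()` returns the well table (one row per well, columns
#'   `well_id`, `assay_name`, `well_class`); `plateId()` returns the plate
#'   identifier.
#' @name layout-accessors
#' @aliases wells plateId
#' @examples
#' lay <- makeDefaultLayout()
#' head(wells(lay))
#' plateId(lay)
NULL

#' @rdname layout-accessors
#' @export
setGeneric("wells", function(x) standardGeneric("wells"))

#' @rdname layout-accessors
#' @export
setGeneric("plateId", function(x) standardGeneric("plateId"))

#' Accessors for ranked miRNA lists
#'
#' @param x a [RankedList-class] object.
#' @return `rankedNames()` the miRNA names in rank order (rank 1 = most
#'   up-regulated in the test condition); `scores()` the matching
#'   non-increasing differential scores.
#' @name rankedlist-accessors
#' @aliases rankedNames scores
NULL

#' @rdname rankedlist-accessors
#' @export
setGeneric("rankedNames", function(x) standardGeneric("rankedNames"))

#' @rdname rankedlist-accessors
#' @export
setGeneric("scores", function(x) standardGeneric("scores"))

#' Accessors for miRNA sets and collections
#'
#' @param x a [MirnaSet-class] or [MirnaSetCollection-class] object.
#' @return `members()` returns the member miRNA names of a set, or a named
#'   list of member vectors for a collection; `category()` returns the set
#'   category (one of target, regulator, cluster, family, tissue, function), or the
#'   per-set category vector for a collection; `tissueSpecificityIndex()`
#'   the tissue-specificity index (`NA` outside the tissue category).
#' @name set-accessors
#' @aliases members category tissueSpecificityIndex
NULL

#' @rdname set-accessors
#' @export
setGeneric("members", function(x) standardGeneric("members"))

#' @rdname set-accessors
#' @export
setGeneric("category", function(x) standardGeneric("category"))

#' @rdname set-accessors
#' @export
setGeneric("tissueSpecificityIndex",
           function(x) standardGeneric("tissueSpecificityIndex"))

#' Accessors for enrichment reports
#'
#' @param x an [EnrichmentReport-class] object.
#' @return `enrichmentResults()` returns the per-set result table (a
#'   `DataFrame` with columns `category`, `set_name`, `size_G`, `es`,
#'   `peak_rank`, `nes`, `p_nominal`, `fdr_q`, `leading_members`,
#'   `members`); `reportParams()` the list of analysis parameters recorded
#'   with the report.
#' @name report-accessors
#' @aliases enrichmentResults reportParams
NULL

#' @rdname report-accessors
#' @export
setGeneric("enrichmentResults",
           function(x) standardGeneric("enrichmentResults"))

#' @rdname report-accessors
#' @export
setGeneric("reportParams", function(x) standardGeneric("reportParams"))
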