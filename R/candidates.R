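#' Read target-prediction evidence
#'
#' Three-column tab-separated text: `mirna`, `target_gene`, `tool` — one
#' row per (miRNA, gene, tool) prediction.  Duplicate triples are dropped.
#' miRNA names are normalized (mature-arm suffixes preserved).
#'
#' @param path file path.
#' @return data.frame with columns `mirna`, `target_gene`, `tool`.
#' @export
#' @examples
#' ev <- readPredictionEvidence(system.file("extdata",
#'   "wwox_predictions.tsv", package = "qpcrSEA"))
#' head(ev)
readPredictionEvidence <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  .assert(all(c("mirna", "target_gene", "tool") %in% names(df)),
          "evidence must have columns mirna, target_gene, tool")
  df$mirna <- normalizeMirnaNames(df$mirna)
  unique(df)
}

#' Multi-tool target-prediction consensus
#'
#' Returns the miRNAs predicted to target `gene` by at least `minTools`
#' distinct prediction tools, with the supporting tool list per miRNA.
#' Raising `minTools` never adds miRNAs.
#'
#' @param evidence evidence data.frame (see [readPredictionEvidence()]).
#' @param gene target gene symbol (case-insensitive match).
#' @param minTools minimum number of distinct supporting tools.
#' @return named list: canonical miRNA name -> character vector of tools.
#' @export
#' @examples
#' ev <- readPredictionEvidence(system.file("extdata",
#'   "wwox_predictions.tsv", package = "qpcrSEA"))
#' consensusTargets(ev, "WWOX")[["hsa-mir-182-5p"]]
consensusTargets <- function(evidence, gene = "WWOX", minTools = 2L) {
  ev <- evidence[toupper(evidence$target_gene) == toupper(gene), ]
  if (nrow(ev) == 0) return(structure(list(), names = character()))
  tools <- lapply(split(ev$tool, normalizeMirnaNames(ev$mirna)), unique)
  tools[vapply(tools, length, integer(1)) >= minTools]
}

#' Annotate candidate miRNAs from enrichment and prediction consensus
#'
#' Joins a (filtered) enrichment report with a target-prediction consensus
#' mapping: one annotation per miRNA that occurs in at least one retained
#' set, listing all retained sets containing it, whether it is a predicted
#' regulator of the consensus target gene, and the supporting tools.
#' With `baseNameMatch = TRUE` (default) the join also matches at the
#' miRNA base-name level ([mirnaBaseName()]), linking mature-arm
#' predictions such as `miR-182-5p` to the panel-level name
#' `hsa-mir-182`.
#'
#' Candidates are ordered by predicted-regulator status, then by the
#' number of enriched sets, then by name.
#'
#' @param report an [EnrichmentReport-class], normally filtered with
#'   [applyReportFilters()].
#' @param consensus named list from [consensusTargets()].
#' @param baseNameMatch match consensus miRNAs at base-name level.
#' @return data.frame with columns `mirna`, `enriched_sets`
#'   (semicolon-joined), `n_enriched_sets`, `predicted_regulator`,
#'   `supporting_tools` (semicolon-joined).
#' @export
annotateCandidates <- function(report, consensus, baseNameMatch = TRUE) {
  df <- report@results
  empty <- data.frame(mirna = character(), enriched_sets = character(),
                      n_enriched_sets = integer(),
                      predicted_regulator = logical(),
                      supporting_tools = character(),
                      stringsAsFactors = FALSE)
  if (nrow(df) == 0) return(empty)
  memb <- as.list(df$members)
  names(memb) <- df$set_name
  long <- data.frame(mirna = unlist(memb, use.names = FALSE),
                     set_name = rep(names(memb),
                                    lengths(memb)),
                     stringsAsFactors = FALSE)
  bySet <- split(long$set_name, long$mirna)
  consNames <- names(consensus)
  consBase <- mirnaBaseName(consNames)
  out <- lapply(names(bySet), function(m) {
    hit <- which(consNames == m)
    if (!length(hit) && baseNameMatch)
      hit <- which(consBase == mirnaBaseName(m))
    toolSet <- unique(unlist(consensus[hit], use.names = FALSE))
    ## ";"-joined because set names may themselves contain commas
    data.frame(mirna = m,
               enriched_sets = paste(unique(bySet[[m]]), collapse = ";"),
               n_enriched_sets = length(unique(bySet[[m]])),
               predicted_regulator = length(toolSet) > 0,
               supporting_tools = paste(toolSet, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out <- out[order(-out$predicted_regulator, -out$n_enriched_sets,
                   out$mirna), ]
  rownames(out) <- NULL
  out
}

#' @rdname annotateCandidates
#' @param candidates candidate table from `annotateCandidates()`.
#' @param path file path for the tab-separated candidate table.
#' @export
writeCandidateTable <- function(candidates, path) {
  utils::write.table(candidates, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
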