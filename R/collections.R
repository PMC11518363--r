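## GMT dialect: tab-separated "set name <TAB> description <TAB> members...".
## The description field carries the set category, optionally followed by
## "|tsi=<value>" for tissue sets and "|src=<tag>" for provenance.

.parseGmtDesc <- function(desc) {
  parts <- strsplit(desc, "|", fixed = TRUE)[[1]]
  out <- list(category = trimws(parts[1]), tsi = NA_real_, src = "")
  for (p in parts[-1]) {
    kv <- strsplit(p, "=", fixed = TRUE)[[1]]
    if (length(kv) == 2 && kv[1] == "tsi") out$tsi <- as.numeric(kv[2])
    if (length(kv) == 2 && kv[1] == "src") out$src <- kv[2]
  }
  out
}

#' Read a miRNA set collection from a GMT file
#'
#' Parses a GMT-style file (tab-separated: set name, description, member
#' miRNAs).  The description field carries the set category (one of target,
#' regulator, cluster, family, tissue, function), optionally followed by
#' `|tsi=<index>` for tissue sets and `|src=<tag>` for provenance.  Member
#' names are normalized with [normalizeMirnaNames()], so e.g.
#' `hsa-miR-182` and `hsa-mir-182` collapse to the same member.
#' Malformed lines (fewer than three fields or an unknown category) are
#' skipped with a warning reporting their line numbers.
#'
#' @param path GMT file path.
#' @return a [MirnaSetCollection-class].
#' @export
#' @examples
#' gmt <- system.file("extdata", "misea_sets.gmt", package = "qpcrSEA")
#' readGmt(gmt)
readGmt <- function(path) {
  .assert(file.exists(path), "GMT file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("empty GMT file: ", path, call. = FALSE)
  sets <- list()
  bad <- integer()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    f <- f[nzchar(trimws(f))]
    if (length(f) < 3) { bad <- c(bad, i); next }
    d <- .parseGmtDesc(f[2])
    if (!d$category %in% .SET_CATEGORIES) { bad <- c(bad, i); next }
    sets[[length(sets) + 1L]] <-
      MirnaSet(name = trimws(f[1]), category = d$category,
               members = f[-(1:2)],
               provenance = if (nzchar(d$src)) d$src else path,
               tsi = d$tsi)
  }
  if (length(bad))
    warning("skipped ", length(bad), " malformed GMT line(s): ",
            paste(bad, collapse = ", "))
  if (length(sets) == 0)
    stop("no valid sets in GMT file: ", path, call. = FALSE)
  key <- paste(vapply(sets, category, character(1)),
               vapply(sets, function(s) s@name, character(1)), sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate set name within a category in ", path, call. = FALSE)
  MirnaSetCollection(sets)
}

#' @rdname readGmt
#' @param collection a [MirnaSetCollection-class] to write.
#' @export
writeGmt <- function(collection, path) {
  lines <- vapply(collection@sets, function(s) {
    desc <- s@category
    if (!is.na(s@tsi)) desc <- paste0(desc, "|tsi=", s@tsi)
    if (nzchar(s@provenance)) desc <- paste0(desc, "|src=", s@provenance)
    paste(c(s@name, desc, s@members), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Filter tissue sets by tissue-specificity index
#'
#' Removes tissue-category sets whose tissue-specificity index is below
#' `minIndex` (the threshold is inclusive: an index equal to `minIndex` is
#' retained).  Sets of other categories are untouched.  A tissue set
#' without an index is a validation error.
#'
#' @param collection a [MirnaSetCollection-class].
#' @param minIndex minimum tissue-specificity index in \[0, 1\].
#' @return the filtered collection.
#' @export
filterTissueSets <- function(collection, minIndex = 0.7) {
  keep <- vapply(collection@sets, function(s) {
    if (s@category != "tissue") return(TRUE)
    if (is.na(s@tsi))
      stop("tissue set '", s@name, "' has no tissue-specificity index",
           call. = FALSE)
    s@tsi >= minIndex
  }, logical(1))
  MirnaSetCollection(collection@sets[keep])
}

#' Restrict a collection to a ranked universe
#'
#' Intersects every set's members with the miRNAs present in a ranked
#' list (the enrichment universe) and drops sets left with fewer than
#' `minSize` members, reporting the dropped sets with a message.  Required
#' for a well-defined running-sum statistic.
#'
#' @param collection a [MirnaSetCollection-class].
#' @param ranked a [RankedList-class] defining the universe.
#' @param minSize minimum post-intersection set size.
#' @return the restricted collection.
#' @export
restrictToUniverse <- function(collection, ranked, minSize = 2L) {
  universe <- rankedNames(ranked)
  out <- list()
  dropped <- character()
  for (s in collection@sets) {
    mem <- intersect(s@members, universe)
    if (length(mem) < minSize) {
      dropped <- c(dropped, s@name)
    } else {
      out[[length(out) + 1L]] <-
        new("MirnaSet", name = s@name, category = s@category, members = mem,
            provenance = s@provenance, tsi = s@tsi)
    }
  }
  if (length(dropped))
    message("dropped ", length(dropped), " set(s) below minimum size ",
            minSize, " after universe restriction: ",
            paste(dropped, collapse = ", "))
  MirnaSetCollection(out)
}
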