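#' Normalize miRNA names to canonical form
#'
#' Lower-cases names, maps the `miR`/`MIR` spellings to `mir`, converts
#' underscores to hyphens and prepends the `hsa-` species prefix when a name
#' starts with `mir-` or `let-`.  Arm suffixes (`-5p`/`-3p`) and letter
#' variants (`-34a`) are preserved.
#'
#' @param x character vector of miRNA names.
#' @return character vector of canonical names, e.g. `"hsa-miR-182"` and
#'   `"hsa-mir-182"` both become `"hsa-mir-182"`.
#' @export
#' @examples
#' normalizeMirnaNames(c("hsa-miR-182", "miR-182-5p", "LET-7d"))
normalizeMirnaNames <- function(x) {
  x <- tolower(trimws(as.character(x)))
  x <- gsub("_", "-", x, fixed = TRUE)
  pre <- grepl("^(mir|let)-", x)
  x[pre] <- paste0("hsa-", x[pre])
  x
}

#' Base name of a miRNA (family-level identifier)
#'
#' Strips the arm suffix (`-5p`/`-3p`) and any trailing letter variant after
#' the numeric id, so that e.g. `hsa-mir-182-5p`, `hsa-mir-182` and
#' `hsa-mir-449a-5p` reduce to `hsa-mir-182`, `hsa-mir-182` and
#' `hsa-mir-449`.  Used by [annotateCandidates()] to join set membership
#' (mature-agnostic names) with target-prediction evidence (mature names).
#'
#' @param x character vector of miRNA names (normalized first).
#' @return character vector of base names.
#' @export
#' @examples
#' mirnaBaseName(c("miR-182-5p", "hsa-mir-449c-5p", "hsa-let-7d"))
mirnaBaseName <- function(x) {
  x <- normalizeMirnaNames(x)
  x <- sub("-(3p|5p)$", "", x)
  sub("(-[0-9]+)[a-z]+$", "\\1", x)
}

## Evaluate expr with a temporary RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

## stopifnot-with-message helper used across modules
.assert <- function(cond, ...) if (!isTRUE(cond)) stop(..., call. = FALSE)
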