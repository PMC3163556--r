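# Comparison of the structure-derived and expression-derived enrichment arms.

#' Compare two enrichment arms for one drug
#'
#' Both arguments are enrichment tables from \code{\link{enrichSet}} over the
#' same ontology. The report gives the top-k category overlap and its Jaccard
#' index, the Spearman correlation of ranks over categories present in both
#' lists (with the shared count, since the correlation is meaningless without
#' it), and the categories significant in both arms after adjustment.
#'
#' @param structureArm,expressionArm data.frames from \code{\link{enrichSet}}.
#' @param k top-k list size (default 10, the conventional short-list length).
#' @param sigAlpha adjusted-p threshold defining "significant in an arm"
#'   (default 0.05).
#' @param drugId drug identifier carried into the report.
#' @return a \linkS4class{ConcordanceReport}.
#' @export
compareArms <- function(structureArm, expressionArm, k = 10L,
                        sigAlpha = 0.05, drugId = "drug") {
  for (arm in list(structureArm, expressionArm))
    stopifnot(is.data.frame(arm),
              all(c("category", "p_value", "p_adjusted", "rank") %in% names(arm)))
  ontS <- attr(structureArm, "ontology"); ontE <- attr(expressionArm, "ontology")
  if (!is.null(ontS) && !is.null(ontE) && !identical(ontS, ontE))
    stop(sprintf("enrichment arms are over different ontologies ('%s' vs '%s')",
                 ontS, ontE), call. = FALSE)
  k <- as.integer(k)
  topS <- structureArm$category[structureArm$rank <= k]
  topE <- expressionArm$category[expressionArm$rank <= k]
  uni <- union(topS, topE)
  inter <- intersect(topS, topE)
  jac <- if (!length(uni)) 0 else length(inter) / length(uni)

  shared <- intersect(structureArm$category, expressionArm$category)
  rc <- NA_real_
  if (length(shared) >= 2L) {
    rs <- structureArm$rank[match(shared, structureArm$category)]
    re <- expressionArm$rank[match(shared, expressionArm$category)]
    rc <- suppressWarnings(stats::cor(rs, re, method = "spearman"))
  }
  sigS <- structureArm$category[structureArm$p_adjusted < sigAlpha]
  sigE <- expressionArm$category[expressionArm$p_adjusted < sigAlpha]

  new("ConcordanceReport", drugId = drugId,
      ontologyName = if (!is.null(ontS)) ontS else NA_character_,
      k = k, topStructure = topS, topExpression = topE,
      overlapCount = length(inter), jaccardTopk = jac,
      sharedCount = length(shared), rankCorrelation = rc,
      sharedSignificant = sort(intersect(sigS, sigE)))
}

#' @describeIn compareArms one-row data.frame summary of a report.
#' @param report a \linkS4class{ConcordanceReport}.
#' @export
concordanceSummary <- function(report) {
  stopifnot(is(report, "ConcordanceReport"))
  data.frame(
    drug = report@drugId, ontology = report@ontologyName, k = report@k,
    overlap_count = report@overlapCount, jaccard_topk = report@jaccardTopk,
    shared_count = report@sharedCount,
    rank_correlation = report@rankCorrelation,
    shared_significant = paste(report@sharedSignificant, collapse = "|"),
    stringsAsFactors = FALSE)
}

#' @describeIn compareArms shared-significant category accessor.
#' @export
sharedSignificant <- function(report) {
  stopifnot(is(report, "ConcordanceReport"))
  report@sharedSignificant
}

setMethod("show", "ConcordanceReport", function(object) {
  cat(sprintf(paste0("ConcordanceReport '%s' over '%s'\n",
                     "  top-%d overlap: %d (Jaccard %.3f)\n",
                     "  rank correlation over %d shared: %.3f\n",
                     "  shared significant: %s\n"),
              object@drugId, object@ontologyName, object@k,
              object@overlapCount, object@jaccardTopk, object@sharedCount,
              object@rankCorrelation,
              if (length(object@sharedSignificant))
                paste(object@sharedSignificant, collapse = ", ") else "(none)"))
})
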