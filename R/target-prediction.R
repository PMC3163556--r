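# The structure arm: Tanimoto similarity search, possible-target collection,
# first-neighbor network expansion, and the k-way common/similar/unique
# partition.

#' Tanimoto similarity search against the compound database
#'
#' Scores every database compound against every query fingerprint (the parent
#' drug and all of its predicted metabolites) and retains compounds whose
#' best Tanimoto similarity reaches the threshold. A database compound
#' similar to several queries is reported once, at its maximum similarity.
#'
#' @param queries named list of \linkS4class{Fingerprint}s (names are query
#'   ids; typically the parent and its metabolites).
#' @param db a \linkS4class{CompoundDb}.
#' @param threshold retention threshold in \code{(0, 1]}; default 0.7, the
#'   conventional cut for fragment-fingerprint similarity searching.
#' @return data.frame (\code{query_id}, \code{db_compound_id},
#'   \code{similarity}) sorted by similarity descending, ties broken by
#'   compound id.
#' @export
similaritySearch <- function(queries, db, threshold = 0.7) {
  stopifnot(is(db, "CompoundDb"))
  if (!length(queries)) stop("no query fingerprints", call. = FALSE)
  if (!compoundCount(db)) stop("empty compound database", call. = FALSE)
  if (!is.numeric(threshold) || threshold <= 0 || threshold > 1)
    stop("threshold must be in (0, 1]", call. = FALSE)
  if (is.null(names(queries)) || any(!nzchar(names(queries))))
    stop("queries must be named", call. = FALSE)

  fps <- db@fingerprints
  best <- data.frame(query_id = character(), db_compound_id = character(),
                     similarity = numeric(), stringsAsFactors = FALSE)
  for (cid in names(fps)) {
    sims <- vapply(queries, tanimoto, 0, b = fps[[cid]])
    j <- which.max(sims)
    if (sims[j] >= threshold) {
      best <- rbind(best, data.frame(
        query_id = names(queries)[j], db_compound_id = cid,
        similarity = unname(sims[j]), stringsAsFactors = FALSE))
    }
  }
  best[order(-best$similarity, best$db_compound_id), , drop = FALSE] ->
    best
  rownames(best) <- NULL
  best
}

#' Collect possible targets from similarity hits
#'
#' The union, over all hit compounds, of their annotated protein targets.
#' Provenance records every contributing (compound, similarity) pair.
#'
#' @param hits data.frame from \code{\link{similaritySearch}}.
#' @param db a \linkS4class{CompoundDb} (source of the interaction table).
#' @param drugId the query drug's identifier.
#' @return a \linkS4class{TargetSet} with \code{stage = "possible"}.
#' @export
collectPossibleTargets <- function(hits, db, drugId) {
  stopifnot(is(db, "CompoundDb"))
  ia <- db@interactions
  joined <- merge(hits, ia, by.x = "db_compound_id", by.y = "compound_id")
  if (nrow(joined)) {
    prov <- data.frame(protein_id = joined$protein_id,
                       source = joined$db_compound_id,
                       detail = sprintf("similarity=%.6f", joined$similarity),
                       stringsAsFactors = FALSE)
    prov <- prov[order(prov$protein_id, prov$source), , drop = FALSE]
    rownames(prov) <- NULL
    members <- sort(unique(joined$protein_id))
  } else {
    prov <- data.frame(protein_id = character(), source = character(),
                       detail = character(), stringsAsFactors = FALSE)
    members <- character()
  }
  new("TargetSet", drugId = drugId, stage = "possible", members = members,
      provenance = prov)
}

#' Expand a target set by its first network neighbors
#'
#' Adds every protein adjacent in the interaction graph to a current member
#' ("first-step" expansion). Seeds are retained; proteins absent from the
#' graph pass through unchanged. \code{hops > 1} repeats the expansion.
#'
#' @param tset a \linkS4class{TargetSet} with \code{stage = "possible"}.
#' @param graph an undirected \code{igraph} protein interaction graph.
#' @param hops number of expansion steps (default 1).
#' @return a \linkS4class{TargetSet} with \code{stage = "expanded"};
#'   always a superset of the input members.
#' @export
expandByNeighbors <- function(tset, graph, hops = 1L) {
  stopifnot(is(tset, "TargetSet"))
  if (tset@stage != "possible")
    stop("expansion starts from a 'possible' target set", call. = FALSE)
  vs <- igraph::V(graph)$name
  members <- tset@members
  prov <- tset@provenance
  for (h in seq_len(max(1L, as.integer(hops)))) {
    seeds <- intersect(members, vs)
    if (!length(seeds)) break
    nb <- unique(unlist(lapply(seeds, function(s)
      igraph::neighbors(graph, s)$name)))
    added <- setdiff(nb, members)
    if (length(added)) {
      src <- vapply(added, function(a) {
        cand <- intersect(igraph::neighbors(graph, a)$name, seeds)
        sort(cand)[1L]
      }, "")
      prov <- rbind(prov, data.frame(
        protein_id = added, source = src,
        detail = sprintf("neighbor-of;hop=%d", h), stringsAsFactors = FALSE))
    }
    members <- sort(union(members, nb))
  }
  prov <- prov[order(prov$protein_id, prov$source), , drop = FALSE]
  rownames(prov) <- NULL
  new("TargetSet", drugId = tset@drugId, stage = "expanded",
      members = members, provenance = prov)
}

#' @describeIn expandByNeighbors member accessor.
#' @export
targetMembers <- function(tset) {
  stopifnot(is(tset, "TargetSet"))
  tset@members
}

#' @describeIn expandByNeighbors provenance accessor.
#' @export
targetProvenance <- function(tset) {
  stopifnot(is(tset, "TargetSet"))
  tset@provenance
}

setMethod("show", "TargetSet", function(object) {
  cat(sprintf("TargetSet '%s' (%s): %d proteins\n",
              object@drugId, object@stage, length(object@members)))
})

#' Partition k named sets into common / similar / unique classes
#'
#' Classifies every element of the union by its membership pattern: in all k
#' sets (common), in exactly one pair of sets (similar), in exactly one set
#' (unique). For k >= 4, elements of at least three but not all sets go to a
#' \code{multi} class keyed by their membership signature. Classes are
#' mutually disjoint and cover the union.
#'
#' @param sets named list (k >= 2) of character vectors.
#' @return a \linkS4class{TargetPartition}.
#' @examples
#' p <- partitionSets(list(A = c("1", "2", "3", "4"), B = c("3", "4", "5"),
#'                         C = c("4", "5", "6")))
#' partitionCommon(p)   # "4"
#' @export
partitionSets <- function(sets) {
  if (length(sets) < 2L) stop("need at least two sets", call. = FALSE)
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    stop("sets must be named", call. = FALSE)
  if (anyDuplicated(names(sets)))
    stop("duplicate set name(s): ",
         paste(unique(names(sets)[duplicated(names(sets))]), collapse = ", "),
         call. = FALSE)
  k <- length(sets)
  drugs <- names(sets)
  sets <- lapply(sets, function(s) unique(as.character(s)))

  elems <- sort(unique(unlist(sets)))
  membership <- vapply(sets, function(s) elems %in% s,
                       logical(length(elems)))
  if (length(elems) == 1L) membership <- matrix(membership, nrow = 1L,
                                                dimnames = list(NULL, drugs))
  counts <- if (length(elems)) rowSums(membership) else integer()

  pairs <- utils::combn(drugs, 2L, simplify = FALSE)
  pairKey <- function(p) paste(sort(p), collapse = "|")
  similar <- stats::setNames(vector("list", length(pairs)),
                             vapply(pairs, pairKey, ""))
  for (i in seq_along(similar)) similar[[i]] <- character()
  uniq <- stats::setNames(replicate(k, character(), simplify = FALSE), drugs)
  common <- character()
  multi <- list()

  for (i in seq_along(elems)) {
    inset <- drugs[membership[i, ]]
    nc <- length(inset)
    if (nc == k) common <- c(common, elems[i])
    else if (nc == 1L) uniq[[inset]] <- c(uniq[[inset]], elems[i])
    else if (nc == 2L) {
      key <- pairKey(inset)
      similar[[key]] <- c(similar[[key]], elems[i])
    } else {
      key <- paste(sort(inset), collapse = "|")
      multi[[key]] <- c(multi[[key]], elems[i])
    }
  }
  new("TargetPartition", drugs = drugs, common = common, similar = similar,
      uniqueSets = uniq, multi = multi)
}

#' @describeIn partitionSets members common to all sets.
#' @param p a \linkS4class{TargetPartition}.
#' @export
partitionCommon <- function(p) p@common

#' @describeIn partitionSets named list of exact-pair classes.
#' @export
partitionSimilar <- function(p) p@similar

#' @describeIn partitionSets named list of single-set classes.
#' @export
partitionUnique <- function(p) p@uniqueSets

#' @describeIn partitionSets per-class size summary as a data.frame.
#' @export
partitionSummary <- function(p) {
  data.frame(
    class = c("common", paste0("similar:", names(p@similar)),
              paste0("unique:", p@drugs),
              if (length(p@multi)) paste0("multi:", names(p@multi))),
    size = c(length(p@common), vapply(p@similar, length, 0L),
             vapply(p@uniqueSets[p@drugs], length, 0L),
             if (length(p@multi)) vapply(p@multi, length, 0L)),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' @describeIn partitionSets long-format table (\code{protein_id},
#'   \code{class}, \code{drugs}).
#' @export
partitionTable <- function(p) {
  block <- function(ids, cls, who) data.frame(
    protein_id = ids, class = rep(cls, length(ids)),
    drugs = rep(who, length(ids)), stringsAsFactors = FALSE)
  rows <- list(block(p@common, "common", paste(p@drugs, collapse = "|")))
  for (nm in names(p@similar))
    rows[[length(rows) + 1L]] <- block(p@similar[[nm]], "similar", nm)
  for (nm in names(p@uniqueSets))
    rows[[length(rows) + 1L]] <- block(p@uniqueSets[[nm]], "unique", nm)
  for (nm in names(p@multi))
    rows[[length(rows) + 1L]] <- block(p@multi[[nm]], "multi", nm)
  out <- do.call(rbind, rows)
  out <- out[order(out$class, out$drugs, out$protein_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

setMethod("show", "TargetPartition", function(object) {
  cat(sprintf("TargetPartition over %d sets (%s)\n", length(object@drugs),
              paste(object@drugs, collapse = ", ")))
  print(partitionSummary(object))
})
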