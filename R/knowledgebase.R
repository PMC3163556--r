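# Loaders for the compound--target knowledge base, the protein interaction
# graph and gene-set ontologies. All loaders sort canonically so in-memory
# content is independent of input row order.

#' Load the compound--target knowledge base
#'
#' Reads a structure file (.smi: one \code{SMILES<TAB>id} per line) and a
#' TSV interaction table (\code{compound_id}, \code{protein_id},
#' \code{effect}, \code{directness}), computes a fingerprint for every
#' compound and enforces referential integrity.
#'
#' @param structuresPath .smi file of database compounds.
#' @param interactionsPath TSV of compound-to-protein interactions.
#' @param maxLength,nbits fingerprint parameters
#'   (see \code{\link{computeFingerprint}}).
#' @param idMap optional 2-column TSV translating foreign protein ids to the
#'   canonical symbol space; unmapped ids are dropped with a message.
#' @return a \linkS4class{CompoundDb}.
#' @export
loadCompoundDb <- function(structuresPath, interactionsPath,
                           maxLength = 7L, nbits = 1024L, idMap = NULL) {
  cmp <- readSmilesFile(structuresPath)
  if (anyDuplicated(cmp$compound_id))
    stop("duplicate compound_id in ", structuresPath, ": ",
         paste(unique(cmp$compound_id[duplicated(cmp$compound_id)]),
               collapse = ", "), call. = FALSE)
  ia <- utils::read.delim(interactionsPath, stringsAsFactors = FALSE)
  need <- c("compound_id", "protein_id", "effect", "directness")
  miss <- setdiff(need, names(ia))
  if (length(miss))
    stop("interaction table lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  unknown <- setdiff(ia$compound_id, cmp$compound_id)
  if (length(unknown))
    stop("interactions reference unknown compounds: ",
         paste(sort(unknown), collapse = ", "), call. = FALSE)
  if (!is.null(idMap)) {
    map <- utils::read.delim(idMap, stringsAsFactors = FALSE)
    if (ncol(map) < 2L) stop("id map must have two columns", call. = FALSE)
    hit <- match(ia$protein_id, map[[1]])
    dropped <- sum(is.na(hit))
    if (dropped) message(dropped, " interaction row(s) with unmapped protein ids dropped")
    ia <- ia[!is.na(hit), , drop = FALSE]
    ia$protein_id <- map[[2]][hit[!is.na(hit)]]
  }

  cmp <- cmp[order(cmp$compound_id), , drop = FALSE]
  rownames(cmp) <- NULL
  mols <- lapply(seq_len(nrow(cmp)), function(i)
    parseStructure(cmp$compound_id[i], cmp$smiles[i]))
  cmp$canonical <- vapply(mols, canonicalForm, "")
  fps <- lapply(mols, computeFingerprint, maxLength = maxLength, nbits = nbits)
  names(fps) <- cmp$compound_id

  ia <- ia[order(ia$compound_id, ia$protein_id, ia$effect, ia$directness), ,
           drop = FALSE]
  ia <- unique(ia[, need])
  rownames(ia) <- NULL

  message(sprintf("loaded %d compounds, %d interactions (%d proteins)",
                  nrow(cmp), nrow(ia), length(unique(ia$protein_id))))
  new("CompoundDb", compounds = cmp[, c("compound_id", "smiles", "canonical")],
      fingerprints = fps, interactions = ia)
}

#' @describeIn loadCompoundDb read a .smi file
#'   (\code{SMILES<TAB>id} per line) into a data.frame.
#' @export
readSmilesFile <- function(structuresPath) {
  lines <- readLines(structuresPath)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty structure file: ", structuresPath, call. = FALSE)
  parts <- strsplit(lines, "[\t ]+")
  bad <- which(vapply(parts, length, 0L) < 2L)
  if (length(bad))
    stop("malformed .smi line(s) (need 'SMILES<TAB>id'): ",
         paste(bad, collapse = ", "), call. = FALSE)
  data.frame(compound_id = vapply(parts, `[`, "", 2L),
             smiles = vapply(parts, `[`, "", 1L), stringsAsFactors = FALSE)
}

#' @describeIn loadCompoundDb number of compounds.
#' @param db a \linkS4class{CompoundDb}.
#' @export
compoundCount <- function(db) nrow(db@compounds)

#' @describeIn loadCompoundDb interaction table accessor.
#' @export
compoundInteractions <- function(db) db@interactions

#' @describeIn loadCompoundDb compound table accessor.
#' @export
compoundTable <- function(db) db@compounds

#' @describeIn loadCompoundDb fingerprint list accessor.
#' @export
compoundFingerprints <- function(db) db@fingerprints

setMethod("show", "CompoundDb", function(object) {
  cat(sprintf("CompoundDb: %d compounds, %d interactions, %d target proteins\n",
              nrow(object@compounds), nrow(object@interactions),
              length(unique(object@interactions$protein_id))))
})

#' Load a protein--protein interaction graph
#'
#' Reads a TSV/SIF edge list (first two whitespace-separated columns are the
#' endpoints; a middle relation column in 3-column SIF files is ignored),
#' drops self-loops with a warning count and deduplicates undirected edges.
#'
#' @param edgesPath edge-list file.
#' @return an undirected simple \code{igraph} graph.
#' @export
loadInteractionGraph <- function(edgesPath) {
  lines <- readLines(edgesPath)
  keep <- nzchar(trimws(lines))
  parts <- strsplit(trimws(lines[keep]), "[\t ]+")
  nf <- vapply(parts, length, 0L)
  bad <- which(nf < 2L)
  if (length(bad))
    stop("malformed edge line(s) at ", edgesPath, ": line ",
         paste(which(keep)[bad], collapse = ", "), call. = FALSE)
  from <- vapply(parts, `[`, "", 1L)
  to <- vapply(parts, function(p) p[length(p)], "")
  loops <- from == to
  if (any(loops))
    warning(sum(loops), " self-loop(s) dropped", call. = FALSE)
  el <- cbind(from[!loops], to[!loops])
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
}

#' Load a gene-set ontology from GMT
#'
#' GMT: one category per line, \code{name<TAB>description<TAB>member...}.
#' The universe defaults to the union of all members unless an explicit
#' universe is supplied.
#'
#' @param gmtPath GMT file.
#' @param name ontology name (default: file base name).
#' @param universe optional explicit identifier universe.
#' @return an \linkS4class{Ontology}.
#' @export
loadOntology <- function(gmtPath, name = NULL, universe = NULL) {
  if (is.null(name))
    name <- sub("\\.gmt$", "", basename(gmtPath))
  if (!file.size(gmtPath) > 0)
    stop("empty GMT file: ", gmtPath, call. = FALSE)
  cats <- fgsea::gmtPathways(gmtPath)
  if (!length(cats)) stop("no categories in ", gmtPath, call. = FALSE)
  if (anyDuplicated(names(cats)))
    stop("duplicate category name(s) in ", gmtPath, ": ",
         paste(unique(names(cats)[duplicated(names(cats))]), collapse = ", "),
         call. = FALSE)
  empty <- names(cats)[vapply(cats, length, 0L) == 0L]
  if (length(empty))
    stop("empty category in ", gmtPath, ": ", paste(empty, collapse = ", "),
         call. = FALSE)
  cats <- lapply(cats, function(x) sort(unique(x)))
  cats <- cats[order(names(cats))]
  members <- sort(unique(unlist(cats)))
  if (is.null(universe)) universe <- members
  else {
    universe <- sort(unique(universe))
    outside <- setdiff(members, universe)
    if (length(outside))
      stop(length(outside), " category member(s) outside the supplied universe",
           call. = FALSE)
  }
  new("Ontology", name = name, categories = cats, universe = universe)
}

#' Write an ontology to GMT
#'
#' @param ont an \linkS4class{Ontology}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeOntologyGmt <- function(ont, path) {
  stopifnot(is(ont, "Ontology"))
  lines <- vapply(names(ont@categories), function(nm)
    paste(c(nm, "na", ont@categories[[nm]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' @describeIn loadOntology category list accessor.
#' @param ont an \linkS4class{Ontology}.
#' @export
ontologyCategories <- function(ont) ont@categories

#' @describeIn loadOntology universe accessor.
#' @export
ontologyUniverse <- function(ont) ont@universe

setMethod("show", "Ontology", function(object) {
  cat(sprintf("Ontology '%s': %d categories over %d identifiers\n",
              object@name, length(object@categories), length(object@universe)))
})
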