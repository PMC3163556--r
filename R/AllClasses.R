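#' @import methods
NULL

#' Molecule: a parsed small-molecule structure
#'
#' Holds a validated structure together with its OpenBabel-canonical SMILES
#' and the internal heavy-atom graph. Metabolites carry the id of the parent
#' molecule and the name of the metabolic rule that produced them.
#'
#' @slot id compound identifier.
#' @slot smiles SMILES string as supplied.
#' @slot canonical canonical SMILES; equal for any atom-order permutation of
#'   the same structure.
#' @slot graph internal atom/bond graph (list with \code{atoms}, \code{bonds}).
#' @slot role \code{"parent"} or \code{"metabolite"}.
#' @slot parentId id of the parent molecule (metabolites only, else \code{NA}).
#' @slot ruleName metabolic rule that generated this metabolite (else \code{NA}).
#' @exportClass Molecule
setClass("Molecule", representation(
  id = "character", smiles = "character", canonical = "character",
  graph = "list", role = "character", parentId = "character",
  ruleName = "character"
))

setValidity("Molecule", function(object) {
  if (length(object@id) != 1L || !nzchar(object@id)) return("id must be a single non-empty string")
  if (!object@role %in% c("parent", "metabolite")) return("role must be 'parent' or 'metabolite'")
  if (object@role == "metabolite" && is.na(object@parentId))
    return("metabolite must record parentId")
  if (object@role == "parent" && !is.na(object@parentId))
    return("parent must not carry parentId")
  if (nrow(object@graph$atoms) < 1L) return("molecule must contain at least one heavy atom")
  TRUE
})

#' Fingerprint: hashed linear-fragment bit signature
#'
#' The set of on-bit positions of a fixed-length fragment fingerprint. Bits
#' are obtained by enumerating all linear heavy-atom paths up to a maximum
#' bond count and hashing each canonical path string into \code{[0, nbits)}.
#'
#' @slot bits sorted integer vector of on-bit positions in \code{[0, nbits)}.
#' @slot nbits fingerprint length in bits.
#' @slot descriptor string recording the fragment scheme and its parameters,
#'   so that similarity values are reproducible.
#' @exportClass Fingerprint
setClass("Fingerprint", representation(
  bits = "integer", nbits = "integer", descriptor = "character"
))

setValidity("Fingerprint", function(object) {
  if (length(object@nbits) != 1L || object@nbits < 1L) return("nbits must be a positive scalar")
  b <- object@bits
  if (anyNA(b)) return("bits must not contain NA")
  if (length(b) && (min(b) < 0L || max(b) >= object@nbits)) return("bit positions out of range")
  if (is.unsorted(b, strictly = TRUE)) return("bits must be strictly increasing")
  TRUE
})

#' CompoundDb: the compound--target knowledge base
#'
#' Compound structures with precomputed fingerprints plus the annotated
#' compound-to-protein interaction table.
#'
#' @slot compounds data.frame with columns \code{compound_id}, \code{smiles},
#'   \code{canonical}.
#' @slot fingerprints list of \linkS4class{Fingerprint}, parallel to
#'   \code{compounds}, named by compound id.
#' @slot interactions data.frame with columns \code{compound_id},
#'   \code{protein_id}, \code{effect}, \code{directness}.
#' @exportClass CompoundDb
setClass("CompoundDb", representation(
  compounds = "data.frame", fingerprints = "list", interactions = "data.frame"
))

setValidity("CompoundDb", function(object) {
  cmp <- object@compounds
  if (!all(c("compound_id", "smiles", "canonical") %in% names(cmp)))
    return("compounds must have compound_id, smiles, canonical")
  if (anyDuplicated(cmp$compound_id)) return("duplicate compound_id")
  if (!identical(names(object@fingerprints), cmp$compound_id))
    return("fingerprints must be named by compound_id in compound order")
  ia <- object@interactions
  if (!all(c("compound_id", "protein_id", "effect", "directness") %in% names(ia)))
    return("interactions must have compound_id, protein_id, effect, directness")
  bad <- setdiff(ia$compound_id, cmp$compound_id)
  if (length(bad)) return(paste("interactions reference unknown compounds:",
                                paste(bad, collapse = ", ")))
  if (!all(ia$effect %in% c("activation", "inhibition", "unspecified")))
    return("effect must be activation/inhibition/unspecified")
  if (!all(ia$directness %in% c("direct", "indirect")))
    return("directness must be direct/indirect")
  TRUE
})

#' Ontology: named gene-set collection
#'
#' @slot name ontology name (e.g. \code{"pathway-maps"}).
#' @slot categories named list of character vectors of member identifiers.
#' @slot universe all identifiers against which enrichment is assessed;
#'   defaults to the union of all category members.
#' @exportClass Ontology
setClass("Ontology", representation(
  name = "character", categories = "list", universe = "character"
))

setValidity("Ontology", function(object) {
  if (!length(object@categories)) return("ontology has no categories")
  if (is.null(names(object@categories)) || any(!nzchar(names(object@categories))))
    return("all categories must be named")
  if (anyDuplicated(names(object@categories))) return("duplicate category names")
  if (any(vapply(object@categories, length, 0L) == 0L)) return("empty category")
  extra <- setdiff(unique(unlist(object@categories)), object@universe)
  if (length(extra)) return("category members outside the universe")
  TRUE
})

#' TargetSet: proteins associated with one drug
#'
#' @slot drugId drug identifier.
#' @slot stage \code{"possible"} (collected from similarity hits) or
#'   \code{"expanded"} (after first-neighbor network expansion).
#' @slot members sorted character vector of protein ids.
#' @slot provenance data.frame (\code{protein_id}, \code{source},
#'   \code{detail}): for possible targets, the contributing database compound
#'   and its similarity; for expansion, the seed protein a neighbor came from.
#' @exportClass TargetSet
setClass("TargetSet", representation(
  drugId = "character", stage = "character", members = "character",
  provenance = "data.frame"
))

setValidity("TargetSet", function(object) {
  if (!object@stage %in% c("possible", "expanded")) return("stage must be possible/expanded")
  if (is.unsorted(object@members, strictly = TRUE)) return("members must be sorted and unique")
  TRUE
})

#' TargetPartition: common / similar / unique decomposition
#'
#' Mutually disjoint classes covering the union of k named sets: members of
#' all k sets (\code{common}), of exactly one pair (\code{similar}), of a
#' single set (\code{unique}), and -- for k >= 4 -- of at least three but not
#' all sets (\code{multi}).
#'
#' @slot drugs the k set names.
#' @slot common character vector.
#' @slot similar named list, one element per unordered pair \code{"a|b"}.
#' @slot uniqueSets named list, one element per drug.
#' @slot multi named list keyed by membership signature (k >= 4 only).
#' @exportClass TargetPartition
setClass("TargetPartition", representation(
  drugs = "character", common = "character", similar = "list",
  uniqueSets = "list", multi = "list"
))

setValidity("TargetPartition", function(object) {
  all_members <- c(object@common, unlist(object@similar),
                   unlist(object@uniqueSets), unlist(object@multi))
  if (anyDuplicated(all_members)) return("partition classes are not disjoint")
  TRUE
})

#' ConcordanceReport: structure-arm vs expression-arm comparison
#'
#' @slot drugId drug identifier.
#' @slot ontologyName ontology both arms were enriched against.
#' @slot k size of the top-k lists compared.
#' @slot topStructure,topExpression top-k category names per arm.
#' @slot overlapCount size of the intersection of the two top-k sets.
#' @slot jaccardTopk Jaccard index of the two top-k sets (0 when both empty).
#' @slot sharedCount number of categories present in both full lists.
#' @slot rankCorrelation Spearman correlation of ranks over shared categories.
#' @slot sharedSignificant categories significant (adjusted p below the run's
#'   alpha) in both arms.
#' @exportClass ConcordanceReport
setClass("ConcordanceReport", representation(
  drugId = "character", ontologyName = "character", k = "integer",
  topStructure = "character", topExpression = "character",
  overlapCount = "integer", jaccardTopk = "numeric", sharedCount = "integer",
  rankCorrelation = "numeric", sharedSignificant = "character"
))
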