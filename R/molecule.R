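# Structure parsing and Molecule accessors.

#' Parse a SMILES structure into a Molecule
#'
#' Validates the SMILES strictly, computes the canonical form, and stores the
#' heavy-atom graph parsed from that canonical form (so all downstream
#' computations are invariant to the input atom ordering).
#'
#' @param id compound identifier.
#' @param smiles SMILES string (non-empty).
#' @param role \code{"parent"} (default) or \code{"metabolite"}.
#' @param parentId parent molecule id, required when \code{role="metabolite"}.
#' @param ruleName name of the generating metabolic rule (metabolites).
#' @return a \linkS4class{Molecule}.
#' @examples
#' m <- parseStructure("ethanol", "CCO")
#' heavyAtomCount(m)   # 3
#' @export
parseStructure <- function(id, smiles, role = "parent",
                           parentId = NA_character_, ruleName = NA_character_) {
  if (!is.character(id) || length(id) != 1L || !nzchar(id))
    stop("'id' must be a single non-empty string", call. = FALSE)
  can <- tryCatch(canonicalSmiles(smiles), error = function(e)
    stop(sprintf("cannot parse structure '%s': %s", id, conditionMessage(e)),
         call. = FALSE))
  g <- parseSmilesGraph(can)
  new("Molecule", id = id, smiles = smiles, canonical = can, graph = g,
      role = role, parentId = parentId, ruleName = ruleName)
}

#' @describeIn parseStructure number of heavy (non-hydrogen) atoms.
#' @param m a \linkS4class{Molecule}.
#' @export
heavyAtomCount <- function(m) {
  stopifnot(is(m, "Molecule"))
  nrow(m@graph$atoms)
}

#' @describeIn parseStructure canonical SMILES accessor.
#' @export
canonicalForm <- function(m) {
  stopifnot(is(m, "Molecule"))
  m@canonical
}

#' @describeIn parseStructure molecule id accessor.
#' @export
moleculeId <- function(m) {
  stopifnot(is(m, "Molecule"))
  m@id
}

setMethod("show", "Molecule", function(object) {
  cat(sprintf("Molecule '%s' (%s%s)\n  %s\n  %d heavy atoms\n",
              object@id, object@role,
              if (!is.na(object@parentId)) paste0(" of ", object@parentId) else "",
              object@canonical, heavyAtomCount(object)))
})
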