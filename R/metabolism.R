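# Rule-based metabolite generation.
#
# A metabolic rule pairs a reactant substructure pattern (SMARTS subset) with
# a named graph transformation from an extensible registry. A general
# reaction-SMARTS interpreter is out of scope; the registry vocabulary covers
# the shipped phase-I rule set and users can register their own
# transformations or supply their own rule table.

.transformRegistry <- new.env(parent = emptyenv())

#' Register a metabolite transformation
#'
#' Adds (or replaces) a named transformation usable from rule tables. The
#' function receives the molecule graph and one pattern match (integer vector
#' of molecule atom indices, one per pattern atom) and must return a list of
#' product graphs.
#'
#' @param name transformation keyword used in rule tables.
#' @param fun function(graph, match) -> list of product graphs.
#' @return \code{name}, invisibly.
#' @export
registerTransformation <- function(name, fun) {
  stopifnot(is.character(name), length(name) == 1L, is.function(fun))
  assign(name, fun, envir = .transformRegistry)
  invisible(name)
}

#' @describeIn registerTransformation names of available transformations.
#' @export
listTransformations <- function() sort(ls(.transformRegistry))

# --- graph-edit helpers ------------------------------------------------------

.deleteBondBetween <- function(g, a, b) {
  keep <- !((g$bonds$from == a & g$bonds$to == b) |
              (g$bonds$from == b & g$bonds$to == a))
  g$bonds <- g$bonds[keep, , drop = FALSE]
  rownames(g$bonds) <- NULL
  g
}

.addHydroxyl <- function(g, at) {
  arow <- g$atoms[1L, , drop = FALSE]
  arow$element <- "O"; arow$aromatic <- FALSE; arow$charge <- 0L
  arow$hcount <- NA_integer_
  if ("conn" %in% names(arow)) arow$conn <- NA_integer_
  g$atoms <- rbind(g$atoms, arow)
  rownames(g$atoms) <- NULL
  brow <- data.frame(from = at, to = nrow(g$atoms), order = 1L,
                     aromatic = FALSE, stringsAsFactors = FALSE)
  for (extra in setdiff(names(g$bonds), names(brow))) brow[[extra]] <- FALSE
  g$bonds <- rbind(g$bonds, brow[, names(g$bonds), drop = FALSE])
  rownames(g$bonds) <- NULL
  g
}

.deleteAtoms <- function(g, idx) {
  keep <- setdiff(seq_len(nrow(g$atoms)), idx)
  .subgraph(g, keep)
}

# reset implicit-H bookkeeping on touched neutral organic atoms, then refresh
.refreshHydrogens <- function(g, touched) {
  touched <- touched[touched <= nrow(g$atoms)]
  for (i in touched) {
    if (g$atoms$element[i] %in% .ORGANIC_SUBSET && g$atoms$charge[i] == 0L)
      g$atoms$hcount[i] <- NA_integer_
  }
  g$atoms$hcount <- .implicitHydrogens(g)
  g
}

# keep the largest fragment by heavy-atom count (tie: fewer characters, then
# lexicographically smaller written SMILES) -- metabolite bookkeeping follows
# the drug-derived major fragment
.largestFragment <- function(g) {
  comps <- .components(g)
  if (length(comps) == 1L) return(g)
  subs <- lapply(comps, function(cm) .subgraph(g, cm))
  sizes <- vapply(subs, function(s) nrow(s$atoms), 0L)
  best <- which(sizes == max(sizes))
  if (length(best) > 1L) {
    smi <- vapply(subs[best], writeSmilesGraph, "")
    best <- best[order(nchar(smi), smi)][1L]
  } else best <- best[1L]
  subs[[best]]
}

# --- shipped transformations -------------------------------------------------
# pattern atom numbering refers to the reactant patterns in
# defaultMetabolicRules()

# [CX3](=O)[OX2][#6]: split the acyl C-O ester bond; acid keeps the pattern
# oxygen, the leaving alcohol gains a hydroxyl
.tfEsterHydrolysis <- function(g, m) {
  cacyl <- m[1L]; oester <- m[3L]; calkyl <- m[4L]
  g2 <- .deleteBondBetween(g, oester, calkyl)
  g2 <- .addHydroxyl(g2, calkyl)
  g2 <- .refreshHydrogens(g2, c(cacyl, oester, calkyl, nrow(g2$atoms)))
  list(.largestFragment(g2))
}

# [CX3](=O)[NX3][#6]: split the amide C-N bond; acid gains a hydroxyl on the
# carbonyl carbon, amine keeps the nitrogen
.tfAmideHydrolysis <- function(g, m) {
  cacyl <- m[1L]; nam <- m[3L]
  g2 <- .deleteBondBetween(g, cacyl, nam)
  g2 <- .addHydroxyl(g2, cacyl)
  g2 <- .refreshHydrogens(g2, c(cacyl, nam, nrow(g2$atoms)))
  list(.largestFragment(g2))
}

# [cH]: hydroxylate an unsubstituted aromatic carbon
.tfAromaticHydroxylation <- function(g, m) {
  g2 <- .addHydroxyl(g, m[1L])
  g2 <- .refreshHydrogens(g2, c(m[1L], nrow(g2$atoms)))
  list(g2)
}

# [#6][OX2][CH3]: remove the O-methyl carbon, leaving a hydroxyl
.tfODemethylation <- function(g, m) {
  g2 <- .deleteAtoms(g, m[3L])
  # renumbering: atoms after the deleted one shift down by one
  o <- m[2L] - (m[2L] > m[3L])
  g2 <- .refreshHydrogens(g2, o)
  list(.largestFragment(g2))
}

registerTransformation("ester_hydrolysis", .tfEsterHydrolysis)
registerTransformation("amide_hydrolysis", .tfAmideHydrolysis)
registerTransformation("aromatic_hydroxylation", .tfAromaticHydroxylation)
registerTransformation("O_demethylation", .tfODemethylation)

#' Default phase-I metabolic rule table
#'
#' A small, documented set of empirical biotransformation rules: ester
#' hydrolysis, amide hydrolysis, aromatic hydroxylation and O-demethylation.
#' Ester hydrolysis reproduces the fenofibrate to fenofibric acid conversion.
#' The table is user-replaceable via \code{\link{readMetabolicRules}}.
#'
#' @return data.frame with columns \code{name}, \code{phase},
#'   \code{reactant_pattern}, \code{transformation}, \code{max_applications}.
#' @export
defaultMetabolicRules <- function() {
  data.frame(
    name = c("ester_hydrolysis", "amide_hydrolysis",
             "aromatic_hydroxylation", "O_demethylation"),
    phase = "I",
    reactant_pattern = c("[CX3](=O)[OX2][#6]", "[CX3](=O)[NX3][#6]",
                         "[cH]", "[#6][OX2][CH3]"),
    transformation = c("ester_hydrolysis", "amide_hydrolysis",
                       "aromatic_hydroxylation", "O_demethylation"),
    max_applications = 1L,
    stringsAsFactors = FALSE
  )
}

#' Read a metabolic rule table from TSV
#'
#' Columns: \code{name}, \code{phase} (I or II), \code{reactant_pattern}
#' (SMARTS subset), \code{transformation} (registered keyword),
#' \code{max_applications} (>= 1). Every pattern is parsed and every
#' transformation resolved at load time.
#'
#' @param path TSV file path.
#' @return validated rule data.frame.
#' @export
readMetabolicRules <- function(path) {
  rules <- utils::read.delim(path, stringsAsFactors = FALSE)
  validateMetabolicRules(rules)
}

#' @describeIn readMetabolicRules validate an in-memory rule table.
#' @param rules rule data.frame.
#' @export
validateMetabolicRules <- function(rules) {
  need <- c("name", "phase", "reactant_pattern", "transformation",
            "max_applications")
  miss <- setdiff(need, names(rules))
  if (length(miss))
    stop("rule table lacks columns: ", paste(miss, collapse = ", "), call. = FALSE)
  if (anyDuplicated(rules$name)) stop("duplicate rule names", call. = FALSE)
  if (!all(rules$phase %in% c("I", "II")))
    stop("rule phase must be 'I' or 'II'", call. = FALSE)
  if (any(rules$max_applications < 1L))
    stop("max_applications must be >= 1", call. = FALSE)
  for (i in seq_len(nrow(rules))) {
    tryCatch(parseSmilesGraph(rules$reactant_pattern[i], pattern = TRUE),
             error = function(e) stop(sprintf(
               "rule '%s': reactant pattern does not parse: %s",
               rules$name[i], conditionMessage(e)), call. = FALSE))
    if (!exists(rules$transformation[i], envir = .transformRegistry))
      stop(sprintf("rule '%s': unknown transformation '%s'",
                   rules$name[i], rules$transformation[i]), call. = FALSE)
  }
  rules
}

#' Generate predicted metabolites for a parent molecule
#'
#' Applies each rule at every matching site of the parent (and, when
#' \code{max_applications > 1} for a rule, successively to that rule's own
#' products). With \code{depth > 1}, the whole rule set is re-applied to the
#' metabolites of the previous round. Products with the same canonical form
#' are collapsed; each metabolite records its parent id and generating rule.
#'
#' @param m parent \linkS4class{Molecule}.
#' @param rules rule data.frame (default \code{defaultMetabolicRules()}).
#' @param depth metabolism passes over the full rule set (default 1:
#'   no metabolites-of-metabolites).
#' @return list of \linkS4class{Molecule} objects with
#'   \code{role = "metabolite"}; empty when nothing matches.
#' @examples
#' ff <- parseStructure("FF", "CC(C)OC(=O)C(C)(C)Oc1ccc(cc1)C(=O)c1ccc(Cl)cc1")
#' mets <- generateMetabolites(ff, defaultMetabolicRules()[1, ])
#' canonicalForm(mets[[1]])  # fenofibric acid
#' @export
generateMetabolites <- function(m, rules = defaultMetabolicRules(), depth = 1L) {
  stopifnot(is(m, "Molecule"))
  if (m@role != "parent")
    stop("metabolites are generated from parent molecules only", call. = FALSE)
  rules <- validateMetabolicRules(rules)

  out <- list()          # canonical -> Molecule
  seen <- c(m@canonical)
  frontier <- list(m)
  for (pass in seq_len(max(1L, as.integer(depth)))) {
    nextFrontier <- list()
    for (mol in frontier) {
      for (ri in seq_len(nrow(rules))) {
        prods <- .applyRuleOnce(mol@graph, rules[ri, ])
        for (pgraph in prods) {
          smi <- writeSmilesGraph(pgraph)
          can <- tryCatch(canonicalSmiles(smi), error = function(e) stop(sprintf(
            "rule '%s' produced an unparsable product ('%s') from '%s'",
            rules$name[ri], smi, mol@id), call. = FALSE))
          if (can %in% seen) next
          seen <- c(seen, can)
          met <- parseStructure(
            id = sprintf("%s_%s_%d", m@id, rules$name[ri], length(out) + 1L),
            smiles = smi, role = "metabolite", parentId = m@id,
            ruleName = rules$name[ri])
          out[[can]] <- met
          nextFrontier[[length(nextFrontier) + 1L]] <- met
        }
      }
    }
    frontier <- nextFrontier
    if (!length(frontier)) break
  }
  unname(out)
}

# single-round application of one rule: one product per matching site, plus
# repeated application up to max_applications on that rule's own products
.applyRuleOnce <- function(g, rule) {
  pg <- parseSmilesGraph(rule$reactant_pattern, pattern = TRUE)
  tf <- get(rule$transformation, envir = .transformRegistry)
  worklist <- list(g)
  products <- list()
  for (round in seq_len(rule$max_applications)) {
    newprods <- list()
    for (wg in worklist) {
      for (mt in matchSubstructure(wg, pg)) {
        for (p in tf(wg, mt)) newprods[[length(newprods) + 1L]] <- p
      }
    }
    if (!length(newprods)) break
    products <- c(products, newprods)
    worklist <- newprods
  }
  products
}
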