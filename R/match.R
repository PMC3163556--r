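# Substructure matching of a SMARTS-subset pattern graph against a molecule
# graph (backtracking, injective on atoms; non-induced, as in SMARTS).
#
# Supported pattern primitives: element symbols (case = aromaticity), [#n]
# (element, any aromaticity), *, Hn (hydrogen count), Xn (connection count),
# charges, bond symbols - = # : and ~ (any order).

.heavyDegree <- function(g) {
  n <- nrow(g$atoms)
  d <- integer(n)
  if (nrow(g$bonds)) {
    tf <- tabulate(g$bonds$from, n); tt <- tabulate(g$bonds$to, n)
    d <- tf + tt
  }
  d
}

.atomCompatible <- function(pa, ma, mdeg, mh) {
  if (pa$element != "*" && pa$element != ma$element) return(FALSE)
  if (!is.na(pa$aromatic) && pa$aromatic != ma$aromatic) return(FALSE)
  if (!is.na(pa$hcount) && pa$hcount != mh) return(FALSE)
  if (!is.na(pa$conn) && pa$conn != mdeg + mh) return(FALSE)
  if (pa$charge != 0L && pa$charge != ma$charge) return(FALSE)
  TRUE
}

.bondCompatible <- function(pb, mb) {
  if (isTRUE(pb$anyorder)) return(TRUE)
  if (pb$aromatic) return(mb$aromatic)
  if (pb$order == 1L) return(mb$order == 1L)   # single also matches exocyclic
  !mb$aromatic && pb$order == mb$order
}

#' Find all substructure matches of a pattern in a molecule graph
#'
#' @param g molecule graph (from \code{parseSmilesGraph}).
#' @param pg pattern graph (from \code{parseSmilesGraph(pattern = TRUE)});
#'   must be connected.
#' @return list of integer vectors; element i of a match is the molecule atom
#'   bound to pattern atom i.
#' @keywords internal
matchSubstructure <- function(g, pg) {
  np <- nrow(pg$atoms); nm <- nrow(g$atoms)
  if (np == 0L || np > nm) return(list())
  mdeg <- .heavyDegree(g)
  mh <- g$atoms$hcount
  mh[is.na(mh)] <- 0L
  pidx <- .bondIndex(pg); midx <- .bondIndex(g)
  padj <- .adjacency(pg); madj <- .adjacency(g)

  # visit order: BFS from pattern atom 1 (patterns are connected)
  ord <- integer(0); seen <- logical(np); queue <- 1L
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    if (seen[v]) next
    seen[v] <- TRUE; ord <- c(ord, v)
    queue <- c(queue, padj[[v]][!seen[padj[[v]]]])
  }
  if (length(ord) < np)
    stop("pattern graph must be connected", call. = FALSE)

  matches <- list()
  assign_ <- rep(NA_integer_, np)
  used <- logical(nm)

  place <- function(pos) {
    if (pos > np) {
      matches[[length(matches) + 1L]] <<- assign_
      return(invisible())
    }
    p <- ord[pos]
    placed_nbrs <- padj[[p]][!is.na(assign_[padj[[p]]])]
    cands <- if (length(placed_nbrs)) {
      # must be adjacent to the image of some placed pattern neighbor
      unique(unlist(lapply(assign_[placed_nbrs], function(mv) madj[[mv]])))
    } else seq_len(nm)
    for (cand in cands) {
      if (used[cand]) next
      if (!.atomCompatible(as.list(pg$atoms[p, ]), as.list(g$atoms[cand, ]),
                           mdeg[cand], mh[cand])) next
      ok <- TRUE
      for (q in placed_nbrs) {
        pb <- pg$bonds[.getBond(pg, pidx, p, q), ]
        mbrow <- .getBond(g, midx, cand, assign_[q])
        if (is.na(mbrow) || !.bondCompatible(as.list(pb), as.list(g$bonds[mbrow, ]))) {
          ok <- FALSE; break
        }
      }
      if (!ok) next
      assign_[p] <<- cand; used[cand] <<- TRUE
      place(pos + 1L)
      assign_[p] <<- NA_integer_; used[cand] <<- FALSE
    }
  }
  place(1L)
  matches
}
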