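# Internal molecular-graph layer: a strict SMILES reader/writer over a plain
# atom/bond representation. OpenBabel (via ChemmineOB) is used only for
# canonicalization; it accepts malformed input silently, so structural
# validation happens here.

.ORGANIC_SUBSET <- c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I")
.AROMATIC_OK <- c("b", "c", "n", "o", "p", "s")
.DEFAULT_VALENCE <- c(B = 3, C = 4, N = 3, O = 2, P = 3, S = 2,
                      F = 1, Cl = 1, Br = 1, I = 1)

.emptyMolGraph <- function() {
  list(
    atoms = data.frame(element = character(), aromatic = logical(),
                       charge = integer(), hcount = integer(),
                       stringsAsFactors = FALSE),
    bonds = data.frame(from = integer(), to = integer(), order = integer(),
                       aromatic = logical(), stringsAsFactors = FALSE)
  )
}

.smilesError <- function(smiles, msg, pos = NA_integer_) {
  where <- if (is.na(pos)) "" else sprintf(" at position %d", pos)
  stop(sprintf("invalid SMILES '%s'%s: %s", smiles, where, msg), call. = FALSE)
}

# Parse a bracket-atom body, e.g. "nH", "O-", "13C@H2", "N+2".
# In pattern mode the SMARTS primitives #<n> (atomic element), X<n>
# (connection count) and a leading-case aromaticity constraint are kept.
.parseBracketAtom <- function(body, smiles, pattern = FALSE) {
  rest <- body
  out <- list(element = NA_character_, aromatic = NA, charge = 0L,
              hcount = 0L, hspec = FALSE, conn = NA_integer_)
  # isotope (ignored)
  m <- regmatches(rest, regexpr("^[0-9]+", rest))
  if (length(m)) rest <- substring(rest, nchar(m) + 1L)
  if (pattern && grepl("^#[0-9]+", rest)) {
    num <- regmatches(rest, regexpr("^#[0-9]+", rest))
    z <- as.integer(substring(num, 2L))
    ptable <- c("H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne",
                "Na", "Mg", "Al", "Si", "P", "S", "Cl", "Ar", "K", "Ca")
    if (z < 1L || z > length(ptable))
      .smilesError(smiles, sprintf("unsupported atomic number %d", z))
    out$element <- ptable[z]
    out$aromatic <- NA        # any aromaticity
    rest <- substring(rest, nchar(num) + 1L)
  } else if (grepl("^\\*", rest)) {
    out$element <- "*"; out$aromatic <- NA
    rest <- substring(rest, 2L)
  } else {
    m <- regmatches(rest, regexpr("^([A-Z][a-z]?|[a-z])", rest))
    if (!length(m)) .smilesError(smiles, sprintf("cannot read atom '[%s]'", body))
    # two-letter match must be a real element, not e.g. "Cc" run together
    if (nchar(m) == 2L && !(m %in% c(.ORGANIC_SUBSET, "Si", "Se", "Na", "Ca",
                                     "Mg", "Al", "Zn", "Fe", "Cu", "Mn")))
      m <- substring(m, 1L, 1L)
    if (m %in% .AROMATIC_OK) {
      out$element <- toupper(m); out$aromatic <- TRUE
    } else {
      out$element <- m; out$aromatic <- FALSE
    }
    rest <- substring(rest, nchar(m) + 1L)
  }
  # chirality tags (ignored)
  rest <- sub("^@{1,2}", "", rest)
  # explicit hydrogen count
  if (grepl("^H", rest)) {
    rest <- substring(rest, 2L)
    out$hspec <- TRUE
    m <- regmatches(rest, regexpr("^[0-9]+", rest))
    if (length(m)) { out$hcount <- as.integer(m); rest <- substring(rest, nchar(m) + 1L) }
    else out$hcount <- 1L
  }
  # SMARTS connection count
  if (pattern && grepl("^X[0-9]", rest)) {
    m <- regmatches(rest, regexpr("^X[0-9]+", rest))
    out$conn <- as.integer(substring(m, 2L))
    rest <- substring(rest, nchar(m) + 1L)
  }
  # charge
  if (grepl("^[+-]", rest)) {
    sign <- if (substring(rest, 1L, 1L) == "+") 1L else -1L
    rest <- substring(rest, 2L)
    m <- regmatches(rest, regexpr("^[0-9]+", rest))
    if (length(m)) { out$charge <- sign * as.integer(m); rest <- substring(rest, nchar(m) + 1L) }
    else {
      extra <- attr(regexpr(if (sign > 0L) "^\\++" else "^-+", rest), "match.length")
      extra <- max(extra, 0L)
      out$charge <- sign * (1L + extra)
      rest <- substring(rest, extra + 1L)
    }
  }
  rest <- sub("^:[0-9]+", "", rest)   # atom map (ignored)
  if (nzchar(rest))
    .smilesError(smiles, sprintf("unsupported bracket-atom content '%s' in '[%s]'", rest, body))
  out
}

# Strict SMILES -> molecular graph. pattern = TRUE enables the SMARTS subset
# used by metabolic-rule reactant patterns (#n, Xn, Hn constraints, *).
parseSmilesGraph <- function(smiles, pattern = FALSE) {
  if (!is.character(smiles) || length(smiles) != 1L || is.na(smiles) || !nzchar(smiles))
    stop("'smiles' must be a single non-empty string", call. = FALSE)
  chars <- strsplit(smiles, "")[[1]]
  n <- length(chars)

  atoms <- list(); bonds <- list()
  prev <- integer()                # branch stack of previous-atom indices
  pending_bond <- NA_character_    # explicit bond symbol awaiting next atom
  ring <- list()                   # open ring closures: label -> (atom, bond)
  i <- 1L
  hadatom <- FALSE

  addAtom <- function(a) {
    atoms[[length(atoms) + 1L]] <<- a
    length(atoms)
  }
  addBond <- function(from, to, sym) {
    if (from == to) .smilesError(smiles, "self-bond")
    ord <- switch(if (is.na(sym)) "default" else sym,
                  "-" = 1L, "=" = 2L, "#" = 3L, ":" = 1L,
                  "/" = 1L, "\\" = 1L, "~" = 0L, "default" = 1L)
    arom <- FALSE
    if (is.na(sym)) {
      a1 <- atoms[[from]]; a2 <- atoms[[to]]
      arom <- isTRUE(a1$aromatic) && isTRUE(a2$aromatic)
    } else if (sym == ":") arom <- TRUE
    bonds[[length(bonds) + 1L]] <<- list(from = from, to = to,
                                         order = ord, aromatic = arom,
                                         anyorder = identical(sym, "~"))
  }
  connect <- function(idx) {
    if (length(prev)) addBond(prev[length(prev)], idx, pending_bond)
    else if (!is.na(pending_bond)) .smilesError(smiles, "bond symbol with no preceding atom", i)
    if (length(prev)) prev[length(prev)] <<- idx else prev <<- idx
    pending_bond <<- NA_character_
    hadatom <<- TRUE
  }

  while (i <= n) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i
      while (j <= n && chars[j] != "]") j <- j + 1L
      if (j > n) .smilesError(smiles, "unclosed '['", i)
      body <- paste(chars[(i + 1L):(j - 1L)], collapse = "")
      if (!nzchar(body)) .smilesError(smiles, "empty bracket atom", i)
      a <- .parseBracketAtom(body, smiles, pattern = pattern)
      a$explicit <- TRUE
      connect(addAtom(a))
      i <- j + 1L
    } else if (ch %in% c("-", "=", "#", ":", "/", "\\", "~")) {
      if (ch == "~" && !pattern) .smilesError(smiles, "'~' bond only allowed in patterns", i)
      if (!is.na(pending_bond)) .smilesError(smiles, "two consecutive bond symbols", i)
      pending_bond <- ch
      i <- i + 1L
    } else if (ch == "(") {
      if (!hadatom) .smilesError(smiles, "branch before any atom", i)
      if (!is.na(pending_bond)) .smilesError(smiles, "bond symbol before '('", i)
      prev <- c(prev, prev[length(prev)])
      i <- i + 1L
    } else if (ch == ")") {
      if (length(prev) < 2L) .smilesError(smiles, "unmatched ')'", i)
      if (!is.na(pending_bond)) .smilesError(smiles, "dangling bond before ')'", i)
      prev <- prev[-length(prev)]
      i <- i + 1L
    } else if (grepl("[0-9]", ch) || ch == "%") {
      if (!hadatom) .smilesError(smiles, "ring closure before any atom", i)
      if (ch == "%") {
        if (i + 2L > n || !grepl("^[0-9]{2}$", paste(chars[i + 1:2], collapse = "")))
          .smilesError(smiles, "'%' must be followed by two digits", i)
        lab <- paste(chars[i + 1:2], collapse = "")
        i <- i + 3L
      } else {
        lab <- ch
        i <- i + 1L
      }
      cur <- prev[length(prev)]
      if (!is.null(ring[[lab]])) {
        open <- ring[[lab]]
        if (open$atom == cur) .smilesError(smiles, "ring closure to same atom", i)
        sym <- if (!is.na(pending_bond)) pending_bond else open$bond
        if (!is.na(open$bond) && !is.na(pending_bond) && open$bond != pending_bond)
          .smilesError(smiles, sprintf("conflicting ring-bond symbols for closure %s", lab))
        addBond(open$atom, cur, sym)
        ring[[lab]] <- NULL
        pending_bond <- NA_character_
      } else {
        ring[[lab]] <- list(atom = cur, bond = pending_bond)
        pending_bond <- NA_character_
      }
    } else if (ch == ".") {
      if (!is.na(pending_bond)) .smilesError(smiles, "bond symbol before '.'", i)
      prev <- integer()
      i <- i + 1L
    } else if (ch == "*") {
      if (!pattern) .smilesError(smiles, "'*' atom only allowed in patterns", i)
      connect(addAtom(list(element = "*", aromatic = NA, charge = 0L,
                           hcount = NA_integer_, conn = NA_integer_, explicit = FALSE)))
      i <- i + 1L
    } else {
      two <- if (i < n) paste0(ch, chars[i + 1L]) else ""
      if (two %in% c("Cl", "Br")) {
        connect(addAtom(list(element = two, aromatic = FALSE, charge = 0L,
                             hcount = NA_integer_, conn = NA_integer_, explicit = FALSE)))
        i <- i + 2L
      } else if (ch %in% .ORGANIC_SUBSET) {
        connect(addAtom(list(element = ch, aromatic = FALSE, charge = 0L,
                             hcount = NA_integer_, conn = NA_integer_, explicit = FALSE)))
        i <- i + 1L
      } else if (ch %in% .AROMATIC_OK) {
        connect(addAtom(list(element = toupper(ch), aromatic = TRUE, charge = 0L,
                             hcount = NA_integer_, conn = NA_integer_, explicit = FALSE)))
        i <- i + 1L
      } else {
        .smilesError(smiles, sprintf("unexpected character '%s'", ch), i)
      }
    }
  }
  if (!is.na(pending_bond)) .smilesError(smiles, "trailing bond symbol")
  if (length(ring)) .smilesError(smiles, sprintf("unclosed ring closure(s): %s",
                                                 paste(names(ring), collapse = ", ")))
  if (length(prev) > 1L) .smilesError(smiles, "unclosed '('")
  if (!length(atoms)) .smilesError(smiles, "no atoms")

  g <- list(
    atoms = data.frame(
      element = vapply(atoms, function(a) a$element, ""),
      aromatic = vapply(atoms, function(a) as.logical(a$aromatic), NA),
      charge = vapply(atoms, function(a) as.integer(a$charge), 0L),
      hcount = vapply(atoms, function(a) {
        if (!isTRUE(a$explicit)) return(NA_integer_)
        if (pattern && !isTRUE(a$hspec)) return(NA_integer_)
        as.integer(a$hcount)
      }, 0L),
      conn = vapply(atoms, function(a)
        if (!is.null(a$conn)) as.integer(a$conn) else NA_integer_, 0L),
      stringsAsFactors = FALSE),
    bonds = if (length(bonds)) data.frame(
      from = vapply(bonds, `[[`, 0L, "from"),
      to = vapply(bonds, `[[`, 0L, "to"),
      order = vapply(bonds, `[[`, 0L, "order"),
      aromatic = vapply(bonds, `[[`, NA, "aromatic"),
      anyorder = vapply(bonds, function(b) isTRUE(b$anyorder), NA),
      stringsAsFactors = FALSE)
    else cbind(.emptyMolGraph()$bonds, anyorder = logical())
  )
  if (!pattern) g$atoms$hcount <- .implicitHydrogens(g)
  g
}

# Implicit hydrogen count per atom under default-valence rules; aromatic
# bonds contribute 1.5 to the bond-order sum (ceiling taken).
.implicitHydrogens <- function(g) {
  n <- nrow(g$atoms)
  ordsum <- numeric(n)
  if (nrow(g$bonds)) {
    for (b in seq_len(nrow(g$bonds))) {
      o <- if (g$bonds$aromatic[b]) 1.5 else g$bonds$order[b]
      ordsum[g$bonds$from[b]] <- ordsum[g$bonds$from[b]] + o
      ordsum[g$bonds$to[b]] <- ordsum[g$bonds$to[b]] + o
    }
  }
  h <- integer(n)
  for (i in seq_len(n)) {
    if (!is.na(g$atoms$hcount[i])) { h[i] <- g$atoms$hcount[i]; next }
    dv <- .DEFAULT_VALENCE[g$atoms$element[i]]
    if (is.na(dv)) { h[i] <- 0L; next }
    used <- ceiling(ordsum[i])
    if (isTRUE(g$atoms$aromatic[i]) && ordsum[i] == floor(ordsum[i]) && ordsum[i] > 0)
      used <- used   # kekulized aromatic input: sum already integral
    h[i] <- max(0L, as.integer(dv) - as.integer(used) - abs(g$atoms$charge[i]))
  }
  h
}

# Adjacency list (heavy atoms only).
.adjacency <- function(g) {
  n <- nrow(g$atoms)
  adj <- vector("list", n)
  if (nrow(g$bonds)) {
    for (b in seq_len(nrow(g$bonds))) {
      f <- g$bonds$from[b]; t <- g$bonds$to[b]
      adj[[f]] <- c(adj[[f]], t)
      adj[[t]] <- c(adj[[t]], f)
    }
  }
  adj
}

.bondIndex <- function(g) {
  # lookup matrix: bond row id by unordered atom pair
  idx <- new.env(hash = TRUE, parent = emptyenv())
  if (nrow(g$bonds)) {
    for (b in seq_len(nrow(g$bonds))) {
      k <- paste(sort(c(g$bonds$from[b], g$bonds$to[b])), collapse = "-")
      assign(k, b, envir = idx)
    }
  }
  idx
}

.getBond <- function(g, idx, a, b) {
  k <- paste(sort(c(a, b)), collapse = "-")
  if (exists(k, envir = idx, inherits = FALSE)) get(k, envir = idx) else NA_integer_
}

# Connected components of the heavy-atom graph; returns list of atom-index vectors.
.components <- function(g) {
  n <- nrow(g$atoms)
  adj <- .adjacency(g)
  seen <- logical(n)
  comps <- list()
  for (s in seq_len(n)) {
    if (seen[s]) next
    stack <- s; comp <- integer()
    while (length(stack)) {
      v <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (seen[v]) next
      seen[v] <- TRUE
      comp <- c(comp, v)
      stack <- c(stack, adj[[v]][!seen[adj[[v]]]])
    }
    comps[[length(comps) + 1L]] <- sort(comp)
  }
  comps
}

# Restrict a graph to an atom subset, renumbering bonds.
.subgraph <- function(g, keep) {
  keep <- sort(keep)
  map <- integer(nrow(g$atoms)); map[keep] <- seq_along(keep)
  bonds <- g$bonds[g$bonds$from %in% keep & g$bonds$to %in% keep, , drop = FALSE]
  bonds$from <- map[bonds$from]; bonds$to <- map[bonds$to]
  rownames(bonds) <- NULL
  atoms <- g$atoms[keep, , drop = FALSE]
  rownames(atoms) <- NULL
  list(atoms = atoms, bonds = bonds)
}

# Write a molecular graph back to SMILES (one component per '.'-separated
# piece). Hydrogens are left implicit for neutral organic-subset atoms.
writeSmilesGraph <- function(g) {
  comps <- .components(g)
  paste(vapply(comps, function(comp) .writeComponent(.subgraph(g, comp)), ""),
        collapse = ".")
}

.writeComponent <- function(g) {
  n <- nrow(g$atoms)
  adj <- .adjacency(g)
  bidx <- .bondIndex(g)

  atomToken <- function(i) {
    el <- g$atoms$element[i]; ar <- isTRUE(g$atoms$aromatic[i])
    ch <- g$atoms$charge[i]
    plain <- el %in% .ORGANIC_SUBSET && ch == 0L &&
      (!ar || tolower(el) %in% .AROMATIC_OK)
    if (plain && !is.na(g$atoms$hcount[i])) {
      # implicit-H recomputation must agree, else bracket it
      tmp <- g; tmp$atoms$hcount[i] <- NA_integer_
      if (.implicitHydrogens(tmp)[i] != g$atoms$hcount[i]) plain <- FALSE
    }
    if (plain) {
      if (ar) tolower(el) else el
    } else {
      h <- g$atoms$hcount[i]
      hs <- if (is.na(h) || h == 0L) "" else if (h == 1L) "H" else paste0("H", h)
      cs <- if (ch == 0L) "" else if (ch == 1L) "+" else if (ch == -1L) "-"
            else sprintf("%+d", ch)
      paste0("[", if (ar) tolower(el) else el, hs, cs, "]")
    }
  }
  bondSym <- function(b) {
    if (g$bonds$aromatic[b]) "" else c("", "=", "#")[g$bonds$order[b]]
  }

  # pass 1: spanning-tree DFS to classify tree vs ring-closure (back) edges
  visited <- logical(n)
  treekid <- vector("list", n)    # ordered child atoms in the spanning tree
  backat <- vector("list", n)     # per atom: back-edge bond row ids
  stack <- 1L
  parent <- rep(NA_integer_, n)
  order <- integer()
  dfs1 <- function(v) {
    visited[v] <<- TRUE
    order[length(order) + 1L] <<- v
    for (w in sort(adj[[v]])) {
      if (!visited[w]) {
        parent[w] <<- v
        treekid[[v]] <<- c(treekid[[v]], w)
        dfs1(w)
      } else if (!identical(w, parent[v])) {
        b <- .getBond(g, bidx, v, w)
        if (!(b %in% backat[[w]])) backat[[v]] <<- c(backat[[v]], b)
      }
    }
  }
  dfs1(1L)

  # assign ring-closure labels; both endpoints emit "<bondsym><label>"
  closures <- vector("list", n)
  lab <- 0L
  for (v in order) {
    for (b in backat[[v]]) {
      lab <- lab + 1L
      tok <- if (lab < 10L) as.character(lab) else sprintf("%%%02d", lab)
      tok <- paste0(bondSym(b), tok)
      other <- if (g$bonds$from[b] == v) g$bonds$to[b] else g$bonds$from[b]
      closures[[v]] <- c(closures[[v]], tok)
      closures[[other]] <- c(closures[[other]], tok)
    }
  }

  # pass 2: emit
  emitAtom <- function(v, fromBond) {
    s <- paste0(if (!is.na(fromBond)) bondSym(fromBond) else "",
                atomToken(v),
                paste(closures[[v]], collapse = ""))
    kids <- treekid[[v]]
    if (length(kids)) {
      parts <- vapply(seq_along(kids), function(j) {
        w <- kids[j]
        b <- .getBond(g, bidx, v, w)
        inner <- emitAtom(w, b)
        if (j < length(kids)) paste0("(", inner, ")") else inner
      }, "")
      s <- paste0(s, paste(parts, collapse = ""))
    }
    s
  }
  emitAtom(1L, NA_integer_)
}

#' Canonicalize a SMILES string
#'
#' Returns the OpenBabel canonical SMILES for a structure, after strict
#' syntactic validation by the package's own reader. Two SMILES spellings of
#' the same structure (e.g. differing atom order) map to the same string.
#'
#' @param smiles single SMILES string.
#' @return canonical SMILES string.
#' @export
canonicalSmiles <- function(smiles) {
  parseSmilesGraph(smiles)   # strict validation
  out <- tryCatch(
    ChemmineOB::convertFormat("SMI", "CAN", paste0(smiles, " m")),
    error = function(e) "")
  can <- sub("[ \t].*$", "", trimws(out))
  if (!nzchar(can))
    stop(sprintf("OpenBabel could not canonicalize SMILES '%s'", smiles),
         call. = FALSE)
  can
}
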