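# Hashed linear-fragment fingerprints and Tanimoto similarity.
#
# Fragments are linear heavy-atom paths of 0..maxLength bonds. Each path is
# serialized as "El[arom]" atom tokens joined by bond-order symbols, read in
# the direction that gives the lexicographically smaller string, and hashed
# to a bit position. The scheme is a fixed, documented substitute for
# proprietary fragment cartridges: similarities are reproducible within this
# package (the descriptor string records the parameters) but are not
# numerically comparable to values from other fingerprint software.

.hashMod <- 2147483647   # 2^31 - 1; Horner hash stays exact in doubles

.hashString <- function(s, nbits) {
  v <- utf8ToInt(s)
  h <- 0
  for (x in v) h <- (h * 31 + x) %% .hashMod
  as.integer(h %% nbits)
}

.pathStrings <- function(g, maxLength) {
  atoms <- g$atoms
  tok <- paste0(atoms$element, ifelse(isTRUE_vec(atoms$aromatic), "~", ""))
  adj <- .adjacency(g)
  bidx <- .bondIndex(g)
  bsym <- function(b) {
    if (g$bonds$aromatic[b]) ":" else c("-", "=", "#")[g$bonds$order[b]]
  }
  out <- new.env(hash = TRUE, parent = emptyenv())
  n <- nrow(atoms)
  interleave <- function(at, bs) {
    if (!length(bs)) return(at)
    paste0(paste0(at[-length(at)], bs, collapse = ""), at[length(at)])
  }
  walk <- function(path, atoks, bsyms) {
    fwd <- interleave(atoks, bsyms)
    rev_ <- interleave(rev(atoks), rev(bsyms))
    assign(if (fwd <= rev_) fwd else rev_, TRUE, envir = out)
    if (length(path) > maxLength) return(invisible())
    v <- path[length(path)]
    for (w in adj[[v]]) {
      if (w %in% path) next
      b <- .getBond(g, bidx, v, w)
      walk(c(path, w), c(atoks, tok[w]), c(bsyms, bsym(b)))
    }
  }
  for (s in seq_len(n)) walk(s, tok[s], character())
  ls(out)
}

isTRUE_vec <- function(x) !is.na(x) & x

#' Compute a fragment fingerprint for a molecule
#'
#' Enumerates all linear heavy-atom paths of up to \code{maxLength} bonds and
#' hashes each canonical path string into a fixed-length bit set. The result
#' is deterministic and invariant to the atom order of the input SMILES.
#'
#' @param m a \linkS4class{Molecule}.
#' @param maxLength maximum path length in bonds (default 7).
#' @param nbits fingerprint length in bits (default 1024).
#' @return a \linkS4class{Fingerprint}; nonempty for any molecule.
#' @examples
#' fp <- computeFingerprint(parseStructure("m", "CCO"))
#' length(fingerprintBits(fp)) > 0
#' @export
computeFingerprint <- function(m, maxLength = 7L, nbits = 1024L) {
  stopifnot(is(m, "Molecule"))
  maxLength <- as.integer(maxLength); nbits <- as.integer(nbits)
  stopifnot(maxLength >= 0L, nbits >= 1L)
  paths <- .pathStrings(m@graph, maxLength)
  bits <- sort(unique(vapply(paths, .hashString, 0L, nbits = nbits)))
  new("Fingerprint", bits = bits, nbits = nbits,
      descriptor = sprintf("linear-paths;maxLength=%d;nbits=%d;hash=horner31",
                           maxLength, nbits))
}

#' @describeIn computeFingerprint on-bit positions accessor.
#' @param fp a \linkS4class{Fingerprint}.
#' @export
fingerprintBits <- function(fp) {
  stopifnot(is(fp, "Fingerprint"))
  fp@bits
}

#' Construct a Fingerprint from explicit bit positions
#'
#' Mainly useful for testing and for reading fingerprints back from disk.
#'
#' @param bits integer vector of on-bit positions in \code{[0, nbits)}.
#' @param nbits fingerprint length.
#' @param descriptor free-text scheme descriptor.
#' @return a \linkS4class{Fingerprint}.
#' @export
makeFingerprint <- function(bits, nbits = 1024L, descriptor = "explicit") {
  new("Fingerprint", bits = sort(unique(as.integer(bits))),
      nbits = as.integer(nbits), descriptor = descriptor)
}

setMethod("show", "Fingerprint", function(object) {
  cat(sprintf("Fingerprint: %d/%d bits set [%s]\n",
              length(object@bits), object@nbits, object@descriptor))
})

#' Tanimoto similarity of two fingerprints
#'
#' \eqn{T = |A \cap B| / |A \cup B|} over the on-bit sets. Symmetric;
#' \eqn{T(a,a) = 1} for a nonempty fingerprint; 0 for disjoint bit sets; by
#' convention 0 when both sets are empty.
#'
#' @param a,b \linkS4class{Fingerprint}s of equal bit length.
#' @return similarity in \code{[0, 1]}.
#' @examples
#' tanimoto(makeFingerprint(c(1, 2, 3)), makeFingerprint(c(2, 3, 4)))  # 0.5
#' @export
tanimoto <- function(a, b) {
  stopifnot(is(a, "Fingerprint"), is(b, "Fingerprint"))
  if (a@nbits != b@nbits)
    stop(sprintf("fingerprint lengths differ (%d vs %d)", a@nbits, b@nbits),
         call. = FALSE)
  # dense-logical route (the brute-force set oracle in the tests is the
  # independent sparse computation)
  va <- logical(a@nbits); va[a@bits + 1L] <- TRUE
  vb <- logical(b@nbits); vb[b@bits + 1L] <- TRUE
  uni <- sum(va | vb)
  if (uni == 0L) return(0)
  sum(va & vb) / uni
}
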