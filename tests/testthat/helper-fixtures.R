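# Shared test helpers: independent oracles and cached fixture generation.

# brute-force Tanimoto on explicit position sets (independent of the
# package's dense-logical implementation)
oracle_tanimoto <- function(bitsA, bitsB) {
  u <- length(unique(c(bitsA, bitsB)))
  if (u == 0L) return(0)
  length(intersect(bitsA, bitsB)) / u
}

# hypergeometric upper tail by direct ratio-of-binomials arithmetic,
# vectorized over k (independent of the package's log-space route)
oracle_hyper_direct <- function(N, K, n, k) {
  if (k == 0) return(1)
  i <- seq.int(k, min(K, n))
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# hypergeometric upper tail by full enumeration of all C(N, n) draws from a
# universe with K marked elements (small N only)
oracle_hyper_enum <- function(N, K, n, k) {
  draws <- utils::combn(N, n)
  hits <- colSums(draws <= K)   # elements 1..K are the marked ones
  mean(hits >= k)
}

# apply a random atom permutation to a parsed molecule graph and rewrite it,
# giving an alternative SMILES spelling of the same structure
permuted_smiles <- function(smiles) {
  g <- targetwise:::parseSmilesGraph(smiles)
  n <- nrow(g$atoms)
  perm <- sample(n)
  inv <- integer(n); inv[perm] <- seq_len(n)
  g$atoms <- g$atoms[perm, , drop = FALSE]
  rownames(g$atoms) <- NULL
  g$bonds$from <- inv[g$bonds$from]
  g$bonds$to <- inv[g$bonds$to]
  targetwise:::writeSmilesGraph(g)
}

# one fixture run directory per session, reused by several test files
fixture_run_dir <- local({
  cache <- new.env(parent = emptyenv())
  function(seed = 17L) {
    key <- as.character(seed)
    if (!is.null(cache[[key]])) return(cache[[key]])
    dir <- file.path(tempdir(), sprintf("targetwise-fixture-%d", seed))
    if (!file.exists(file.path(dir, "config.json")))
      generateFixtureRun(fixtureSpec(seed = seed), dir)
    cache[[key]] <- dir
    dir
  }
})

# small in-code compound database: three compounds, five interactions
write_tiny_db <- function(dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  smi <- file.path(dir, "structures.smi")
  writeLines(c("CCO\tcmpA", "CCN\tcmpB", "c1ccccc1O\tcmpC"), smi)
  ia <- file.path(dir, "interactions.tsv")
  writeLines(c("compound_id\tprotein_id\teffect\tdirectness",
               "cmpA\tP1\tactivation\tdirect",
               "cmpA\tP2\tinhibition\tindirect",
               "cmpB\tP2\tunspecified\tdirect",
               "cmpB\tP3\tactivation\tdirect",
               "cmpC\tP4\tinhibition\tdirect"), ia)
  list(structures = smi, interactions = ia)
}

# synthetic expression matrix with planted log2 effects; returns the matrix,
# groups and planted truth
make_expression <- function(seed, n_genes = 200L, n_planted = 20L,
                            effect = 2, n_per_group = 5L, sigma = 0.25) {
  set.seed(seed)
  genes <- sprintf("G%04d", seq_len(n_genes))
  base <- runif(n_genes, 5, 12)
  planted <- sort(sample(genes, n_planted))
  sign <- setNames(sample(c(-1, 1), n_planted, replace = TRUE), planted)
  lg <- matrix(rep(base, 2L * n_per_group), nrow = n_genes)
  treat_cols <- seq_len(n_per_group)
  idx <- match(planted, genes)
  lg[idx, treat_cols] <- lg[idx, treat_cols] + sign * effect
  lg <- lg + rnorm(length(lg), 0, sigma)
  mat <- 2^lg
  dimnames(mat) <- list(genes,
                        c(sprintf("T%d", seq_len(n_per_group)),
                          sprintf("C%d", seq_len(n_per_group))))
  list(mat = mat,
       groups = rep(c("treat", "ctrl"), each = n_per_group),
       planted = planted, sign = sign)
}
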