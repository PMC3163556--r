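# Similarity search, target collection, network expansion, set partition.

make_db_from_fps <- function(fps, interactions = NULL) {
  ids <- names(fps)
  cmp <- data.frame(compound_id = ids, smiles = rep("C", length(ids)),
                    canonical = rep("C", length(ids)), stringsAsFactors = FALSE)
  ia <- if (is.null(interactions))
    data.frame(compound_id = character(), protein_id = character(),
               effect = character(), directness = character(),
               stringsAsFactors = FALSE)
  else interactions
  new("CompoundDb", compounds = cmp, fingerprints = fps, interactions = ia)
}

test_that("similarity search returns self-matches first and honors threshold", {
  set.seed(3)
  fps <- lapply(1:5, function(i) makeFingerprint(sample(0:127, 30), nbits = 128))
  names(fps) <- sprintf("db%d", 1:5)
  db <- make_db_from_fps(fps)
  hits <- similaritySearch(list(q = fps$db3), db, threshold = 0.7)
  expect_equal(hits$db_compound_id[1], "db3")
  expect_equal(hits$similarity[1], 1.0)

  # threshold 1.0 with no exact match
  q2 <- makeFingerprint(0:5, nbits = 128)
  expect_equal(nrow(similaritySearch(list(q = q2), db, threshold = 1.0)), 0L)

  expect_error(similaritySearch(list(), db), "no query")
  empty <- make_db_from_fps(stats::setNames(list(), character()))
  expect_error(similaritySearch(list(q = q2), empty), "empty")
})

test_that("similarity search equals an exhaustive Tanimoto scan", {
  run <- fixture_run_dir(17L)
  db <- suppressMessages(loadCompoundDb(file.path(run, "structures.smi"),
                                        file.path(run, "interactions.tsv")))
  drugs <- readSmilesFile(file.path(run, "drugs.smi"))
  fps <- compoundFingerprints(db)
  for (i in seq_len(nrow(drugs))) {
    q <- computeFingerprint(parseStructure(drugs$compound_id[i], drugs$smiles[i]))
    hits <- similaritySearch(list(q = q), db, threshold = 0.7)
    # oracle: brute-force scan over the whole db with the set-arithmetic form
    sims <- vapply(fps, function(f)
      oracle_tanimoto(fingerprintBits(q), fingerprintBits(f)), 0)
    expect_setequal(hits$db_compound_id, names(sims)[sims >= 0.7])
    expect_equal(hits$similarity,
                 unname(sort(sims[hits$db_compound_id], decreasing = TRUE)))
  }
})

test_that("lowering the threshold never shrinks the hit set", {
  run <- fixture_run_dir(17L)
  db <- suppressMessages(loadCompoundDb(file.path(run, "structures.smi"),
                                        file.path(run, "interactions.tsv")))
  drugs <- readSmilesFile(file.path(run, "drugs.smi"))
  q <- computeFingerprint(parseStructure("q", drugs$smiles[1]))
  prev <- character()
  for (thr in c(0.9, 0.7, 0.5, 0.3)) {
    cur <- similaritySearch(list(q = q), db, threshold = thr)$db_compound_id
    expect_true(all(prev %in% cur))
    prev <- cur
  }
})

test_that("possible-target collection is a provenance-keeping union", {
  ia <- data.frame(
    compound_id = c("c1", "c1", "c2", "c3"),
    protein_id = c("P1", "P2", "P2", "P9"),
    effect = "unspecified", directness = "direct", stringsAsFactors = FALSE)
  fps <- stats::setNames(
    lapply(1:3, function(i) makeFingerprint(i, nbits = 16)),
    c("c1", "c2", "c3"))
  db <- make_db_from_fps(fps, ia)
  hits <- data.frame(query_id = "q", db_compound_id = c("c1", "c2"),
                     similarity = c(0.9, 0.8), stringsAsFactors = FALSE)
  ts <- collectPossibleTargets(hits, db, "drugX")
  expect_equal(targetMembers(ts), c("P1", "P2"))
  expect_equal(sum(targetProvenance(ts)$protein_id == "P2"), 2L)
  # relational-join oracle
  joined <- merge(hits, ia, by.x = "db_compound_id", by.y = "compound_id")
  expect_setequal(targetMembers(ts), unique(joined$protein_id))
  # empty hits
  none <- collectPossibleTargets(hits[0, ], db, "drugX")
  expect_length(targetMembers(none), 0L)
})

test_that("neighbor expansion adds exactly the first-step partners", {
  star <- igraph::make_star(5, mode = "undirected", center = 1)
  igraph::V(star)$name <- c("center", paste0("leaf", 1:4))
  seed <- new("TargetSet", drugId = "d", stage = "possible",
              members = "center",
              provenance = data.frame(protein_id = character(),
                                      source = character(),
                                      detail = character()))
  ex <- expandByNeighbors(seed, star)
  expect_length(targetMembers(ex), 5L)
  expect_equal(ex@stage, "expanded")

  # isolated protein (absent from graph) passes through unchanged
  iso <- new("TargetSet", drugId = "d", stage = "possible",
             members = "nowhere",
             provenance = data.frame(protein_id = character(),
                                     source = character(),
                                     detail = character()))
  expect_equal(targetMembers(expandByNeighbors(iso, star)), "nowhere")
  expect_error(expandByNeighbors(ex, star), "possible")
})

test_that("expansion is a superset of the input on random fixtures", {
  set.seed(9)
  for (i in 1:10) {
    g <- igraph::sample_gnp(30, 0.1)
    igraph::V(g)$name <- sprintf("P%02d", 1:30)
    members <- sort(sample(igraph::V(g)$name, 5))
    ts <- new("TargetSet", drugId = "d", stage = "possible", members = members,
              provenance = data.frame(protein_id = character(),
                                      source = character(),
                                      detail = character()))
    ex <- expandByNeighbors(ts, g)
    expect_true(all(members %in% targetMembers(ex)))
    # adjacency-enumeration oracle
    nbrs <- unique(unlist(lapply(members, function(v)
      igraph::neighbors(g, v)$name)))
    expect_setequal(targetMembers(ex), union(members, nbrs))
  }
})

test_that("partition reproduces the worked three-set example", {
  p <- partitionSets(list(A = c("1", "2", "3", "4"), B = c("3", "4", "5"),
                          C = c("4", "5", "6")))
  expect_equal(partitionCommon(p), "4")
  expect_equal(partitionSimilar(p)[["A|B"]], "3")
  expect_equal(partitionSimilar(p)[["B|C"]], "5")
  expect_equal(partitionSimilar(p)[["A|C"]], character())
  expect_equal(partitionUnique(p)$A, c("1", "2"))
  expect_equal(partitionUnique(p)$B, character())
  expect_equal(partitionUnique(p)$C, "6")
})

test_that("degenerate partitions: identical and disjoint families", {
  s <- c("x", "y", "z")
  pid <- partitionSets(list(A = s, B = s, C = s))
  expect_setequal(partitionCommon(pid), s)
  expect_equal(sum(lengths(partitionSimilar(pid))), 0L)
  expect_equal(sum(lengths(partitionUnique(pid))), 0L)

  pdj <- partitionSets(list(A = "a", B = "b", C = "c"))
  expect_length(partitionCommon(pdj), 0L)
  expect_equal(sum(lengths(partitionUnique(pdj))), 3L)
  expect_error(partitionSets(list(A = "a")), "two sets")
  expect_error(partitionSets(stats::setNames(list("a", "b"), c("A", "A"))),
               "duplicate")
})

test_that("partition equals per-element membership classification", {
  set.seed(77)
  for (i in 1:300) {
    sets <- lapply(1:3, function(j)
      unique(sample(as.character(1:15), sample(0:10, 1), replace = TRUE)))
    names(sets) <- c("A", "B", "C")
    p <- partitionSets(sets)
    everything <- sort(unique(unlist(sets)))
    got <- c(partitionCommon(p), unlist(partitionSimilar(p)),
             unlist(partitionUnique(p)))
    # disjoint and covering
    expect_false(anyDuplicated(got) > 0)
    expect_setequal(got, everything)
    # element-wise oracle
    for (e in everything) {
      inwhich <- names(sets)[vapply(sets, function(s) e %in% s, NA)]
      cls <- if (length(inwhich) == 3L) "common"
             else if (length(inwhich) == 2L) "similar" else "unique"
      found <- if (e %in% partitionCommon(p)) "common"
               else if (e %in% unlist(partitionSimilar(p))) "similar"
               else "unique"
      expect_equal(found, cls, info = e)
      if (cls == "similar")
        expect_true(e %in% partitionSimilar(p)[[paste(sort(inwhich),
                                                      collapse = "|")]])
      if (cls == "unique")
        expect_true(e %in% partitionUnique(p)[[inwhich]])
    }
  }
})

test_that("k=4 partition routes triple memberships to the multi class", {
  p <- partitionSets(list(A = c("t", "q"), B = c("t", "q"), C = "t", D = "z"))
  expect_length(partitionCommon(p), 0L)
  expect_equal(p@multi[["A|B|C"]], "t")
  expect_equal(partitionSimilar(p)[["A|B"]], "q")
  expect_equal(partitionUnique(p)$D, "z")
})
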