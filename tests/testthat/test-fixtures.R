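# Synthetic-fixture generators: determinism, planted structure, calibration.

small_spec <- function(seed = 17L, ...) {
  fixtureSpec(seed = seed, n_compounds = 12L, n_clusters = 2L,
              n_proteins = 60L, n_categories = 8L, n_genes = 60L,
              block_size = 8L, ...)
}

test_that("generators are pure functions of the spec", {
  d1 <- file.path(withr::local_tempdir(), "a")
  d2 <- file.path(withr::local_tempdir(), "b")
  for (d in c(d1, d2)) {
    spec <- small_spec()
    generateCompoundDb(spec, d)
    generateInteractionGraph(spec, d)
    generateOntology(spec, d)
    generateExpression(spec, d, drugs = c("D1", "D2"))
  }
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
})

test_that("compound clusters satisfy the planted similarity contract", {
  d <- withr::local_tempdir()
  spec <- small_spec()
  generateCompoundDb(spec, d)
  db <- suppressMessages(loadCompoundDb(file.path(d, "structures.smi"),
                                        file.path(d, "interactions.tsv")))
  truth <- read.delim(file.path(d, "truth_compounds.tsv"))
  fps <- compoundFingerprints(db)
  cl <- truth$cluster[match(names(fps), truth$compound_id)]
  for (i in seq_along(fps)) for (j in seq_len(i - 1L)) {
    s <- tanimoto(fps[[i]], fps[[j]])
    if (cl[i] == cl[j]) expect_gte(s, spec$cluster_tightness)
    else expect_lt(s, 0.5)
  }
  # each cluster's interactions stay inside its characteristic block
  blocks <- read.delim(file.path(d, "truth_blocks.tsv"))
  ia <- compoundInteractions(db)
  for (r in seq_len(nrow(ia))) {
    cluster <- truth$cluster[truth$compound_id == ia$compound_id[r]]
    expect_true(ia$protein_id[r] %in%
                  blocks$protein_id[blocks$cluster == cluster])
  }
})

test_that("a single-cluster spec yields one similarity block", {
  d <- withr::local_tempdir()
  spec <- fixtureSpec(seed = 5L, n_compounds = 6L, n_clusters = 1L,
                      n_proteins = 30L, block_size = 6L)
  generateCompoundDb(spec, d)
  db <- suppressMessages(loadCompoundDb(file.path(d, "structures.smi"),
                                        file.path(d, "interactions.tsv")))
  fps <- compoundFingerprints(db)
  for (i in seq_along(fps)) for (j in seq_len(i - 1L))
    expect_gte(tanimoto(fps[[i]], fps[[j]]), spec$cluster_tightness)
})

test_that("interaction graph hits its expected degree; zero degree is empty", {
  d <- withr::local_tempdir()
  spec <- fixtureSpec(seed = 8L, n_proteins = 400L, graph_degree = 5)
  generateInteractionGraph(spec, d)
  edges <- read.delim(file.path(d, "ppi_edges.tsv"), header = FALSE)
  realized <- 2 * nrow(edges) / spec$n_proteins
  expect_lt(abs(realized - 5) / 5, 0.1)
  expect_false(any(edges[[1]] == edges[[2]]))

  spec0 <- fixtureSpec(seed = 8L, n_proteins = 50L, graph_degree = 0)
  d0 <- withr::local_tempdir()
  generateInteractionGraph(spec0, d0)
  expect_length(readLines(file.path(d0, "ppi_edges.tsv")), 0L)
})

test_that("the planted category is drawn from the first target block", {
  d <- withr::local_tempdir()
  spec <- small_spec()
  generateOntology(spec, d)
  ont <- loadOntology(file.path(d, "pathway-maps.gmt"))
  planted <- ontologyCategories(ont)$GS_planted
  block1 <- sprintf("P%04d", seq_len(spec$block_size))
  expect_true(all(planted %in% block1))
  truth <- read.delim(file.path(d, "truth_ontology.tsv"))
  expect_setequal(truth$protein_id, planted)

  # no planted category -> none in the GMT
  spec2 <- small_spec(planted_category = NULL)
  d2 <- withr::local_tempdir()
  generateOntology(spec2, d2)
  ont2 <- loadOntology(file.path(d2, "pathway-maps.gmt"))
  expect_false("GS_planted" %in% names(ontologyCategories(ont2)))
})

test_that("planted expression shifts match the spec within sampling error", {
  d <- withr::local_tempdir()
  spec <- fixtureSpec(seed = 99L)
  generateExpression(spec, d, drugs = c("D1", "D2", "D3"))
  mat <- readExpressionMatrix(file.path(d, "expression.tsv"))
  design <- readDesign(file.path(d, "design.tsv"))
  truth <- read.delim(file.path(d, "truth_expression.tsv"))
  lg <- log2(pmax(mat, 10))
  for (drug in c("D1", "D3")) {
    tcols <- design$sample[design$group == drug]
    ccols <- design$sample[design$group == "Ctrl"]
    tg <- truth[truth$drug == drug, ]
    shift <- rowMeans(lg[tg$gene, tcols]) - rowMeans(lg[tg$gene, ccols])
    eff <- ifelse(tg$direction == "up", 1, -1) * spec$planted_log2_effect
    tol <- 3 * spec$noise_sigma / sqrt(spec$n_samples_per_group)
    expect_true(all(abs(shift - eff) < 3 * tol))
    expect_lt(abs(mean(shift - eff)), tol)
  }
  # null spec produces no planted rows
  d0 <- withr::local_tempdir()
  generateExpression(fixtureSpec(seed = 99L, planted_deg_count = 0L), d0)
  truth0 <- read.delim(file.path(d0, "truth_expression.tsv"))
  expect_equal(nrow(truth0), 0L)
})

test_that("infeasible specs fail with actionable errors", {
  expect_error(fixtureSpec(cluster_tightness = 1.2), "tightness")
  expect_error(fixtureSpec(n_genes = 0), "positive")
  expect_error(fixtureSpec(planted_deg_count = 500), "planted_deg_count")
  expect_error(fixtureSpec(n_clusters = 10, block_size = 40), "universe")
  d <- withr::local_tempdir()
  expect_error(
    generateCompoundDb(fixtureSpec(seed = 1L, cluster_tightness = 0.99), d),
    "infeasible")
})
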