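# Preprocessing, the DEG cascade, fold threshold, DEG-list partition.

test_that("preprocessing floors intensities and removes all-absent genes", {
  mat <- matrix(c(7, 20, 5, 40, 100, 3), nrow = 3,
                dimnames = list(c("g1", "g2", "g3"), c("s1", "s2")))
  pres <- matrix(c(TRUE, FALSE, FALSE, TRUE, TRUE, FALSE), nrow = 3)
  se <- preprocessMatrix(mat, groups = c("a", "b"), presence = pres)
  # g3 absent in all arrays -> removed; g2 absent in one -> retained
  expect_equal(rownames(se), c("g1", "g2"))
  x <- SummarizedExperiment::assay(se, "intensity")
  expect_equal(unname(x["g1", "s1"]), 10)   # 7 floored to 10
  expect_equal(unname(x["g2", "s2"]), 100)
  expect_equal(SummarizedExperiment::assay(se, "log2"), log2(x))
  expect_equal(S4Vectors::metadata(se)$floor, 10)

  # already >= 10 everywhere, no presence calls: unchanged except log2
  m2 <- matrix(c(10, 30, 12, 11), 2, dimnames = list(c("a", "b"), c("x", "y")))
  se2 <- preprocessMatrix(m2, groups = c("g", "g"))
  expect_equal(SummarizedExperiment::assay(se2, "intensity"), m2)

  m2[1, 1] <- NA
  expect_error(preprocessMatrix(m2, groups = c("g", "g")), "row 1, column 1")
})

test_that("the cascade recovers planted effects with few false calls", {
  sim <- make_expression(seed = 7)
  se <- preprocessMatrix(sim$mat, groups = sim$groups)
  degs <- callDegs(se, c("treat", "ctrl"))
  split_ <- applyFoldThreshold(degs)
  called <- c(split_$up$gene, split_$down$gene)
  sens <- mean(sim$planted %in% called)
  false_calls <- sum(!called %in% sim$planted)
  expect_gte(sens, 0.9)
  expect_lte(false_calls, 2L)
  # directions match the planted signs
  agree <- split_$up$gene %in% names(sim$sign)[sim$sign > 0]
  expect_true(all(agree))
})

test_that("planted log2 effects are estimated accurately", {
  sim <- make_expression(seed = 21)
  se <- preprocessMatrix(sim$mat, groups = sim$groups)
  degs <- callDegs(se, c("treat", "ctrl"))
  est <- degs$log2_ratio[match(sim$planted, degs$gene)]
  mae <- mean(abs(est - sim$sign * 2))
  expect_lt(mae, 0.2)
})

test_that("the class-comparison p matches stats::t.test gene by gene", {
  sim <- make_expression(seed = 31, n_genes = 40L)
  se <- preprocessMatrix(sim$mat, groups = sim$groups)
  degs <- callDegs(se, c("treat", "ctrl"))
  lg <- SummarizedExperiment::assay(se, "log2")
  for (g in sample(rownames(lg), 10)) {
    ref <- stats::t.test(lg[g, 1:5], lg[g, 6:10], var.equal = TRUE)
    row <- degs[degs$gene == g, ]
    expect_equal(row$p_class, ref$p.value, tolerance = 1e-12)
    expect_equal(row$log2_ratio, unname(diff(rev(ref$estimate))),
                 tolerance = 1e-12)
  }
})

test_that("degenerate and undersized inputs follow the stated conventions", {
  mat <- matrix(16, nrow = 2, ncol = 6,
                dimnames = list(c("const", "var"), sprintf("s%d", 1:6)))
  set.seed(2); mat["var", ] <- 2^(rnorm(6, 5, 1))
  se <- preprocessMatrix(mat, groups = rep(c("t", "c"), each = 3))
  degs <- callDegs(se, c("t", "c"))
  expect_equal(degs$p_class[degs$gene == "const"], 1.0)
  expect_false(degs$is_deg[degs$gene == "const"])
  se1 <- preprocessMatrix(mat[, 1:3], groups = c("t", "t", "c"))
  expect_error(callDegs(se1, c("t", "c")), ">= 2 samples")
})

test_that("null data keep the class-comparison near its nominal level", {
  fracs <- vapply(1:100, function(s) {
    sim <- make_expression(seed = 1000 + s, n_planted = 0L)
    se <- preprocessMatrix(sim$mat, groups = sim$groups)
    degs <- callDegs(se, c("treat", "ctrl"))
    mean(degs$p_class < 0.01)
  }, 0)
  expect_gte(mean(fracs), 0.005)
  expect_lte(mean(fracs), 0.015)
})

test_that("fold threshold applies an inclusive 1.1 log2 boundary", {
  rec <- data.frame(
    gene = c("a", "b", "c", "d"),
    log2_ratio = c(1.2, 1.0, -1.1, 2.0),
    p_class = 0.001, fdr_pass = TRUE, p_t = 0.001,
    direction = c("up", "up", "down", "up"),
    is_deg = c(TRUE, TRUE, TRUE, FALSE),
    stringsAsFactors = FALSE)
  split_ <- applyFoldThreshold(rec)
  expect_equal(split_$up$gene, "a")        # 1.2 retained
  expect_equal(split_$down$gene, "c")      # -1.1 exactly: retained, down
  expect_false("b" %in% c(split_$up$gene, split_$down$gene))  # 1.0 dropped
  expect_false("d" %in% split_$up$gene)    # failed significance upstream
})

test_that("DEG calling is invariant to sample and gene order", {
  sim <- make_expression(seed = 47, n_genes = 60L)
  se <- preprocessMatrix(sim$mat, groups = sim$groups)
  ref <- callDegs(se, c("treat", "ctrl"))
  set.seed(4)
  pc <- sample(ncol(sim$mat)); pr <- sample(nrow(sim$mat))
  se2 <- preprocessMatrix(sim$mat[pr, pc], groups = sim$groups[pc])
  expect_equal(callDegs(se2, c("treat", "ctrl")), ref)
})

test_that("relaxing any cascade threshold never removes a called DEG", {
  sim <- make_expression(seed = 53, effect = 1.4)
  se <- preprocessMatrix(sim$mat, groups = sim$groups)
  base <- callDegs(se, c("treat", "ctrl"))
  baseGenes <- unlist(lapply(applyFoldThreshold(base), function(d) d$gene))
  relaxed <- list(
    callDegs(se, c("treat", "ctrl"), alpha = 0.05),
    callDegs(se, c("treat", "ctrl"), fdr = 0.2),
    callDegs(se, c("treat", "ctrl"), tAlpha = 0.05))
  for (r in relaxed) {
    genes <- unlist(lapply(applyFoldThreshold(r), function(d) d$gene))
    expect_true(all(baseGenes %in% genes))
  }
  wide <- unlist(lapply(applyFoldThreshold(base, log2Cut = 0.8),
                        function(d) d$gene))
  expect_true(all(baseGenes %in% wide))
})

test_that("DEG-list partition mirrors the set partition semantics", {
  p <- partitionDegLists(list(A = c("g1", "g2"), B = c("g2", "g3"), C = "g2"))
  expect_equal(partitionCommon(p), "g2")
  expect_equal(partitionUnique(p)$A, "g1")
  expect_equal(partitionUnique(p)$B, "g3")
  p2 <- partitionDegLists(list(A = c("g1"), B = character(), C = "g1"))
  expect_equal(partitionUnique(p2)$B, character())
})
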