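# Structure parsing, fingerprints, Tanimoto, metabolite generation.

fenofibrate <- "CC(C)OC(=O)C(C)(C)Oc1ccc(cc1)C(=O)c1ccc(Cl)cc1"
fenofibric_acid <- "CC(C)(Oc1ccc(cc1)C(=O)c1ccc(Cl)cc1)C(=O)O"

test_that("parseStructure validates input and counts heavy atoms", {
  m <- parseStructure("x", "CCO")
  expect_s4_class(m, "Molecule")
  expect_equal(heavyAtomCount(m), 3L)
  expect_error(parseStructure("y", "C("), "y")
  expect_error(parseStructure("z", ""), "non-empty")
  expect_error(parseStructure("w", "C1CC"), "ring")
})

test_that("canonical form is invariant to atom-order permutation", {
  expect_equal(canonicalForm(parseStructure("a", "OCC")),
               canonicalForm(parseStructure("b", "CCO")))
  set.seed(11)
  for (smi in c(fenofibrate, "CC(=O)Nc1ccc(O)cc1", "c1ccc2ccccc2c1CCN")) {
    ref <- canonicalForm(parseStructure("ref", smi))
    for (rep_ in 1:5) {
      alt <- permuted_smiles(smi)
      expect_equal(canonicalForm(parseStructure("alt", alt)), ref,
                   info = paste("spelling:", alt))
    }
  }
})

test_that("parsed fenofibrate contains an ester substructure", {
  # independent oracle: OpenBabel SMARTS match count on the same structure
  obmol <- ChemmineOB::forEachMol("SMILES", paste0(fenofibrate, " ff"),
                                  function(m) m)
  expect_equal(ChemmineOB::smartsSearch_OB(obmol, "[CX3](=O)[OX2][#6]"), 1)
  g <- targetwise:::parseSmilesGraph(fenofibrate)
  pg <- targetwise:::parseSmilesGraph("[CX3](=O)[OX2][#6]", pattern = TRUE)
  expect_length(targetwise:::matchSubstructure(g, pg), 1L)
})

test_that("fingerprints are deterministic, nonempty and order-invariant", {
  m <- parseStructure("m", "C")
  expect_gte(length(fingerprintBits(computeFingerprint(m))), 1L)
  f1 <- computeFingerprint(parseStructure("a", "CCO"))
  f2 <- computeFingerprint(parseStructure("a", "CCO"))
  expect_identical(fingerprintBits(f1), fingerprintBits(f2))
  expect_identical(fingerprintBits(computeFingerprint(parseStructure("b", "OCC"))),
                   fingerprintBits(f1))
  set.seed(23)
  for (smi in c(fenofibrate, "CCn1cc(C(=O)O)c(=O)c2ccccc21")) {
    ref <- fingerprintBits(computeFingerprint(parseStructure("r", smi)))
    for (rep_ in 1:5) {
      alt <- permuted_smiles(smi)
      expect_identical(
        fingerprintBits(computeFingerprint(parseStructure("p", alt))), ref,
        info = paste("spelling:", alt))
    }
  }
})

test_that("tanimoto matches direct set arithmetic and its conventions", {
  expect_equal(tanimoto(makeFingerprint(c(1, 2, 3)), makeFingerprint(c(2, 3, 4))),
               0.5)
  f <- makeFingerprint(c(5, 9, 100))
  expect_equal(tanimoto(f, f), 1)
  expect_equal(tanimoto(makeFingerprint(1:3), makeFingerprint(7:9)), 0)
  expect_equal(tanimoto(makeFingerprint(integer()), makeFingerprint(integer())), 0)
  expect_error(tanimoto(makeFingerprint(1, nbits = 64),
                        makeFingerprint(1, nbits = 128)), "lengths differ")
})

test_that("tanimoto equals the brute-force set oracle on random pairs", {
  set.seed(41)
  for (i in 1:1000) {
    a <- sample(0:255, sample(0:40, 1))
    b <- sample(0:255, sample(0:40, 1))
    fa <- makeFingerprint(a, nbits = 256)
    fb <- makeFingerprint(b, nbits = 256)
    expect_identical(tanimoto(fa, fb), oracle_tanimoto(a, b))
    expect_identical(tanimoto(fa, fb), tanimoto(fb, fa))
  }
})

test_that("ester hydrolysis of fenofibrate yields fenofibric acid", {
  ff <- parseStructure("FF", fenofibrate)
  mets <- generateMetabolites(ff, defaultMetabolicRules()[1, ])
  expect_length(mets, 1L)
  expect_equal(canonicalForm(mets[[1]]),
               canonicalSmiles(fenofibric_acid))
  expect_equal(mets[[1]]@parentId, "FF")
  expect_equal(mets[[1]]@ruleName, "ester_hydrolysis")
  expect_equal(mets[[1]]@role, "metabolite")
})

test_that("metabolite generation enumerates all matching sites", {
  # two chemically distinct ester sites -> two distinct major products
  two <- parseStructure("di", "CCOC(=O)CCCCC(=O)OCc1ccccc1")
  mets <- generateMetabolites(two, defaultMetabolicRules()[1, ])
  expect_length(mets, 2L)
  expect_length(unique(vapply(mets, canonicalForm, "")), 2L)
  # symmetric aromatic positions collapse to distinct products only
  ani <- parseStructure("an", "COc1ccccc1")
  hyd <- generateMetabolites(
    ani, defaultMetabolicRules()[defaultMetabolicRules()$name ==
                                   "aromatic_hydroxylation", ])
  expect_length(hyd, 3L)   # ortho, meta, para
})

test_that("molecules lacking the reactant pattern give no products", {
  rules <- defaultMetabolicRules()
  expect_length(generateMetabolites(parseStructure("x", "CCO"),
                                    rules[rules$name == "ester_hydrolysis", ]),
                0L)
})

test_that("metabolism is idempotent on pattern-free products", {
  ff <- parseStructure("FF", fenofibrate)
  esterRule <- defaultMetabolicRules()[1, ]
  acid <- generateMetabolites(ff, esterRule)[[1]]
  reparent <- parseStructure("acid", canonicalForm(acid))
  expect_length(generateMetabolites(reparent, esterRule), 0L)
})

test_that("O-demethylation and rule-table validation behave", {
  rules <- defaultMetabolicRules()
  dem <- generateMetabolites(parseStructure("an", "COc1ccccc1"),
                             rules[rules$name == "O_demethylation", ])
  expect_equal(canonicalForm(dem[[1]]), canonicalSmiles("Oc1ccccc1"))
  bad <- rules; bad$reactant_pattern[1] <- "[[["
  expect_error(validateMetabolicRules(bad), "ester_hydrolysis")
  bad2 <- rules; bad2$transformation[2] <- "nope"
  expect_error(validateMetabolicRules(bad2), "unknown transformation")
  expect_error(generateMetabolites(
    parseStructure("m", "CCO", role = "metabolite", parentId = "p"), rules),
    "parent")
})
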