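chainHierarchy <- new("DiseaseHierarchy", records = list(
  a = "A", b = "A.B", c = "A.B.C", x = "R.X", y = "R.Y"))

test_that("DAG construction expands prefix chains", {
  dag <- buildDiseaseDAG("c", chainHierarchy)
  expect_setequal(dagNodes(dag), c("A", "A.B", "A.B.C"))
  expect_equal(dag@targets, "A.B.C")
  expect_equal(dag@children[["A"]], "A.B")

  h2 <- new("DiseaseHierarchy", records = list(d = c("R.A.T1", "R.B.T2")))
  dag2 <- buildDiseaseDAG("d", h2)
  expect_setequal(dagNodes(dag2), c("R", "R.A", "R.A.T1", "R.B", "R.B.T2"))
  expect_setequal(dag2@children[["R"]], c("R.A", "R.B"))

  expect_warning(dag0 <- buildDiseaseDAG("nope", chainHierarchy), "no hierarchy record")
  expect_length(dagNodes(dag0), 0)
})

test_that("decay contributions follow the max-over-children recursion", {
  dag <- buildDiseaseDAG("c", chainHierarchy)
  lc <- localContributions(dag, delta = 0.5)
  expect_equal(lc$values[["A.B.C"]], 1)
  expect_equal(lc$values[["A.B"]], 0.5)
  expect_equal(lc$values[["A"]], 0.25)
  expect_equal(lc$total, 1.75)

  dag1 <- buildDiseaseDAG("a", chainHierarchy)
  lc1 <- localContributions(dag1)
  expect_equal(unname(lc1$values), 1)
  expect_equal(lc1$total, 1)

  # diamond: two length-2 paths from the root to the disease
  hD <- new("DiseaseHierarchy", records = list(d = c("R.A.T", "R.B.U")))
  lcD <- localContributions(buildDiseaseDAG("d", hD), delta = 0.5)
  expect_equal(lcD$values[["R"]], 0.25) # max over paths, not their sum

  # multi-path ancestor takes delta^(shortest path)
  hS <- new("DiseaseHierarchy", records = list(d = c("R.A.T", "R.X")))
  lcS <- localContributions(buildDiseaseDAG("d", hS), delta = 0.5)
  expect_equal(lcS$values[["R"]], 0.5)

  expect_error(localContributions(suppressWarnings(
    buildDiseaseDAG("nope", chainHierarchy))), "no semantic record")
})

test_that("decay-based pair similarity matches hand computations", {
  dx <- buildDiseaseDAG("x", chainHierarchy)
  dy <- buildDiseaseDAG("y", chainHierarchy)
  dc <- buildDiseaseDAG("c", chainHierarchy)
  db <- buildDiseaseDAG("b", chainHierarchy)
  expect_equal(disss1Pair(dc, dc), 1)
  expect_equal(disss1Pair(dx, dy), 1 / 3)            # siblings under one root
  expect_equal(disss1Pair(dc, db), 2.25 / 3.25)      # chain vs its parent
  expect_equal(disss1Pair(dc, db), disss1Pair(db, dc))
  expect_equal(disss1Pair(dc, dx), 0)                # disjoint ancestry
})

test_that("global contributions are corpus information content", {
  dags <- lapply(c("a", "b", "c", "x"), buildDiseaseDAG, hierarchy = chainHierarchy)
  expect_equal(globalContribution("A", dags), 0 - log(3 / 4))
  expect_equal(globalContribution("R.X", dags), -log(1 / 4))
  expect_equal(globalContribution("R.X", dags, sign = "as_printed"), log(1 / 4))
  # a term in every DAG carries no information
  hU <- new("DiseaseHierarchy",
            records = list(p = "R.A", q = "R.B", r = "R.C", s = "R.D"))
  dU <- lapply(c("p", "q", "r", "s"), buildDiseaseDAG, hierarchy = hU)
  expect_equal(globalContribution("R", dU), 0)
  expect_error(globalContribution("ZZZ", dags), "no disease DAG")
})

test_that("frequency-based pair similarity handles universal roots", {
  hU <- new("DiseaseHierarchy",
            records = list(p = "R.A", q = "R.B", r = "R.C", s = "R.D"))
  dU <- lapply(c("p", "q", "r", "s"), buildDiseaseDAG, hierarchy = hU)
  terms <- unique(unlist(lapply(dU, dagNodes)))
  ic <- vapply(terms, globalContribution, numeric(1), dags = dU)
  # siblings share only the root, which carries zero information
  expect_equal(disss2Pair(dU[[1]], dU[[2]], ic), 0)
  expect_equal(disss2Pair(dU[[1]], dU[[1]], ic), 1)
})

test_that("similarity matrices agree with pairwise calls and flag unmapped", {
  s <- semanticSimilarityMatrices(c("a", "b", "c"), chainHierarchy)
  dags <- lapply(c("a", "b", "c"), buildDiseaseDAG, hierarchy = chainHierarchy)
  for (i in 1:3) for (j in 1:3) {
    if (i == j) next
    expect_equal(s$DISSS1[i, j], disss1Pair(dags[[i]], dags[[j]]))
  }
  expect_equal(diag(s$DISSS1), c(a = 1, b = 1, c = 1))

  expect_warning(z <- semanticSimilarityMatrices(c("u", "v"), chainHierarchy),
                 "hierarchy record")
  expect_equal(unname(z$DISSS1), diag(2))
  expect_equal(unname(z$DISSS2), diag(2))
})

test_that("matrices match the brute-force oracle on random hierarchies", {
  set.seed(202)
  for (rep in 1:10) {
    nd <- sample(3:8, 1)
    h <- randomHierarchy(nd)
    dis <- names(hierarchyRecords(h))
    s <- semanticSimilarityMatrices(dis, h)
    codes <- hierarchyRecords(h)
    for (i in seq_len(nd)) for (j in seq_len(nd)) {
      if (i == j) next
      expect_equal(s$DISSS1[i, j], oracleDISSS1(codes[[i]], codes[[j]]),
                   tolerance = 1e-12)
      expect_equal(s$DISSS2[i, j], oracleDISSS2(codes, i, j),
                   tolerance = 1e-12)
    }
    # structural invariants
    expect_true(all(s$DISSS1 >= 0 & s$DISSS1 <= 1))
    expect_true(all(s$DISSS2 >= 0 & s$DISSS2 <= 1 + 1e-12))
    expect_lt(max(abs(s$DISSS1 - t(s$DISSS1))), 1e-12)
    expect_lt(max(abs(s$DISSS2 - t(s$DISSS2))), 1e-12)
    expect_equal(unname(diag(s$DISSS1)), rep(1, nd))
  }
})
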