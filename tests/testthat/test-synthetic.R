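test_that("spec validation rejects impossible settings", {
  expect_error(syntheticSpec(pIn = 0.1, pOut = 0.2), "pOut < pIn")
  expect_error(syntheticSpec(nClusters = 30, nDiseases = 10), "more clusters")
  expect_error(generateHierarchy(syntheticSpec(nDiseases = 40, nClusters = 2,
                                               branching = 2, depth = 2)),
               "leaves")
})

test_that("hierarchy is a single rooted tree with cluster subtrees", {
  spec <- syntheticSpec(nDiseases = 12, nLncrnas = 20, nClusters = 4,
                        branching = 2, depth = 2)
  h <- generateHierarchy(spec)
  rec <- hierarchyRecords(h$hierarchy)
  expect_length(rec, 12)
  codes <- unlist(rec)
  expect_true(all(startsWith(codes, "C.")))
  # same-cluster diseases share the depth-1 ancestor, the cluster subtree
  sub <- vapply(strsplit(codes, ".", fixed = TRUE), `[`, "", 2)
  expect_equal(unname(as.integer(sub)), unname(h$diseaseCluster))
  # distinct leaves per disease
  expect_false(any(duplicated(codes)))
  h2 <- generateHierarchy(spec)
  expect_identical(rec, hierarchyRecords(h2$hierarchy))
})

test_that("planted association density matches the block probabilities", {
  spec <- syntheticSpec(nDiseases = 60, nLncrnas = 120, nClusters = 5,
                        pIn = 0.6, pOut = 0.02, seed = 13)
  h <- generateHierarchy(spec)
  a <- generatePlantedAssociations(spec, h$diseaseCluster)
  m <- as.matrix(a$interaction)
  same <- outer(h$diseaseCluster, a$lncCluster, "==")
  nIn <- sum(same); nOut <- sum(!same)
  # within 3 binomial standard deviations of expectation
  expect_lt(abs(sum(m[same]) - nIn * 0.6), 3 * sqrt(nIn * 0.6 * 0.4) + 1)
  expect_lt(abs(sum(m[!same]) - nOut * 0.02), 3 * sqrt(nOut * 0.02 * 0.98) + 1)
})

test_that("degenerate probability settings give the expected structure", {
  spec <- syntheticSpec(nDiseases = 8, nLncrnas = 12, nClusters = 4,
                        pIn = 1, pOut = 0, branching = 2, depth = 1, seed = 1)
  b <- generateBundle(spec)
  m <- as.matrix(b@interaction)
  same <- outer(b@diseaseCluster, b@lncCluster, "==")
  expect_true(all(m[same] == 1))
  expect_true(all(m[!same] == 0))
})

test_that("bundles are seed-deterministic and round-trip through TSV", {
  spec <- syntheticSpec(nDiseases = 10, nLncrnas = 15, nClusters = 5,
                        branching = 2, depth = 2, seed = 21)
  b1 <- generateBundle(spec)
  b2 <- generateBundle(spec)
  expect_identical(as.matrix(b1@interaction), as.matrix(b2@interaction))
  b3 <- generateBundle(syntheticSpec(nDiseases = 10, nLncrnas = 15,
                                     nClusters = 5, branching = 2, depth = 2,
                                     seed = 22))
  expect_false(identical(as.matrix(b1@interaction), as.matrix(b3@interaction)))
  expect_equal(dim(as.matrix(b3@interaction)), dim(as.matrix(b1@interaction)))

  dir <- withr::local_tempdir()
  paths <- writeBundle(b1, dir)
  m <- readMatrixTSV(paths["interaction"])
  expect_equal(m, as.matrix(b1@interaction))
  im <- buildInteractionMatrix(readAssociationPairs(paths["pairs"]))
  expect_equal(sum(as.matrix(im)), sum(as.matrix(b1@interaction)))
  h <- readHierarchy(paths["hierarchy"])
  expect_identical(hierarchyRecords(h), hierarchyRecords(b1@hierarchy))
})

test_that("label noise flips the stated fraction of cells", {
  spec0 <- syntheticSpec(nDiseases = 20, nLncrnas = 40, nClusters = 4,
                         pIn = 1, pOut = 0, seed = 9)
  specN <- syntheticSpec(nDiseases = 20, nLncrnas = 40, nClusters = 4,
                         pIn = 1, pOut = 0, noiseRate = 0.1, seed = 9)
  m0 <- as.matrix(generateBundle(spec0)@interaction)
  mN <- as.matrix(generateBundle(specN)@interaction)
  flips <- sum(m0 != mN)
  expect_lt(abs(flips - 0.1 * length(m0)), 3 * sqrt(length(m0) * 0.1 * 0.9))
})
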