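test_that("fusion averages semantics and falls back to the kernel", {
  nm <- list(c("a", "b"), c("a", "b"))
  s1 <- matrix(c(1, 0.4, 0.4, 1), 2, 2, dimnames = nm)
  s2 <- matrix(c(1, 0.6, 0.6, 1), 2, 2, dimnames = nm)
  gp <- matrix(c(1, 0.9, 0.9, 1), 2, 2, dimnames = nm)
  f <- fuseSimilarity(s1, s2, gp)
  expect_equal(f["a", "b"], 0.5)           # semantic wins
  s1["a", "b"] <- s1["b", "a"] <- 0
  s2["a", "b"] <- s2["b", "a"] <- 0
  f <- fuseSimilarity(s1, s2, gp)
  expect_equal(f["a", "b"], 0.9)           # kernel fallback
  expect_equal(unname(diag(f)), c(1, 1))
  expect_error(fuseSimilarity(s1, s2, matrix(0, 3, 3)), "share a shape")
})

test_that("layout presets cover the 15 documented networks", {
  p <- layoutPresets()
  expect_length(p, 15)
  expect_setequal(p$FHN, c("DISSS", "LNCFS", "LNCGS", "DISGS", "LNCDIS"))
  expect_equal(sum(startsWith(names(p), "THN")), 4)
  expect_equal(sum(startsWith(names(p), "TriHN")), 6)
  expect_equal(sum(startsWith(names(p), "DHN")), 4)
  expect_true(all(lengths(p[startsWith(names(p), "TriHN")]) == 3))
  expect_false(anyDuplicated(lapply(p, sort)) > 0)

  custom <- featureLayout(c("DISSS", "LNCDIS"))
  expect_equal(custom$name, "custom")
  expect_error(featureLayout("NOPE"))
})

test_that("negative sampling is reproducible and bounded", {
  m <- matrix(0, 3, 4, dimnames = list(paste0("d", 1:3), paste0("l", 1:4)))
  m[cbind(1:3, 1:3)] <- 1
  im <- new("InteractionMatrix", assoc = m)
  n1 <- sampleNegativePairs(im, 3, seed = 0)
  n2 <- sampleNegativePairs(im, 3, seed = 0)
  expect_identical(n1, n2)
  expect_equal(nrow(unique(n1[, 1:2])), 3)
  expect_true(all(m[cbind(n1$disease, n1$lncRNA)] == 0))
  nAll <- sampleNegativePairs(im, 9, seed = 1)
  expect_equal(nrow(nAll), 9)
  expect_error(sampleNegativePairs(im, 10, seed = 1), "only 9 zero entries")
})

test_that("balanced pair sets are half positive", {
  b <- tinyBundle()
  ps <- labeledPairSet(b@interaction, seed = 2)
  expect_equal(mean(ps$label), 0.5)
  expect_equal(sum(ps$label), sum(as.matrix(b@interaction)))
})

test_that("feature dimensions follow the layout", {
  set.seed(21)
  nd <- 4; nl <- 6
  m <- matrix(rbinom(nd * nl, 1, 0.2), nd, nl,
              dimnames = list(paste0("d", 1:nd), paste0("l", 1:nl)))
  m[1, 1] <- 1
  im <- new("InteractionMatrix", assoc = m)
  sym <- function(n) { s <- matrix(runif(n * n), n, n); s <- (s + t(s)) / 2
                       diag(s) <- 1; s }
  sims <- list(DISSS1 = sym(nd), DISSS2 = sym(nd), DISGS = sym(nd),
               LNCFS1 = sym(nl), LNCFS2 = sym(nl), LNCGS = sym(nl))
  pairs <- labeledPairSet(im, nNegatives = 5, seed = 1)

  fs <- assemblePairFeatures(pairs, "FHN", sims, im)
  expect_equal(ncol(pairFeatures(fs)), nd + nl + nl + nd)   # 20
  fs2 <- assemblePairFeatures(pairs, c("DISSS", "LNCFS"), sims, im)
  expect_equal(ncol(pairFeatures(fs2)), nd + nl)            # 10
  fs3 <- assemblePairFeatures(pairs, "FHN", sims, im,
                              interactionBlocks = "disease_row")
  expect_equal(ncol(pairFeatures(fs3)), nd + nl + nl)
  for (lay in names(layoutPresets())) {
    f <- assemblePairFeatures(pairs, lay, sims, im)
    blocks <- layoutPresets()[[lay]]
    dSide <- if (any(c("DISSS", "DISGS") %in% blocks)) nd else 0
    lSide <- if (any(c("LNCFS", "LNCGS") %in% blocks)) nl else 0
    inter <- if ("LNCDIS" %in% blocks) nd + nl else 0
    expect_equal(ncol(pairFeatures(f)), dSide + lSide + inter)
  }
  expect_error(assemblePairFeatures(pairs, "FHN", sims["DISSS1"], im),
               "layout needs matrix")
})

test_that("target masking removes the pair's own cell from its features", {
  b <- tinyBundle()
  im <- b@interaction
  m <- as.matrix(im)
  cfg <- tinyConfig()
  sims <- computeSimilarityMatrices(im, b@hierarchy, cfg)
  pos <- which(m == 1, arr.ind = TRUE)
  pairs <- data.frame(disease = pos[, 1], lncRNA = pos[, 2], label = 1L)
  fs <- assemblePairFeatures(pairs, "FHN", sims, im, maskTarget = TRUE)
  nd <- nrow(m); nl <- ncol(m)
  for (k in seq_len(min(nrow(pairs), 8))) {
    row <- pairFeatures(fs)[k, ]
    dBlock <- row[(nd + nl + 1):(nd + nl + nl)]      # interaction profile of d
    lBlock <- row[(nd + nl + nl + 1):(nd + nl + nl + nd)]
    expect_equal(unname(dBlock[pairs$lncRNA[k]]), 0)
    expect_equal(unname(lBlock[pairs$disease[k]]), 0)
    # exactly one fewer association than the raw profiles
    expect_equal(sum(dBlock), sum(m[pairs$disease[k], ]) - 1)
  }
  fsOff <- assemblePairFeatures(pairs, "FHN", sims, im, maskTarget = FALSE)
  k <- 1
  expect_equal(unname(pairFeatures(fsOff)[k, nd + nl + pairs$lncRNA[k]]), 1)
})
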