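test_that("cosine similarity matches hand values and the brute-force oracle", {
  v <- rbind(i1 = c(1, 0, 1), i2 = c(1, 1, 0), i3 = c(0, 2, 0),
             i4 = c(2, 0, 2))
  fm <- FeatureMatrix(v, c(1000, 1500, 2000), "protein")
  s <- similarityValues(cosineSimilarity(fm))
  expect_equal(s["i1", "i2"], 0.5)        # 1 / (sqrt(2) * sqrt(2))
  expect_equal(s["i1", "i3"], 0)          # orthogonal
  expect_equal(s["i1", "i4"], 1)          # parallel
  expect_equal(diag(s), setNames(rep(1, 4), rownames(v)))

  set.seed(5)
  fm2 <- randomFeatureMatrix(10, 20)
  s2 <- similarityValues(cosineSimilarity(fm2))
  expect_lt(max(abs(s2 - bfCosine(featureValues(fm2)))), 1e-12)
  expect_true(all(s2 >= 0 & s2 <= 1))
})

test_that("all-zero feature vectors get similarity 0 with a warning", {
  v <- rbind(i1 = c(1, 2), i2 = c(0, 0), i3 = c(2, 1))
  ## bypass the constructor's zero-column guard by keeping columns nonzero
  fm <- FeatureMatrix(v, c(1000, 1200), "sm")
  expect_warning(s <- cosineSimilarity(fm), "all-zero")
  sv <- similarityValues(s)
  expect_equal(sv["i2", "i1"], 0)
  expect_equal(sv["i2", "i2"], 1)
})

test_that("Ward linkage reproduces base cases and the exhaustive ESS oracle", {
  ## two isolates at dissimilarity 0.4 merge at height 0.4
  s2 <- new("SimilarityMatrix",
            values = matrix(c(1, 0.6, 0.6, 1), 2, 2,
                            dimnames = list(c("a", "b"), c("a", "b"))),
            msMode = "protein")
  d2 <- wardDendrogram(s2)
  expect_equal(mergeHeights(d2), 0.4)

  ## three identical isolates: both merges at height 0
  s3 <- new("SimilarityMatrix",
            values = matrix(1, 3, 3, dimnames = list(letters[1:3],
                                                     letters[1:3])),
            msMode = "protein")
  expect_equal(mergeHeights(wardDendrogram(s3)), c(0, 0))

  ## exhaustive naive Ward (recompute ESS increase for every candidate
  ## merge) agrees on merge sequence and heights for n <= 7
  for (trial in 1:12) {
    set.seed(400 + trial)
    n <- sample(4:7, 1)
    fm <- randomFeatureMatrix(n, 12)
    s <- cosineSimilarity(fm)
    D <- 1 - similarityValues(s)
    d <- wardDendrogram(s)
    bf <- bfWard(D)
    expect_equal(mergeHeights(d), bf$heights, tolerance = 1e-9)
    mine <- dendMergeSets(d)
    for (k in seq_along(mine)) expect_identical(mine[[k]], bf$merges[[k]])
  }
})

test_that("Ward agrees with stats::hclust ward.D2 and is order-invariant", {
  set.seed(17)
  fm <- randomFeatureMatrix(15, 30)
  s <- cosineSimilarity(fm)
  d <- wardDendrogram(s)
  hc <- stats::hclust(stats::as.dist(1 - similarityValues(s)),
                      method = "ward.D2")
  expect_equal(sort(mergeHeights(d)), sort(hc$height), tolerance = 1e-9)
  ## monotone heights
  expect_true(all(diff(mergeHeights(d)) >= -1e-12))
  ## permuting input rows changes nothing
  perm <- sample(nrow(featureValues(fm)))
  v <- featureValues(fm)[perm, , drop = FALSE]
  dPerm <- wardDendrogram(cosineSimilarity(
    FeatureMatrix(v, binMz(fm), "protein")))
  expect_equal(mergeHeights(dPerm), mergeHeights(d))
  expect_identical(toNewick(dPerm), toNewick(d))
})

test_that("matched-plate filtering removes counterpart plates symmetrically", {
  meta <- rbind(
    metaFor(c("a1", "a2"), c("A", "A")),
    metaFor(c("b1", "b2"), c("B", "B")),
    data.frame(isolate_id = c("a3", "b3"), source = c("A", "B"),
               plate_id = c("A_M2_heat_d10", "B_M2_heat_d10"), media = "M2",
               pretreatment = "heat", dilution = "1/10"))
  ## excluding the A-side plate of the (M2, heat, 1/10) condition also
  ## removes its B-side counterpart
  keep <- matchedPlateFilter(meta, "A_M2_heat_d10")
  expect_setequal(keep, c("a1", "a2", "b1", "b2"))
  ## no exclusions: identity
  expect_setequal(matchedPlateFilter(meta), meta$isolate_id)
  ## a plate without a counterpart warns and its isolates are retained
  lonely <- rbind(meta,
                  data.frame(isolate_id = "a9", source = "A",
                             plate_id = "A_M9_heat_d100", media = "M9",
                             pretreatment = "heat", dilution = "1/100"))
  expect_warning(keep2 <- matchedPlateFilter(lonely, "A_M2_heat_d10"),
                 "counterpart")
  expect_true("a9" %in% keep2)
})

test_that("pruning preserves heights and commutes with cutting", {
  sim <- simulateDataset(simConfig(nGenera = 2L, isolatesPerStrain = 2L),
                         seed = 31)
  d <- wardDendrogram(cosineSimilarity(proteinMatrix(sim)))
  ## prune nothing: identical tree
  expect_identical(toNewick(pruneDendrogram(d, isolateIds(d))), toNewick(d))
  ## 3-leaf hand case: drop one leaf of a cherry, survivors keep their
  ## original join height
  v <- rbind(x = c(10, 0, 0.2), y = c(10, 0.3, 0), z = c(0, 5, 5))
  d3 <- wardDendrogram(cosineSimilarity(FeatureMatrix(v, c(1, 2, 3) * 1000,
                                                      "protein")))
  coph <- as.matrix(stats::cophenetic(asHclust(d3)))
  p3 <- pruneDendrogram(d3, c("x", "z"))
  expect_equal(mergeHeights(p3), coph["x", "z"])
  ## property: cut(prune(d, keep), h) == restrict(cut(d, h), keep)
  set.seed(8)
  for (trial in 1:3) {
    keep <- sort(sample(isolateIds(d), 20))
    pd <- pruneDendrogram(d, keep)
    for (h in seq(0.05, max(mergeHeights(d)) + 0.1, length.out = 12)) {
      a <- groupAssignments(cutDendrogram(pd, h))[keep]
      b <- groupAssignments(cutDendrogram(d, h))[keep]
      expect_equal(mclust::adjustedRandIndex(a, b), 1)
    }
  }
  expect_error(pruneDendrogram(d, isolateIds(d)[1]), "at least 2")
  expect_error(pruneDendrogram(d, c(isolateIds(d)[1], "ghost")), "not in")
})

test_that("cutting obeys the boundary and counting identities", {
  set.seed(12)
  fm <- randomFeatureMatrix(12, 25)
  d <- wardDendrogram(cosineSimilarity(fm))
  n <- nLeaves(d)
  ## h = 0 below the first merge: all singletons
  expect_identical(nGroups(cutDendrogram(d, 0)), n)
  ## h at or above the top merge: one group
  expect_identical(nGroups(cutDendrogram(d, max(mergeHeights(d)))), 1L)
  ## counting identity: #groups at h = n - #(merges with height <= h)
  for (h in seq(0, max(mergeHeights(d)) + 0.2, length.out = 25))
    expect_identical(nGroups(cutDendrogram(d, h)),
                     n - sum(mergeHeights(d) <= h))
  ## groups are named after their smallest member
  p <- cutDendrogram(d, max(mergeHeights(d)) / 2)
  a <- groupAssignments(p)
  for (g in unique(a)) expect_identical(min(names(a)[a == g]), g)
})

test_that("k-means recovers well-separated clusters and is deterministic", {
  set.seed(2)
  v <- rbind(matrix(rep(c(9, 0, 0, 9), each = 8), 8) + runif(32, 0, 0.3),
             matrix(rep(c(0, 9, 9, 0), each = 8), 8) + runif(32, 0, 0.3))
  rownames(v) <- sprintf("i%02d", 1:16)
  fm <- FeatureMatrix(v, c(1, 2, 3, 4) * 1000, "protein")
  truthLab <- rep(c("c1", "c2"), each = 8)
  p <- kmeansPartition(fm, k = 2, seed = 7)
  expect_equal(mclust::adjustedRandIndex(groupAssignments(p), truthLab), 1)
  ## determinism under the same seed
  p2 <- kmeansPartition(fm, k = 2, seed = 7)
  expect_identical(groupAssignments(p), groupAssignments(p2))
  ## k = n gives singleton clusters (inertia 0)
  pk <- kmeansPartition(fm, k = 16, seed = 7)
  expect_identical(nGroups(pk), 16L)
  expect_error(kmeansPartition(fm, k = 0), "k must be")
  expect_error(kmeansPartition(fm, k = 17), "exceeds")
})

test_that("Newick serialization is canonical and parseable by ape", {
  s2 <- new("SimilarityMatrix",
            values = matrix(c(1, 0.6, 0.6, 1), 2, 2,
                            dimnames = list(c("b", "a"), c("b", "a"))),
            msMode = "protein")
  expect_identical(toNewick(wardDendrogram(s2)), "(a:0.4,b:0.4);")

  set.seed(23)
  fm <- randomFeatureMatrix(9, 18)
  d <- wardDendrogram(cosineSimilarity(fm))
  tr <- ape::read.tree(text = toNewick(d))
  expect_setequal(tr$tip.label, isolateIds(d))
  ## leaf-to-leaf path length in the tree is twice the merge height
  coph <- as.matrix(stats::cophenetic(asHclust(d)))
  ids <- rownames(coph)
  expect_equal(ape::cophenetic.phylo(tr)[ids, ids] / 2, coph,
               tolerance = 1e-8)
})
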