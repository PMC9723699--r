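smFixture <- function() {
  ## X produces m1,m2; Y produces m2,m3; Z nothing
  v <- rbind(X = c(3, 1, 0), Y = c(0, 2, 5), Z = c(0, 0, 0))
  FeatureMatrix(v, c(400, 900, 1500), "sm")
}

test_that("MAN construction mirrors the positive cells exactly", {
  man <- buildMan(smFixture(), c("X", "Y"))
  g <- manGraph(man)
  expect_setequal(isolateNodes(man), c("X", "Y"))
  expect_equal(sort(featureNodes(man)), c(400, 900, 1500))
  el <- apply(igraph::as_edgelist(g), 1, paste, collapse = "-")
  expect_setequal(el, c("X-mz_400.0000", "X-mz_900.0000",
                        "Y-mz_900.0000", "Y-mz_1500.0000"))
  expect_true(validObject(man))

  ## isolate with no SM peaks: isolated node of degree 0, and features
  ## absent from the subset are dropped
  man2 <- buildMan(smFixture(), c("X", "Z"))
  expect_equal(unname(igraph::degree(manGraph(man2))[["Z"]]), 0)
  expect_equal(sort(featureNodes(man2)), c(400, 900))
  expect_error(buildMan(smFixture(), character(0)), "empty")
  expect_error(buildMan(smFixture(), "W"), "not in SM matrix")
})

test_that("random presence matrices give edge sets equal to positive cells", {
  set.seed(9)
  v <- matrix(rbinom(20 * 50, 1, 0.2) * runif(1000), 20, 50)
  v[1, colSums(v) == 0] <- 1  # no all-zero bins
  rownames(v) <- sprintf("i%02d", 1:20)
  fm <- FeatureMatrix(v, sort(runif(50, 200, 2000)), "sm")
  man <- buildMan(fm)
  expect_equal(igraph::ecount(manGraph(man)), sum(v > 0))
  ## connectivity through a feature iff presence dot product positive
  stats <- sharedFeatureStats(man)
  pres <- (v > 0) * 1L
  dot <- tcrossprod(pres)
  for (r in sample(nrow(stats$pairs), 50)) {
    i <- stats$pairs$isolate_1[r]; j <- stats$pairs$isolate_2[r]
    expect_equal(stats$pairs$shared_features[r], dot[i, j])
  }
})

test_that("partition coloring touches attributes, never topology", {
  man <- buildMan(smFixture(), c("X", "Y"))
  p2 <- new("IsolatePartition",
            assignments = c(X = "X", Y = "Y"), method = "cut", parameter = 1)
  colored <- colorByPartition(man, p2)
  cols <- igraph::vertex_attr(manGraph(colored), "group_color")
  kind <- igraph::vertex_attr(manGraph(colored), "kind")
  expect_identical(length(unique(cols[kind == "isolate"])), 2L)
  expect_true(all(is.na(cols[kind == "feature"])))
  expect_true(all(grepl("^#", cols[kind == "isolate"])))
  ## single group: one color
  p1 <- new("IsolatePartition", assignments = c(X = "X", Y = "X"),
            method = "cut", parameter = 9)
  one <- colorByPartition(man, p1)
  expect_identical(length(unique(igraph::vertex_attr(manGraph(one),
                                                     "group_color")[
    igraph::vertex_attr(manGraph(one), "kind") == "isolate"])), 1L)
  ## recoloring preserves the edge set exactly
  expect_identical(igraph::as_edgelist(manGraph(colored)),
                   igraph::as_edgelist(manGraph(man)))
  ## uncovered isolate is an error naming it
  expect_error(colorByPartition(man, p1Sub <- new("IsolatePartition",
                                                  assignments = c(X = "X"),
                                                  method = "cut",
                                                  parameter = 1)), "Y")
})

test_that("five groups get five distinct colors", {
  set.seed(13)
  v <- matrix(runif(10 * 8), 10, 8)
  rownames(v) <- sprintf("i%02d", 1:10)
  fm <- FeatureMatrix(v, sort(runif(8, 200, 2000)), "sm")
  p <- new("IsolatePartition",
           assignments = setNames(rep(sprintf("g%d", 1:5), each = 2),
                                  rownames(v)),
           method = "cut", parameter = 2)
  man <- colorByPartition(buildMan(fm), p)
  cols <- igraph::vertex_attr(manGraph(man), "group_color")
  kind <- igraph::vertex_attr(manGraph(man), "kind")
  expect_identical(length(unique(cols[kind == "isolate"])), 5L)
})

test_that("shared-feature statistics expose specificity", {
  man <- buildMan(smFixture(), c("X", "Y"))
  p <- new("IsolatePartition", assignments = c(X = "gx", Y = "gy"),
           method = "cut", parameter = 1)
  stats <- sharedFeatureStats(colorByPartition(man, p))
  expect_equal(stats$pairs$shared_features, 1)  # only m2 shared
  f <- stats$features
  expect_identical(f$n_groups[f$feature == "mz_900.0000"], 2L)
  expect_identical(f$n_groups[f$feature == "mz_400.0000"], 1L)
})

test_that("GraphML export round-trips the network", {
  man <- colorByPartition(
    buildMan(smFixture(), c("X", "Y"),
             meta = metaFor(c("X", "Y"), c("A", "B"))),
    new("IsolatePartition", assignments = c(X = "X", Y = "Y"),
        method = "cut", parameter = 1))
  path <- withr::local_tempfile(fileext = ".graphml")
  exportGraphml(man, path)
  back <- readGraphml(path)
  elA <- apply(igraph::as_edgelist(manGraph(man)), 1, paste, collapse = "-")
  elB <- apply(igraph::as_edgelist(manGraph(back)), 1, paste, collapse = "-")
  expect_setequal(elA, elB)
  expect_equal(igraph::vcount(manGraph(back)),
               length(isolateNodes(man)) + length(featureNodes(man)))
  expect_setequal(igraph::vertex_attr(manGraph(back), "source")[
    igraph::vertex_attr(manGraph(back), "kind") == "isolate"], c("A", "B"))

  ## a MAN with no features still exports its isolate nodes
  fmzz <- FeatureMatrix(matrix(c(1, 0), 2, 1,
                               dimnames = list(c("X", "Z"), NULL)),
                        500, "sm")
  manOnlyZ <- buildMan(fmzz, "Z")
  expect_identical(length(featureNodes(manOnlyZ)), 0L)
  path2 <- withr::local_tempfile(fileext = ".graphml")
  exportGraphml(manOnlyZ, path2)
  expect_equal(igraph::vcount(manGraph(readGraphml(path2))), 1)
})

test_that("with species in both hosts, feature sharing shows no host effect", {
  ## all species occupy both hosts and chemotype follows taxonomy only, so
  ## within-host and between-host shared-feature counts should agree
  cfg <- simConfig(hostModel = c(aOnly = 0, bOnly = 0, both = 1),
                   coupling = 1)
  sim <- simulateDataset(cfg, seed = 51)
  fmSm <- smMatrix(sim)
  iso <- sim$truth$isolates
  pres <- (featureValues(fmSm) > 0) * 1L
  shared <- tcrossprod(pres)
  ids <- rownames(pres)
  src <- iso$source[match(ids, iso$isolate_id)]
  gen <- iso$genus[match(ids, iso$isolate_id)]
  within <- c(); between <- c()
  for (g in unique(gen)) {
    sel <- which(gen == g)
    for (i in sel) for (j in sel) {
      if (i >= j) next
      if (src[i] == src[j]) within <- c(within, shared[i, j])
      else between <- c(between, shared[i, j])
    }
  }
  expect_lt(abs(mean(within) - mean(between)) / mean(c(within, between)),
            0.10)
})
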