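## Independent brute-force oracles and small fixture builders used across
## the suite. These deliberately avoid the package's own code paths.

## naive double-loop cosine similarity
bfCosine <- function(v) {
  n <- nrow(v)
  out <- matrix(0, n, n, dimnames = list(rownames(v), rownames(v)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    ni <- sqrt(sum(v[i, ]^2)); nj <- sqrt(sum(v[j, ]^2))
    out[i, j] <- if (ni == 0 || nj == 0) {
      if (i == j) 1 else 0
    } else sum(v[i, ] * v[j, ]) / (ni * nj)
  }
  diag(out) <- 1
  out
}

## exhaustive Ward: at each step recompute, for every candidate pair, the
## increase in within-cluster sum of squares from the original pairwise
## distances (centroid formula), merge the minimum; height = sqrt(2 * cost).
bfWard <- function(D) {
  n <- nrow(D)
  D2 <- D^2
  clusters <- lapply(seq_len(n), identity)
  merges <- list()
  heights <- numeric(0)
  while (length(clusters) > 1L) {
    best <- NULL; bestCost <- Inf
    for (a in seq_along(clusters)) for (b in seq_along(clusters)) {
      if (a >= b) next
      A <- clusters[[a]]; B <- clusters[[b]]
      na <- length(A); nb <- length(B)
      CAB <- sum(D2[A, B, drop = FALSE])
      WA <- if (na > 1) sum(D2[A, A]) / 2 else 0
      WB <- if (nb > 1) sum(D2[B, B]) / 2 else 0
      cen2 <- CAB / (na * nb) - WA / na^2 - WB / nb^2
      cost <- (na * nb / (na + nb)) * cen2
      if (cost < bestCost - 1e-12) {
        bestCost <- cost; best <- c(a, b)
      } else if (abs(cost - bestCost) <= 1e-12 && !is.null(best)) {
        cur <- c(min(clusters[[best[1]]]), min(clusters[[best[2]]]))
        cand <- c(min(A), min(B))
        if (cand[1] < cur[1] || (cand[1] == cur[1] && cand[2] < cur[2]))
          best <- c(a, b)
      }
    }
    merges[[length(merges) + 1L]] <-
      sort(c(clusters[[best[1]]], clusters[[best[2]]]))
    heights <- c(heights, sqrt(2 * max(bestCost, 0)))
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters <- clusters[-best[2]]
  }
  list(merges = merges, heights = heights)
}

## merged leaf-index set per step of a SpectraDendrogram (labels assumed to
## be in lexicographic order so leaf index == label rank)
dendMergeSets <- function(d) {
  m <- d@merge
  sets <- list()
  out <- list()
  for (k in seq_len(nrow(m))) {
    get <- function(nd) if (nd < 0) -nd else sets[[nd]]
    out[[k]] <- sort(c(get(m[k, 1]), get(m[k, 2])))
    sets[[k]] <- out[[k]]
  }
  out
}

## transitive-closure grouping oracle: union peaks whose pairwise gap is
## within tolerance of their mean m/z; returns number of groups and group
## index per (sorted) peak
bfTransitiveBins <- function(mz, tolerance) {
  n <- length(mz)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j && abs(mz[i] - mz[j]) <= tolerance * mean(c(mz[i], mz[j]))) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[rj] <- ri
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

## exhaustive composition tally
bfTally <- function(groups, sources) {
  gs <- unique(groups)
  a <- b <- both <- 0L
  ia <- ib <- iboth <- 0L
  for (g in gs) {
    mem <- sources[groups == g]
    hasA <- any(mem == "A"); hasB <- any(mem == "B")
    if (hasA && hasB) { both <- both + 1L; iboth <- iboth + length(mem) }
    else if (hasA) { a <- a + 1L; ia <- ia + length(mem) }
    else { b <- b + 1L; ib <- ib + length(mem) }
  }
  list(n_groups = length(gs), groups_A_only = a, groups_B_only = b,
       groups_both = both, isolates_A_only = ia, isolates_B_only = ib,
       isolates_both = iboth)
}

## a chain dendrogram with prescribed (sorted) merge heights; labels get
## alternating A/B-flavoured ids via the accompanying metadata builder
chainDendrogram <- function(heights, labels = NULL) {
  n <- length(heights) + 1L
  if (is.null(labels)) labels <- sprintf("iso%03d", seq_len(n))
  heights <- sort(heights)
  merge <- matrix(0L, n - 1L, 2L)
  merge[1L, ] <- c(-1L, -2L)
  if (n > 2L) for (k in 2:(n - 1L)) merge[k, ] <- c(k - 1L, -(k + 1L))
  new("SpectraDendrogram", merge = merge, height = heights,
      labels = labels, order = seq_len(n))
}

metaFor <- function(ids, sources = NULL) {
  if (is.null(sources))
    sources <- rep(c("A", "B"), length.out = length(ids))
  data.frame(isolate_id = ids, source = sources,
             plate_id = paste0(sources, "_M1_none_d0"), media = "M1",
             pretreatment = "none", dilution = "0",
             stringsAsFactors = FALSE)
}

## random non-negative feature matrix
randomFeatureMatrix <- function(n, p, mode = "protein", density = 0.5) {
  v <- matrix(runif(n * p) * (runif(n * p) < density), n, p)
  v[1, 1] <- v[1, 1] + 0.5  # guarantee no all-zero first column
  keep <- colSums(v) > 0
  v <- v[, keep, drop = FALSE]
  rownames(v) <- sprintf("i%03d", seq_len(n))
  FeatureMatrix(v, sort(runif(ncol(v), 1000, 2000)), mode)
}

## protein feature matrix from a simulated dataset with default params
proteinMatrix <- function(sim, params = preprocessParams()) {
  binPeaksReference(consensusByIsolate(sim$proteinPeaks, params),
                    params$binTolerance)
}

smMatrix <- function(sim, params = preprocessParams()) {
  binPeaksReference(consensusByIsolate(sim$smPeaks, params),
                    params$binTolerance)
}

readTsvForTest <- function(path)
  utils::read.delim(path, sep = "\t", comment.char = "#",
                    check.names = FALSE, stringsAsFactors = FALSE)

## best ARI over all cut heights of a dendrogram against reference labels
bestCutAri <- function(d, ref) {
  hs <- sort(unique(mergeHeights(d)))
  mids <- c(hs[1] / 2, (head(hs, -1) + tail(hs, -1)) / 2,
            max(hs) + 0.1)
  best <- -Inf; bestH <- NA_real_
  cm <- stats::cutree(asHclust(d), h = mids)
  if (is.null(dim(cm))) cm <- matrix(cm, ncol = 1)
  for (j in seq_len(ncol(cm))) {
    ari <- mclust::adjustedRandIndex(cm[names(ref), j], ref)
    if (ari > best) { best <- ari; bestH <- mids[j] }
  }
  list(ari = best, h = bestH)
}
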