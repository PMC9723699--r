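## Spectrum similarity, Ward dendrogram construction, matched-plate
## filtering, pruning, cutting, and the k-means robustness check.

#' @describeIn cosineSimilarity cosine similarity of a feature matrix.
#'
#' For non-negative feature vectors the similarity lies in \[0, 1\]:
#' `s_ij = <v_i, v_j> / (||v_i|| ||v_j||)`. Rows that are entirely zero
#' (isolates with no peaks) get similarity 0 to every other isolate and 1
#' to themselves, with a warning.
#'
#' @param presence use presence/absence (0/1) vectors instead of
#'   intensities.
#' @export
setMethod("cosineSimilarity", "FeatureMatrix", function(x, presence = FALSE) {
  v <- x@values
  if (nrow(v) < 2L) stop("need at least 2 isolates")
  if (presence) v <- (v > 0) * 1
  nrm <- sqrt(rowSums(v * v))
  zero <- nrm == 0
  if (any(zero))
    warning(sum(zero), " isolate(s) with all-zero feature vectors: ",
            paste(utils::head(rownames(v)[zero], 5), collapse = ", "),
            call. = FALSE)
  nrm[zero] <- 1
  u <- v / nrm
  s <- tcrossprod(u)
  s[zero, ] <- 0
  s[, zero] <- 0
  diag(s) <- 1
  s <- pmin(pmax((s + t(s)) / 2, 0), 1)  # symmetrize away rounding fuzz
  dimnames(s) <- list(rownames(v), rownames(v))
  new("SimilarityMatrix", values = s, msMode = x@msMode)
})

#' Ward dendrogram from a similarity matrix
#'
#' Agglomerative Ward clustering (ward.D2-style Lance-Williams recursion on
#' squared dissimilarities) on `d = 1 - s`. Isolates are first put in
#' lexicographic id order and ties in the merge criterion are broken by the
#' lexicographically smallest cluster pair, so the tree is bit-reproducible
#' and invariant to input row order. For two singletons at dissimilarity d
#' the merge height is d; heights are monotone non-decreasing.
#'
#' @param sim a [SimilarityMatrix-class] (or a plain symmetric
#'   dissimilarity matrix with dimnames when `isDissimilarity = TRUE`).
#' @param isDissimilarity interpret `sim` as a ready dissimilarity matrix.
#' @return a [SpectraDendrogram-class].
#' @export
wardDendrogram <- function(sim, isDissimilarity = FALSE) {
  if (is(sim, "SimilarityMatrix")) {
    D <- 1 - sim@values
  } else {
    D <- as.matrix(sim)
    if (!isDissimilarity) D <- 1 - D
  }
  if (is.null(rownames(D))) stop("isolate ids required as dimnames")
  if (nrow(D) != ncol(D) || max(abs(D - t(D))) > 1e-8)
    stop("input must be a symmetric matrix")
  labs <- rownames(D)
  o <- order(labs)
  D <- D[o, o]
  labs <- labs[o]
  n <- nrow(D)
  if (n < 2L) stop("need at least 2 isolates")
  Q <- D * D                      # squared dissimilarities, LW state
  diag(Q) <- Inf
  active <- rep(TRUE, n)
  size <- rep(1L, n)
  node <- -seq_len(n)             # hclust convention: negatives are leaves
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  for (k in seq_len(n - 1L)) {
    idx <- which.min(Q)           # column-major first minimum ==
    j <- (idx - 1L) %/% n + 1L    # lexicographically smallest (min, max)
    i <- idx - (j - 1L) * n       # pair among ties (Q is symmetric)
    a <- min(i, j); b <- max(i, j)
    qab <- Q[a, b]
    height[k] <- sqrt(max(qab, 0))
    pair <- sort(c(node[a], node[b]))
    merge[k, ] <- pair
    sa <- size[a]; sb <- size[b]
    l <- which(active); l <- l[l != a & l != b]
    if (length(l)) {
      newQ <- ((sa + size[l]) * Q[a, l] + (sb + size[l]) * Q[b, l] -
                 size[l] * qab) / (sa + sb + size[l])
      Q[a, l] <- newQ; Q[l, a] <- newQ
    }
    Q[b, ] <- Inf; Q[, b] <- Inf; Q[a, a] <- Inf
    active[b] <- FALSE
    size[a] <- sa + sb
    node[a] <- k
  }
  new("SpectraDendrogram", merge = merge, height = height, labels = labs,
      order = computeLeafOrder(merge, n))
}

## Leaf ordering for plotting: iterative left-to-right traversal.
computeLeafOrder <- function(merge, n) {
  if (n == 1L) return(1L)
  out <- integer(n); pos <- 0L
  stack <- nrow(merge)            # node indices; negative = leaf
  while (length(stack)) {
    top <- stack[length(stack)]
    stack <- stack[-length(stack)]
    if (top < 0L) {
      pos <- pos + 1L
      out[pos] <- -top
    } else {
      stack <- c(stack, merge[top, 2L], merge[top, 1L])
    }
  }
  out
}

#' @describeIn asHclust bridge to stats (cutree, cophenetic, plotting)
#' @export
setMethod("asHclust", "SpectraDendrogram", function(x) {
  structure(list(merge = x@merge, height = x@height, order = x@order,
                 labels = x@labels, method = "ward.D2",
                 call = match.call(), dist.method = "1 - cosine"),
            class = "hclust")
})

#' @describeIn cutDendrogram cut via connected components below `h`
#' @export
setMethod("cutDendrogram", "SpectraDendrogram", function(x, h) {
  stopifnot(h >= 0)
  hc <- asHclust(x)
  g <- stats::cutree(hc, h = h)
  ids <- canonicalGroupIds(stats::setNames(as.character(g), names(g)))
  new("IsolatePartition", assignments = ids, method = "cut", parameter = h)
})

#' Matched-plate filter
#'
#' When a diversity plate is excluded (e.g. overgrown by fungus), the plate
#' with matching conditions (media, pretreatment, dilution) from the other
#' source host is removed as well, so the two hosts stay directly
#' comparable. The returned keep set is symmetric by construction.
#'
#' @param meta metadata data.frame (see [readMetadata()]).
#' @param excludedPlates character vector of excluded plate ids (may be
#'   empty).
#' @return character vector of retained isolate ids, sorted.
#' @export
matchedPlateFilter <- function(meta, excludedPlates = character(0)) {
  plates <- unique(meta[c("plate_id", "source", "media", "pretreatment",
                          "dilution")])
  key <- paste(plates$media, plates$pretreatment, plates$dilution, sep = "|")
  counts <- table(key)
  lonely <- key %in% names(counts)[counts < 2L]
  if (any(lonely))
    warning("plate(s) without a matched counterpart in the other source: ",
            paste(plates$plate_id[lonely], collapse = ", "),
            "; their isolates are retained unless explicitly excluded",
            call. = FALSE)
  unknown <- setdiff(excludedPlates, plates$plate_id)
  if (length(unknown))
    warning("excluded plate id(s) not present in metadata: ",
            paste(unknown, collapse = ", "), call. = FALSE)
  exKey <- key[plates$plate_id %in% excludedPlates]
  drop <- plates$plate_id[plates$plate_id %in% excludedPlates |
                            key %in% exKey]
  sort(meta$isolate_id[!meta$plate_id %in% drop])
}

#' Prune a dendrogram to a leaf subset
#'
#' Removes leaves outside `keep` while leaving all surviving merge heights
#' unchanged (pruning the tree, not re-clustering): internal nodes left with
#' a single child are contracted. Implemented exactly via the tree's
#' cophenetic (ultrametric) matrix restricted to `keep`, from which the
#' pruned tree is reconstructed by single linkage; on an ultrametric matrix
#' this reproduces the restriction of the original tree, height for height.
#' Consequently `cutDendrogram(pruneDendrogram(d, keep), h)` equals the
#' restriction of `cutDendrogram(d, h)` to `keep` for every h.
#'
#' @param x a [SpectraDendrogram-class].
#' @param keep isolate ids to retain (>= 2, all present as leaves).
#' @return a [SpectraDendrogram-class] over `keep`.
#' @export
pruneDendrogram <- function(x, keep) {
  stopifnot(is(x, "SpectraDendrogram"))
  keep <- sort(unique(keep))
  missing <- setdiff(keep, x@labels)
  if (length(missing))
    stop("leaves not in dendrogram: ", paste(missing, collapse = ", "))
  if (length(keep) < 2L) stop("need at least 2 leaves to keep")
  if (length(keep) == length(x@labels)) return(x)
  coph <- as.matrix(stats::cophenetic(asHclust(x)))
  sub <- coph[keep, keep]
  hc <- stats::hclust(stats::as.dist(sub), method = "single")
  hts <- hc$height
  hts[hts < 0] <- 0
  new("SpectraDendrogram", merge = hc$merge, height = hts,
      labels = hc$labels, order = as.integer(hc$order))
}

#' k-means partition of a feature matrix
#'
#' Flat-clustering robustness check: rows are L2-normalized first so that
#' Euclidean k-means approximates cosine geometry, then `stats::kmeans` is
#' run with `nInit` restarts under a fixed seed (deterministic given the
#' seed).
#'
#' @param x a [FeatureMatrix-class].
#' @param k number of clusters (1 <= k <= number of isolates).
#' @param seed RNG seed.
#' @param nInit number of random restarts (best inertia kept).
#' @return an [IsolatePartition-class] with provenance
#'   `("kmeans", list(k, seed))`.
#' @export
kmeansPartition <- function(x, k, seed = 1L, nInit = 10L) {
  stopifnot(is(x, "FeatureMatrix"))
  v <- x@values
  if (k < 1L) stop("k must be >= 1")
  if (k > nrow(v)) stop("k exceeds the number of isolates")
  nrm <- sqrt(rowSums(v * v))
  nrm[nrm == 0] <- 1
  u <- v / nrm
  o <- order(rownames(u))
  u <- u[o, , drop = FALSE]
  if (k == nrow(u)) {
    ## degenerate: every isolate its own cluster (inertia 0);
    ## Hartigan-Wong does not accept k == n
    a <- stats::setNames(rownames(u), rownames(u))
    return(new("IsolatePartition", assignments = canonicalGroupIds(a),
               method = "kmeans", parameter = list(k = k, seed = seed)))
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  km <- stats::kmeans(u, centers = k, nstart = nInit, iter.max = 100L)
  a <- stats::setNames(as.character(km$cluster), rownames(u))
  new("IsolatePartition", assignments = canonicalGroupIds(a),
      method = "kmeans", parameter = list(k = k, seed = seed))
}

#' @describeIn toNewick canonical Newick serialization
#' @export
setMethod("toNewick", "SpectraDendrogram", function(x) {
  merge <- x@merge; height <- x@height; labs <- x@labels
  nm <- nrow(merge)
  ## smallest leaf label under each internal node, bottom-up (merges are
  ## ordered so children always precede parents)
  minLab <- character(nm)
  labOf <- function(nd) if (nd < 0L) labs[-nd] else minLab[nd]
  for (k in seq_len(nm))
    minLab[k] <- min(labOf(merge[k, 1L]), labOf(merge[k, 2L]))
  node_str <- function(nd, parentH) {
    if (nd < 0L) return(sprintf("%s:%.10g", labs[-nd], parentH))
    kids <- merge[nd, ]
    strs <- c(node_str(kids[1L], height[nd]), node_str(kids[2L], height[nd]))
    strs <- strs[order(c(labOf(kids[1L]), labOf(kids[2L])))]
    sprintf("(%s):%.10g", paste(strs, collapse = ","), parentH - height[nd])
  }
  kids <- merge[nm, ]
  strs <- c(node_str(kids[1L], height[nm]), node_str(kids[2L], height[nm]))
  strs <- strs[order(c(labOf(kids[1L]), labOf(kids[2L])))]
  paste0("(", paste(strs, collapse = ","), ");")
})
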