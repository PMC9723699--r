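## Phylotype-chemotype correlation: Pearson r between protein-spectrum and
## SM-spectrum similarities over unordered isolate pairs, per dendrogram
## group and globally, with an optional Mantel-style permutation null.

pairVectors <- function(pSim, smSim, ids) {
  P <- similarityValues(pSim)[ids, ids, drop = FALSE]
  S <- similarityValues(smSim)[ids, ids, drop = FALSE]
  ut <- upper.tri(P)
  list(protein = P[ut], sm = S[ut])
}

safePearson <- function(x, y) {
  if (length(x) < 2L || stats::sd(x) == 0 || stats::sd(y) == 0)
    return(NA_real_)  # undefined, reported distinctly rather than coerced to 0
  stats::cor(x, y, method = "pearson")
}

#' Per-group phylotype-chemotype correlation
#'
#' For every group of the partition with at least `minSize` isolates,
#' computes the Pearson correlation between protein similarity and SM
#' similarity over the group's unordered within-group isolate pairs
#' (n*(n-1)/2 pairs per group). Groups whose pair vectors have zero
#' variance get `NA` (undefined) rather than 0; groups below `minSize` are
#' skipped with a warning.
#'
#' @param proteinSim,smSim [SimilarityMatrix-class] objects covering the
#'   partition's isolates.
#' @param p an [IsolatePartition-class].
#' @param minSize smallest group analysed (default 3).
#' @return data.frame with group_id, n_isolates, n_pairs, pearson_r.
#' @export
pairwiseCorrelation <- function(proteinSim, smSim, p, minSize = 3L) {
  stopifnot(is(proteinSim, "SimilarityMatrix"), is(smSim, "SimilarityMatrix"),
            is(p, "IsolatePartition"))
  a <- groupAssignments(p)
  covered <- intersect(names(a), intersect(isolateIds(proteinSim),
                                           isolateIds(smSim)))
  if (length(covered) < length(a))
    stop("similarity matrices do not cover the partition")
  groups <- split(names(a), a)
  small <- names(groups)[lengths(groups) < minSize]
  if (length(small))
    warning(length(small), " group(s) below minSize skipped", call. = FALSE)
  groups <- groups[lengths(groups) >= minSize]
  rows <- lapply(names(groups), function(gid) {
    ids <- groups[[gid]]
    v <- pairVectors(proteinSim, smSim, ids)
    data.frame(group_id = gid, n_isolates = length(ids),
               n_pairs = length(v$protein),
               pearson_r = safePearson(v$protein, v$sm))
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(group_id = character(0), n_isolates = integer(0),
                      n_pairs = integer(0), pearson_r = numeric(0))
  rownames(out) <- NULL
  out[order(out$group_id), , drop = FALSE]
}

#' Global all-pairs phylotype-chemotype correlation
#'
#' Pearson r between protein and SM similarity over all unordered isolate
#' pairs shared by the two matrices.
#'
#' @param proteinSim,smSim [SimilarityMatrix-class] objects.
#' @return single numeric r (NA when undefined).
#' @export
globalPairCorrelation <- function(proteinSim, smSim) {
  ids <- intersect(isolateIds(proteinSim), isolateIds(smSim))
  if (length(ids) < 3L) stop("need >= 3 shared isolates")
  v <- pairVectors(proteinSim, smSim, sort(ids))
  safePearson(v$protein, v$sm)
}

#' Mantel-style permutation test for one group
#'
#' Permutation null for the observed within-group pair correlation:
#' isolate labels of the SM matrix are permuted `nPerm` times and
#' `p = (1 + #(r_perm >= r_obs)) / (1 + nPerm)` (one-sided, positive
#' association). Deterministic given `seed`.
#'
#' @param proteinSim,smSim [SimilarityMatrix-class] objects.
#' @param isolates isolate ids of the group (>= 4, else skipped with NA).
#' @param nPerm number of permutations (>= 99).
#' @param seed RNG seed.
#' @return list with `r` (observed), `p` (permutation p-value or NA) and
#'   `n_perm`.
#' @export
mantelPermutation <- function(proteinSim, smSim, isolates, nPerm = 999L,
                              seed = 1L) {
  if (nPerm < 99L) stop("nPerm must be >= 99")
  isolates <- sort(isolates)
  if (length(isolates) < 4L) {
    warning("group too small for a permutation test; skipped", call. = FALSE)
    return(list(r = NA_real_, p = NA_real_, n_perm = nPerm))
  }
  P <- similarityValues(proteinSim)[isolates, isolates]
  S <- similarityValues(smSim)[isolates, isolates]
  ut <- upper.tri(P)
  rObs <- safePearson(P[ut], S[ut])
  if (is.na(rObs)) return(list(r = NA_real_, p = NA_real_, n_perm = nPerm))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  n <- length(isolates)
  pv <- P[ut]
  ge <- 0L
  for (b in seq_len(nPerm)) {
    perm <- sample.int(n)
    Sp <- S[perm, perm]
    rp <- safePearson(pv, Sp[ut])
    if (!is.na(rp) && rp >= rObs) ge <- ge + 1L
  }
  list(r = rObs, p = (1 + ge) / (1 + nPerm), n_perm = nPerm)
}
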