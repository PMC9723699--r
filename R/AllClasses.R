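## Central S4 containers. Peak data are stored as plain data.frames inside
## validated classes; heavy numeric work happens on the matrix slots.

#' MaldiSpectrum: one raw acquisition
#'
#' A single profile-mode acquisition (m/z, intensity) for one isolate,
#' one biological replicate and one acquisition mode ("protein" for
#' linear-mode intact-protein spectra, "sm" for reflectron-mode
#' small-molecule spectra).
#'
#' @slot isolateId single isolate identifier.
#' @slot replicate biological replicate number (1-based).
#' @slot msMode `"protein"` or `"sm"`.
#' @slot mz strictly increasing m/z values (Da); may be empty.
#' @slot intensity non-negative abundances, same length as `mz`.
#' @export
setClass("MaldiSpectrum",
  representation(isolateId = "character", replicate = "integer",
                 msMode = "character", mz = "numeric", intensity = "numeric"))

setValidity("MaldiSpectrum", function(object) {
  msgs <- character()
  if (length(object@isolateId) != 1L) msgs <- c(msgs, "isolateId must be length 1")
  if (length(object@replicate) != 1L || object@replicate < 1L)
    msgs <- c(msgs, "replicate must be a single positive integer")
  if (!object@msMode %in% c("protein", "sm"))
    msgs <- c(msgs, "msMode must be 'protein' or 'sm'")
  if (length(object@mz) != length(object@intensity))
    msgs <- c(msgs, "mz and intensity differ in length")
  if (length(object@mz) > 1L && any(diff(object@mz) <= 0))
    msgs <- c(msgs, "mz must be strictly increasing")
  if (any(object@intensity < 0)) msgs <- c(msgs, "intensities must be >= 0")
  if (length(msgs)) msgs else TRUE
})

#' PeakSet: picked peaks for one or more acquisitions
#'
#' Picked-peak representation. The `peaks` slot is a data.frame with columns
#' `isolate_id`, `replicate`, `mz`, `intensity`, `snr`, canonically sorted by
#' (isolate_id, replicate, mz) so downstream results never depend on file
#' loading order. `snr = Inf` is the sentinel for "no SNR recorded"; such
#' peaks pass any SNR filter.
#'
#' @slot peaks data.frame of peaks (see Description).
#' @slot msMode `"protein"` or `"sm"`.
#' @export
setClass("PeakSet",
  representation(peaks = "data.frame", msMode = "character"))

setValidity("PeakSet", function(object) {
  need <- c("isolate_id", "replicate", "mz", "intensity", "snr")
  if (!all(need %in% names(object@peaks)))
    return(paste("peaks must have columns:", paste(need, collapse = ", ")))
  p <- object@peaks
  msgs <- character()
  if (!object@msMode %in% c("protein", "sm"))
    msgs <- c(msgs, "msMode must be 'protein' or 'sm'")
  if (nrow(p)) {
    if (any(p$intensity < 0)) msgs <- c(msgs, "intensities must be >= 0")
    if (any(p$snr < 0)) msgs <- c(msgs, "snr must be >= 0")
    key <- paste(p$isolate_id, p$replicate)
    mzsplit <- split(p$mz, key)
    if (any(vapply(mzsplit, function(z) any(diff(z) <= 0), logical(1))))
      msgs <- c(msgs, "mz must be strictly increasing within each (isolate, replicate)")
  }
  if (length(msgs)) msgs else TRUE
})

#' ConsensusPeakSet: replicate-consensus peaks for one isolate
#'
#' Peaks surviving replicate-presence filtering for one isolate and mode.
#' `peaks` has columns `mz` (intensity-weighted consensus m/z), `intensity`
#' (median across the replicates carrying the peak) and `presence_fraction`
#' (replicates carrying the peak over replicates present for the isolate).
#'
#' @slot isolateId isolate identifier.
#' @slot msMode `"protein"` or `"sm"`.
#' @slot peaks data.frame (see Description), mz strictly increasing.
#' @slot nReplicates number of replicates that were present for the isolate.
#' @export
setClass("ConsensusPeakSet",
  representation(isolateId = "character", msMode = "character",
                 peaks = "data.frame", nReplicates = "integer"))

setValidity("ConsensusPeakSet", function(object) {
  need <- c("mz", "intensity", "presence_fraction")
  if (!all(need %in% names(object@peaks)))
    return(paste("peaks must have columns:", paste(need, collapse = ", ")))
  p <- object@peaks
  msgs <- character()
  if (nrow(p) > 1L && any(diff(p$mz) <= 0))
    msgs <- c(msgs, "consensus mz must be strictly increasing")
  if (nrow(p) && (any(p$presence_fraction <= 0) || any(p$presence_fraction > 1)))
    msgs <- c(msgs, "presence_fraction must be in (0, 1]")
  if (length(msgs)) msgs else TRUE
})

#' FeatureMatrix: isolates x binned m/z features
#'
#' The input to all similarity computations: one row per isolate, one column
#' per m/z bin, cell values the (non-negative) summed consensus intensity of
#' the isolate's peaks falling in the bin; 0 means absent. Bin reference m/z
#' values are strictly increasing and no bin column is all zero.
#'
#' @slot values numeric matrix, rownames = isolate ids.
#' @slot bins strictly increasing bin reference m/z (Da), one per column.
#' @slot msMode `"protein"` or `"sm"`.
#' @export
setClass("FeatureMatrix",
  representation(values = "matrix", bins = "numeric", msMode = "character"))

setValidity("FeatureMatrix", function(object) {
  v <- object@values
  msgs <- character()
  if (ncol(v) != length(object@bins))
    msgs <- c(msgs, "one bin reference per column required")
  if (is.null(rownames(v)) && nrow(v) > 0)
    msgs <- c(msgs, "rownames must carry isolate ids")
  if (length(object@bins) > 1L && any(diff(object@bins) <= 0))
    msgs <- c(msgs, "bins must be strictly increasing")
  if (length(v) && any(v < 0)) msgs <- c(msgs, "values must be >= 0")
  if (nrow(v) > 0 && ncol(v) > 0 && any(colSums(v) == 0))
    msgs <- c(msgs, "all-zero bin columns are not allowed")
  if (!object@msMode %in% c("protein", "sm"))
    msgs <- c(msgs, "msMode must be 'protein' or 'sm'")
  if (length(msgs)) msgs else TRUE
})

#' SimilarityMatrix: pairwise cosine similarities
#'
#' Symmetric matrix of cosine similarities in \[0, 1\] between isolate
#' feature vectors. Rows/columns are named by isolate id; the diagonal is 1
#' for every isolate with at least one nonzero feature.
#'
#' @slot values symmetric numeric matrix with isolate-id dimnames.
#' @slot msMode `"protein"` or `"sm"`.
#' @export
setClass("SimilarityMatrix",
  representation(values = "matrix", msMode = "character"))

setValidity("SimilarityMatrix", function(object) {
  v <- object@values
  msgs <- character()
  if (nrow(v) != ncol(v)) msgs <- c(msgs, "matrix must be square")
  if (nrow(v) && is.null(rownames(v))) msgs <- c(msgs, "dimnames required")
  if (nrow(v) && max(abs(v - t(v))) > 1e-12)
    msgs <- c(msgs, "matrix must be symmetric within 1e-12")
  if (length(v) && (min(v) < -1e-12 || max(v) > 1 + 1e-12))
    msgs <- c(msgs, "similarities must lie in [0, 1]")
  if (length(msgs)) msgs else TRUE
})

#' SpectraDendrogram: agglomerative tree over isolates
#'
#' Ward dendrogram in hclust-compatible encoding: `merge` is the
#' (n-1) x 2 merge table (negative entries are leaves, positive entries
#' earlier merges), `height` the merge heights (non-decreasing, as Ward
#' linkage guarantees), `labels` the isolate ids and `order` a leaf ordering
#' for plotting. Convert with [asHclust()].
#'
#' @slot merge integer matrix of merges, hclust convention.
#' @slot height numeric merge heights (dissimilarity units).
#' @slot labels isolate ids, one per leaf.
#' @slot order integer leaf permutation.
#' @export
setClass("SpectraDendrogram",
  representation(merge = "matrix", height = "numeric",
                 labels = "character", order = "integer"))

setValidity("SpectraDendrogram", function(object) {
  n <- length(object@labels)
  msgs <- character()
  if (nrow(object@merge) != n - 1L)
    msgs <- c(msgs, "a tree over n leaves must have n - 1 merges")
  if (length(object@height) != n - 1L)
    msgs <- c(msgs, "one height per merge required")
  if (n > 2L && any(diff(object@height) < -1e-9))
    msgs <- c(msgs, "merge heights must be non-decreasing")
  if (anyDuplicated(object@labels)) msgs <- c(msgs, "leaf labels must be unique")
  if (length(msgs)) msgs else TRUE
})

#' IsolatePartition: flat grouping of isolates
#'
#' A partition of isolates into groups, from a dendrogram cut or from
#' k-means. Groups are identified by their smallest member isolate id so
#' reporting is stable across runs. Provenance (method and parameter) is
#' carried along.
#'
#' @slot assignments named character vector: isolate id -> group id.
#' @slot method `"cut"`, `"kmeans"`, or another provenance tag.
#' @slot parameter the defining parameter (cut height; k and seed; ...).
#' @export
setClass("IsolatePartition",
  representation(assignments = "character", method = "character",
                 parameter = "ANY"))

setValidity("IsolatePartition", function(object) {
  a <- object@assignments
  msgs <- character()
  if (length(a) && is.null(names(a))) msgs <- c(msgs, "assignments must be named by isolate id")
  if (anyDuplicated(names(a))) msgs <- c(msgs, "each isolate appears exactly once")
  if (length(a) && any(is.na(a))) msgs <- c(msgs, "every isolate must be assigned a group")
  if (length(msgs)) msgs else TRUE
})

#' MAN: metabolite association network
#'
#' Bipartite graph linking isolate nodes to the small-molecule mass-feature
#' nodes they produce. Isolate nodes carry `source` (host) and `group_color`
#' attributes; feature nodes carry their bin reference m/z. Strict
#' bipartiteness (no isolate-isolate or feature-feature edges) is enforced
#' by the validity method.
#'
#' @slot graph an igraph object with vertex attributes `kind`
#'   ("isolate"/"feature"), `type` (logical bipartite mapping), `mz`,
#'   `source`, `group_color`.
#' @export
setClass("MAN", representation(graph = "ANY"))

setValidity("MAN", function(object) {
  g <- object@graph
  if (!inherits(g, "igraph")) return("graph slot must hold an igraph object")
  kind <- igraph::vertex_attr(g, "kind")
  if (is.null(kind) || !all(kind %in% c("isolate", "feature")))
    return("every vertex needs kind 'isolate' or 'feature'")
  if (igraph::ecount(g) > 0) {
    el <- igraph::as_edgelist(g, names = FALSE)
    k1 <- kind[el[, 1]]; k2 <- kind[el[, 2]]
    if (any(k1 == k2)) return("MAN must be strictly bipartite")
  }
  TRUE
})
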