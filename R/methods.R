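## Accessor methods, constructors and show() methods.

#' @describeIn MaldiSpectrum isolate id
#' @param x object.
#' @export
setMethod("isolateIds", "MaldiSpectrum", function(x) x@isolateId)

#' @describeIn PeakSet isolate ids present
#' @param x object.
#' @export
setMethod("isolateIds", "PeakSet", function(x) unique(x@peaks$isolate_id))

#' @describeIn ConsensusPeakSet isolate id
#' @param x object.
#' @export
setMethod("isolateIds", "ConsensusPeakSet", function(x) x@isolateId)

#' @describeIn FeatureMatrix isolate ids (rownames)
#' @param x object.
#' @export
setMethod("isolateIds", "FeatureMatrix", function(x) rownames(x@values))

#' @describeIn SimilarityMatrix isolate ids
#' @param x object.
#' @export
setMethod("isolateIds", "SimilarityMatrix", function(x) rownames(x@values))

#' @describeIn SpectraDendrogram leaf labels
#' @param x object.
#' @export
setMethod("isolateIds", "SpectraDendrogram", function(x) x@labels)

#' @describeIn IsolatePartition isolate ids covered
#' @param x object.
#' @export
setMethod("isolateIds", "IsolatePartition", function(x) names(x@assignments))

setMethod("msMode", "MaldiSpectrum", function(x) x@msMode)
setMethod("msMode", "PeakSet", function(x) x@msMode)
setMethod("msMode", "ConsensusPeakSet", function(x) x@msMode)
setMethod("msMode", "FeatureMatrix", function(x) x@msMode)
setMethod("msMode", "SimilarityMatrix", function(x) x@msMode)

setMethod("peakTable", "PeakSet", function(x) x@peaks)
setMethod("peakTable", "ConsensusPeakSet", function(x) x@peaks)

setMethod("binMz", "FeatureMatrix", function(x) x@bins)
setMethod("featureValues", "FeatureMatrix", function(x) x@values)
setMethod("similarityValues", "SimilarityMatrix", function(x) x@values)

setMethod("nLeaves", "SpectraDendrogram", function(x) length(x@labels))
setMethod("mergeHeights", "SpectraDendrogram", function(x) x@height)

setMethod("groupAssignments", "IsolatePartition", function(x) x@assignments)
setMethod("nGroups", "IsolatePartition",
          function(x) length(unique(x@assignments)))

setMethod("manGraph", "MAN", function(x) x@graph)
setMethod("isolateNodes", "MAN", function(x) {
  g <- x@graph
  igraph::V(g)$name[igraph::vertex_attr(g, "kind") == "isolate"]
})
setMethod("featureNodes", "MAN", function(x) {
  g <- x@graph
  igraph::vertex_attr(g, "mz")[igraph::vertex_attr(g, "kind") == "feature"]
})

#' Construct a MaldiSpectrum
#'
#' @param isolateId,replicate,msMode,mz,intensity see [MaldiSpectrum-class].
#' @return a [MaldiSpectrum-class].
#' @export
MaldiSpectrum <- function(isolateId, replicate, msMode, mz, intensity) {
  new("MaldiSpectrum", isolateId = as.character(isolateId),
      replicate = as.integer(replicate), msMode = msMode,
      mz = as.numeric(mz), intensity = as.numeric(intensity))
}

#' Construct a PeakSet from a peak data.frame
#'
#' Rows are canonically sorted by (isolate_id, replicate, mz); a missing
#' `snr` column defaults to the `Inf` sentinel (passes any SNR filter).
#'
#' @param peaks data.frame with columns isolate_id, replicate, mz,
#'   intensity and optionally snr.
#' @param msMode `"protein"` or `"sm"`.
#' @return a [PeakSet-class].
#' @export
PeakSet <- function(peaks, msMode) {
  if (is.null(peaks$snr)) peaks$snr <- Inf
  peaks$isolate_id <- as.character(peaks$isolate_id)
  peaks$replicate <- as.integer(peaks$replicate)
  peaks <- peaks[order(peaks$isolate_id, peaks$replicate, peaks$mz),
                 c("isolate_id", "replicate", "mz", "intensity", "snr")]
  rownames(peaks) <- NULL
  new("PeakSet", peaks = peaks, msMode = msMode)
}

#' Construct a FeatureMatrix
#'
#' @param values numeric matrix (rownames = isolate ids).
#' @param bins strictly increasing bin reference m/z values.
#' @param msMode `"protein"` or `"sm"`.
#' @return a [FeatureMatrix-class].
#' @export
FeatureMatrix <- function(values, bins, msMode) {
  storage.mode(values) <- "double"
  colnames(values) <- sprintf("mz_%.6f", bins)
  new("FeatureMatrix", values = values, bins = as.numeric(bins), msMode = msMode)
}

#' Subset a FeatureMatrix by isolate
#'
#' Bins left with no positive value among the retained isolates are dropped,
#' preserving the no-all-zero-column invariant.
#'
#' @param x a [FeatureMatrix-class].
#' @param ids isolate ids to keep (must be present).
#' @param dropEmpty drop all-zero bin columns after subsetting (default TRUE).
#' @return a [FeatureMatrix-class].
#' @export
subsetIsolates <- function(x, ids, dropEmpty = TRUE) {
  stopifnot(is(x, "FeatureMatrix"))
  missing <- setdiff(ids, isolateIds(x))
  if (length(missing))
    stop("isolates not in matrix: ", paste(missing, collapse = ", "))
  v <- x@values[ids, , drop = FALSE]
  bins <- x@bins
  if (dropEmpty && nrow(v)) {
    keep <- colSums(v) > 0
    v <- v[, keep, drop = FALSE]
    bins <- bins[keep]
  }
  FeatureMatrix(v, bins, x@msMode)
}

setMethod("show", "MaldiSpectrum", function(object) {
  cat(sprintf("MaldiSpectrum %s rep %d [%s]: %d points", object@isolateId,
              object@replicate, object@msMode, length(object@mz)))
  if (length(object@mz))
    cat(sprintf(", m/z %.1f-%.1f", min(object@mz), max(object@mz)))
  cat("\n")
})

setMethod("show", "PeakSet", function(object) {
  p <- object@peaks
  cat(sprintf("PeakSet [%s]: %d peaks, %d isolates, %d acquisitions\n",
              object@msMode, nrow(p), length(unique(p$isolate_id)),
              nrow(unique(p[c("isolate_id", "replicate")]))))
})

setMethod("show", "ConsensusPeakSet", function(object) {
  cat(sprintf("ConsensusPeakSet %s [%s]: %d peaks from %d replicate(s)\n",
              object@isolateId, object@msMode, nrow(object@peaks),
              object@nReplicates))
})

setMethod("show", "FeatureMatrix", function(object) {
  cat(sprintf("FeatureMatrix [%s]: %d isolates x %d bins",
              object@msMode, nrow(object@values), ncol(object@values)))
  if (length(object@bins))
    cat(sprintf(" (%.1f-%.1f Da)", min(object@bins), max(object@bins)))
  cat(sprintf("; %.1f%% nonzero\n",
              if (length(object@values)) 100 * mean(object@values > 0) else 0))
})

setMethod("show", "SimilarityMatrix", function(object) {
  cat(sprintf("SimilarityMatrix [%s]: %d isolates, cosine in [%.3f, 1]\n",
              object@msMode, nrow(object@values),
              if (length(object@values)) min(object@values) else NA))
})

setMethod("show", "SpectraDendrogram", function(object) {
  cat(sprintf("SpectraDendrogram: %d leaves, merge heights %.3g-%.3g\n",
              length(object@labels), min(object@height), max(object@height)))
})

setMethod("show", "IsolatePartition", function(object) {
  cat(sprintf("IsolatePartition (%s): %d isolates in %d groups\n",
              paste(object@method, collapse = " "),
              length(object@assignments), nGroups(object)))
})

setMethod("show", "MAN", function(object) {
  g <- object@graph
  kind <- igraph::vertex_attr(g, "kind")
  cat(sprintf("MAN: %d isolate nodes, %d feature nodes, %d edges\n",
              sum(kind == "isolate"), sum(kind == "feature"),
              igraph::ecount(g)))
})
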