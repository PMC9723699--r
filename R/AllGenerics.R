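## Generics and accessors. Slots are never reached into from user code.

#' Isolate identifiers of an object
#' @param x a spectrotype object.
#' @return character vector of isolate ids.
#' @export
setGeneric("isolateIds", function(x) standardGeneric("isolateIds"))

#' Acquisition mode of an object
#' @param x a spectrotype object.
#' @return `"protein"` or `"sm"`.
#' @export
setGeneric("msMode", function(x) standardGeneric("msMode"))

#' Peak table of a peak-bearing object
#' @param x a [PeakSet-class] or [ConsensusPeakSet-class].
#' @return data.frame of peaks.
#' @export
setGeneric("peakTable", function(x) standardGeneric("peakTable"))

#' Bin reference m/z values of a feature matrix
#' @param x a [FeatureMatrix-class].
#' @return numeric vector of bin reference m/z (Da).
#' @export
setGeneric("binMz", function(x) standardGeneric("binMz"))

#' Numeric matrix of a feature matrix
#' @param x a [FeatureMatrix-class].
#' @return numeric matrix, isolates x bins.
#' @export
setGeneric("featureValues", function(x) standardGeneric("featureValues"))

#' Numeric matrix of a similarity matrix
#' @param x a [SimilarityMatrix-class].
#' @return symmetric numeric matrix.
#' @export
setGeneric("similarityValues", function(x) standardGeneric("similarityValues"))

#' Cosine similarity between isolate feature vectors
#'
#' @param x a [FeatureMatrix-class].
#' @param ... passed to methods; see [cosineSimilarity,FeatureMatrix-method].
#' @return a [SimilarityMatrix-class].
#' @export
setGeneric("cosineSimilarity", function(x, ...) standardGeneric("cosineSimilarity"))

#' Cut a dendrogram at a height
#'
#' @param x a [SpectraDendrogram-class].
#' @param h cut height (>= 0). Groups are the connected components after
#'   removing all merges strictly above `h`; below the first merge every
#'   leaf is its own group, at or above the last merge there is one group.
#' @return an [IsolatePartition-class] with provenance `("cut", h)`.
#' @export
setGeneric("cutDendrogram", function(x, h) standardGeneric("cutDendrogram"))

#' Serialize a dendrogram to Newick
#'
#' Branch lengths are height differences (leaf depth equals its merge
#' height); children are ordered by smallest leaf label, so any leaf-order
#' permutation of the input yields the identical string.
#'
#' @param x a [SpectraDendrogram-class].
#' @return single Newick string, semicolon-terminated.
#' @export
setGeneric("toNewick", function(x) standardGeneric("toNewick"))

#' Convert a SpectraDendrogram to a base-R hclust object
#' @param x a [SpectraDendrogram-class].
#' @return an object of class `hclust`.
#' @export
setGeneric("asHclust", function(x) standardGeneric("asHclust"))

#' Number of leaves of a dendrogram
#' @param x a [SpectraDendrogram-class].
#' @return integer.
#' @export
setGeneric("nLeaves", function(x) standardGeneric("nLeaves"))

#' Merge heights of a dendrogram
#' @param x a [SpectraDendrogram-class].
#' @return numeric vector of n - 1 non-decreasing heights.
#' @export
setGeneric("mergeHeights", function(x) standardGeneric("mergeHeights"))

#' Group assignments of a partition
#' @param x an [IsolatePartition-class].
#' @return named character vector, isolate id -> group id.
#' @export
setGeneric("groupAssignments", function(x) standardGeneric("groupAssignments"))

#' Number of groups in a partition
#' @param x an [IsolatePartition-class].
#' @return integer.
#' @export
setGeneric("nGroups", function(x) standardGeneric("nGroups"))

#' igraph object underlying a MAN
#' @param x a [MAN-class].
#' @return igraph object.
#' @export
setGeneric("manGraph", function(x) standardGeneric("manGraph"))

#' Isolate node names of a MAN
#' @param x a [MAN-class].
#' @return character vector.
#' @export
setGeneric("isolateNodes", function(x) standardGeneric("isolateNodes"))

#' Feature node m/z values of a MAN
#' @param x a [MAN-class].
#' @return numeric vector of bin reference m/z (Da).
#' @export
setGeneric("featureNodes", function(x) standardGeneric("featureNodes"))
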