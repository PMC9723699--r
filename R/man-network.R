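## Metabolite association networks: bipartite isolate-feature graphs built
## from small-molecule feature matrices. An edge exists iff the isolate's
## SM consensus set has a positive intensity in the feature's bin; edges are
## unweighted (the analysis is about shared mass features, not abundances).

featureNodeName <- function(mz) sprintf("mz_%.4f", mz)

#' Build a metabolite association network
#'
#' Creates the bipartite isolate-feature graph for a subset of isolates of
#' an SM feature matrix. A feature node is created only for bins with at
#' least one positive value among the selected isolates; an edge is added
#' for every positive cell. Isolates with no SM peaks become isolated
#' nodes of degree 0. MANs are typically built per dendrogram grouping
#' (genus-level subset); pass all isolates for a global network.
#'
#' @param smMatrix a [FeatureMatrix-class] of mode `"sm"`.
#' @param isolates isolate ids to include (default: all rows).
#' @param meta optional metadata data.frame; when given, isolate nodes get
#'   a `source` attribute.
#' @return a [MAN-class].
#' @export
buildMan <- function(smMatrix, isolates = NULL, meta = NULL) {
  stopifnot(is(smMatrix, "FeatureMatrix"))
  if (is.null(isolates)) isolates <- isolateIds(smMatrix)
  if (!length(isolates)) stop("empty isolate subset")
  missing <- setdiff(isolates, isolateIds(smMatrix))
  if (length(missing))
    stop("isolate(s) not in SM matrix: ", paste(missing, collapse = ", "))
  isolates <- sort(isolates)
  v <- featureValues(smMatrix)[isolates, , drop = FALSE]
  present <- colSums(v) > 0
  v <- v[, present, drop = FALSE]
  bins <- binMz(smMatrix)[present]
  featNames <- featureNodeName(bins)
  verts <- data.frame(
    name = c(isolates, featNames),
    kind = c(rep("isolate", length(isolates)),
             rep("feature", length(featNames))),
    type = c(rep(FALSE, length(isolates)), rep(TRUE, length(featNames))),
    mz = c(rep(NA_real_, length(isolates)), bins),
    stringsAsFactors = FALSE)
  verts$source <- NA_character_
  if (!is.null(meta)) {
    m <- match(verts$name, meta$isolate_id)
    verts$source <- ifelse(verts$kind == "isolate",
                           meta$source[m], NA_character_)
  }
  verts$group_color <- NA_character_
  pos <- which(v > 0, arr.ind = TRUE)
  edges <- data.frame(from = isolates[pos[, 1L]],
                      to = featNames[pos[, 2L]],
                      stringsAsFactors = FALSE)
  edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = verts)
  new("MAN", graph = g)
}

#' Color MAN isolate nodes by a partition
#'
#' Sets the `group` and `group_color` attributes of every isolate node from
#' the given partition (distinct hex colors per group, assigned in sorted
#' group-id order). Feature nodes stay uncolored; the topology is never
#' touched, so recoloring with a refined partition changes attributes only.
#'
#' @param man a [MAN-class].
#' @param p an [IsolatePartition-class] covering the MAN's isolates.
#' @return the recolored [MAN-class].
#' @export
colorByPartition <- function(man, p) {
  stopifnot(is(man, "MAN"), is(p, "IsolatePartition"))
  g <- man@graph
  iso <- isolateNodes(man)
  a <- groupAssignments(p)
  uncovered <- setdiff(iso, names(a))
  if (length(uncovered))
    stop("partition does not cover isolate(s): ",
         paste(uncovered, collapse = ", "))
  grp <- a[iso]
  lev <- sort(unique(grp))
  pal <- grDevices::hcl.colors(max(length(lev), 2L), palette = "Dark 3")
  pal <- substr(pal, 1, 7)[seq_along(lev)]
  vidx <- match(iso, igraph::V(g)$name)
  g <- igraph::set_vertex_attr(g, "group", index = vidx, value = unname(grp))
  g <- igraph::set_vertex_attr(g, "group_color", index = vidx,
                               value = pal[match(grp, lev)])
  new("MAN", graph = g)
}

#' Shared-feature statistics of a MAN
#'
#' For every isolate pair, the number of shared feature nodes (equal to the
#' dot product of the isolates' SM presence vectors); for every feature,
#' the set of partition groups its isolates span. A feature spanning a
#' single group is specific to that group -- these are the candidate
#' isolate-specific metabolites worth prioritizing.
#'
#' @param man a [MAN-class] (>= 2 isolates).
#' @return list with `pairs` (data.frame isolate_1, isolate_2,
#'   shared_features) and `features` (data.frame feature, mz, degree,
#'   n_groups, groups -- group columns NA when the MAN is uncolored).
#' @export
sharedFeatureStats <- function(man) {
  g <- man@graph
  iso <- isolateNodes(man)
  if (length(iso) < 2L) stop("need >= 2 isolates")
  featNames <- igraph::V(g)$name[igraph::vertex_attr(g, "kind") == "feature"]
  ## presence matrix isolates x features from the edge list
  el <- igraph::as_edgelist(g)
  isIsoFirst <- el[, 1L] %in% iso
  fromIso <- ifelse(isIsoFirst, el[, 1L], el[, 2L])
  toFeat <- ifelse(isIsoFirst, el[, 2L], el[, 1L])
  A <- matrix(0L, length(iso), length(featNames),
              dimnames = list(iso, featNames))
  if (nrow(el)) A[cbind(match(fromIso, iso), match(toFeat, featNames))] <- 1L
  shared <- tcrossprod(A)
  ut <- which(upper.tri(shared), arr.ind = TRUE)
  pairs <- data.frame(isolate_1 = iso[ut[, 1L]], isolate_2 = iso[ut[, 2L]],
                      shared_features = shared[ut])
  grp <- igraph::vertex_attr(g, "group") %||%
    rep(NA_character_, igraph::vcount(g))
  names(grp) <- igraph::V(g)$name
  nGrpSpanned <- vapply(featNames, function(f) {
    members <- fromIso[toFeat == f]
    gs <- grp[members]
    if (all(is.na(gs))) NA_integer_ else length(unique(gs[!is.na(gs)]))
  }, integer(1))
  groupsSpanned <- vapply(featNames, function(f) {
    members <- fromIso[toFeat == f]
    gs <- unique(grp[members])
    if (all(is.na(gs))) NA_character_ else paste(sort(gs), collapse = ",")
  }, character(1))
  feats <- data.frame(feature = featNames,
                      mz = igraph::vertex_attr(g, "mz")[
                        match(featNames, igraph::V(g)$name)],
                      degree = as.integer(colSums(A)),
                      n_groups = nGrpSpanned,
                      groups = groupsSpanned,
                      stringsAsFactors = FALSE)
  rownames(feats) <- NULL
  list(pairs = pairs, features = feats)
}

#' Export / import a MAN as GraphML
#'
#' Node attributes (`kind`, `type`, `mz`, `source`, `group`,
#' `group_color`) travel with the graph; node ordering is deterministic
#' (isolates sorted, then features by m/z).
#'
#' @param man a [MAN-class].
#' @param path file path.
#' @return `path` (write) or a [MAN-class] (read).
#' @export
exportGraphml <- function(man, path) {
  stopifnot(is(man, "MAN"))
  igraph::write_graph(man@graph, path, format = "graphml")
  invisible(path)
}

#' @rdname exportGraphml
#' @export
readGraphml <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  ## igraph stores 'name' as an attribute named 'name' already; kind/mz too
  new("MAN", graph = g)
}

#' Export a MAN edge list as TSV
#' @param man a [MAN-class].
#' @param path output path.
#' @param comment optional provenance line.
#' @return `path`, invisibly.
#' @export
writeManEdges <- function(man, path, comment = NULL) {
  el <- igraph::as_edgelist(man@graph)
  df <- data.frame(isolate = el[, 1L], feature = el[, 2L])
  writeTsv(df[order(df$isolate, df$feature), , drop = FALSE], path, comment)
}
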