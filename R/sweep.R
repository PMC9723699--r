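## The central statistic: cut the dendrogram on a height grid and tally,
## per cut, whether each phylotype group contains isolates from host A,
## host B, or both. The group-level "Both" proportion equals the Jaccard
## index of the two hosts' group sets.

## internal: tally one cut given group ids and source labels
tallyOne <- function(groups, sources, height = NA_real_) {
  tab <- table(groups, factor(sources, levels = c("A", "B")))
  hasA <- tab[, "A"] > 0
  hasB <- tab[, "B"] > 0
  sizes <- rowSums(tab)
  nG <- nrow(tab)
  gBoth <- sum(hasA & hasB)
  gA <- sum(hasA & !hasB)
  gB <- sum(hasB & !hasA)
  data.frame(height = height,
             n_groups = nG,
             groups_A_only = gA, groups_B_only = gB, groups_both = gBoth,
             prop_A_only = gA / nG, prop_B_only = gB / nG,
             prop_both = gBoth / nG,
             isolates_A_only = as.integer(sum(sizes[hasA & !hasB])),
             isolates_B_only = as.integer(sum(sizes[hasB & !hasA])),
             isolates_both = as.integer(sum(sizes[hasA & hasB])),
             jaccard = gBoth / sum(hasA | hasB))
}

sourcesFor <- function(p, meta) {
  ids <- isolateIds(p)
  src <- meta$source[match(ids, meta$isolate_id)]
  if (anyNA(src))
    stop("isolate(s) without source label: ",
         paste(utils::head(ids[is.na(src)], 5), collapse = ", "))
  bad <- setdiff(unique(src), c("A", "B"))
  if (length(bad)) stop("source labels must be 'A'/'B'; found: ",
                        paste(bad, collapse = ", "))
  src
}

#' Tally the host composition of a partition
#'
#' Classifies every group of the partition as A-only, B-only or Both by the
#' source hosts of its member isolates, and reports group-level counts and
#' proportions together with raw isolate counts per category (raw counts
#' matter because the number of groups shrinks as the cut height grows).
#'
#' @param p an [IsolatePartition-class].
#' @param meta metadata data.frame with `isolate_id` and `source`
#'   (`"A"`/`"B"`) columns covering the partition's isolates.
#' @param height optional height annotation copied into the result.
#' @return one-row data.frame with columns height, n_groups,
#'   groups_A_only/B_only/both, prop_A_only/B_only/both,
#'   isolates_A_only/B_only/both and jaccard.
#' @export
tallyComposition <- function(p, meta, height = NA_real_) {
  stopifnot(is(p, "IsolatePartition"))
  tallyOne(groupAssignments(p), sourcesFor(p, meta), height)
}

#' Jaccard overlap of the two hosts' group sets
#'
#' `J = |G_A intersect G_B| / |G_A union G_B|` where `G_X` is the set of
#' group ids containing at least one isolate from host X. Because every
#' group contains at least one isolate from A or B, `G_A union G_B` covers
#' all groups and J is identical to the proportion of groups classified
#' "Both" by [tallyComposition()].
#'
#' @inheritParams tallyComposition
#' @return Jaccard index in \[0, 1\].
#' @export
jaccardOfCut <- function(p, meta) {
  stopifnot(is(p, "IsolatePartition"))
  g <- groupAssignments(p)
  src <- sourcesFor(p, meta)
  gA <- unique(g[src == "A"])
  gB <- unique(g[src == "B"])
  length(intersect(gA, gB)) / length(union(gA, gB))
}

#' Cut-height sweep of a dendrogram
#'
#' Cuts the dendrogram at heights `step, 2*step, ...,
#' ceiling(maxHeight/step)*step` and tallies the host composition of every
#' cut. The grid starts at `step` (not 0) and its last point is at or above
#' the top merge, so the final cut always yields a single group; with
#' `step = 0.05` and a maximum height in (7.95, 8.00] the sweep has exactly
#' 160 cuts.
#'
#' @param d a [SpectraDendrogram-class].
#' @param meta metadata data.frame with `isolate_id` and `source`.
#' @param step grid step in dendrogram height units (> 0), default 0.05.
#' @return data.frame with one row per cut (columns as in
#'   [tallyComposition()]); the grid step is attached as attribute `step`.
#' @export
sweepDendrogram <- function(d, meta, step = 0.05) {
  stopifnot(is(d, "SpectraDendrogram"))
  if (step <= 0) stop("step must be > 0")
  maxH <- max(mergeHeights(d))
  nCuts <- max(1L, as.integer(ceiling(maxH / step - 1e-9)))
  heights <- step * seq_len(nCuts)
  hc <- asHclust(d)
  ids <- d@labels
  src <- meta$source[match(ids, meta$isolate_id)]
  if (anyNA(src))
    stop("isolate(s) without source label: ",
         paste(utils::head(ids[is.na(src)], 5), collapse = ", "))
  cutMat <- stats::cutree(hc, h = heights)
  if (is.null(dim(cutMat))) cutMat <- matrix(cutMat, ncol = 1L)
  rows <- lapply(seq_len(ncol(cutMat)), function(j)
    tallyOne(cutMat[, j], src, heights[j]))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "step") <- step
  out
}

#' Mean composition within height bands
#'
#' Averages the group-level composition proportions of a sweep over height
#' bands `(lo, hi]`, e.g. a species-level band (0, 2] and a genus-level
#' band (2.5, max]. Used to test the pattern that species-level groups are
#' mostly single-host while genus-level groups are shared.
#'
#' @param sweep data.frame from [sweepDendrogram()].
#' @param bands list of `c(lo, hi)` pairs.
#' @return data.frame with one row per non-empty band: lo, hi, n_cuts and
#'   the mean of prop_A_only, prop_B_only, prop_both and jaccard. Empty
#'   bands are skipped with a warning.
#' @export
summarizeBands <- function(sweep, bands) {
  stopifnot(is.data.frame(sweep), length(bands) >= 1L)
  rows <- lapply(bands, function(b) {
    sel <- sweep$height > b[1] & sweep$height <= b[2]
    if (!any(sel)) {
      warning(sprintf("band (%g, %g] contains no cuts; skipped", b[1], b[2]),
              call. = FALSE)
      return(NULL)
    }
    data.frame(lo = b[1], hi = b[2], n_cuts = sum(sel),
               mean_prop_A_only = mean(sweep$prop_A_only[sel]),
               mean_prop_B_only = mean(sweep$prop_B_only[sel]),
               mean_prop_both = mean(sweep$prop_both[sel]),
               mean_jaccard = mean(sweep$jaccard[sel]))
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame()
  rownames(out) <- NULL
  out
}

#' Plot a sweep's composition and raw-count curves
#'
#' Two-panel summary of a cut-height sweep: group-level proportions
#' (A-only / B-only / Both) and raw isolate counts per category as a
#' function of cut height.
#'
#' @param sweep data.frame from [sweepDendrogram()].
#' @param path optional output path (SVG/PNG decided by extension); when
#'   NULL the ggplot object is returned.
#' @return a ggplot object, invisibly when written to `path`.
#' @export
plotSweep <- function(sweep, path = NULL) {
  long <- rbind(
    data.frame(height = sweep$height, value = sweep$prop_A_only,
               category = "A only", panel = "proportion of groups"),
    data.frame(height = sweep$height, value = sweep$prop_B_only,
               category = "B only", panel = "proportion of groups"),
    data.frame(height = sweep$height, value = sweep$prop_both,
               category = "Both", panel = "proportion of groups"),
    data.frame(height = sweep$height, value = sweep$isolates_A_only,
               category = "A only", panel = "isolate counts"),
    data.frame(height = sweep$height, value = sweep$isolates_B_only,
               category = "B only", panel = "isolate counts"),
    data.frame(height = sweep$height, value = sweep$isolates_both,
               category = "Both", panel = "isolate counts"))
  p <- ggplot2::ggplot(long, ggplot2::aes(x = height, y = value,
                                          colour = category)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~panel, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "dendrogram cut height", y = NULL,
                  colour = "group contains") +
    ggplot2::theme_minimal()
  if (!is.null(path)) {
    ggplot2::ggsave(path, p, width = 7, height = 6)
    return(invisible(p))
  }
  p
}
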