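## Raw spectrum -> consensus peak sets -> feature matrices.
## The chain follows the standard intact-cell MALDI protocol family:
## sqrt intensity transform, Savitzky-Golay smoothing, SNIP baseline,
## SNR-thresholded local-maximum picking, replicate consensus, m/z binning.

#' Preprocessing parameters
#'
#' Defaults follow common intact-cell MALDI practice: square-root intensity
#' transform (variance stabilization), Savitzky-Golay smoothing with
#' half-width 10 points, 100 SNIP iterations, SNR threshold 3 for protein
#' spectra and 5 for the noisier small-molecule mode, protein analysis range
#' 4--20 kDa (the legacy 3--15 kDa window is available via
#' `proteinPreset = "legacy"`), SM range 200--2000 Da (the 200 Da floor
#' excludes the MALDI matrix-cluster region), peaks retained when present in
#' at least 2 of 3 replicates, and relative binning tolerance 0.002.
#'
#' @param transform `"sqrt"` or `"none"`.
#' @param smoothingHalfWidth smoothing half-width in points.
#' @param baselineIterations SNIP iterations.
#' @param snrThreshold named numeric, SNR cutoffs per mode.
#' @param proteinRange,smRange analysis windows in Da, `c(min, max)`.
#' @param proteinPreset `"default"` (4--20 kDa) or `"legacy"` (3--15 kDa);
#'   ignored when `proteinRange` is given explicitly.
#' @param replicateMinFraction minimum fraction of present replicates a
#'   peak must appear in, in (0, 1].
#' @param binTolerance relative m/z tolerance used both for replicate
#'   merging and for reference binning (0.002 = 2 Da at 1000 Da).
#' @return a validated list of class `PreprocessParams`.
#' @export
preprocessParams <- function(transform = c("sqrt", "none"),
                             smoothingHalfWidth = 10L,
                             baselineIterations = 100L,
                             snrThreshold = c(protein = 3, sm = 5),
                             proteinRange = NULL,
                             proteinPreset = c("default", "legacy"),
                             smRange = c(200, 2000),
                             replicateMinFraction = 2 / 3,
                             binTolerance = 0.002) {
  transform <- match.arg(transform)
  proteinPreset <- match.arg(proteinPreset)
  if (is.null(proteinRange))
    proteinRange <- if (proteinPreset == "legacy") c(3000, 15000)
                    else c(4000, 20000)
  stopifnot(proteinRange[1] < proteinRange[2], smRange[1] < smRange[2],
            all(snrThreshold > 0), replicateMinFraction > 0,
            replicateMinFraction <= 1, binTolerance > 0,
            smoothingHalfWidth >= 0, baselineIterations >= 0)
  if (!all(c("protein", "sm") %in% names(snrThreshold)))
    stop("snrThreshold needs entries named 'protein' and 'sm'")
  structure(list(transform = transform,
                 smoothingHalfWidth = as.integer(smoothingHalfWidth),
                 baselineIterations = as.integer(baselineIterations),
                 snrThreshold = snrThreshold,
                 proteinRange = proteinRange, smRange = smRange,
                 replicateMinFraction = replicateMinFraction,
                 binTolerance = binTolerance),
            class = "PreprocessParams")
}

modeRange <- function(params, mode) {
  if (mode == "protein") params$proteinRange else params$smRange
}

#' SNIP baseline estimation
#'
#' Statistics-sensitive non-linear iterative peak-clipping: at iteration i
#' each point is replaced by the minimum of itself and the mean of its
#' neighbours i points away (boundaries clamped). The window grows with the
#' iteration, so `iterations` bounds the half-width of the widest structure
#' treated as baseline.
#'
#' @param y numeric signal (e.g. smoothed intensities).
#' @param iterations number of clipping passes.
#' @return numeric baseline estimate, same length as `y`.
#' @export
snipBaseline <- function(y, iterations = 100L) {
  n <- length(y)
  if (n < 3L || iterations < 1L) return(y)
  b <- y
  for (i in seq_len(min(iterations, (n - 1L) %/% 2L))) {
    left <- c(rep(b[1L], i), b[seq_len(n - i)])
    right <- c(b[-seq_len(i)], rep(b[n], i))
    b <- pmin(b, (left + right) / 2)
  }
  b
}

#' Pick peaks from a raw spectrum
#'
#' Applies the intensity transform, Savitzky-Golay smoothing, SNIP baseline
#' subtraction, then keeps local maxima of the residual whose SNR (residual
#' height over `1.4826 * MAD` of the residual) reaches the mode's threshold,
#' restricted to the mode's analysis range.
#'
#' @param spectrum a [MaldiSpectrum-class].
#' @param params a [preprocessParams()] object.
#' @return a [PeakSet-class] holding this acquisition's peaks. A spectrum
#'   entirely outside the mode range yields an empty set with a warning.
#' @export
pickPeaks <- function(spectrum, params = preprocessParams()) {
  stopifnot(is(spectrum, "MaldiSpectrum"), inherits(params, "PreprocessParams"))
  mode <- spectrum@msMode
  rng <- modeRange(params, mode)
  empty <- data.frame(isolate_id = character(0), replicate = integer(0),
                      mz = numeric(0), intensity = numeric(0),
                      snr = numeric(0))
  if (length(spectrum@mz) == 0L) return(PeakSet(empty, mode))
  if (max(spectrum@mz) < rng[1] || min(spectrum@mz) > rng[2]) {
    warning("spectrum ", spectrum@isolateId, " rep ", spectrum@replicate,
            " lies entirely outside the ", mode, " range", call. = FALSE)
    return(PeakSet(empty, mode))
  }
  x <- spectrum@intensity
  if (params$transform == "sqrt") x <- sqrt(x)
  hw <- params$smoothingHalfWidth
  flen <- 2L * hw + 1L
  sm <- if (hw > 0L && length(x) > flen)
    signal::sgolayfilt(x, p = 3, n = flen) else x
  base <- snipBaseline(sm, params$baselineIterations)
  resid <- sm - base
  noise <- stats::mad(resid)   # already scaled by 1.4826
  if (noise <= 0) noise <- max(stats::sd(resid), .Machine$double.eps)
  n <- length(resid)
  isMax <- if (n >= 3L)
    c(FALSE, resid[2:(n - 1)] > resid[1:(n - 2)] &
             resid[2:(n - 1)] >= resid[3:n], FALSE)
  else rep(TRUE, n)
  snr <- resid / noise
  thr <- params$snrThreshold[[mode]]
  keep <- isMax & snr >= thr &
    spectrum@mz >= rng[1] & spectrum@mz <= rng[2]
  nKeep <- sum(keep)
  PeakSet(data.frame(isolate_id = rep(spectrum@isolateId, nKeep),
                     replicate = rep(spectrum@replicate, nKeep),
                     mz = spectrum@mz[keep],
                     intensity = resid[keep],
                     snr = snr[keep]), mode)
}

#' Merge replicate peak lists into a consensus peak set
#'
#' Peaks from all replicates of one isolate are pooled, SNR-filtered, and
#' grouped by the same relative m/z tolerance used for binning. A group is
#' retained when its presence fraction (replicates carrying the peak over
#' replicates actually present) reaches `replicateMinFraction`; consensus
#' m/z is the intensity-weighted mean and consensus intensity the median of
#' the per-replicate intensities. Missing replicates are tolerated: the
#' denominator is the number of replicates observed, not the nominal three.
#'
#' @param peakSet a [PeakSet-class] containing one isolate's replicates.
#' @param params a [preprocessParams()] object.
#' @return a [ConsensusPeakSet-class].
#' @export
mergeReplicates <- function(peakSet, params = preprocessParams()) {
  stopifnot(is(peakSet, "PeakSet"))
  p <- peakSet@peaks
  ids <- unique(p$isolate_id)
  if (length(ids) > 1L)
    stop("mixed isolate ids in mergeReplicates: ",
         paste(ids, collapse = ", "))
  mode <- peakSet@msMode
  thr <- params$snrThreshold[[mode]]
  p <- p[p$snr >= thr, , drop = FALSE]
  nRep <- length(unique(peakSet@peaks$replicate))
  emptyOut <- new("ConsensusPeakSet",
                  isolateId = if (length(ids)) ids else NA_character_,
                  msMode = mode,
                  peaks = data.frame(mz = numeric(0), intensity = numeric(0),
                                     presence_fraction = numeric(0)),
                  nReplicates = as.integer(max(nRep, 0L)))
  if (!nrow(p)) return(emptyOut)
  o <- order(p$mz)
  p <- p[o, , drop = FALSE]
  grp <- groupByTolerance(p$mz, params$binTolerance, relative = TRUE)
  perRep <- stats::aggregate(intensity ~ grp + replicate, data = cbind(p, grp = grp),
                             FUN = sum)
  pres <- tapply(perRep$replicate, perRep$grp, function(r) length(unique(r)))
  frac <- as.numeric(pres) / nRep
  keepGrp <- as.integer(names(pres))[frac >= params$replicateMinFraction]
  if (!length(keepGrp)) return(emptyOut)
  mzCons <- vapply(keepGrp, function(g) {
    sel <- grp == g
    sum(p$mz[sel] * p$intensity[sel]) / sum(p$intensity[sel])
  }, numeric(1))
  intCons <- vapply(keepGrp, function(g)
    stats::median(perRep$intensity[perRep$grp == g]), numeric(1))
  fracKeep <- frac[match(keepGrp, as.integer(names(pres)))]
  o2 <- order(mzCons)
  new("ConsensusPeakSet", isolateId = ids, msMode = mode,
      peaks = data.frame(mz = mzCons[o2], intensity = intCons[o2],
                         presence_fraction = fracKeep[o2]),
      nReplicates = as.integer(nRep))
}

#' Split a multi-isolate PeakSet and merge replicates per isolate
#'
#' Convenience wrapper applying [mergeReplicates()] to every isolate in a
#' loaded peak table.
#'
#' @param peakSet a [PeakSet-class].
#' @param params a [preprocessParams()] object.
#' @return named list of [ConsensusPeakSet-class], sorted by isolate id.
#' @export
consensusByIsolate <- function(peakSet, params = preprocessParams()) {
  stopifnot(is(peakSet, "PeakSet"))
  ids <- sort(unique(peakSet@peaks$isolate_id))
  out <- lapply(ids, function(id) {
    sub <- peakSet@peaks[peakSet@peaks$isolate_id == id, , drop = FALSE]
    mergeReplicates(new("PeakSet", peaks = sub, msMode = peakSet@msMode),
                    params)
  })
  names(out) <- ids
  out
}

#' Optional matrix-blank subtraction
#'
#' Removes consensus peaks matching (within the binning tolerance) any peak
#' of a solvent/matrix control consensus set. Standard practice in the
#' intact-cell MALDI protocol family; off by default in [runPipeline()].
#'
#' @param consensus a [ConsensusPeakSet-class].
#' @param blank a [ConsensusPeakSet-class] from the matrix control.
#' @param tolerance relative m/z tolerance.
#' @return the filtered [ConsensusPeakSet-class].
#' @export
subtractBlank <- function(consensus, blank, tolerance = 0.002) {
  stopifnot(is(consensus, "ConsensusPeakSet"), is(blank, "ConsensusPeakSet"))
  if (!nrow(blank@peaks) || !nrow(consensus@peaks)) return(consensus)
  keep <- vapply(consensus@peaks$mz, function(m)
    !any(abs(blank@peaks$mz - m) <= tolerance * m), logical(1))
  methods::initialize(consensus, peaks = consensus@peaks[keep, , drop = FALSE])
}

#' Bin consensus peaks into a feature matrix (reference binning)
#'
#' Greedy single-linkage grouping of the pooled, m/z-sorted peak list:
#' consecutive peaks join the open bin while their gap to the bin's running
#' reference (mean of member m/z) stays within `tolerance * reference`. The
#' bin reference is the mean of member m/z; each isolate contributes its
#' summed intensity per bin. Rows are canonically sorted by isolate id, so
#' the result is invariant to input order.
#'
#' @param consensusSets list of [ConsensusPeakSet-class], all of one mode.
#' @param tolerance relative m/z tolerance (default 0.002).
#' @return a [FeatureMatrix-class]; empty input yields a 0 x 0 matrix.
#' @export
binPeaksReference <- function(consensusSets, tolerance = 0.002) {
  if (!length(consensusSets))
    return(FeatureMatrix(matrix(0, 0, 0), numeric(0), "protein"))
  modes <- unique(vapply(consensusSets, msMode, character(1)))
  if (length(modes) > 1L) stop("mixed modes in binPeaksReference")
  ids <- vapply(consensusSets, isolateIds, character(1))
  pooled <- do.call(rbind, lapply(consensusSets, function(cs)
    if (nrow(cs@peaks)) data.frame(isolate_id = cs@isolateId,
                                   mz = cs@peaks$mz,
                                   intensity = cs@peaks$intensity)
    else NULL))
  rowIds <- sort(unique(ids))
  if (is.null(pooled) || !nrow(pooled)) {
    v <- matrix(0, length(rowIds), 0, dimnames = list(rowIds, NULL))
    return(FeatureMatrix(v, numeric(0), modes))
  }
  o <- order(pooled$mz)
  pooled <- pooled[o, , drop = FALSE]
  grp <- groupByTolerance(pooled$mz, tolerance, relative = TRUE)
  bins <- as.numeric(tapply(pooled$mz, grp, mean))
  v <- matrix(0, nrow = length(rowIds), ncol = length(bins),
              dimnames = list(rowIds, NULL))
  idx <- cbind(match(pooled$isolate_id, rowIds), grp)
  for (r in seq_len(nrow(pooled)))
    v[idx[r, 1L], idx[r, 2L]] <- v[idx[r, 1L], idx[r, 2L]] +
      pooled$intensity[r]
  FeatureMatrix(v, bins, modes)
}

#' Bin consensus peaks on a fixed grid (strict binning)
#'
#' Alternate binning used for the robustness check: bin index is
#' `floor(mz / gridWidth)`, the bin reference the bin-centre m/z. Peaks
#' separated by less than a grid width can land in different bins when they
#' straddle a boundary; this boundary effect is inherent to fixed grids.
#'
#' @param consensusSets list of [ConsensusPeakSet-class], all of one mode.
#' @param gridWidth bin width in Da (> 0).
#' @return a [FeatureMatrix-class].
#' @export
binPeaksStrict <- function(consensusSets, gridWidth = 1) {
  if (gridWidth <= 0) stop("gridWidth must be > 0")
  if (!length(consensusSets))
    return(FeatureMatrix(matrix(0, 0, 0), numeric(0), "protein"))
  modes <- unique(vapply(consensusSets, msMode, character(1)))
  if (length(modes) > 1L) stop("mixed modes in binPeaksStrict")
  ids <- vapply(consensusSets, isolateIds, character(1))
  pooled <- do.call(rbind, lapply(consensusSets, function(cs)
    if (nrow(cs@peaks)) data.frame(isolate_id = cs@isolateId,
                                   mz = cs@peaks$mz,
                                   intensity = cs@peaks$intensity)
    else NULL))
  rowIds <- sort(unique(ids))
  if (is.null(pooled) || !nrow(pooled)) {
    v <- matrix(0, length(rowIds), 0, dimnames = list(rowIds, NULL))
    return(FeatureMatrix(v, numeric(0), modes))
  }
  binIdx <- floor(pooled$mz / gridWidth)
  uIdx <- sort(unique(binIdx))
  bins <- (uIdx + 0.5) * gridWidth
  v <- matrix(0, nrow = length(rowIds), ncol = length(bins),
              dimnames = list(rowIds, NULL))
  ri <- match(pooled$isolate_id, rowIds)
  ci <- match(binIdx, uIdx)
  for (r in seq_along(ri))
    v[ri[r], ci[r]] <- v[ri[r], ci[r]] + pooled$intensity[r]
  FeatureMatrix(v, bins, modes)
}
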