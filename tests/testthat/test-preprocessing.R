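test_that("a planted Gaussian peak on a flat baseline is found exactly once", {
  mz <- seq(4000, 20000, by = 0.5)
  y <- rep(100, length(mz)) + 1000 * exp(-0.5 * ((mz - 5000) / 2)^2)
  sp <- MaldiSpectrum("iso1", 1L, "protein", mz, y)
  params <- preprocessParams(transform = "none", smoothingHalfWidth = 3L,
                             snrThreshold = c(protein = 3, sm = 5))
  pk <- peakTable(pickPeaks(sp, params))
  expect_identical(nrow(pk), 1L)
  expect_lt(abs(pk$mz - 5000), 1)
  expect_gte(pk$snr, 3)
})

test_that("pure noise rarely yields peaks at SNR threshold 10", {
  mz <- seq(4000, 12000, by = 2)
  params <- preprocessParams(transform = "none",
                             snrThreshold = c(protein = 10, sm = 10))
  hits <- vapply(1:100, function(i) {
    set.seed(1000 + i)
    y <- abs(rnorm(length(mz), 0, 5)) + 50
    nrow(peakTable(pickPeaks(MaldiSpectrum("n", 1L, "protein", mz, y),
                             params)))
  }, numeric(1))
  expect_gte(mean(hits == 0), 0.95)
})

test_that("peaks outside the mode's analysis range are excluded", {
  ## peak at 2500 Da with the 4-20 kDa protein analysis window
  mz <- seq(2000, 20000, by = 1)
  y <- rep(10, length(mz)) + 800 * exp(-0.5 * ((mz - 2500) / 2)^2) +
    800 * exp(-0.5 * ((mz - 9000) / 3)^2)
  sp <- MaldiSpectrum("iso1", 1L, "protein", mz, y)
  pk <- peakTable(pickPeaks(sp, preprocessParams(transform = "none")))
  expect_false(any(abs(pk$mz - 2500) < 10))
  expect_true(any(abs(pk$mz - 9000) < 10))

  ## legacy preset keeps the Intro-era 3-15 kDa window selectable
  legacy <- preprocessParams(proteinPreset = "legacy")
  expect_identical(legacy$proteinRange, c(3000, 15000))

  ## spectrum entirely outside the window: empty result with a warning
  out <- MaldiSpectrum("iso1", 1L, "protein", seq(2000, 3000, 1),
                       runif(1001, 10, 20))
  expect_warning(pk2 <- pickPeaks(out, preprocessParams(transform = "none")),
                 "outside")
  expect_identical(nrow(peakTable(pk2)), 0L)
})

test_that("picked m/z set is scale-equivariant without the sqrt transform", {
  set.seed(99)
  mz <- seq(4000, 16000, by = 2)
  y <- abs(rnorm(length(mz), 0, 3)) + 40 +
    Reduce(`+`, lapply(c(5000, 8000, 12000), function(c0)
      600 * exp(-0.5 * ((mz - c0) / (c0 * 5e-4))^2)))
  params <- preprocessParams(transform = "none")
  base <- peakTable(pickPeaks(MaldiSpectrum("s", 1L, "protein", mz, y),
                              params))$mz
  scaled <- peakTable(pickPeaks(MaldiSpectrum("s", 1L, "protein", mz, 7.3 * y),
                                params))$mz
  expect_identical(base, scaled)
  expect_gte(length(base), 3)
})

test_that("replicate consensus applies the presence rule over replicates present", {
  params <- preprocessParams(replicateMinFraction = 0.6)
  mk <- function(reps, mzs) {
    df <- do.call(rbind, lapply(seq_along(reps), function(i)
      data.frame(isolate_id = "isoX", replicate = reps[i], mz = mzs[[i]],
                 intensity = 10, snr = 20)))
    PeakSet(df, "protein")
  }
  ## peak at 5000 in replicates 1 and 2 of 3 -> 2/3 >= 0.6, retained
  cs <- mergeReplicates(mk(1:3, list(c(5000, 7000), 5000.5, 9000)), params)
  expect_true(any(abs(peakTable(cs)$mz - 5000) < 5))
  pf <- peakTable(cs)$presence_fraction[abs(peakTable(cs)$mz - 5000) < 5]
  expect_equal(pf, 2 / 3)
  ## peak only in replicate 1 of 3 -> dropped
  expect_false(any(abs(peakTable(cs)$mz - 7000) < 5))
  ## only 2 replicates present, peak in both -> denominator 2, fraction 1
  cs2 <- mergeReplicates(mk(1:2, list(5000, 5000.5)), params)
  expect_equal(peakTable(cs2)$presence_fraction, 1)
  expect_identical(cs2@nReplicates, 2L)
  ## mixed isolates are rejected
  bad <- PeakSet(data.frame(isolate_id = c("a", "b"), replicate = 1L,
                            mz = c(5000, 6000), intensity = 1, snr = 20),
                 "protein")
  expect_error(mergeReplicates(bad, params), "mixed isolate")
})

test_that("replicate consensus is invariant to replicate order", {
  set.seed(4)
  df <- data.frame(isolate_id = "iso1",
                   replicate = rep(1:3, each = 8),
                   mz = rep(sort(runif(8, 4000, 20000)), 3) *
                     (1 + rnorm(24, 0, 1e-5)),
                   intensity = rlnorm(24, log(50), 0.3), snr = 20)
  a <- mergeReplicates(PeakSet(df, "protein"))
  dfPerm <- df
  dfPerm$replicate <- c(3L, 1L, 2L)[df$replicate]
  b <- mergeReplicates(PeakSet(dfPerm, "protein"))
  expect_equal(peakTable(a)$mz, peakTable(b)$mz)
  expect_equal(peakTable(a)$intensity, peakTable(b)$intensity)
})

test_that("reference binning groups peaks by relative tolerance", {
  mkCs <- function(id, mzs) new("ConsensusPeakSet", isolateId = id,
                                msMode = "sm",
                                peaks = data.frame(mz = mzs, intensity = 1,
                                                   presence_fraction = 1),
                                nReplicates = 3L)
  ## 1000.0 vs 1000.4 at relative tolerance 0.002 (2 Da at 1000): same bin
  fm <- binPeaksReference(list(mkCs("a", 1000.0), mkCs("b", 1000.4)), 0.002)
  expect_identical(ncol(featureValues(fm)), 1L)
  ## 1000.0 vs 1003.0: different bins
  fm2 <- binPeaksReference(list(mkCs("a", 1000.0), mkCs("b", 1003.0)), 0.002)
  expect_identical(ncol(featureValues(fm2)), 2L)
  ## empty input
  fm3 <- binPeaksReference(list(), 0.002)
  expect_identical(nrow(featureValues(fm3)), 0L)
})

test_that("reference binning matches the transitive-closure oracle on sparse peaks", {
  ## simulated consensus sets: well-separated peak positions, <= 50 peaks
  for (trial in 1:20) {
    set.seed(200 + trial)
    nIso <- sample(2:5, 1)
    centers <- sort(runif(sample(5:12, 1), 300, 1900))
    centers <- centers[c(TRUE, diff(centers) > 12)]  # keep clusters apart
    sets <- lapply(seq_len(nIso), function(i) {
      mzs <- sort(unique(centers * (1 + rnorm(length(centers), 0, 3e-4))))
      new("ConsensusPeakSet", isolateId = sprintf("i%d", i), msMode = "sm",
          peaks = data.frame(mz = mzs, intensity = 1, presence_fraction = 1),
          nReplicates = 3L)
    })
    fm <- binPeaksReference(sets, 0.002)
    pooled <- sort(unlist(lapply(sets, function(s) peakTable(s)$mz)))
    oracle <- bfTransitiveBins(pooled, 0.002)
    expect_identical(ncol(featureValues(fm)), length(unique(oracle)))
  }
})

test_that("strict grid binning behaves at boundaries and never merges more than reference", {
  mkCs <- function(id, mzs) new("ConsensusPeakSet", isolateId = id,
                                msMode = "sm",
                                peaks = data.frame(mz = mzs, intensity = 1,
                                                   presence_fraction = 1),
                                nReplicates = 3L)
  fm <- binPeaksStrict(list(mkCs("a", 1000.4)), gridWidth = 1)
  expect_equal(binMz(fm), 1000.5)   # bin [1000, 1001)
  ## boundary effect: 999.9 and 1000.1 straddle a grid line
  fm2 <- binPeaksStrict(list(mkCs("a", 999.9), mkCs("b", 1000.1)), 1)
  expect_identical(ncol(featureValues(fm2)), 2L)
  expect_error(binPeaksStrict(list(mkCs("a", 1000)), 0), "gridWidth")

  ## property: strict binning with gridWidth <= tol * min(mz) gives at
  ## least as many bins as reference binning
  for (trial in 1:10) {
    set.seed(300 + trial)
    sets <- lapply(1:3, function(i)
      mkCs(sprintf("i%d", i), sort(runif(20, 300, 1900))))
    minMz <- min(unlist(lapply(sets, function(s) peakTable(s)$mz)))
    gw <- 0.002 * minMz
    nStrict <- ncol(featureValues(binPeaksStrict(sets, gw)))
    nRef <- ncol(featureValues(binPeaksReference(sets, 0.002)))
    expect_gte(nStrict, nRef)
  }
})

test_that("planted protein peaks are recovered end-to-end at default noise", {
  sim <- simulateDataset(simConfig(nGenera = 2L, speciesPerGenus = 2L),
                         seed = 21)
  params <- preprocessParams()
  fm <- proteinMatrix(sim, params)
  v <- featureValues(fm)
  bins <- binMz(fm)
  iso <- sim$truth$isolates
  panels <- sim$proteinPanels
  found <- total <- 0L
  for (i in seq_len(nrow(iso))) {
    planted <- c(panels$genus[[iso$genus[i]]]$mz,
                 panels$species[[iso$species[i]]]$mz,
                 panels$strain[[iso$strain[i]]]$mz)
    row <- v[iso$isolate_id[i], ]
    hit <- vapply(planted, function(m) {
      j <- which(abs(bins - m) <= 0.002 * m)
      length(j) > 0 && any(row[j] > 0)
    }, logical(1))
    found <- found + sum(hit); total <- total + length(hit)
  }
  expect_gte(found / total, 0.95)
})

test_that("matrix-blank subtraction removes matching consensus peaks", {
  cs <- new("ConsensusPeakSet", isolateId = "i1", msMode = "sm",
            peaks = data.frame(mz = c(500, 800, 1200), intensity = 1,
                               presence_fraction = 1), nReplicates = 3L)
  blank <- new("ConsensusPeakSet", isolateId = "blank", msMode = "sm",
               peaks = data.frame(mz = c(800.5, 1500), intensity = 1,
                                  presence_fraction = 1), nReplicates = 3L)
  out <- subtractBlank(cs, blank, tolerance = 0.002)
  expect_equal(peakTable(out)$mz, c(500, 1200))
})
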