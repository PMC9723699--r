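test_that("simulation is exactly reproducible from one seed", {
  a <- simulateDataset(simConfig(), seed = 7)
  b <- simulateDataset(simConfig(), seed = 7)
  expect_identical(a$truth$isolates, b$truth$isolates)
  expect_identical(peakTable(a$proteinPeaks), peakTable(b$proteinPeaks))
  expect_identical(peakTable(a$smPeaks), peakTable(b$smPeaks))
  c <- simulateDataset(simConfig(), seed = 8)
  expect_false(identical(peakTable(a$proteinPeaks), peakTable(c$proteinPeaks)))
})

test_that("fixtures are written deterministically and reload losslessly", {
  sim <- simulateDataset(simConfig(nGenera = 2L, plateExclusionProb = 0.1),
                         seed = 9)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  emitFixture(sim, d1)
  emitFixture(sim, d2)
  for (f in c("peaks_protein.tsv", "peaks_sm.tsv", "metadata.tsv",
              "excluded_plates.txt", "ground_truth.json"))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  back <- loadFixture(d1)
  expect_equal(peakTable(back$proteinPeaks)$mz,
               peakTable(sim$proteinPeaks)$mz, tolerance = 1e-6)
  expect_identical(back$meta$isolate_id, sort(sim$meta$isolate_id))
  expect_setequal(back$excludedPlates, sim$excludedPlates)
})

test_that("host occupancy follows the host model", {
  ## forced both-host occupancy: every species in both hosts
  both <- simulateTaxonomy(simConfig(hostModel = c(aOnly = 0, bOnly = 0,
                                                   both = 1),
                                     isolatesPerStrain = 8L), seed = 13)
  expect_true(all(both$species$occupancy == "both"))
  bySp <- split(both$isolates$source, both$isolates$species)
  expect_true(all(vapply(bySp, function(s)
    all(c("A", "B") %in% s), logical(1))))
  ## all-A occupancy
  onlyA <- simulateTaxonomy(simConfig(hostModel = c(aOnly = 1, bOnly = 0,
                                                    both = 0)), seed = 13)
  expect_true(all(onlyA$isolates$source == "A"))
  ## default weights: the fraction of both-host species is near 0.10
  fracs <- vapply(1:20, function(i) {
    gt <- simulateTaxonomy(simConfig(nGenera = 6L, speciesPerGenus = 4L),
                           seed = 700 + i)
    mean(gt$species$occupancy == "both")
  }, numeric(1))
  expect_lt(abs(mean(fracs) - 0.10), 0.05)
})

test_that("noise-free replicates reproduce the planted panel exactly", {
  cfg <- simConfig(nGenera = 1L, speciesPerGenus = 1L,
                   strainsPerSpecies = 1L, isolatesPerStrain = 2L,
                   mzJitterPpm = 0, intensityCv = 0,
                   replicateDropoutProb = 0, spuriousPeakRate = 0)
  sim <- simulateDataset(cfg, seed = 15)
  iso <- sim$truth$isolates
  panel <- sort(c(sim$proteinPanels$genus[[iso$genus[1]]]$mz,
                  sim$proteinPanels$species[[iso$species[1]]]$mz,
                  sim$proteinPanels$strain[[iso$strain[1]]]$mz))
  p <- peakTable(sim$proteinPeaks)
  for (r in 1:3) {
    got <- sort(p$mz[p$isolate_id == iso$isolate_id[1] & p$replicate == r])
    expect_equal(got, panel)
  }
  ## same-strain isolates carry identical panels
  got2 <- sort(p$mz[p$isolate_id == iso$isolate_id[2] & p$replicate == 1])
  expect_equal(got2, panel)
})

test_that("different genera share essentially no protein features", {
  cfg <- simConfig(nGenera = 4L, mzJitterPpm = 0, spuriousPeakRate = 0)
  sim <- simulateDataset(cfg, seed = 17)
  fm <- proteinMatrix(sim)
  pres <- (featureValues(fm) > 0) * 1L
  iso <- sim$truth$isolates
  gen <- iso$genus[match(rownames(pres), iso$isolate_id)]
  shared <- tcrossprod(pres)
  cross <- shared[outer(gen, gen, `!=`)]
  ## only random m/z collisions of independently drawn panels remain; the
  ## expected number of colliding pairs between two 35-peak panels drawn
  ## uniformly on (lo, hi) with relative tolerance t is about
  ## n1 * n2 * 2 * t * meanMz / (hi - lo)
  rng <- preprocessParams()$proteinRange
  nPanel <- sum(simConfig()$proteinPanel)
  bound <- nPanel^2 * 2 * 0.002 * mean(rng) / diff(rng)
  expect_lt(mean(cross), 2 * bound)
})

test_that("SM sharing tracks the species tree when coupled and not when decoupled", {
  jac <- function(a, b) length(intersect(a, b)) / length(union(a, b))
  sharingGap <- function(coupling, seed) {
    cfg <- simConfig(coupling = coupling, speciesPerGenus = 3L,
                     strainsPerSpecies = 1L, isolatesPerStrain = 3L)
    sim <- simulateDataset(cfg, seed = seed)
    sets <- sim$sm$isolateBgc
    iso <- sim$truth$isolates
    within <- c(); between <- c()
    for (i in seq_len(nrow(iso))) for (j in seq_len(nrow(iso))) {
      if (i >= j) next
      s <- jac(sets[[iso$isolate_id[i]]], sets[[iso$isolate_id[j]]])
      if (iso$species[i] == iso$species[j]) within <- c(within, s)
      else between <- c(between, s)
    }
    c(within = mean(within), between = mean(between))
  }
  coupled <- sharingGap(1, 19)
  expect_gt(coupled["within"], coupled["between"])
  decoupledGaps <- vapply(1:5, function(i) {
    g <- sharingGap(0, 800 + i); g["within"] - g["between"]
  }, numeric(1))
  ## decoupled: within-species and between-species sharing coincide
  expect_lt(abs(mean(decoupledGaps)), 0.05)
})

test_that("a BGC-free configuration yields empty SM data and undefined r", {
  sim <- simulateDataset(simConfig(nBgcPerGenus = 0L), seed = 23)
  expect_identical(nrow(peakTable(sim$smPeaks)), 0L)
  cons <- consensusByIsolate(sim$smPeaks)
  expect_length(cons, 0)
})

test_that("the campaign-shaped preset reproduces the expected bookkeeping", {
  pf <- campaignFixture(seed = 2)
  expect_identical(nrow(pf$meta), 851L)
  expect_identical(sum(pf$meta$source == "A"), 522L)
  expect_identical(sum(pf$meta$source == "B"), 329L)
  keep <- suppressWarnings(matchedPlateFilter(pf$meta, pf$excludedPlates))
  expect_identical(length(keep), 692L)
  expect_identical(nrow(pf$meta) - length(keep), 159L)
  ## deterministic given the seed
  pf2 <- campaignFixture(seed = 2)
  expect_identical(pf$meta, pf2$meta)
})
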