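## Synthetic isolate collections with planted taxonomy, host structure and
## tunable phylotype-chemotype coupling. The generator emulates the study
## design the analysis assumes: two source hosts, a plate factorial of
## media x pretreatment x dilution per host, triplicate acquisitions per
## isolate, hierarchical protein peak inheritance (genus core / species /
## strain panels) and genus-level BGC panels whose species retention drives
## small-molecule feature sharing. All randomness flows from a single seed.

#' Simulation configuration
#'
#' Defaults describe a compact two-host collection: 4 genera x 3 species x
#' 2 strains x 4 isolates = 96 isolates; species occupy host A only, host B
#' only, or both with weights 0.45/0.45/0.10 (weighted toward single-host
#' species, planting species-level non-overlap under genus-level overlap);
#' protein panels of 20 genus-core + 10 species + 5 strain peaks on
#' 4--20 kDa (genus cores dominate similarity above the species level);
#' 10 candidate BGCs per genus emitting 1--3 SM features each on
#' 200--2000 Da with 0.5 Da minimum separation inside a genus; low
#' measurement noise (200 ppm m/z jitter, 30% intensity CV, 5% replicate
#' dropout, 1 spurious peak per acquisition on average).
#'
#' @param nGenera,speciesPerGenus,strainsPerSpecies,isolatesPerStrain
#'   taxonomy sizes.
#' @param hostModel per-species occupancy probabilities, named
#'   `aOnly`/`bOnly`/`both` (isolates of a "both" species are placed in
#'   either host at random).
#' @param proteinPanel peak counts, named `genusCore`/`species`/`strain`.
#' @param proteinRange,smRange acquisition windows (Da).
#' @param nBgcPerGenus candidate BGCs per genus.
#' @param featuresPerBgc integer range `c(min, max)` of SM features per BGC.
#' @param speciesRetentionProb expected fraction of the genus BGC panel a
#'   species retains after inheritance losses along the species tree.
#' @param coupling rho in \[0, 1\]: probability an isolate's BGC set follows
#'   its species (phylotype-chemotype coupling); a decoupled isolate draws
#'   the same number of BGCs from the study-wide pool instead.
#' @param smMinSeparation minimum m/z distance between SM features of one
#'   genus (Da), keeping planted sharing interpretable after binning.
#' @param mzJitterPpm,intensityCv,replicateDropoutProb,spuriousPeakRate
#'   per-replicate noise: Gaussian m/z jitter (ppm), log-normal intensity
#'   CV, per-peak dropout probability, Poisson rate of spurious peaks.
#' @param nReplicates biological replicates per isolate.
#' @param nMedia,pretreatments,dilutions plate factorial (per host).
#' @param plateExclusionProb probability a plate joins the exclusion list
#'   (emulating overgrown plates), exercising the matched-plate filter.
#' @return validated list of class `SimConfig`.
#' @export
simConfig <- function(nGenera = 4L, speciesPerGenus = 3L,
                      strainsPerSpecies = 2L, isolatesPerStrain = 4L,
                      hostModel = c(aOnly = 0.45, bOnly = 0.45, both = 0.10),
                      proteinPanel = c(genusCore = 20L, species = 10L,
                                       strain = 5L),
                      proteinRange = c(4000, 20000),
                      smRange = c(200, 2000),
                      nBgcPerGenus = 10L, featuresPerBgc = c(1L, 3L),
                      speciesRetentionProb = 0.6, coupling = 1,
                      smMinSeparation = 0.5,
                      mzJitterPpm = 200, intensityCv = 0.3,
                      replicateDropoutProb = 0.05, spuriousPeakRate = 1,
                      nReplicates = 3L,
                      nMedia = 9L, pretreatments = c("none", "heat"),
                      dilutions = c("0", "1/10", "1/100"),
                      plateExclusionProb = 0) {
  stopifnot(nGenera >= 1, speciesPerGenus >= 1, strainsPerSpecies >= 1,
            isolatesPerStrain >= 1,
            abs(sum(hostModel) - 1) < 1e-9, all(hostModel >= 0),
            all(c("aOnly", "bOnly", "both") %in% names(hostModel)),
            all(c("genusCore", "species", "strain") %in% names(proteinPanel)),
            all(proteinPanel >= 0),
            proteinRange[1] < proteinRange[2], smRange[1] < smRange[2],
            nBgcPerGenus >= 0, featuresPerBgc[1] >= 1,
            featuresPerBgc[1] <= featuresPerBgc[2],
            speciesRetentionProb >= 0, speciesRetentionProb <= 1,
            coupling >= 0, coupling <= 1,
            mzJitterPpm >= 0, intensityCv >= 0,
            replicateDropoutProb >= 0, replicateDropoutProb < 1,
            spuriousPeakRate >= 0, nReplicates >= 1,
            plateExclusionProb >= 0, plateExclusionProb < 1)
  structure(as.list(environment()), class = "SimConfig")
}

plateGrid <- function(cfg) {
  g <- expand.grid(media = sprintf("M%d", seq_len(cfg$nMedia)),
                   pretreatment = cfg$pretreatments,
                   dilution = cfg$dilutions,
                   stringsAsFactors = FALSE)
  g <- g[order(g$media, g$pretreatment, g$dilution), , drop = FALSE]
  rownames(g) <- NULL
  g
}

plateId <- function(source, media, pretreatment, dilution) {
  dcode <- c("0" = "d0", "1/10" = "d10", "1/100" = "d100")[dilution]
  sprintf("%s_%s_%s_%s", source, media, pretreatment, dcode)
}

#' Simulate the taxonomy and plate skeleton
#'
#' Generates genera shared between the hosts, assigns each species a host
#' occupancy from `hostModel`, places isolates on strains and assigns each
#' isolate uniformly to one of its host's diversity plates.
#'
#' @param cfg a [simConfig()] object.
#' @param seed optional seed (when NULL, the ambient RNG stream is used, as
#'   inside [simulateDataset()]).
#' @return list of class `SimTruth` with `isolates` (data.frame:
#'   isolate_id, genus, species, strain, source, plate_id, media,
#'   pretreatment, dilution), `species` (data.frame: species, genus,
#'   occupancy) and the config.
#' @export
simulateTaxonomy <- function(cfg = simConfig(), seed = NULL) {
  withSeed(seed, {
    nIso <- cfg$nGenera * cfg$speciesPerGenus * cfg$strainsPerSpecies *
      cfg$isolatesPerStrain
    if (nIso < 1L) stop("configuration yields zero isolates")
    genera <- sprintf("g%02d", seq_len(cfg$nGenera))
    spTab <- expand.grid(spIdx = seq_len(cfg$speciesPerGenus),
                         genus = genera, stringsAsFactors = FALSE)
    spTab$species <- sprintf("%s_s%02d", spTab$genus, spTab$spIdx)
    occ <- sample(c("aOnly", "bOnly", "both"), nrow(spTab), replace = TRUE,
                  prob = cfg$hostModel[c("aOnly", "bOnly", "both")])
    spTab$occupancy <- occ
    strains <- expand.grid(stIdx = seq_len(cfg$strainsPerSpecies),
                           species = spTab$species, stringsAsFactors = FALSE)
    strains$strain <- sprintf("%s_t%02d", strains$species, strains$stIdx)
    iso <- strains[rep(seq_len(nrow(strains)), each = cfg$isolatesPerStrain),
                   c("species", "strain")]
    iso$isolate_id <- sprintf("iso%04d", seq_len(nrow(iso)))
    iso$genus <- spTab$genus[match(iso$species, spTab$species)]
    occIso <- spTab$occupancy[match(iso$species, spTab$species)]
    iso$source <- ifelse(occIso == "aOnly", "A",
                         ifelse(occIso == "bOnly", "B",
                                sample(c("A", "B"), nrow(iso), replace = TRUE)))
    plates <- plateGrid(cfg)
    pick <- sample.int(nrow(plates), nrow(iso), replace = TRUE)
    iso$media <- plates$media[pick]
    iso$pretreatment <- plates$pretreatment[pick]
    iso$dilution <- plates$dilution[pick]
    iso$plate_id <- plateId(iso$source, iso$media, iso$pretreatment,
                            iso$dilution)
    iso <- iso[order(iso$isolate_id),
               c("isolate_id", "genus", "species", "strain", "source",
                 "plate_id", "media", "pretreatment", "dilution")]
    rownames(iso) <- NULL
    structure(list(isolates = iso,
                   species = spTab[c("species", "genus", "occupancy")],
                   config = cfg),
              class = "SimTruth")
  })
}

## hierarchical peak panel per isolate: genus core + species + strain peaks
makeProteinPanels <- function(truth, cfg) {
  drawPanel <- function(n, tag)
    data.frame(mz = sort(stats::runif(n, cfg$proteinRange[1],
                                      cfg$proteinRange[2])),
               intensity = stats::rlnorm(n, log(100), 0.5),
               level = tag)
  genera <- unique(truth$isolates$genus)
  speciesTab <- unique(truth$isolates[c("species", "genus")])
  strainTab <- unique(truth$isolates[c("strain", "species")])
  list(genus = stats::setNames(lapply(genera, function(g)
         drawPanel(cfg$proteinPanel[["genusCore"]], "genus")), genera),
       species = stats::setNames(lapply(speciesTab$species, function(s)
         drawPanel(cfg$proteinPanel[["species"]], "species")),
         speciesTab$species),
       strain = stats::setNames(lapply(strainTab$strain, function(s)
         drawPanel(cfg$proteinPanel[["strain"]], "strain")), strainTab$strain))
}

## render one panel into nReplicates noisy peak lists (long data.frame)
renderReplicates <- function(panel, isolateId, cfg, range) {
  out <- vector("list", cfg$nReplicates)
  for (r in seq_len(cfg$nReplicates)) {
    keep <- stats::runif(nrow(panel)) >= cfg$replicateDropoutProb
    p <- panel[keep, , drop = FALSE]
    nSpur <- stats::rpois(1L, cfg$spuriousPeakRate)
    if (nSpur > 0)
      p <- rbind(p[c("mz", "intensity")],
                 data.frame(mz = stats::runif(nSpur, range[1], range[2]),
                            intensity = stats::rlnorm(nSpur, log(20), 0.5)))
    else p <- p[c("mz", "intensity")]
    if (nrow(p)) {
      sdlog <- sqrt(log(1 + cfg$intensityCv^2))
      p$mz <- p$mz * (1 + stats::rnorm(nrow(p), 0, cfg$mzJitterPpm * 1e-6))
      p$intensity <- p$intensity * stats::rlnorm(nrow(p), 0, sdlog)
      p$snr <- stats::rlnorm(nrow(p), log(20), 0.4)
      ## jitter can in principle create exact duplicates; enforce uniqueness
      p <- p[!duplicated(p$mz), , drop = FALSE]
      p$isolate_id <- isolateId
      p$replicate <- r
    } else {
      p <- data.frame(mz = numeric(0), intensity = numeric(0),
                      snr = numeric(0), isolate_id = character(0),
                      replicate = integer(0))
    }
    out[[r]] <- p
  }
  do.call(rbind, out)
}

#' Simulate triplicate protein peak lists (or profile spectra)
#'
#' Each isolate's peak panel is the union of its genus core, species and
#' strain panels; replicates apply m/z jitter, log-normal intensity noise,
#' per-peak dropout and spurious peaks. `render = "profile"` additionally
#' rasterizes each replicate onto an m/z grid with Gaussian peak shapes, an
#' exponentially decaying baseline and detector noise, for exercising
#' [pickPeaks()].
#'
#' @param truth a `SimTruth` from [simulateTaxonomy()].
#' @param cfg the same [simConfig()].
#' @param render `"peaks"` (default) or `"profile"`.
#' @param seed optional seed.
#' @param gridStep m/z grid spacing for profile rendering (Da).
#' @return `render = "peaks"`: list with `peaks` (a [PeakSet-class], mode
#'   protein) and `panels` (the planted per-taxon peak panels).
#'   `render = "profile"`: list with `spectra` (list of
#'   [MaldiSpectrum-class]) and `panels`.
#' @export
simulateProteinSpectra <- function(truth, cfg = truth$config,
                                   render = c("peaks", "profile"),
                                   seed = NULL, gridStep = 2) {
  render <- match.arg(render)
  withSeed(seed, {
    panels <- makeProteinPanels(truth, cfg)
    iso <- truth$isolates
    rows <- vector("list", nrow(iso))
    for (i in seq_len(nrow(iso))) {
      panel <- rbind(panels$genus[[iso$genus[i]]],
                     panels$species[[iso$species[i]]],
                     panels$strain[[iso$strain[i]]])
      rows[[i]] <- renderReplicates(panel, iso$isolate_id[i], cfg,
                                    cfg$proteinRange)
    }
    long <- do.call(rbind, rows)
    if (render == "peaks")
      return(list(peaks = PeakSet(long, "protein"), panels = panels))
    spectra <- renderProfiles(long, cfg$proteinRange, "protein", gridStep)
    list(spectra = spectra, panels = panels)
  })
}

## rasterize noisy peak lists into profile spectra
renderProfiles <- function(long, range, mode, gridStep) {
  grid <- seq(range[1], range[2], by = gridStep)
  keys <- unique(long[c("isolate_id", "replicate")])
  keys <- keys[order(keys$isolate_id, keys$replicate), , drop = FALSE]
  lapply(seq_len(nrow(keys)), function(k) {
    sel <- long$isolate_id == keys$isolate_id[k] &
      long$replicate == keys$replicate[k]
    p <- long[sel, , drop = FALSE]
    y <- 60 * exp(-(grid - range[1]) / ((range[2] - range[1]) / 3)) + 20
    for (j in seq_len(nrow(p))) {
      sigma <- p$mz[j] * 5e-4
      win <- abs(grid - p$mz[j]) < 5 * sigma
      y[win] <- y[win] + p$intensity[j] *
        exp(-0.5 * ((grid[win] - p$mz[j]) / sigma)^2)
    }
    y <- y + abs(stats::rnorm(length(grid), 0, 1.5))
    MaldiSpectrum(keys$isolate_id[k], keys$replicate[k], mode, grid, y)
  })
}

## genus BGC panels and tree-inherited species retention
makeBgcPanels <- function(truth, cfg) {
  genera <- unique(truth$species$genus)
  allFeatures <- list()
  bgcTab <- list()
  for (g in genera) {
    nb <- cfg$nBgcPerGenus
    if (nb == 0L) next
    nf <- sample(seq(cfg$featuresPerBgc[1], cfg$featuresPerBgc[2]),
                 nb, replace = TRUE)
    mzs <- numeric(0)
    need <- sum(nf)
    tries <- 0L
    while (length(mzs) < need && tries < 10000L) {
      cand <- stats::runif(1, cfg$smRange[1], cfg$smRange[2])
      if (!length(mzs) || min(abs(mzs - cand)) >= cfg$smMinSeparation)
        mzs <- c(mzs, cand)
      tries <- tries + 1L
    }
    if (length(mzs) < need)
      stop("could not place ", need, " SM features with separation ",
           cfg$smMinSeparation, " Da in the SM range")
    bgcId <- rep(sprintf("%s_bgc%02d", g, seq_len(nb)), nf)
    bgcTab[[g]] <- data.frame(genus = g, bgc = bgcId, mz = mzs,
                              intensity = stats::rlnorm(need, log(50), 0.5))
  }
  do.call(rbind, bgcTab)
}

## recursive inheritance of BGC presence along a random species tree
inheritRetention <- function(speciesIds, bgcIds, edgeLoss) {
  recur <- function(ids, present) {
    present <- present[stats::runif(length(present)) >= edgeLoss]
    if (length(ids) == 1L)
      return(stats::setNames(list(present), ids))
    cut <- sample(seq_len(length(ids) - 1L), 1L)
    perm <- sample(ids)
    c(recur(perm[seq_len(cut)], present),
      recur(perm[-seq_len(cut)], present))
  }
  recur(speciesIds, bgcIds)
}

#' Simulate small-molecule (SM) peak lists
#'
#' Each genus carries a panel of candidate BGCs, each emitting 1--3 SM mass
#' features. Species inherit subsets of the genus panel along a random
#' species tree (per-branch loss calibrated so a species retains about
#' `speciesRetentionProb` of the panel), creating phylotype-chemotype
#' coupling. With probability `1 - coupling` an isolate is decoupled: it
#' draws the same number of BGCs from the study-wide pool instead of
#' following its species, erasing the association between protein and SM
#' similarity (at `coupling = 0` within-species and between-species SM
#' sharing coincide in expectation). Noise model as for protein spectra.
#'
#' @inheritParams simulateProteinSpectra
#' @return list with `peaks` (a [PeakSet-class], mode sm), `speciesBgc`
#'   (named list: species -> retained BGC ids), `isolateBgc` (named list),
#'   `bgcFeatures` (data.frame genus, bgc, mz, intensity) and `coupled`
#'   (named logical per isolate).
#' @export
simulateSmFeatures <- function(truth, cfg = truth$config, seed = NULL) {
  withSeed(seed, {
    iso <- truth$isolates
    bgc <- makeBgcPanels(truth, cfg)
    if (is.null(bgc) || !nrow(bgc)) {
      empty <- data.frame(isolate_id = character(0), replicate = integer(0),
                          mz = numeric(0), intensity = numeric(0),
                          snr = numeric(0))
      return(list(peaks = PeakSet(empty, "sm"), speciesBgc = list(),
                  isolateBgc = list(), bgcFeatures = bgc,
                  coupled = stats::setNames(logical(0), character(0))))
    }
    genera <- unique(truth$species$genus)
    depth <- log2(max(cfg$speciesPerGenus, 2)) + 1
    edgeLoss <- 1 - cfg$speciesRetentionProb^(1 / depth)
    speciesBgc <- list()
    for (g in genera) {
      sp <- truth$species$species[truth$species$genus == g]
      ids <- unique(bgc$bgc[bgc$genus == g])
      speciesBgc <- c(speciesBgc, inheritRetention(sp, ids, edgeLoss))
    }
    poolBgc <- unique(bgc$bgc)
    coupled <- stats::runif(nrow(iso)) < cfg$coupling
    names(coupled) <- iso$isolate_id
    isolateBgc <- vector("list", nrow(iso))
    names(isolateBgc) <- iso$isolate_id
    for (i in seq_len(nrow(iso))) {
      own <- speciesBgc[[iso$species[i]]]
      isolateBgc[[i]] <- if (coupled[i]) own
        else sample(poolBgc, min(length(own), length(poolBgc)))
    }
    rows <- vector("list", nrow(iso))
    for (i in seq_len(nrow(iso))) {
      panel <- bgc[bgc$bgc %in% isolateBgc[[i]], c("mz", "intensity"),
                   drop = FALSE]
      rows[[i]] <- renderReplicates(panel, iso$isolate_id[i], cfg,
                                    cfg$smRange)
    }
    long <- do.call(rbind, rows)
    list(peaks = PeakSet(long, "sm"), speciesBgc = speciesBgc,
         isolateBgc = isolateBgc, bgcFeatures = bgc, coupled = coupled)
  })
}

#' Simulate a complete dataset
#'
#' Runs [simulateTaxonomy()], [simulateProteinSpectra()] and
#' [simulateSmFeatures()] under a single seed and assembles the
#' pipeline-ready bundle, including the plate exclusion list drawn with
#' `plateExclusionProb`.
#'
#' @param cfg a [simConfig()].
#' @param seed single RNG seed; the whole dataset is reproducible from it.
#' @param render passed to [simulateProteinSpectra()].
#' @return list of class `SimDataset`: `truth`, `proteinPeaks` (or
#'   `proteinSpectra`), `smPeaks`, `sm` (full SM ground truth), `meta`,
#'   `excludedPlates`, `config`, `seed`.
#' @export
simulateDataset <- function(cfg = simConfig(), seed = 1L,
                            render = c("peaks", "profile")) {
  render <- match.arg(render)
  withSeed(seed, {
    truth <- simulateTaxonomy(cfg)
    prot <- simulateProteinSpectra(truth, cfg, render = render)
    sm <- simulateSmFeatures(truth, cfg)
    meta <- truth$isolates[c("isolate_id", "source", "plate_id", "media",
                             "pretreatment", "dilution", "genus")]
    plates <- unique(truth$isolates$plate_id)
    excluded <- plates[stats::runif(length(plates)) < cfg$plateExclusionProb]
    out <- list(truth = truth, smPeaks = sm$peaks, sm = sm, meta = meta,
                excludedPlates = excluded, config = cfg, seed = seed)
    if (render == "peaks") out$proteinPeaks <- prot$peaks
    else out$proteinSpectra <- prot$spectra
    out$proteinPanels <- prot$panels
    structure(out, class = "SimDataset")
  })
}

#' Write a simulated dataset as a pipeline-ready fixture directory
#'
#' Layout: `peaks_protein.tsv`, `peaks_sm.tsv` (or `spectra_protein.mzML` /
#' `spectra_sm.mzML` for `format = "mzml"`), `metadata.tsv`,
#' `excluded_plates.txt`, `ground_truth.json`. Writing is deterministic:
#' the same dataset yields byte-identical files.
#'
#' @param sim a `SimDataset` from [simulateDataset()].
#' @param path output directory (created if needed).
#' @param format `"peaks"` or `"mzml"`.
#' @return `path`, invisibly.
#' @export
emitFixture <- function(sim, path, format = c("peaks", "mzml")) {
  format <- match.arg(format)
  stopifnot(inherits(sim, "SimDataset"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (is.null(sim$proteinPeaks))
    stop("emitFixture needs a dataset rendered as peak lists")
  if (format == "peaks") {
    writePeakTable(sim$proteinPeaks, file.path(path, "peaks_protein.tsv"))
    if (!is.null(sim$smPeaks))
      writePeakTable(sim$smPeaks, file.path(path, "peaks_sm.tsv"))
  } else {
    writeMzml(peakSetToSpectra(sim$proteinPeaks),
              file.path(path, "spectra_protein.mzML"))
    if (!is.null(sim$smPeaks))
      writeMzml(peakSetToSpectra(sim$smPeaks),
                file.path(path, "spectra_sm.mzML"))
  }
  writeTsv(sim$meta, file.path(path, "metadata.tsv"))
  writeLines(sort(sim$excludedPlates), file.path(path, "excluded_plates.txt"))
  gt <- list(isolates = sim$truth$isolates, species = sim$truth$species,
             species_bgc = sim$sm$speciesBgc,
             coupled = as.list(sim$sm$coupled), seed = sim$seed)
  jsonlite::write_json(gt, file.path(path, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Convert a PeakSet into centroided MaldiSpectrum objects
#' @param x a [PeakSet-class].
#' @return list of [MaldiSpectrum-class], one per acquisition.
#' @export
peakSetToSpectra <- function(x) {
  stopifnot(is(x, "PeakSet"))
  p <- x@peaks
  keys <- unique(p[c("isolate_id", "replicate")])
  keys <- keys[order(keys$isolate_id, keys$replicate), , drop = FALSE]
  lapply(seq_len(nrow(keys)), function(k) {
    sel <- p$isolate_id == keys$isolate_id[k] &
      p$replicate == keys$replicate[k]
    MaldiSpectrum(keys$isolate_id[k], keys$replicate[k], x@msMode,
                  p$mz[sel], p$intensity[sel])
  })
}

#' Load a fixture directory written by [emitFixture()]
#'
#' @param path fixture directory.
#' @return list with `proteinPeaks`, `smPeaks`, `meta`, `excludedPlates`.
#' @export
loadFixture <- function(path) {
  protTsv <- file.path(path, "peaks_protein.tsv")
  if (file.exists(protTsv)) {
    prot <- readPeakTable(protTsv, "protein")
    smTsv <- file.path(path, "peaks_sm.tsv")
    sm <- if (file.exists(smTsv)) readPeakTable(smTsv, "sm") else NULL
  } else {
    prot <- spectraToPeakSet(readMzml(file.path(path, "spectra_protein.mzML"),
                                      "protein"))
    sm <- spectraToPeakSet(readMzml(file.path(path, "spectra_sm.mzML"), "sm"))
  }
  exPath <- file.path(path, "excluded_plates.txt")
  excluded <- if (file.exists(exPath)) readLines(exPath) else character(0)
  excluded <- excluded[nzchar(excluded)]
  list(proteinPeaks = prot, smPeaks = sm,
       meta = readMetadata(file.path(path, "metadata.tsv")),
       excludedPlates = excluded)
}

#' Collapse centroided MaldiSpectrum objects into a PeakSet
#'
#' Inverse of [peakSetToSpectra()] for already-centroided data (every point
#' is a peak; the `Inf` SNR sentinel is used).
#'
#' @param spectra list of [MaldiSpectrum-class] of one mode.
#' @return a [PeakSet-class].
#' @export
spectraToPeakSet <- function(spectra) {
  stopifnot(length(spectra) >= 1L)
  modes <- unique(vapply(spectra, msMode, character(1)))
  if (length(modes) > 1L) stop("mixed modes")
  rows <- lapply(spectra, function(s)
    if (length(s@mz)) data.frame(isolate_id = s@isolateId,
                                 replicate = s@replicate, mz = s@mz,
                                 intensity = s@intensity) else NULL)
  df <- do.call(rbind, rows)
  if (is.null(df)) df <- data.frame(isolate_id = character(0),
                                    replicate = integer(0), mz = numeric(0),
                                    intensity = numeric(0))
  PeakSet(df, modes)
}

#' A collection shaped like a full two-host isolation campaign
#'
#' Builds a deterministic 851-isolate collection (522 from host A, 329 from
#' host B) over the full 9 media x 2 pretreatments x 3 dilutions plate
#' factorial per host, with 8 plate conditions marked excluded such that
#' exactly 159 isolates sit on non-matched plates; the matched-plate filter
#' therefore retains exactly 692 isolates. Protein peak lists are simulated
#' over an 11-genus taxonomy; SM spectra are omitted (this preset exists
#' for dendrogram pruning / filter bookkeeping at realistic scale).
#'
#' @param seed RNG seed.
#' @param cfg optional [simConfig()] override; taxonomy sizes and plate
#'   factors are taken from it.
#' @return a `SimDataset` (without SM peaks).
#' @export
campaignFixture <- function(seed = 1L,
                               cfg = simConfig(nGenera = 11L,
                                               speciesPerGenus = 4L,
                                               strainsPerSpecies = 2L)) {
  withSeed(seed, {
    nA <- 522L; nB <- 329L
    plates <- plateGrid(cfg)           # 54 conditions per host
    condKey <- paste(plates$media, plates$pretreatment, plates$dilution,
                     sep = "|")
    nDoomed <- 8L
    doomed <- seq_len(nDoomed)         # first 8 conditions, fixed
    ## per-condition isolate counts: A side 12 per doomed condition (96),
    ## B side 8,8,...,7 (63) -> 159 isolates on non-matched plates
    doomedA <- rep(12L, nDoomed)
    doomedB <- c(rep(8L, nDoomed - 1L), 7L)
    restIdx <- setdiff(seq_len(nrow(plates)), doomed)
    spreadCounts <- function(total, k) {
      base <- total %/% k
      extra <- total %% k
      c(rep(base + 1L, extra), rep(base, k - extra))
    }
    restA <- spreadCounts(nA - sum(doomedA), length(restIdx))
    restB <- spreadCounts(nB - sum(doomedB), length(restIdx))
    mkAssign <- function(counts, idx, source) {
      reps <- rep(idx, counts)
      data.frame(source = source, media = plates$media[reps],
                 pretreatment = plates$pretreatment[reps],
                 dilution = plates$dilution[reps])
    }
    assign <- rbind(mkAssign(doomedA, doomed, "A"),
                    mkAssign(restA, restIdx, "A"),
                    mkAssign(doomedB, doomed, "B"),
                    mkAssign(restB, restIdx, "B"))
    assign$isolate_id <- sprintf("iso%04d", seq_len(nrow(assign)))
    assign$plate_id <- plateId(assign$source, assign$media,
                               assign$pretreatment, assign$dilution)
    ## taxonomy: species occupancy by hostModel, isolates draw a species
    ## occupying their host
    genera <- sprintf("g%02d", seq_len(cfg$nGenera))
    spTab <- expand.grid(spIdx = seq_len(cfg$speciesPerGenus),
                         genus = genera, stringsAsFactors = FALSE)
    spTab$species <- sprintf("%s_s%02d", spTab$genus, spTab$spIdx)
    repeat {
      occ <- sample(c("aOnly", "bOnly", "both"), nrow(spTab), replace = TRUE,
                    prob = cfg$hostModel[c("aOnly", "bOnly", "both")])
      if (any(occ != "bOnly") && any(occ != "aOnly")) break
    }
    spTab$occupancy <- occ
    okA <- spTab$species[occ %in% c("aOnly", "both")]
    okB <- spTab$species[occ %in% c("bOnly", "both")]
    assign$species <- ifelse(assign$source == "A",
                             sample(okA, nrow(assign), replace = TRUE),
                             sample(okB, nrow(assign), replace = TRUE))
    assign$genus <- spTab$genus[match(assign$species, spTab$species)]
    assign$strain <- sprintf("%s_t%02d", assign$species,
                             sample.int(cfg$strainsPerSpecies, nrow(assign),
                                        replace = TRUE))
    iso <- assign[order(assign$isolate_id),
                  c("isolate_id", "genus", "species", "strain", "source",
                    "plate_id", "media", "pretreatment", "dilution")]
    rownames(iso) <- NULL
    truth <- structure(list(isolates = iso,
                            species = spTab[c("species", "genus",
                                              "occupancy")],
                            config = cfg),
                       class = "SimTruth")
    prot <- simulateProteinSpectra(truth, cfg, render = "peaks")
    ## excluded plates: A side for 5 doomed conditions, B side for 3 --
    ## the filter removes counterparts symmetrically either way
    exSide <- c(rep("A", 5L), rep("B", 3L))
    excluded <- plateId(exSide, plates$media[doomed],
                        plates$pretreatment[doomed],
                        plates$dilution[doomed])
    meta <- iso[c("isolate_id", "source", "plate_id", "media",
                  "pretreatment", "dilution", "genus")]
    structure(list(truth = truth, proteinPeaks = prot$peaks,
                   proteinPanels = prot$panels, smPeaks = NULL, sm = NULL,
                   meta = meta, excludedPlates = excluded, config = cfg,
                   seed = seed),
              class = "SimDataset")
  })
}
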