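## End-to-end orchestration: spectra -> consensus -> feature matrices ->
## dendrogram -> matched-plate pruning -> cut-height sweep -> per-group
## MANs -> phylotype-chemotype correlation, with all artifacts on disk so
## stages compose via files and partial reruns are possible.

#' Default pipeline configuration
#'
#' Returns the configuration skeleton consumed by [runPipeline()]; override
#' fields as needed or write it to YAML as a template. Input is either a
#' fixture directory (`input$fixture_dir`, see [emitFixture()]) or a
#' simulation request (`input$simulate = TRUE`, using `input$sim_config`
#' overrides for [simConfig()]).
#'
#' @param output_dir where artifacts are written.
#' @param seed master seed for every stochastic stage.
#' @return nested list of class `PipelineConfig`.
#' @export
defaultPipelineConfig <- function(output_dir = "spectrotype_out", seed = 1L) {
  structure(list(
    seed = seed,
    output_dir = output_dir,
    input = list(fixture_dir = NULL, simulate = FALSE, sim_config = list()),
    preprocess = list(),              # overrides for preprocessParams()
    sweep = list(step = 0.05),
    man = list(cut_height = NULL,     # NULL: half the top merge height
               subgroup_height = NULL,  # NULL: half of cut_height
               min_group_size = 3L,
               global = FALSE),
    correlation = list(min_group_size = 3L, mantel = FALSE,
                       n_perm = 999L),
    plots = FALSE
  ), class = "PipelineConfig")
}

#' Run the full analysis pipeline
#'
#' Executes every stage from a single configuration and writes all tables,
#' trees and graphs into `output_dir`: protein/SM feature matrices and
#' similarity matrices (TSV), full and pruned dendrograms (Newick), the
#' cut-height sweep (TSV, optional plot), per-group MANs (GraphML), the
#' per-group correlation table (TSV) and a YAML run log echoing every
#' parameter value plus the config hash. Each table carries a '#' header
#' with the config hash and seed. Rerunning with the same configuration
#' and seed yields bit-identical outputs.
#'
#' @param config a `PipelineConfig` list (see [defaultPipelineConfig()]) or
#'   the path to a YAML file holding one.
#' @return invisibly, a list with the main in-memory objects and the
#'   output paths.
#' @export
runPipeline <- function(config = defaultPipelineConfig()) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(unclass(defaultPipelineConfig()), config,
                           keep.null = TRUE)
  outDir <- cfg$output_dir
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  ## hash the analysis-relevant configuration (the output location is
  ## provenance-neutral: the same analysis in two directories is one run)
  hashCfg <- cfg[setdiff(names(cfg), "output_dir")]
  stamp <- sprintf("spectrotype config=%s seed=%s", configHash(hashCfg),
                   cfg$seed)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  ## ---- input -------------------------------------------------------------
  dat <- stage("input", {
    if (!is.null(cfg$input$fixture_dir)) {
      loadFixture(cfg$input$fixture_dir)
    } else if (isTRUE(cfg$input$simulate)) {
      sc <- do.call(simConfig, cfg$input$sim_config)
      sim <- simulateDataset(sc, seed = cfg$seed)
      list(proteinPeaks = sim$proteinPeaks, smPeaks = sim$smPeaks,
           meta = sim$meta, excludedPlates = sim$excludedPlates)
    } else stop("config$input must name a fixture_dir or set simulate=TRUE")
  })
  checkMetadataCoverage(dat$meta, dat$proteinPeaks)

  ## ---- preprocessing -----------------------------------------------------
  params <- stage("preprocess-params",
                  do.call(preprocessParams, cfg$preprocess))
  consensus <- stage("consensus", {
    list(protein = consensusByIsolate(dat$proteinPeaks, params),
         sm = if (!is.null(dat$smPeaks))
           consensusByIsolate(dat$smPeaks, params) else NULL)
  })
  fmProt <- stage("binning",
                  binPeaksReference(consensus$protein, params$binTolerance))
  writeFeatureMatrix(fmProt, file.path(outDir, "feature_matrix_protein.tsv"),
                     comment = stamp)
  fmSm <- NULL
  if (!is.null(consensus$sm)) {
    fmSm <- stage("binning-sm",
                  binPeaksReference(consensus$sm, params$binTolerance))
    writeFeatureMatrix(fmSm, file.path(outDir, "feature_matrix_sm.tsv"),
                       comment = stamp)
  }

  ## ---- clustering --------------------------------------------------------
  simProt <- stage("similarity", cosineSimilarity(fmProt))
  writeSimilarityTsv(simProt, file.path(outDir, "similarity_protein.tsv"),
                     stamp)
  dendFull <- stage("dendrogram", wardDendrogram(simProt))
  writeLines(toNewick(dendFull), file.path(outDir, "dendrogram_full.nwk"))
  keep <- stage("matched-plate-filter",
                matchedPlateFilter(dat$meta, dat$excludedPlates))
  keep <- intersect(keep, isolateIds(dendFull))
  dend <- if (length(keep) < nLeaves(dendFull)) {
    pr <- stage("prune", pruneDendrogram(dendFull, keep))
    writeLines(toNewick(pr), file.path(outDir, "dendrogram_pruned.nwk"))
    pr
  } else dendFull

  ## ---- overlap sweep -----------------------------------------------------
  sweep <- stage("sweep", sweepDendrogram(dend, dat$meta,
                                          step = cfg$sweep$step))
  writeTsv(sweep, file.path(outDir, "sweep.tsv"), comment = stamp)
  if (isTRUE(cfg$plots))
    plotSweep(sweep, file.path(outDir, "sweep.png"))

  ## ---- MANs --------------------------------------------------------------
  maxH <- max(mergeHeights(dend))
  cutH <- cfg$man$cut_height %||% (maxH / 2)
  subH <- cfg$man$subgroup_height %||% (cutH / 2)
  part <- stage("cut", cutDendrogram(dend, cutH))
  writePartition(part, file.path(outDir, "partition.tsv"), comment = stamp)
  subPart <- stage("subcut", cutDendrogram(dend, subH))
  mans <- list()
  if (!is.null(fmSm)) {
    groups <- split(names(groupAssignments(part)), groupAssignments(part))
    groups <- groups[lengths(groups) >= cfg$man$min_group_size]
    mans <- stage("man", lapply(names(groups), function(gid) {
      ids <- intersect(groups[[gid]], isolateIds(fmSm))
      if (length(ids) < cfg$man$min_group_size) return(NULL)
      m <- buildMan(fmSm, ids, meta = dat$meta)
      m <- colorByPartition(m, subPart)
      exportGraphml(m, file.path(outDir,
                                 sprintf("man_group_%s.graphml", gid)))
      m
    }))
    names(mans) <- names(groups)
    mans <- Filter(Negate(is.null), mans)
    if (isTRUE(cfg$man$global)) {
      gm <- buildMan(fmSm, intersect(isolateIds(dend), isolateIds(fmSm)),
                     meta = dat$meta)
      exportGraphml(colorByPartition(gm, part),
                    file.path(outDir, "man_global.graphml"))
    }
  }

  ## ---- correlation -------------------------------------------------------
  corTab <- NULL
  if (!is.null(fmSm)) {
    simSm <- stage("similarity-sm", cosineSimilarity(fmSm))
    writeSimilarityTsv(simSm, file.path(outDir, "similarity_sm.tsv"), stamp)
    shared <- intersect(isolateIds(simProt), isolateIds(simSm))
    partShared <- new("IsolatePartition",
                      assignments = groupAssignments(part)[
                        intersect(names(groupAssignments(part)), shared)],
                      method = part@method, parameter = part@parameter)
    corTab <- stage("correlation",
                    pairwiseCorrelation(simProt, simSm, partShared,
                                        cfg$correlation$min_group_size))
    corTab$global_r <- globalPairCorrelation(simProt, simSm)
    if (isTRUE(cfg$correlation$mantel)) {
      groups <- split(names(groupAssignments(partShared)),
                      groupAssignments(partShared))
      corTab$mantel_p <- vapply(corTab$group_id, function(gid) {
        mantelPermutation(simProt, simSm, groups[[gid]],
                          nPerm = cfg$correlation$n_perm,
                          seed = deriveSeed(cfg$seed, 7L))$p
      }, numeric(1))
    }
    writeTsv(corTab, file.path(outDir, "correlation.tsv"), comment = stamp)
  }

  ## ---- run log -----------------------------------------------------------
  log <- list(config = rapply(cfg, as.vector, how = "replace"),
              config_hash = configHash(hashCfg),
              seed = cfg$seed,
              package_version = as.character(utils::packageVersion("spectrotype")),
              r_version = R.version.string,
              n_isolates = nLeaves(dendFull),
              n_isolates_after_filter = nLeaves(dend),
              n_sweep_cuts = nrow(sweep),
              preprocess = params[setdiff(names(params), "")])
  yaml::write_yaml(log, file.path(outDir, "run_log.yaml"))

  invisible(list(featureMatrixProtein = fmProt, featureMatrixSm = fmSm,
                 similarityProtein = simProt, dendrogramFull = dendFull,
                 dendrogram = dend, sweep = sweep, partition = part,
                 mans = mans, correlation = corTab, outputDir = outDir))
}

## similarity matrix as TSV (isolate_id + one column per isolate)
writeSimilarityTsv <- function(sim, path, comment = NULL) {
  v <- similarityValues(sim)
  df <- data.frame(isolate_id = rownames(v),
                   signif(v, 10), check.names = FALSE)
  writeTsv(df, path, comment)
}
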