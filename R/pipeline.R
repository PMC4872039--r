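#' @include AllClasses.R AllGenerics.R synthetic-data.R domain-pca.R
#' @include solvent-density.R state-kinetics.R height-analysis.R
NULL

#' Default pipeline configuration
#'
#' A complete, self-contained run on synthetic data: a two-domain hinge
#' trajectory with a Markov-hydrated pocket, domain PCA, sliding-window
#' density/Q series, state kinetics and height-distribution analysis.
#' Any entry may be overridden via `modifyList`-style nesting in
#' [runPipeline()].
#'
#' @param seed master seed for all stages.
#' @return nested configuration list.
#' @export
defaultRunConfig <- function(seed = 1) {
  list(
    seed = as.integer(seed),
    synthetic = list(
      nFrames = 400, dt = 1,
      hingeAxis = c(0, 0, 1), hingePoint = c(0, 0, 0),
      angleOpen = 0, angleClosed = 18,
      dwellTauOpen = 60, dwellTauClosed = 60,
      atomNoiseSigma = 0.05,
      box = c(24, 24, 24), bulkDensity = 0.0334,
      pocketCenter = c(12, 12, 12), pocketRadius = 3.5,
      pocketWatersPerState = c(dry = 0L, wet = 2L),
      tauWetting = 81, tauDrying = 57),
    pca = list(fitChain = "C", analysisChain = "N",
               openThreshold = 5, closedThreshold = -5),
    density = list(window = 50, stride = 1, exclusionDistance = 4),
    kinetics = list(tMin = 5, qWet = 8, qDry = 4),
    heights = list(normal = c(0, 1, 0), sigma = NULL, binWidth = 1,
                   tipResidues = NULL))
}

deepMerge <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]))
      base[[nm]] <- deepMerge(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

configHash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(as.character(jsonlite::toJSON(config, auto_unbox = TRUE,
                                           digits = NA)), f)
  unname(tools::md5sum(f))
}

writeTSV <- function(df, path) {
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  path
}

#' Run the full hydration-dynamics analysis pipeline
#'
#' Orchestrates trajectory generation (or loading), domain PCA,
#' sliding-window solvent density and pocket charge Q, hydration-state
#' classification and rate fitting, and height-distribution analysis.
#' Stage outputs are written to `outDir` as TSV as soon as each stage
#' completes (partial outputs survive a later failure); a failing stage
#' aborts with its name. The run summary (JSON) carries the seed and a
#' hash of the effective configuration; reruns with the same config are
#' bit-identical.
#'
#' @param config overrides merged onto [defaultRunConfig()] (a YAML file
#'   path is also accepted).
#' @param outDir output directory (created if needed).
#' @return invisibly, a list with the summary and the computed objects.
#' @export
runPipeline <- function(config = list(), outDir = tempfile("hydrokin_run")) {
  if (is.character(config) && length(config) == 1)
    config <- yaml::read_yaml(config)
  cfg <- deepMerge(defaultRunConfig(), config)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  stageNo <- 0
  stage <- function(name, expr) {
    stageNo <<- stageNo + 1
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }
  seed <- cfg$seed
  s <- cfg$synthetic

  scene <- stage("simulate", {
    template <- buildTemplateProtein()
    hcfg <- hingeConfig(nFrames = s$nFrames, dt = s$dt,
                        hingeAxis = s$hingeAxis, hingePoint = s$hingePoint,
                        angleOpen = s$angleOpen,
                        angleClosed = s$angleClosed,
                        dwellTauOpen = s$dwellTauOpen,
                        dwellTauClosed = s$dwellTauClosed,
                        atomNoiseSigma = s$atomNoiseSigma, seed = seed)
    prot <- genHingeTrajectory(hcfg, template)
    # recentre the protein into the water box
    shift <- s$box / 2 - colMeans(coords(template))
    prot@coords <- prot@coords + array(rep(shift, each = nAtoms(prot)),
                                       dim(prot@coords))
    prot@topology@coords <- sweep(prot@topology@coords, 2, shift, "+")
    scheme <- kineticScheme(c("dry", "wet"),
                            c("dry->wet" = s$tauWetting,
                              "wet->dry" = s$tauDrying))
    wcfg <- waterSceneConfig(box = s$box, bulkDensity = s$bulkDensity,
                             pocketCenter = s$pocketCenter,
                             pocketRadius = s$pocketRadius,
                             pocketWatersPerState =
                               s$pocketWatersPerState,
                             scheme = scheme, seed = seed + 100L)
    genWaterScene(wcfg, prot)
  })

  pcaRes <- stage("pca", {
    fitSel <- selectAtoms(scene, chain = cfg$pca$fitChain)
    anaSel <- selectAtoms(scene, chain = cfg$pca$analysisChain,
                          elety = "CA")
    model <- fitPCA(scene, fitSel, anaSel)
    proj <- projectPCA(model, scene)
    cls <- classifyConformation(proj[, 1],
                                openThreshold = cfg$pca$openThreshold,
                                closedThreshold = cfg$pca$closedThreshold)
    writeTSV(data.frame(time = frameTimes(scene), pc1 = proj[, 1],
                        class = cls), file.path(outDir, "projections.tsv"))
    list(model = model, projections = proj, classifications = cls)
  })

  qRes <- stage("density", {
    d <- cfg$density
    anchor <- selectAtoms(scene, chain = cfg$pca$fitChain, elety = "CA")
    grid <- gridFromBox(s$pocketCenter - s$pocketRadius - 2,
                        s$pocketCenter + s$pocketRadius + 2)
    maps <- slidingDensitySeries(scene, windowLength = d$window,
                                 stride = d$stride,
                                 anchorSelection = anchor, grid = grid)
    mask <- maskSphere(grid, s$pocketCenter, s$pocketRadius)
    qs <- integrateQSeries(maps, mask)
    writeTSV(qs, file.path(outDir, "qseries.tsv"))
    list(maps = maps, qSeries = qs,
         bulk = bulkDensity(maps[[1]], d$exclusionDistance))
  })

  kinRes <- stage("kinetics", {
    k <- cfg$kinetics
    dtQ <- with(qRes$qSeries, if (length(tStart) > 1)
      tStart[2] - tStart[1] else 1)
    # wet/dry from Q alone: plateaus at 10 e per prescribed pocket water
    plat <- sort(unique(10 * as.integer(s$pocketWatersPerState)))
    lab <- classifyHS2(qRes$qSeries$Q, plateaus = plat)
    ser <- resolveBoundaries(stateSeries(qRes$qSeries$tStart, lab))
    dw <- extractDwells(ser, tMin = k$tMin)
    rates <- fitAllRates(ser, tMin = k$tMin)
    ts <- transitionStats(ser)
    writeTSV(data.frame(time = stateTimes(ser), state = stateLabels(ser)),
             file.path(outDir, "states.tsv"))
    writeTSV(dw, file.path(outDir, "dwells.tsv"))
    writeTSV(rates, file.path(outDir, "rates.tsv"))
    list(series = ser, dwells = dw, rates = rates, stats = ts)
  })

  htRes <- stage("heights", {
    h <- cfg$heights
    tipRes <- h$tipResidues
    a <- atoms(scene)
    if (is.null(tipRes))
      tipRes <- max(a$resno[a$chain == cfg$pca$analysisChain])
    tip <- selectAtoms(scene, chain = cfg$pca$analysisChain,
                       resno = tipRes)
    hts <- projectHeights(scene, tip, normal = h$normal)
    fit <- fitTwoGaussians(hts, sigmaFixed = h$sigma,
                           binWidth = h$binWidth)
    writeTSV(data.frame(time = frameTimes(scene), height = hts),
             file.path(outDir, "heights.tsv"))
    list(heights = hts, fit = fit)
  })

  summary <- list(
    seed = seed,
    configHash = configHash(cfg),
    nFrames = nFrames(scene),
    nAtoms = nAtoms(scene),
    pc1Fraction = varianceFractions(pcaRes$model)[1],
    classCounts = as.list(table(pcaRes$classifications)),
    bulkDensityPerVoxel = qRes$bulk,
    populations = as.list(kinRes$stats$populations),
    rates = kinRes$rates,
    heightSeparation = htRes$fit@separation,
    heightUnimodal = htRes$fit@unimodal)
  jsonlite::write_json(summary, file.path(outDir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(summary = summary, config = cfg, scene = scene,
                 pca = pcaRes, density = qRes, kinetics = kinRes,
                 heights = htRes, outDir = outDir))
}
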