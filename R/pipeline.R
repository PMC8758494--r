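# Study-shaped orchestration: simulate (or ingest) a cohort, compute
# per-cell gamma metrics / coupling results / event statistics, assemble
# per-metric cohort tables with control normalization, and run the group
# comparison layer. Deterministic under a fixed master seed.

#' Assemble and validate a pipeline run configuration
#'
#' @param mode `"simulate"` (generate a synthetic cohort from `design`) or
#'   `"ingest"` (read recordings listed in a `manifest` CSV with columns
#'   `cellId, genotype, age, lfpPath, cellPath`).
#' @param design a [cohortDesign()] (simulate mode).
#' @param manifest path of the manifest CSV (ingest mode).
#' @param spectral a [spectralConfig()].
#' @param filter a [filterConfig()] for the coupling band.
#' @param spikes a [spikeDetectConfig()].
#' @param eventThreshold scaled-template criterion threshold.
#' @param alpha significance level (Rayleigh gate and contrasts).
#' @param Q ROUT false-outlier rate.
#' @param nMin minimum spike count for a defined coupling vector.
#' @param controlLabel genotype label of the control group.
#' @param metrics subset of `c("power", "coupling", "events")` to compute.
#' @param masterSeed integer master seed (required in simulate mode;
#'   overrides the design's seed when given).
#' @param outDir optional output directory for tables and reports.
#' @param samplingRate sampling rate for ingested CSVs without sidecars.
#' @return a validated list of class `RunConfig`.
#' @export
runConfig <- function(mode = c("simulate", "ingest"), design = NULL,
                      manifest = NULL, spectral = spectralConfig(),
                      filter = filterConfig(), spikes = spikeDetectConfig(),
                      eventThreshold = 3.5, alpha = 0.05, Q = 0.01,
                      nMin = 10, controlLabel = "WT",
                      metrics = c("power", "coupling", "events"),
                      masterSeed = NULL, outDir = NULL, samplingRate = NULL) {
  mode <- match.arg(mode)
  metrics <- match.arg(metrics, several.ok = TRUE)
  stopifnot(inherits(spectral, "SpectralConfig"),
            inherits(filter, "FilterConfig"),
            inherits(spikes, "SpikeDetectConfig"))
  assertScalar(alpha, "alpha", lower = 0, upper = 1, strictLower = TRUE,
               strictUpper = TRUE)
  assertScalar(Q, "Q", lower = 0, upper = 1, strictLower = TRUE,
               strictUpper = TRUE)
  assertScalar(eventThreshold, "eventThreshold", lower = 0, strictLower = TRUE)
  if (mode == "simulate") {
    if (!inherits(design, "CohortDesign"))
      stop("simulate mode requires a cohortDesign()", call. = FALSE)
    if (is.null(masterSeed)) masterSeed <- design$masterSeed
    assertScalar(masterSeed, "masterSeed", lower = 0, upper = 2^31 - 1)
    fs <- design$lfp$samplingRate
    if (spectral$bandHigh > fs / 2)
      stop(sprintf("spectral bandHigh (%g Hz) exceeds the Nyquist frequency (%g Hz)",
                   spectral$bandHigh, fs / 2), call. = FALSE)
    if (filter$highCut >= fs / 2)
      stop(sprintf("filter highCut (%g Hz) must be below the Nyquist frequency (%g Hz)",
                   filter$highCut, fs / 2), call. = FALSE)
  } else {
    if (is.null(manifest) || !file.exists(manifest))
      stop("ingest mode requires an existing manifest CSV", call. = FALSE)
  }
  structure(list(mode = mode, design = design, manifest = manifest,
                 spectral = spectral, filter = filter, spikes = spikes,
                 eventThreshold = eventThreshold, alpha = alpha, Q = Q,
                 nMin = nMin, controlLabel = controlLabel, metrics = metrics,
                 masterSeed = if (is.null(masterSeed)) NA_integer_
                              else as.integer(masterSeed),
                 outDir = outDir, samplingRate = samplingRate),
            class = "RunConfig")
}

#' Read a pipeline configuration from YAML
#'
#' Mirrors the arguments of [runConfig()]; sub-configs are nested maps
#' (`spectral:`, `filter:`, `spikes:`) and the simulate-mode design is a map
#' with `groups` (list of genotype/age/nCells records), optional `effects`
#' and base generator parameter maps (`lfp`, `coupling`, `synaptic`).
#'
#' @param path YAML file path.
#' @return a validated [runConfig()].
#' @export
readRunConfig <- function(path) {
  y <- yaml::read_yaml(path)
  callWith <- function(fun, args) do.call(fun, args[names(args) %in% names(formals(fun))])
  design <- NULL
  if (!is.null(y$design)) {
    groups <- do.call(rbind, lapply(y$design$groups, function(g)
      data.frame(genotype = g$genotype, age = as.character(g$age),
                 nCells = g$nCells, stringsAsFactors = FALSE)))
    design <- cohortDesign(
      groups = groups,
      effects = if (is.null(y$design$effects)) list() else y$design$effects,
      lfp = callWith(gammaLfpParams, y$design$lfp %||% list()),
      coupling = callWith(couplingParams, y$design$coupling %||% list()),
      synaptic = callWith(synapticTraceParams, y$design$synaptic %||% list()),
      masterSeed = y$design$masterSeed %||% 1L)
  }
  args <- list(
    mode = y$mode %||% "simulate", design = design, manifest = y$manifest,
    spectral = callWith(spectralConfig, y$spectral %||% list()),
    filter = callWith(filterConfig, y$filter %||% list()),
    spikes = callWith(spikeDetectConfig, y$spikes %||% list()))
  for (nm in c("eventThreshold", "alpha", "Q", "nMin", "controlLabel",
               "metrics", "masterSeed", "outDir", "samplingRate"))
    if (!is.null(y[[nm]])) args[[nm]] <- y[[nm]]
  do.call(runConfig, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

loadIngestCells <- function(config) {
  man <- read.csv(config$manifest, stringsAsFactors = FALSE)
  need <- c("cellId", "genotype", "age", "lfpPath", "cellPath")
  if (!all(need %in% names(man)))
    stop("manifest must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  base <- dirname(config$manifest)
  resolve <- function(p) if (file.exists(p)) p else file.path(base, p)
  lapply(seq_len(nrow(man)), function(i) {
    list(cellId = man$cellId[i], genotype = man$genotype[i],
         age = as.character(man$age[i]),
         lfp = readTrace(resolve(man$lfpPath[i]),
                         samplingRate = config$samplingRate),
         cellTrace = readTrace(resolve(man$cellPath[i]),
                               samplingRate = config$samplingRate),
         synTrace = NULL, synEvents = NULL)
  })
}

# Per-cell metric computation; any error is caught by the caller and
# quarantined to the ledger.
computeCellMetrics <- function(cell, config) {
  out <- list(cellId = cell$cellId, genotype = cell$genotype, age = cell$age)
  if ("power" %in% config$metrics) {
    ps <- computePowerSpectrum(cell$lfp, config$spectral)
    gm <- gammaMetrics(ps)
    out$bandPower <- bandPower(gm)
    out$peakFrequency <- peakFrequency(gm)
    out$frequencyVariance <- gm@frequencyVariance
  }
  if ("coupling" %in% config$metrics) {
    cellTrace <- cell$cellTrace
    if (is.null(cellTrace))
      cellTrace <- simulateApTrace(cell$spikes, samplingRate(cell$lfp),
                                   seed = deriveSeed(config$masterSeed, 9973L,
                                                     sum(utf8ToInt(cell$cellId))))
    cr <- analyzeCell(cell$lfp, cellTrace, filterCfg = config$filter,
                      spikeCfg = config$spikes, alpha = config$alpha,
                      nMin = config$nMin)
    out$nSpikes <- nSpikes(cr)
    out$vectorLength <- vectorLength(cr)
    out$phaseAngle <- phaseAngle(cr)
    out$rayleighP <- rayleighP(cr)
    out$firingRate <- firingRate(cr)
    out$included <- isIncluded(cr)
    out$exclusionReason <- excludedReason(cr)
  }
  if ("events" %in% config$metrics && !is.null(cell$synTrace)) {
    ev <- cell$synEvents
    kernLen <- round(samplingRate(cell$synTrace) *
                       8 * cell$trueParams$synaptic$decayTau) + 1L
    snips <- extractSnippets(cell$synTrace, ev$onset, kernLen)
    if (length(snips) >= 20L) {
      tpl <- buildTemplate(snips[seq_len(min(40L, length(snips)))],
                           samplingRate(cell$synTrace))
      det <- detectEvents(cell$synTrace, tpl, config$eventThreshold)
      st <- eventStatistics(det, duration(cell$synTrace))
      out$eventAmplitude <- st$meanAmplitude
      out$eventFrequency <- st$frequency
    } else {
      out$eventAmplitude <- NA_real_
      out$eventFrequency <- NA_real_
      out$eventNote <- "fewer than 20 ground-truth events for a template"
    }
  }
  out
}

#' Run the full study-shaped pipeline
#'
#' Simulates (or ingests) a genotype x age cohort, computes the requested
#' per-cell metric families, normalizes band power and frequency variance to
#' the age-matched control mean, assembles per-metric cohort tables, and
#' runs [compareGroups()] per metric. Per-cell failures are quarantined to
#' the inclusion ledger, never fatal; every input cell appears exactly once,
#' either with results or in the ledger.
#'
#' @param config a [runConfig()].
#' @return a [RunReport-class]. If `config$outDir` is set, per-cell and
#'   cohort tables (CSV), comparisons (JSON) and provenance (JSON) are also
#'   written there.
#' @export
runPipeline <- function(config) {
  if (!inherits(config, "RunConfig"))
    stop("'config' must be created with runConfig()", call. = FALSE)
  cells <- if (config$mode == "simulate") {
    design <- config$design
    design$masterSeed <- config$masterSeed
    cohort <- simulateCohort(design,
                             simulateSynaptic = "events" %in% config$metrics)
    cohort$cells
  } else {
    loadIngestCells(config)
  }

  results <- list()
  ledger <- list()
  for (cell in cells) {
    res <- tryCatch(computeCellMetrics(cell, config), error = function(e) e)
    if (inherits(res, "error")) {
      ledger[[length(ledger) + 1L]] <- data.frame(
        cellId = cell$cellId, stage = "per-cell metrics",
        reason = conditionMessage(res), stringsAsFactors = FALSE)
    } else {
      if (!is.null(res$included) && !res$included) {
        reason <- if (nzchar(res$exclusionReason %||% "")) res$exclusionReason
                  else sprintf("Rayleigh p >= %g", config$alpha)
        ledger[[length(ledger) + 1L]] <- data.frame(
          cellId = cell$cellId, stage = "coupling inclusion gate",
          reason = reason, stringsAsFactors = FALSE)
      }
      results[[cell$cellId]] <- res
    }
  }
  perCell <- if (length(results)) {
    cols <- unique(unlist(lapply(results, names)))
    do.call(rbind, lapply(results, function(r) {
      r[setdiff(cols, names(r))] <- NA
      as.data.frame(r[cols], stringsAsFactors = FALSE)
    }))
  } else data.frame()
  rownames(perCell) <- NULL
  ledgerDf <- if (length(ledger))
    do.call(rbind, c(ledger, list(make.row.names = FALSE)))
  else data.frame(cellId = character(0), stage = character(0),
                  reason = character(0), stringsAsFactors = FALSE)

  # control normalization of power metrics within each age
  if (all(c("bandPower", "frequencyVariance") %in% names(perCell)) &&
      any(perCell$genotype == config$controlLabel)) {
    perCell$normPower <- NA_real_
    perCell$normFreqVariance <- NA_real_
    for (a in unique(perCell$age)) {
      inAge <- perCell$age == a
      ctrl <- inAge & perCell$genotype == config$controlLabel
      if (any(ctrl)) {
        perCell$normPower[inAge] <-
          normalizeToControl(perCell$bandPower[inAge], perCell$bandPower[ctrl])
        perCell$normFreqVariance[inAge] <-
          normalizeToControl(perCell$frequencyVariance[inAge],
                             perCell$frequencyVariance[ctrl])
      }
    }
  }

  metricCols <- intersect(c("normPower", "normFreqVariance", "vectorLength",
                            "phaseAngle", "firingRate", "eventAmplitude",
                            "eventFrequency"), names(perCell))
  tables <- list()
  comparisons <- list()
  for (mc in metricCols) {
    keep <- is.finite(perCell[[mc]])
    if (mc %in% c("vectorLength", "phaseAngle"))
      keep <- keep & perCell$included %in% TRUE
    if (!any(keep)) next
    tab <- cohortTable(perCell[[mc]][keep], perCell$genotype[keep],
                       perCell$age[keep], cellId = perCell$cellId[keep])
    tables[[mc]] <- tab
    comparisons[[mc]] <- tryCatch(
      compareGroups(tab, alpha = config$alpha, Q = config$Q,
                    controlLabel = config$controlLabel),
      error = function(e) paste("comparison unavailable:", conditionMessage(e)))
  }

  provenance <- list(
    mode = config$mode, masterSeed = config$masterSeed,
    metrics = config$metrics,
    spectral = unclass(config$spectral), filter = unclass(config$filter),
    spikes = unclass(config$spikes), alpha = config$alpha, Q = config$Q,
    eventThreshold = config$eventThreshold,
    packageVersion = as.character(utils::packageVersion("gammaSpike")))

  report <- new("RunReport", perCell = perCell, tables = tables,
                comparisons = comparisons, ledger = ledgerDf,
                provenance = provenance)
  if (!is.null(config$outDir)) writeRunReport(report, config$outDir)
  report
}

writeRunReport <- function(report, outDir) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report@perCell, file.path(outDir, "per_cell.csv"),
                   row.names = FALSE)
  for (nm in names(report@tables))
    utils::write.csv(report@tables[[nm]],
                     file.path(outDir, sprintf("table_%s.csv", nm)),
                     row.names = FALSE)
  utils::write.csv(report@ledger, file.path(outDir, "inclusion_ledger.csv"),
                   row.names = FALSE)
  comp <- lapply(report@comparisons, function(cr) {
    if (is(cr, "ComparisonResult"))
      list(anova = anovaTable(cr), pairwise = pairwiseTable(cr),
           outliersRemoved = cr@outliersRemoved, notes = cr@notes)
    else cr
  })
  jsonlite::write_json(comp, file.path(outDir, "comparisons.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(report@provenance, file.path(outDir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(outDir)
}
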