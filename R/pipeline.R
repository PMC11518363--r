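#' Pipeline configuration
#'
#' Collects the paths, thresholds and stage parameters of an end-to-end
#' run.  Exactly one input route is used: either `simulation` (a
#' [simulationConfig()], the synthetic route) or `cqTablePath` +
#' `conditionsPath` (a precomputed Cq record table with a sidecar
#' sample-to-condition table).  All referenced paths are checked up front
#' so a misconfigured run fails before any computation.
#'
#' @param gmtPath GMT file with the miRNA set collection.
#' @param evidencePath target-prediction evidence table
#'   (see [readPredictionEvidence()]).
#' @param simulation a [simulationConfig()] or `NULL`.
#' @param cqTablePath precomputed Cq table (columns `sample_id`,
#'   `assay_name`, `cq`, `well_class`, `plate_id`) or `NULL`.
#' @param conditionsPath two-column table (`sample_id`, `condition`)
#'   accompanying `cqTablePath`.
#' @param targetGene consensus target gene.
#' @param seed integer seed controlling every random stage.
#' @param permutations permutation count for the enrichment null.
#' @param pCut,absEsCut report filters, see [applyReportFilters()].
#' @param minTools consensus threshold, see [consensusTargets()].
#' @param tissueMinIndex tissue-set filter, see [filterTissueSets()].
#' @param minSetSize minimum set size, see [restrictToUniverse()].
#' @param metric ranking metric, see [rankDifferential()].
#' @param maxUndetermined detectability filter, see [filterDetected()].
#' @param spikeToleranceSd spike-in QC tolerance, see [qcSpikeIns()].
#' @return a validated `PipelineConfig` list.
#' @export
pipelineConfig <- function(gmtPath,
                           evidencePath = NULL,
                           simulation = simulationConfig(),
                           cqTablePath = NULL,
                           conditionsPath = NULL,
                           targetGene = "WWOX",
                           seed = 1L,
                           permutations = 1000L,
                           pCut = 0.05,
                           absEsCut = 0.25,
                           minTools = 2L,
                           tissueMinIndex = 0.7,
                           minSetSize = 2L,
                           metric = "log2_fold_change",
                           maxUndetermined = 0.5,
                           spikeToleranceSd = 3) {
  .assert(file.exists(gmtPath), "GMT file not found: ", gmtPath)
  if (!is.null(evidencePath))
    .assert(file.exists(evidencePath),
            "evidence file not found: ", evidencePath)
  if (is.null(cqTablePath)) {
    .assert(inherits(simulation, "SimulationConfig"),
            "either a simulation config or a Cq table path is required")
  } else {
    .assert(file.exists(cqTablePath), "Cq table not found: ", cqTablePath)
    .assert(!is.null(conditionsPath) && file.exists(conditionsPath),
            "a conditions table must accompany the Cq table")
  }
  .assert(pCut >= 0 && pCut <= 1, "pCut must lie in [0, 1]")
  .assert(absEsCut >= 0 && absEsCut <= 1, "absEsCut must lie in [0, 1]")
  .assert(tissueMinIndex >= 0 && tissueMinIndex <= 1,
          "tissueMinIndex must lie in [0, 1]")
  .assert(minTools >= 1, "minTools must be >= 1")
  .assert(permutations >= 1, "permutations must be >= 1")
  structure(list(gmtPath = gmtPath, evidencePath = evidencePath,
                 simulation = simulation, cqTablePath = cqTablePath,
                 conditionsPath = conditionsPath, targetGene = targetGene,
                 seed = as.integer(seed),
                 permutations = as.integer(permutations),
                 pCut = pCut, absEsCut = absEsCut,
                 minTools = as.integer(minTools),
                 tissueMinIndex = tissueMinIndex,
                 minSetSize = as.integer(minSetSize), metric = metric,
                 maxUndetermined = maxUndetermined,
                 spikeToleranceSd = spikeToleranceSd),
            class = "PipelineConfig")
}

#' Demo configuration: planted WWOX case-study structure
#'
#' A packaged end-to-end demonstration: the simulator plants the
#' `Coregulate MTOR` set (containing hsa-mir-182) up-regulated and the
#' `Regulated by TWIST1` set (containing hsa-mir-214) down-regulated in
#' the WWOX-deficient condition, enrichment runs against the packaged set
#' collection, and candidate selection joins the packaged WWOX
#' target-prediction evidence.
#'
#' @param seed integer seed.
#' @param permutations permutation count.
#' @return a `PipelineConfig`.
#' @export
#' @examples
#' cfg <- demoConfig(seed = 7)
demoConfig <- function(seed = 1L, permutations = 1000L) {
  gmt <- system.file("extdata", "misea_sets.gmt", package = "qpcrSEA")
  ev <- system.file("extdata", "wwox_predictions.tsv", package = "qpcrSEA")
  coll <- readGmt(gmt)
  planted <- list(
    list(name = "Coregulate MTOR",
         members = members(coll[["Coregulate MTOR"]]), direction = "up"),
    list(name = "Regulated by TWIST1",
         members = members(coll[["Regulated by TWIST1"]]),
         direction = "down"))
  pipelineConfig(gmtPath = gmt, evidencePath = ev,
                 simulation = simulationConfig(plantedSets = planted,
                                               seed = seed),
                 seed = seed, permutations = permutations)
}

#' Read a flat key-value pipeline configuration file
#'
#' Lines of the form `key = value` (comments start with `#`).  Recognized
#' keys: `gmt`, `evidence`, `cq_table`, `conditions`, `target_gene`,
#' `seed`, `permutations`, `p_cut`, `abs_es_cut`, `min_tools`,
#' `tissue_min_index`, `min_set_size`, `metric`, `max_undetermined`,
#' `spike_tolerance_sd`, `n_samples_per_condition`, `n_de_mirnas`,
#' `de_effect_size`, `noise_sd`, `planted_up`, `planted_down` (set names
#' resolved against the GMT collection).
#'
#' @param path configuration file path.
#' @return a `PipelineConfig`.
#' @export
readPipelineConfig <- function(path) {
  .assert(file.exists(path), "config file not found: ", path)
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- lines[grepl("=", lines, fixed = TRUE)]
  kv <- do.call(rbind, strsplit(lines, "=", fixed = TRUE))
  vals <- stats::setNames(trimws(kv[, 2]), trimws(kv[, 1]))
  get <- function(k, default = NULL) if (k %in% names(vals)) vals[[k]] else default
  num <- function(k, default) as.numeric(get(k, default))

  gmt <- get("gmt")
  .assert(!is.null(gmt), "config must name a gmt file")
  planted <- list()
  for (key in c("planted_up", "planted_down")) {
    nm <- get(key)
    if (!is.null(nm)) {
      coll <- readGmt(gmt)
      planted[[length(planted) + 1L]] <-
        list(name = nm, members = members(coll[[nm]]),
             direction = sub("planted_", "", key))
    }
  }
  cp <- defaultCurveParams()
  cp$noiseSd <- num("noise_sd", cp$noiseSd)
  sim <- if (is.null(get("cq_table")))
    simulationConfig(
      nSamplesPerCondition = num("n_samples_per_condition", 3),
      nDeMirnas = num("n_de_mirnas", 0),
      deEffectSize = num("de_effect_size", 2),
      curveParams = cp, plantedSets = planted,
      seed = as.integer(num("seed", 1)))
  else NULL
  pipelineConfig(gmtPath = gmt, evidencePath = get("evidence"),
                 simulation = sim, cqTablePath = get("cq_table"),
                 conditionsPath = get("conditions"),
                 targetGene = get("target_gene", "WWOX"),
                 seed = as.integer(num("seed", 1)),
                 permutations = as.integer(num("permutations", 1000)),
                 pCut = num("p_cut", 0.05),
                 absEsCut = num("abs_es_cut", 0.25),
                 minTools = as.integer(num("min_tools", 2)),
                 tissueMinIndex = num("tissue_min_index", 0.7),
                 minSetSize = as.integer(num("min_set_size", 2)),
                 metric = get("metric", "log2_fold_change"),
                 maxUndetermined = num("max_undetermined", 0.5),
                 spikeToleranceSd = num("spike_tolerance_sd", 3))
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate (synthetic route) or load (precomputed-Cq route),
#' preprocess (Cq calling, interplate calibration, spike-in QC, delta-Cq
#' normalization, detectability filter), rank, enrich, and select, writing
#' every intermediate artifact plus a run manifest (package and R
#' versions, seed, thresholds, input and output MD5 digests) to `outDir`.
#' Identical configuration and seed give byte-identical outputs.
#'
#' @param config a `PipelineConfig` from [pipelineConfig()],
#'   [demoConfig()] or [readPipelineConfig()].
#' @param outDir output directory, created if missing.
#' @param verbose emit per-stage progress messages.
#' @return invisibly, a list with the in-memory stage results: `cq`,
#'   `qc`, `se`, `ranked`, `report`, `filtered`, `candidates`,
#'   `manifest`.
#' @export
#' @examples
#' \donttest{
#' out <- runPipeline(demoConfig(seed = 1, permutations = 200),
#'                    outDir = tempfile("demo_run_"))
#' head(out$candidates)
#' }
runPipeline <- function(config, outDir, verbose = TRUE) {
  .assert(inherits(config, "PipelineConfig"), "config must be a PipelineConfig")
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (verbose) message("[qpcrSEA] ", ...)
  art <- function(f) file.path(outDir, f)
  wtab <- function(df, f) {
    utils::write.table(df, art(f), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    f
  }
  written <- character()

  if (is.null(config$cqTablePath)) {
    say("stage simulate")
    sim <- .stage("simulate", {
      layout <- makeDefaultLayout()
      simulateExperiment(layout, config$simulation)
    })
    written <- c(written, wtab(wells(makeDefaultLayout()), "layout.tsv"),
                 wtab(sim$samples, "samples.tsv"),
                 wtab(sim$truth, "ground_truth.tsv"))
    say("stage preprocess (Cq calling on ",
        length(unique(paste(sim$curves$sample_id, sim$curves$well_id))),
        " wells)")
    cq <- .stage("preprocess", callCqTable(sim$curves, makeDefaultLayout()))
    conditions <- stats::setNames(sim$samples$condition,
                                  sim$samples$sample_id)
  } else {
    say("stage load")
    cq <- .stage("load", {
      df <- utils::read.table(config$cqTablePath, header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE)
      need <- c("sample_id", "assay_name", "cq", "well_class", "plate_id")
      .assert(all(need %in% names(df)),
              "Cq table must have columns ", paste(need, collapse = ", "))
      df
    })
    cdf <- utils::read.table(config$conditionsPath, header = TRUE,
                             sep = "\t", stringsAsFactors = FALSE)
    conditions <- stats::setNames(cdf$condition, cdf$sample_id)
  }

  cq <- .stage("preprocess", interplateCalibrate(cq))
  qc <- .stage("preprocess", qcSpikeIns(cq, config$spikeToleranceSd))
  se <- .stage("preprocess", {
    se <- normalizeDeltaCq(cq, conditions)
    filterDetected(se, config$maxUndetermined)
  })
  written <- c(written, wtab(cq, "cq_table.tsv"), wtab(qc, "qc_report.tsv"))
  expr <- SummarizedExperiment::assay(se, "relexpr")
  written <- c(written,
               wtab(data.frame(mirna = rownames(expr), expr,
                               check.names = FALSE), "expression_matrix.tsv"),
               wtab(data.frame(
                 sample_id = colnames(expr),
                 condition = SummarizedExperiment::colData(se)$condition),
                 "conditions.tsv"))

  say("stage rank")
  ranked <- .stage("rank", rankDifferential(se, metric = config$metric))
  writeRankedList(ranked, art("ranked_list.tsv"))
  written <- c(written, "ranked_list.tsv")

  say("stage enrich (", config$permutations, " permutations)")
  report <- .stage("enrich", {
    coll <- filterTissueSets(readGmt(config$gmtPath), config$tissueMinIndex)
    mirnaSEA(ranked, coll, permutations = config$permutations,
             seed = config$seed, minSize = config$minSetSize)
  })
  filtered <- applyReportFilters(report, config$pCut, config$absEsCut)
  writeEnrichmentReport(report, art("enrichment_report.tsv"))
  writeEnrichmentReport(filtered, art("enrichment_report_filtered.tsv"))
  written <- c(written, "enrichment_report.tsv",
               "enrichment_report_filtered.tsv",
               wtab(significancePlotData(report), "plot_significance.tsv"),
               wtab(esPlotData(report), "plot_es_rank.tsv"))

  say("stage select")
  candidates <- .stage("select", {
    if (is.null(config$evidencePath)) {
      annotateCandidates(filtered, structure(list(), names = character()))
    } else {
      ev <- readPredictionEvidence(config$evidencePath)
      cons <- consensusTargets(ev, config$targetGene, config$minTools)
      annotateCandidates(filtered, cons)
    }
  })
  written <- c(written, wtab(candidates, "candidates.tsv"))

  inputs <- c(gmt = config$gmtPath, evidence = config$evidencePath,
              cq_table = config$cqTablePath,
              conditions = config$conditionsPath)
  inputs <- inputs[!vapply(inputs, is.null, logical(1))]
  manifest <- list(
    package = "qpcrSEA",
    package_version = as.character(utils::packageVersion("qpcrSEA")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    thresholds = list(p_cut = config$pCut, abs_es_cut = config$absEsCut,
                      min_tools = config$minTools,
                      tissue_min_index = config$tissueMinIndex,
                      min_set_size = config$minSetSize),
    permutations = config$permutations,
    metric = config$metric,
    input_md5 = as.list(tools::md5sum(unlist(inputs))),
    output_md5 = as.list(tools::md5sum(file.path(outDir, written))))
  jsonlite::write_json(manifest, art("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  say("done: ", length(written) + 1L, " artifacts in ", outDir)
  invisible(list(cq = cq, qc = qc, se = se, ranked = ranked,
                 report = report, filtered = filtered,
                 candidates = candidates, manifest = manifest))
}
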