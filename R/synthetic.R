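#' Default amplification-curve parameters
#'
#' Parameters of the four-parameter logistic curve model used by the
#' simulator: plateau fluorescence `fmax`, slope `k` (per cycle), baseline
#' fluorescence, and the standard deviation `noiseSd` of additive i.i.d.
#' Gaussian noise on the fluorescence readings.  Units are arbitrary
#' fluorescence units; the defaults give a high signal-to-noise trace
#' typical of a well-behaved LNA qPCR assay.
#'
#' @return a named list with elements `fmax`, `k`, `baseline`, `noiseSd`.
#' @export
#' @examples
#' defaultCurveParams()
defaultCurveParams <- function() {
  list(fmax = 10, k = 1, baseline = 1, noiseSd = 0.1)
}

#' Default miRNome panel layout
#'
#' Builds the 384-well layout of a human miRNome PCR panel: 372 miRNA
#' assays, three interplate calibrators, three reference-gene assays, five
#' RNA spike-in controls and one blank well.  miRNA assay names come from a
#' packaged representative human miRNA list
#' (`inst/extdata/panel_assays.txt`).
#'
#' @param plateId plate identifier for the layout.
#' @return a [PanelLayout-class] with 384 wells.
#' @export
#' @examples
#' lay <- makeDefaultLayout()
#' table(wells(lay)$well_class)
makeDefaultLayout <- function(plateId = "plate_01") {
  assays <- readLines(system.file("extdata", "panel_assays.txt",
                                  package = "qpcrSEA"))
  .assert(length(assays) == 372L, "packaged panel assay list must have 372 names")
  wellIds <- paste0(rep(LETTERS[1:16], each = 24),
                    sprintf("%02d", rep(1:24, times = 16)))
  assayName <- c(assays,
                 paste0("UniSp3_IPC_", 1:3),
                 c("SNORD48", "SNORD49A", "U6-snRNA"),
                 c("UniSp2", "UniSp4", "UniSp5", "UniSp6", "cel-mir-39-3p"),
                 NA_character_)
  wellClass <- c(rep("mirna_assay", 372L),
                 rep("interplate_calibrator", 3L),
                 rep("reference_gene", 3L),
                 rep("spike_in", 5L),
                 "blank")
  new("PanelLayout",
      wells = data.frame(well_id = wellIds, assay_name = assayName,
                         well_class = wellClass, stringsAsFactors = FALSE),
      plateId = plateId)
}

#' Simulation configuration for a two-condition panel experiment
#'
#' Collects and validates all parameters of the synthetic experiment: the
#' replicate count per condition, the number of randomly planted
#' differential miRNAs and their log2 fold-change magnitude `deEffectSize`
#' (in Cq cycles; one cycle = one log2 unit of expression), the curve
#' model, optional planted enriched sets with a coherent direction, the
#' between-plate Cq offset spread, and the seed that makes the whole
#' simulation reproducible.
#'
#' Direction semantics follow qPCR convention: an `up`-regulated miRNA has
#' its true Cq in the second (test) condition lowered by `deEffectSize`
#' cycles.
#'
#' @param nSamplesPerCondition replicates per condition (>= 1).
#' @param nDeMirnas number of randomly chosen differential miRNAs (outside
#'   any planted set).
#' @param deEffectSize positive Cq shift magnitude for differential miRNAs.
#' @param curveParams curve model parameters, see [defaultCurveParams()].
#' @param plantedSets list of `list(name=, members=, direction=)` entries;
#'   `direction` is `"up"` or `"down"` and members must be panel assays.
#' @param seed integer seed for the simulation.
#' @param conditions character(2): condition labels, the second being the
#'   test condition.
#' @param cycles integer cycle index of every curve.
#' @param interplateSd standard deviation of the per-plate Cq offset.
#' @return a validated `SimulationConfig` list.
#' @export
#' @examples
#' cfg <- simulationConfig(nDeMirnas = 5, seed = 7)
simulationConfig <- function(nSamplesPerCondition = 3L,
                             nDeMirnas = 0L,
                             deEffectSize = 2,
                             curveParams = defaultCurveParams(),
                             plantedSets = list(),
                             seed = 1L,
                             conditions = c("WWOX_sufficient",
                                            "WWOX_deficient"),
                             cycles = 1:45,
                             interplateSd = 0.2) {
  .assert(nSamplesPerCondition >= 1, "nSamplesPerCondition must be >= 1")
  .assert(nDeMirnas >= 0, "nDeMirnas must be >= 0")
  .assert(is.finite(deEffectSize) && deEffectSize > 0,
          "deEffectSize must be positive and finite")
  .assert(all(c("fmax", "k", "baseline", "noiseSd") %in% names(curveParams)),
          "curveParams must have fmax, k, baseline, noiseSd")
  .assert(curveParams$fmax > 0 && curveParams$k > 0 &&
            curveParams$noiseSd >= 0 && is.finite(curveParams$noiseSd),
          "curveParams must satisfy fmax > 0, k > 0, noiseSd >= 0, all finite")
  .assert(length(conditions) == 2L && !anyDuplicated(conditions),
          "conditions must be two distinct labels")
  .assert(interplateSd >= 0, "interplateSd must be >= 0")
  for (ps in plantedSets) {
    .assert(all(c("name", "members", "direction") %in% names(ps)),
            "each planted set needs name, members, direction")
    .assert(ps$direction %in% c("up", "down"),
            "planted-set direction must be 'up' or 'down'")
  }
  structure(list(nSamplesPerCondition = as.integer(nSamplesPerCondition),
                 nDeMirnas = as.integer(nDeMirnas),
                 deEffectSize = deEffectSize,
                 curveParams = curveParams,
                 plantedSets = plantedSets,
                 seed = as.integer(seed),
                 conditions = conditions,
                 cycles = as.integer(cycles),
                 interplateSd = interplateSd),
            class = "SimulationConfig")
}

## SDM of a logistic with midpoint m and slope k sits at m - ln(2+sqrt(3))/k
.SDM_SHIFT <- log(2 + sqrt(3))

#' Simulate one amplification curve
#'
#' Generates a four-parameter logistic fluorescence trace whose
#' second-derivative-maximum cycle equals `trueCq`: the logistic midpoint is
#' placed at `trueCq + ln(2 + sqrt(3)) / k`.  Additive Gaussian noise with
#' standard deviation `noiseSd` is drawn from the caller's RNG state.
#'
#' @param trueCq the target SDM cycle; must lie within `cycles`.
#' @param curveParams curve model, see [defaultCurveParams()].
#' @param cycles integer cycle index (strictly increasing, >= 10 cycles).
#' @return data.frame with columns `cycle` and `fluorescence`.
#' @export
#' @examples
#' set.seed(1)
#' head(simulateCurve(23.7))
simulateCurve <- function(trueCq, curveParams = defaultCurveParams(),
                          cycles = 1:45) {
  .assert(length(cycles) >= 10L && all(diff(cycles) > 0),
          "cycles must be >= 10 strictly increasing values")
  if (trueCq < min(cycles) || trueCq > max(cycles))
    stop("trueCq (", trueCq, ") outside the cycle range [",
         min(cycles), ", ", max(cycles), "]", call. = FALSE)
  p <- curveParams
  m <- trueCq + .SDM_SHIFT / p$k
  f <- p$baseline + p$fmax / (1 + exp(-p$k * (cycles - m)))
  if (p$noiseSd > 0) f <- f + stats::rnorm(length(cycles), 0, p$noiseSd)
  data.frame(cycle = cycles, fluorescence = f)
}

#' Simulate a full two-condition panel experiment
#'
#' Draws per-assay baseline Cq values, applies condition-specific Cq shifts
#' to randomly planted differential miRNAs and to the members of planted
#' enriched sets (coherently in the stated direction), adds one Cq offset
#' per plate (one plate per sample), and renders every well as a noisy
#' amplification curve.  Blank wells yield flat no-amplification traces.
#' Reference genes, calibrators and spike-ins are condition-invariant by
#' construction.
#'
#' @param layout a [PanelLayout-class]; one physical plate is simulated per
#'   sample using this layout.
#' @param config a [simulationConfig()] object.
#' @return a list with elements
#'   \describe{
#'     \item{curves}{long data.frame: `plate_id`, `well_id`, `sample_id`,
#'       `cycle`, `fluorescence`.}
#'     \item{samples}{data.frame: `sample_id`, `condition`, `plate_id`.}
#'     \item{truth}{ground truth: `assay_name`, `direction`, `delta`,
#'       `source` for every planted differential miRNA.}
#'     \item{trueCq}{per sample and well the noiseless SDM cycle (`NA` for
#'       the blank), including the plate offset.}
#'   }
#' @export
#' @examples
#' lay <- makeDefaultLayout()
#' sim <- simulateExperiment(lay, simulationConfig(nDeMirnas = 3, seed = 2))
#' sim$truth
simulateExperiment <- function(layout, config = simulationConfig()) {
  .assert(is(layout, "PanelLayout"), "layout must be a PanelLayout")
  w <- wells(layout)
  mirnas <- w$assay_name[w$well_class == "mirna_assay"]
  planted <- character()
  for (ps in config$plantedSets) {
    mem <- normalizeMirnaNames(ps$members)
    bad <- setdiff(mem, mirnas)
    if (length(bad))
      stop("planted-set member(s) absent from the panel layout: ",
           paste(bad, collapse = ", "), call. = FALSE)
    planted <- c(planted, mem)
  }
  .assert(!anyDuplicated(planted), "planted sets must not share members")

  withSeed(config$seed, {
    p <- config$curveParams
    cycles <- config$cycles
    nW <- nrow(w)

    ## per-assay baseline Cq (condition 1 truth)
    baseCq <- numeric(nW)
    isMir <- w$well_class == "mirna_assay"
    baseCq[isMir] <- pmin(pmax(stats::rnorm(sum(isMir), 25, 3), 18), 33)
    baseCq[w$well_class == "interplate_calibrator"] <- 20
    baseCq[w$well_class == "reference_gene"] <- c(19, 20, 21)
    baseCq[w$well_class == "spike_in"] <- c(21, 21.5, 22, 22.5, 23)
    baseCq[w$well_class == "blank"] <- NA_real_

    ## condition-2 Cq shift per well: up-regulated => lower Cq
    pool <- setdiff(mirnas, planted)
    .assert(config$nDeMirnas <= length(pool),
            "nDeMirnas exceeds the number of free panel miRNAs")
    deNames <- if (config$nDeMirnas > 0)
      sort(sample(pool, config$nDeMirnas)) else character()
    deDir <- if (length(deNames))
      sample(c("up", "down"), length(deNames), replace = TRUE) else character()
    truth <- data.frame(assay_name = deNames, direction = deDir,
                        delta = rep(config$deEffectSize, length(deNames)),
                        source = rep("random_de", length(deNames)),
                        stringsAsFactors = FALSE)
    for (ps in config$plantedSets) {
      mem <- normalizeMirnaNames(ps$members)
      truth <- rbind(truth,
                     data.frame(assay_name = mem,
                                direction = ps$direction,
                                delta = config$deEffectSize,
                                source = paste0("planted_set:", ps$name),
                                stringsAsFactors = FALSE))
    }
    shift <- numeric(nW)
    if (nrow(truth)) {
      j <- match(truth$assay_name, w$assay_name)
      shift[j] <- ifelse(truth$direction == "up", -1, 1) * truth$delta
    }

    nPer <- config$nSamplesPerCondition
    sampleIds <- c(paste0(config$conditions[1], "_", seq_len(nPer)),
                   paste0(config$conditions[2], "_", seq_len(nPer)))
    sampleCond <- rep(config$conditions, each = nPer)
    plateIds <- paste0("plate_", sampleIds)
    plateOffset <- if (config$interplateSd > 0)
      stats::rnorm(length(sampleIds), 0, config$interplateSd)
    else rep(0, length(sampleIds))

    curveList <- vector("list", length(sampleIds))
    trueCqList <- vector("list", length(sampleIds))
    for (si in seq_along(sampleIds)) {
      cq <- baseCq + plateOffset[si]
      if (sampleCond[si] == config$conditions[2]) cq <- cq + shift
      ## render all wells at once: cycles x wells logistic + noise
      m <- cq + .SDM_SHIFT / p$k
      fm <- p$baseline + p$fmax / (1 + exp(-p$k * outer(cycles, m, "-")))
      fm[, is.na(cq)] <- p$baseline   # blank: flat, no amplification
      if (p$noiseSd > 0)
        fm <- fm + stats::rnorm(length(fm), 0, p$noiseSd)
      curveList[[si]] <- data.frame(
        plate_id = plateIds[si], well_id = rep(w$well_id, each = length(cycles)),
        sample_id = sampleIds[si], cycle = rep(cycles, times = nW),
        fluorescence = as.vector(fm), stringsAsFactors = FALSE)
      trueCqList[[si]] <- data.frame(
        sample_id = sampleIds[si], well_id = w$well_id,
        assay_name = w$assay_name, true_cq = cq, stringsAsFactors = FALSE)
    }
    list(curves = do.call(rbind, curveList),
         samples = data.frame(sample_id = sampleIds, condition = sampleCond,
                              plate_id = plateIds, stringsAsFactors = FALSE),
         truth = truth,
         trueCq = do.call(rbind, trueCqList))
  })
}
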