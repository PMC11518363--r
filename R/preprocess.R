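#' Call the quantification cycle by the second-derivative maximum
#'
#' Returns the sub-cycle position of the maximum of the second derivative of
#' the amplification curve.  The trace is screened for amplification (the
#' smoothed amplitude rise must exceed `detectionNoiseMult` times a robust
#' baseline-noise estimate), then a four-parameter logistic
#' `b + a / (1 + exp(-k (c - m)))` is fitted by Levenberg–Marquardt least
#' squares and the SDM is taken in closed form at `m - ln(2 + sqrt(3)) / k`.
#' Traces without detectable amplification (e.g. blank wells), failed fits,
#' or SDM positions outside the observed cycle range return `NA`
#' (undetermined).
#'
#' The moving-average smoothing window is used only for the detection screen
#' and the fit's starting values; the fit itself runs on the raw trace, so
#' smoothing cannot bias the Cq estimate.
#'
#' @param fluorescence numeric fluorescence trace.
#' @param cycles cycle index, strictly increasing, length >= 10.
#' @param smoothingWindow odd moving-average window (< number of cycles)
#'   for the detection screen and starting values.
#' @param detectionNoiseMult amplitude rise must exceed this multiple of
#'   the baseline noise estimate to count as amplification.
#' @return the Cq in cycles, or `NA_real_` when undetermined.
#' @export
#' @examples
#' cv <- simulateCurve(23.683, within(defaultCurveParams(), noiseSd <- 0))
#' callCqSdm(cv$fluorescence, cv$cycle)   # ~ 23.683
callCqSdm <- function(fluorescence, cycles = seq_along(fluorescence),
                      smoothingWindow = 5L, detectionNoiseMult = 5) {
  .assert(length(fluorescence) == length(cycles),
          "fluorescence and cycles lengths differ")
  .assert(length(cycles) >= 10L, "need at least 10 cycles")
  if (any(diff(cycles) <= 0))
    stop("cycle index must be strictly increasing", call. = FALSE)
  .assert(all(is.finite(fluorescence)), "fluorescence must be finite")
  .assert(smoothingWindow %% 2 == 1 && smoothingWindow >= 1 &&
            smoothingWindow < length(cycles),
          "smoothingWindow must be odd and smaller than the cycle count")

  ## robust noise estimate from first differences (signal-sparse for qPCR)
  noise <- stats::mad(diff(fluorescence)) / sqrt(2)

  s <- if (smoothingWindow > 1)
    as.numeric(stats::filter(fluorescence,
                             rep(1 / smoothingWindow, smoothingWindow),
                             sides = 2))
  else fluorescence
  ok <- !is.na(s)
  rise <- diff(range(s[ok]))
  detect <- max(detectionNoiseMult * noise,
                1e-6 * max(1, abs(stats::median(fluorescence))))
  if (rise < detect) return(NA_real_)

  b0 <- min(s[ok])
  a0 <- rise
  half <- b0 + a0 / 2
  m0 <- cycles[ok][which.min(abs(s[ok] - half))]
  ds <- max(diff(s[ok]) / diff(cycles[ok]))
  k0 <- min(5, max(0.1, 4 * ds / a0))
  co <- .fit4pl(cycles, fluorescence, c(b = b0, a = a0, k = k0, m = m0))
  if (is.null(co) || !is.finite(co[["k"]]) || co[["k"]] <= 0 ||
      co[["a"]] < detect)
    return(NA_real_)
  cq <- co[["m"]] - .SDM_SHIFT / co[["k"]]
  if (cq < min(cycles) || cq > max(cycles)) return(NA_real_)
  unname(cq)
}

## Levenberg-Marquardt fit of b + a / (1 + exp(-k (c - m))) with analytic
## Jacobian; returns the coefficient vector or NULL on failure.
.fit4pl <- function(cycles, y, start) {
  resid <- function(p)
    y - (p[1] + p[2] / (1 + exp(-p[3] * (cycles - p[4]))))
  jac <- function(p) {
    e <- exp(-p[3] * (cycles - p[4]))
    L <- 1 / (1 + e)
    -cbind(1, L, p[2] * L^2 * e * (cycles - p[4]), -p[2] * L^2 * e * p[3])
  }
  fit <- tryCatch(
    minpack.lm::nls.lm(start, fn = resid, jac = jac,
                       control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit) || fit$info < 1 || fit$info > 4) return(NULL)
  fit$par
}

#' Call Cq values for a whole curve table
#'
#' Applies [callCqSdm()] to every (sample, well) trace of a long-format
#' curve table and attaches the assay annotation from the panel layout.
#'
#' @param curves long data.frame with columns `plate_id`, `well_id`,
#'   `sample_id`, `cycle`, `fluorescence` (as written by
#'   [simulateExperiment()]).
#' @param layout the [PanelLayout-class] mapping wells to assays.
#' @param ... passed to [callCqSdm()].
#' @return a Cq record data.frame: `sample_id`, `assay_name`, `cq`,
#'   `well_class`, `plate_id` (one row per non-blank and blank well alike;
#'   undetermined Cq is `NA`).
#' @export
callCqTable <- function(curves, layout, ...) {
  need <- c("plate_id", "well_id", "sample_id", "cycle", "fluorescence")
  .assert(all(need %in% names(curves)),
          "curves must have columns ", paste(need, collapse = ", "))
  w <- wells(layout)
  key <- paste(curves$sample_id, curves$well_id, sep = "\r")
  o <- order(key, curves$cycle)
  curves <- curves[o, ]
  key <- key[o]
  start <- which(!duplicated(key))
  end <- c(start[-1] - 1L, length(key))
  fl <- curves$fluorescence
  cy <- curves$cycle
  cq <- vapply(seq_along(start), function(g) {
    i <- start[g]:end[g]
    callCqSdm(fl[i], cy[i], ...)
  }, numeric(1))
  j <- match(curves$well_id[start], w$well_id)
  .assert(!anyNA(j), "curve table contains wells absent from the layout")
  data.frame(sample_id = curves$sample_id[start],
             assay_name = w$assay_name[j],
             cq = cq,
             well_class = w$well_class[j],
             plate_id = curves$plate_id[start],
             stringsAsFactors = FALSE)
}

#' Interplate calibration
#'
#' Removes between-plate Cq offsets using the interplate calibrator assays:
#' for every plate, the plate-mean calibrator Cq minus the global mean of
#' the plate-mean calibrator Cqs is subtracted from every Cq on that plate.
#' Applying the calibration twice therefore equals applying it once.
#'
#' @param cq a Cq record data.frame with columns `sample_id`, `assay_name`,
#'   `cq`, `well_class`, `plate_id`.
#' @return the calibrated Cq records, with the per-plate offsets attached
#'   as `attr(, "plate_offsets")`.
#' @export
interplateCalibrate <- function(cq) {
  cal <- cq[cq$well_class == "interplate_calibrator", ]
  .assert(nrow(cal) > 0, "no interplate calibrator records present")
  plateMean <- tapply(cal$cq, cal$plate_id, mean, na.rm = TRUE)
  bad <- names(plateMean)[!is.finite(plateMean)]
  if (length(bad))
    stop("QC failure: plate(s) with no defined calibrator Cq: ",
         paste(bad, collapse = ", "), call. = FALSE)
  missing <- setdiff(unique(cq$plate_id), names(plateMean))
  if (length(missing))
    stop("QC failure: plate(s) without calibrator wells: ",
         paste(missing, collapse = ", "), call. = FALSE)
  offset <- c(plateMean - mean(plateMean))
  cq$cq <- as.numeric(cq$cq - offset[cq$plate_id])
  attr(cq, "plate_offsets") <- offset
  cq
}

#' Spike-in quality control
#'
#' Flags samples whose spike-in Cq deviates from the cross-sample location
#' of the same spike-in assay by more than `toleranceSd` scale units.
#' Location and scale are estimated robustly (median and MAD) so that a
#' single strongly deviating sample cannot mask itself by inflating the
#' scale estimate at small sample counts.  Undetermined spike-in Cq also
#' fails the sample.  Blank and non-spike-in wells are ignored.
#'
#' @param cq a Cq record data.frame (see [interplateCalibrate()]).
#' @param toleranceSd allowed deviation in robust standard-deviation
#'   (MAD) units.
#' @return data.frame with one row per sample: `sample_id`,
#'   `n_spike_ins`, `max_abs_z`, `pass`.  Empty when no spike-in records
#'   are present.
#' @export
qcSpikeIns <- function(cq, toleranceSd = 3) {
  sp <- cq[cq$well_class == "spike_in", ]
  if (nrow(sp) == 0)
    return(data.frame(sample_id = character(), n_spike_ins = integer(),
                      max_abs_z = numeric(), pass = logical()))
  mu <- c(tapply(sp$cq, sp$assay_name, stats::median, na.rm = TRUE))
  sdv <- c(tapply(sp$cq, sp$assay_name, stats::mad, na.rm = TRUE))
  sdv[!is.finite(sdv)] <- 0
  z <- (sp$cq - mu[sp$assay_name]) /
    ifelse(sdv[sp$assay_name] > 0, sdv[sp$assay_name], 1)
  z[sdv[sp$assay_name] == 0 & is.finite(z)] <-
    ifelse(abs(z[sdv[sp$assay_name] == 0 & is.finite(z)]) > 0, Inf, 0)
  z[is.na(sp$cq)] <- Inf     # undetermined spike-in fails the sample
  maxZ <- tapply(abs(z), sp$sample_id, max)
  data.frame(sample_id = names(maxZ),
             n_spike_ins = as.integer(table(sp$sample_id)[names(maxZ)]),
             max_abs_z = as.numeric(maxZ),
             pass = as.numeric(maxZ) <= toleranceSd,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Reference-gene delta-Cq normalization
#'
#' Per sample, computes `dCq(miRNA) = Cq(miRNA) - mean(reference Cq)` over
#' the defined reference-gene Cqs and converts to relative expression
#' `2^(-dCq)`.  Undetermined miRNA Cq propagates to a missing value (`NA`),
#' never to zero.  Adding a constant to every Cq of a sample leaves the
#' result unchanged, since the reference subtraction removes it.
#'
#' @param cq a Cq record data.frame (see [interplateCalibrate()]).
#' @param conditions named character vector mapping every sample id to one
#'   of exactly two condition labels.
#' @return a [SummarizedExperiment::SummarizedExperiment] with assay
#'   `relexpr` (miRNAs x samples) and a `condition` column in `colData`.
#' @export
normalizeDeltaCq <- function(cq, conditions) {
  samples <- unique(cq$sample_id)
  .assert(all(samples %in% names(conditions)),
          "conditions must name every sample in the Cq table")
  ## column order follows the conditions vector, so its first label is the
  ## reference condition downstream (see rankDifferential)
  samples <- intersect(names(conditions), samples)
  cond <- conditions[samples]
  .assert(length(unique(cond)) == 2L,
          "exactly two distinct condition labels are required")

  ref <- cq[cq$well_class == "reference_gene", ]
  refMean <- tapply(ref$cq, ref$sample_id, mean, na.rm = TRUE)
  bad <- samples[!samples %in% names(refMean) | !is.finite(refMean[samples])]
  if (length(bad))
    stop("QC failure: sample(s) with no defined reference-gene Cq: ",
         paste(bad, collapse = ", "), call. = FALSE)

  mir <- cq[cq$well_class == "mirna_assay", ]
  assays <- unique(mir$assay_name)
  mat <- matrix(NA_real_, nrow = length(assays), ncol = length(samples),
                dimnames = list(assays, samples))
  mat[cbind(match(mir$assay_name, assays), match(mir$sample_id, samples))] <-
    2^(-(mir$cq - refMean[mir$sample_id]))
  SummarizedExperiment::SummarizedExperiment(
    assays = list(relexpr = mat),
    colData = S4Vectors::DataFrame(condition = unname(cond),
                                   row.names = samples))
}

#' Drop miRNAs with too many undetermined values
#'
#' Removes miRNAs whose relative expression is missing in more than
#' `maxUndetermined` (fraction) of the samples of either condition, the
#' detectability filter applied before differential ranking.
#'
#' @param se SummarizedExperiment from [normalizeDeltaCq()].
#' @param maxUndetermined maximum tolerated missing fraction per condition.
#' @return the filtered SummarizedExperiment.
#' @export
filterDetected <- function(se, maxUndetermined = 0.5) {
  mat <- SummarizedExperiment::assay(se, "relexpr")
  cond <- SummarizedExperiment::colData(se)$condition
  keep <- rep(TRUE, nrow(mat))
  for (cl in unique(cond)) {
    sub <- mat[, cond == cl, drop = FALSE]
    keep <- keep & rowMeans(is.na(sub)) <= maxUndetermined
  }
  se[keep, ]
}
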