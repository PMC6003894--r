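#' Analyze one patient: volumes and masks to a metrics row
#'
#' Runs the full per-patient pipeline: resample the PET volume onto the ADC
#' grid, segment the metabolic tumor volume at \code{thresholdFraction} of
#' SUVmax within the tumor VOI, compute the global PET and ADC metrics,
#' extract matched voxel (SUV, ADC) pairs and fit their least-squares /
#' Pearson association.
#'
#' @param pet PET \linkS4class{ImageVolume} (native grid).
#' @param adc ADC \linkS4class{ImageVolume}.
#' @param tumorVoi \linkS4class{RegionMask} of the tumor on the ADC grid
#'   (the primary tumor definition; set \code{pairRegion = "MTV"} to extract
#'   pairs within the PET-segmented MTV instead, for tumors that are not
#'   delineable on ADC).
#' @param muscle Optional muscle \linkS4class{RegionMask} on the ADC grid.
#' @param id Patient identifier.
#' @param thresholdFraction MTV threshold as a fraction of SUVmax.
#' @param method Interpolation for the PET resampling.
#' @param pairRegion \code{"VOI"} (default) or \code{"MTV"}.
#' @return One-row data.frame: id, the nine global metrics (SUVmax, SUVmean,
#'   SUV_TM, MTV, TLG, ADCmin, ADCmean, ADC_TM, ADCvol) and the association
#'   fields (r, slope, intercept, p, n).
#' @export
analyzePatient <- function(pet, adc, tumorVoi, muscle = NULL, id = "patient",
                           thresholdFraction = 0.4,
                           method = c("trilinear", "nearest"),
                           pairRegion = c("VOI", "MTV")) {
  method <- match.arg(method)
  pairRegion <- match.arg(pairRegion)
  petOn <- resampleToGrid(pet, adc, method = method)
  mtv <- segmentMTV(petOn, tumorVoi, thresholdFraction)
  pm <- computePetMetrics(petOn, tumorVoi, mtv, muscle)
  am <- computeAdcMetrics(adc, tumorVoi, muscle)
  region <- if (pairRegion == "VOI") tumorVoi else mtv
  pairs <- extractPairs(petOn, adc, region, id = id)
  assoc <- fitAssociation(pairs)
  data.frame(id = id,
             SUVmax = pm$SUVmax, SUVmean = pm$SUVmean, SUV_TM = pm$SUV_TM,
             MTV = pm$MTV, TLG = pm$TLG,
             ADCmin = am$ADCmin, ADCmean = am$ADCmean, ADC_TM = am$ADC_TM,
             ADCvol = am$ADCvol,
             r = assoc$r, slope = assoc$slope, intercept = assoc$intercept,
             p = assoc$p, n = assoc$n)
}

#' Analyze a generated cohort end to end
#'
#' Applies [analyzePatient()] to every phantom of a [generateCohort()] result
#' and joins the imaging metrics to the clinical table on patient id,
#' producing the cohort table used by [metricCorrelation()],
#' [groupCompare()], [correlationVsVolume()] and [survivalTable()].
#'
#' @param cohort Result of \code{generateCohort(..., phantoms = TRUE)}.
#' @param ... Passed to [analyzePatient()].
#' @return Data.frame with one row per patient (clinical + metrics columns).
#' @export
analyzeCohort <- function(cohort, ...) {
  if (is.null(cohort$phantoms))
    stop("cohort has no phantoms; run generateCohort(phantoms = TRUE)")
  rows <- lapply(names(cohort$phantoms), function(id) {
    ph <- cohort$phantoms[[id]]
    suppressWarnings(
      analyzePatient(ph$pet, ph$adc, ph$tumorVoi, ph$muscle, id = id, ...))
  })
  metrics <- do.call(rbind, rows)
  merge(cohort$clinical, metrics, by = "id", sort = FALSE)
}
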