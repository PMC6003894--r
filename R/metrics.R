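#' Global PET metrics of a tumor
#'
#' Computes SUVmax over the tumor VOI, SUVmean within the metabolic tumor
#' volume (MTV), MTV in mL, total lesion glycolysis TLG = MTV x SUVmean, and
#' the tumor-to-muscle ratio SUV_TM = SUVmean / mean muscle SUV. Only voxels
#' flagged valid in the PET volume enter the statistics.
#'
#' @param pet \linkS4class{ImageVolume} in SUV units.
#' @param tumorVoi \linkS4class{RegionMask}: the tumor volume of interest.
#' @param mtvMask \linkS4class{RegionMask}: the thresholded MTV (from
#'   [segmentMTV()]).
#' @param muscle Optional \linkS4class{RegionMask} of the gluteal-muscle
#'   reference; if missing or empty, the ratio field is \code{NA} and a
#'   warning is raised.
#' @return Named list: \code{SUVmax}, \code{SUVmean}, \code{SUV_TM},
#'   \code{MTV} (mL), \code{TLG}.
#' @export
computePetMetrics <- function(pet, tumorVoi, mtvMask, muscle = NULL) {
  stopifnot(is(pet, "ImageVolume"))
  for (m in list(tumorVoi, mtvMask))
    if (!sameGrid(pet, m)) stop("mask not aligned to the PET grid")
  voi <- tumorVoi@mask & pet@valid
  mtv <- mtvMask@mask & pet@valid
  if (!any(voi)) stop("tumor VOI empty after validity filtering")
  if (!any(mtv)) stop("MTV mask empty after validity filtering")
  suvmax <- max(pet@data[voi])
  suvmean <- mean(pet@data[mtv])
  mtvMl <- maskVolumeMl(mtvMask)
  suvTm <- NA_real_
  if (!is.null(muscle) && any(muscle@mask)) {
    if (!sameGrid(pet, muscle)) stop("muscle mask not aligned to the PET grid")
    mus <- muscle@mask & pet@valid
    if (any(mus)) suvTm <- suvmean / mean(pet@data[mus])
  }
  if (is.na(suvTm))
    warning("muscle reference missing or empty; SUV_TM not computed")
  list(SUVmax = suvmax, SUVmean = suvmean, SUV_TM = suvTm,
       MTV = mtvMl, TLG = mtvMl * suvmean)
}

#' Global ADC metrics of a tumor
#'
#' Computes ADCmin and ADCmean over tumor-VOI voxels, the VOI volume
#' (ADCvol, mL), and the tumor-to-muscle ratio ADC_TM. Voxels with
#' non-positive ADC inside the VOI are excluded from the statistics (ratio /
#' log safety); the count of exclusions is attached as attribute
#' \code{"nExcluded"}. ADCvol is the volume of the full VOI mask.
#'
#' @param adc \linkS4class{ImageVolume} in 10^-6 mm^2/s.
#' @param tumorVoi \linkS4class{RegionMask} of the tumor.
#' @param muscle Optional \linkS4class{RegionMask} of the muscle reference.
#' @return Named list: \code{ADCmin}, \code{ADCmean}, \code{ADC_TM},
#'   \code{ADCvol} (mL), with attribute \code{nExcluded}.
#' @export
computeAdcMetrics <- function(adc, tumorVoi, muscle = NULL) {
  stopifnot(is(adc, "ImageVolume"))
  if (!sameGrid(adc, tumorVoi)) stop("tumor VOI not aligned to the ADC grid")
  voi <- tumorVoi@mask & adc@valid
  keep <- voi & adc@data > 0
  nExcl <- sum(voi) - sum(keep)
  if (!any(keep))
    stop("all tumor voxels have non-positive ADC; no ADC statistics possible")
  adcTm <- NA_real_
  adcmean <- mean(adc@data[keep])
  if (!is.null(muscle) && any(muscle@mask)) {
    if (!sameGrid(adc, muscle)) stop("muscle mask not aligned to the ADC grid")
    mus <- muscle@mask & adc@valid & adc@data > 0
    if (any(mus)) adcTm <- adcmean / mean(adc@data[mus])
  }
  if (is.na(adcTm))
    warning("muscle reference missing or empty; ADC_TM not computed")
  out <- list(ADCmin = min(adc@data[keep]), ADCmean = adcmean,
              ADC_TM = adcTm, ADCvol = maskVolumeMl(tumorVoi))
  attr(out, "nExcluded") <- nExcl
  out
}
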