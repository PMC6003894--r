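#' Extract matched per-voxel (SUV, ADC) pairs within a tumor
#'
#' Walks the tumor VOI in array scan order and collects, for every voxel that
#' carries a valid (in-field) resampled PET value and a strictly positive
#' ADC, the matched (SUV, ADC) pair. Exclusion counts per filter are stored
#' on the returned object.
#'
#' @param petOnAdcGrid PET \linkS4class{ImageVolume} already resampled onto
#'   the ADC grid (see [resampleToGrid()]); shapes must match.
#' @param adc ADC \linkS4class{ImageVolume} (10^-6 mm^2/s).
#' @param tumorVoi \linkS4class{RegionMask} of the tumor on the ADC grid.
#' @param id Patient/tumor identifier attached to the pair set.
#' @return A \linkS4class{VoxelPairSet}. Errors if fewer than 3 pairs survive
#'   filtering, naming the filters responsible.
#' @export
extractPairs <- function(petOnAdcGrid, adc, tumorVoi, id = "tumor") {
  stopifnot(is(petOnAdcGrid, "ImageVolume"), is(adc, "ImageVolume"))
  if (!sameGrid(petOnAdcGrid, adc))
    stop("PET and ADC volumes are not on the same grid; resample first")
  if (!sameGrid(adc, tumorVoi))
    stop("tumor VOI is not aligned to the ADC grid")
  voi <- tumorVoi@mask
  outOfField <- voi & !(petOnAdcGrid@valid & adc@valid)
  nonPosAdc <- voi & !outOfField & adc@data <= 0
  keep <- voi & !outOfField & !nonPosAdc
  excl <- c(out_of_field = sum(outOfField), non_positive_adc = sum(nonPosAdc))
  n <- sum(keep)
  if (n < 3)
    stop(sprintf(
      "only %d voxel pair(s) remain after filtering (out_of_field removed %d, non_positive_adc removed %d); need >= 3",
      n, excl[1], excl[2]))
  new("VoxelPairSet", suv = petOnAdcGrid@data[keep], adc = adc@data[keep],
      id = id, excluded = stats::setNames(as.integer(excl), names(excl)))
}

#' Least-squares fit and Pearson correlation of voxel SUV-ADC pairs
#'
#' Fits ordinary least squares with ADC as the response and SUV as the
#' regressor (slope in 10^-6 mm^2/s per SUV unit), and computes the sample
#' Pearson correlation r with its two-sided t test:
#' \eqn{t = r \sqrt{(n-2)/(1-r^2)}} on \eqn{n-2} degrees of freedom. r is
#' symmetric in the two variables, so the biomarker itself does not depend on
#' the regression orientation.
#'
#' Neighboring tumor voxels are spatially autocorrelated; the per-tumor p
#' value treats voxels as independent samples (as is conventional for this
#' analysis) and should be read descriptively.
#'
#' @param pairs A \linkS4class{VoxelPairSet}, or a numeric vector (then
#'   interpreted as the x variable, with \code{y} supplied).
#' @param y Optional numeric response when \code{pairs} is a vector.
#' @return One-row data.frame: \code{r}, \code{slope}, \code{intercept},
#'   \code{p}, \code{n} (and \code{id} when available).
#' @examples
#' fitAssociation(c(1, 2, 3, 4), y = 1000 - 50 * c(1, 2, 3, 4))
#' @export
fitAssociation <- function(pairs, y = NULL) {
  id <- NA_character_
  if (is(pairs, "VoxelPairSet")) {
    x <- pairs@suv; yy <- pairs@adc; id <- pairs@id
  } else {
    if (is.null(y)) stop("supply a VoxelPairSet or two numeric vectors")
    x <- as.numeric(pairs); yy <- as.numeric(y)
  }
  n <- length(x)
  if (n != length(yy)) stop("x and y must have equal length")
  if (n < 3) stop("need at least 3 pairs for a fit, got ", n)
  sx <- stats::sd(x); sy <- stats::sd(yy)
  if (sx == 0 || sy == 0)
    stop("zero variance in ", if (sx == 0) "SUV" else "ADC",
         "; correlation undefined")
  r <- sum((x - mean(x)) * (yy - mean(yy))) / ((n - 1) * sx * sy)
  r <- max(-1, min(1, r))
  slope <- r * sy / sx
  intercept <- mean(yy) - slope * mean(x)
  if (abs(r) < 1) {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  } else {
    p <- .Machine$double.xmin  # perfect collinearity
  }
  p <- max(p, .Machine$double.xmin)
  data.frame(id = id, r = r, slope = slope, intercept = intercept,
             p = p, n = n)
}
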