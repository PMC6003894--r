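#' Synthesize diffusion-weighted signal volumes from a true ADC map
#'
#' Mono-exponential diffusion model: \eqn{S(b) = S_0 \exp(-b \cdot ADC)} per
#' voxel, with ADC converted from 10^-6 mm^2/s to mm^2/s and b in s/mm^2.
#' Additive Gaussian noise (SD in signal units) is applied independently per
#' b-value volume and clipped at 0.
#'
#' @param adcTrue \linkS4class{ImageVolume} of the true ADC (10^-6 mm^2/s),
#'   strictly positive in the field of view.
#' @param S0 Baseline (b = 0) signal, > 0.
#' @param bValues Acquisition scheme in s/mm^2; the protocols emulated here
#'   are (50, 500, 1000), (50, 500, 800) and (50, 400, 600).
#' @param noiseSd Gaussian noise SD in signal units (0 = noise-free).
#' @return List of \linkS4class{ImageVolume}s (modality \code{"DWI"}), one
#'   per b-value, with attribute \code{"bValues"}.
#' @examples
#' adc <- ImageVolume(array(1000, c(4, 4, 4)), c(3.4, 3.4, 5), modality = "ADC")
#' dwi <- synthesizeDwi(adc, S0 = 1000, bValues = c(50, 500, 1000))
#' imgData(dwi[[3]])[1]  # 1000 * exp(-1) ~= 367.88
#' @export
synthesizeDwi <- function(adcTrue, S0, bValues = c(50, 500, 1000),
                          noiseSd = 0) {
  stopifnot(is(adcTrue, "ImageVolume"))
  if (S0 <= 0) stop("S0 must be positive")
  if (any(adcTrue@data <= 0))
    stop("true ADC must be strictly positive everywhere in the field of view")
  d <- dim(adcTrue@data)
  out <- lapply(bValues, function(b) {
    s <- S0 * exp(-b * adcTrue@data * 1e-6)
    if (noiseSd > 0)
      s <- pmax(array(s + stats::rnorm(length(s), sd = noiseSd), d), 0)
    ImageVolume(s, spacing = adcTrue@spacing, origin = adcTrue@origin,
                modality = "DWI", valid = adcTrue@valid)
  })
  attr(out, "bValues") <- bValues
  out
}

#' Fit an ADC map from diffusion-weighted volumes
#'
#' Per-voxel ordinary least squares of log S(b) on b; ADC is minus the slope,
#' reported in 10^-6 mm^2/s. Voxels with any non-positive signal cannot be
#' log-transformed and are flagged invalid (value 0, \code{valid} FALSE).
#'
#' @param dwi List of \linkS4class{ImageVolume}s on a common grid (as from
#'   [synthesizeDwi()]).
#' @param bValues b-values (s/mm^2) matching \code{dwi}; at least 2. Taken
#'   from the \code{"bValues"} attribute of \code{dwi} when omitted.
#' @return ADC \linkS4class{ImageVolume} (10^-6 mm^2/s).
#' @export
fitAdcMap <- function(dwi, bValues = attr(dwi, "bValues")) {
  if (is.null(bValues) || length(bValues) < 2)
    stop("need at least 2 b-values")
  if (length(dwi) != length(bValues))
    stop("number of volumes does not match number of b-values")
  d <- dim(dwi[[1]]@data)
  ok <- dwi[[1]]@valid
  for (v in dwi) {
    if (!sameGrid(v, dwi[[1]])) stop("DWI volumes are not on a common grid")
    ok <- ok & v@valid & v@data > 0
  }
  if (!any(ok)) stop("no voxel has positive signal at every b-value")
  bc <- bValues - mean(bValues)
  den <- sum(bc^2)
  num <- array(0, d)
  for (i in seq_along(dwi)) {
    ls <- array(0, d)
    ls[ok] <- log(dwi[[i]]@data[ok])
    num <- num + bc[i] * ls
  }
  adc <- -num / den * 1e6
  adc[!ok] <- 0
  ImageVolume(adc, spacing = dwi[[1]]@spacing, origin = dwi[[1]]@origin,
              modality = "ADC", valid = ok)
}
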