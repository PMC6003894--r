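#' @import methods
NULL

.MODALITIES <- c("PET_SUV", "ADC", "DWI")
.MASK_LABELS <- c("tumor_VOI", "MTV", "muscle")

#' ImageVolume: a 3D scalar field with grid geometry
#'
#' Carrier for PET-SUV volumes (unitless), ADC maps (10^-6 mm^2/s) and
#' diffusion-weighted signal volumes. World coordinates follow a voxel-center
#' convention: voxel with 0-based index \code{(i, j, k)} sits at
#' \code{origin + c(i, j, k) * spacing}, axes ordered (x, y, z) in mm.
#'
#' The \code{valid} slot is a logical array flagging voxels carrying usable
#' values; resampling marks voxels whose center falls outside the source
#' field of view as invalid instead of filling them with padding, so masked
#' statistics are never contaminated.
#'
#' @slot data 3D numeric array, all values finite.
#' @slot spacing Numeric length-3, per-axis voxel size in mm (> 0).
#' @slot origin Numeric length-3, world position of the first voxel center (mm).
#' @slot modality One of \code{"PET_SUV"}, \code{"ADC"}, \code{"DWI"}.
#' @slot valid Logical array, same shape as \code{data}.
#'
#' @exportClass ImageVolume
setClass("ImageVolume",
  representation(
    data = "array",
    spacing = "numeric",
    origin = "numeric",
    modality = "character",
    valid = "array"
  )
)

setValidity("ImageVolume", function(object) {
  msgs <- character(0)
  d <- dim(object@data)
  if (length(d) != 3L || any(d < 1L))
    msgs <- c(msgs, "data must be a 3D array with each axis of length >= 1")
  if (length(object@spacing) != 3L || !all(is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    msgs <- c(msgs, "spacing must be 3 strictly positive finite values (mm)")
  if (length(object@origin) != 3L || !all(is.finite(object@origin)))
    msgs <- c(msgs, "origin must be 3 finite values (mm)")
  if (!all(is.finite(object@data)))
    msgs <- c(msgs, sprintf("data contains %d non-finite voxel(s)",
                            sum(!is.finite(object@data))))
  if (length(object@modality) != 1L || !(object@modality %in% .MODALITIES))
    msgs <- c(msgs, sprintf("modality must be one of: %s",
                            paste(.MODALITIES, collapse = ", ")))
  if (!identical(dim(object@valid), d))
    msgs <- c(msgs, "valid mask must have the same shape as data")
  if (!is.logical(object@valid))
    msgs <- c(msgs, "valid mask must be logical")
  if (length(msgs)) msgs else TRUE
})

#' Construct an ImageVolume
#'
#' @param data 3D numeric array of voxel values.
#' @param spacing Per-axis voxel size in mm, length 3.
#' @param origin World position (mm) of the first voxel center, length 3.
#' @param modality \code{"PET_SUV"}, \code{"ADC"} or \code{"DWI"}.
#' @param valid Optional logical array of usable voxels; defaults to all TRUE.
#' @return An \linkS4class{ImageVolume}.
#' @examples
#' v <- ImageVolume(array(1, c(4, 4, 4)), spacing = c(3.4, 3.4, 5))
#' voxelSpacing(v)
#' @export
ImageVolume <- function(data, spacing, origin = c(0, 0, 0),
                        modality = "PET_SUV", valid = NULL) {
  data <- array(as.double(data), dim(data))  # plain array, no foreign class
  if (is.null(valid)) valid <- array(TRUE, dim(data))
  new("ImageVolume", data = data, spacing = as.numeric(spacing),
      origin = as.numeric(origin), modality = modality, valid = valid)
}

#' RegionMask: a boolean field on a reference grid
#'
#' Tumor VOIs, metabolic tumor volumes and muscle reference regions are
#' represented as logical arrays tied to the grid (spacing/origin) of the
#' volume they index.
#'
#' @slot mask 3D logical array.
#' @slot spacing,origin Grid geometry of the reference volume (mm).
#' @slot label One of \code{"tumor_VOI"}, \code{"MTV"}, \code{"muscle"}.
#' @exportClass RegionMask
setClass("RegionMask",
  representation(
    mask = "array",
    spacing = "numeric",
    origin = "numeric",
    label = "character"
  )
)

setValidity("RegionMask", function(object) {
  msgs <- character(0)
  if (length(dim(object@mask)) != 3L)
    msgs <- c(msgs, "mask must be a 3D array")
  if (!is.logical(object@mask))
    msgs <- c(msgs, "mask must be logical")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    msgs <- c(msgs, "spacing must be 3 strictly positive finite values (mm)")
  if (length(object@origin) != 3L || !all(is.finite(object@origin)))
    msgs <- c(msgs, "origin must be 3 finite values (mm)")
  if (length(object@label) != 1L || !(object@label %in% .MASK_LABELS))
    msgs <- c(msgs, sprintf("label must be one of: %s",
                            paste(.MASK_LABELS, collapse = ", ")))
  if (object@label %in% c("tumor_VOI", "MTV") && !any(object@mask))
    msgs <- c(msgs, sprintf("%s mask must be non-empty", object@label))
  if (length(msgs)) msgs else TRUE
})

#' Construct a RegionMask
#'
#' @param mask 3D logical (or 0/1) array.
#' @param spacing,origin Grid geometry (mm) the mask is defined on; may be
#'   supplied via \code{reference} instead.
#' @param label \code{"tumor_VOI"}, \code{"MTV"} or \code{"muscle"}.
#' @param reference Optional \linkS4class{ImageVolume} whose grid the mask
#'   inherits.
#' @return A \linkS4class{RegionMask}.
#' @export
RegionMask <- function(mask, spacing = NULL, origin = NULL,
                       label = "tumor_VOI", reference = NULL) {
  mask <- as.array(mask)
  if (!is.logical(mask)) mask <- array(mask != 0, dim(mask))
  if (!is.null(reference)) {
    stopifnot(is(reference, "ImageVolume"))
    if (!identical(dim(mask), dim(reference@data)))
      stop("mask shape does not match the reference volume")
    spacing <- reference@spacing
    origin <- reference@origin
  }
  if (is.null(spacing) || is.null(origin))
    stop("supply either spacing+origin or a reference volume")
  new("RegionMask", mask = mask, spacing = as.numeric(spacing),
      origin = as.numeric(origin), label = label)
}

#' VoxelPairSet: matched per-voxel (SUV, ADC) samples for one tumor
#'
#' Pairs originate from tumor-VOI voxels on the ADC grid that carry a valid
#' (in-field) resampled PET value and a strictly positive ADC; exclusion
#' counts are kept alongside.
#'
#' @slot suv,adc Equal-length numeric vectors (SUV unitless; ADC 10^-6 mm^2/s).
#' @slot id Patient/tumor identifier.
#' @slot excluded Named integer vector of voxels dropped per filter.
#' @exportClass VoxelPairSet
setClass("VoxelPairSet",
  representation(
    suv = "numeric",
    adc = "numeric",
    id = "character",
    excluded = "integer"
  )
)

setValidity("VoxelPairSet", function(object) {
  msgs <- character(0)
  if (length(object@suv) != length(object@adc))
    msgs <- c(msgs, "suv and adc must have equal length")
  if (!all(is.finite(object@suv)) || !all(is.finite(object@adc)))
    msgs <- c(msgs, "pair values must be finite")
  if (length(msgs)) msgs else TRUE
})
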