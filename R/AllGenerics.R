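#' @include AllClasses.R
NULL

#' Accessors for ImageVolume and RegionMask
#'
#' \code{imgData} returns the voxel array; \code{voxelSpacing} and
#' \code{voxelOrigin} the grid geometry in mm; \code{modality} the modality
#' tag; \code{validMask} the logical in-field/usable-voxel array;
#' \code{maskArray} and \code{maskLabel} the logical array and label of a
#' \linkS4class{RegionMask}.
#'
#' @param x An \linkS4class{ImageVolume} or \linkS4class{RegionMask}.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("imgData", function(x) standardGeneric("imgData"))
#' @rdname accessors
#' @export
setGeneric("voxelSpacing", function(x) standardGeneric("voxelSpacing"))
#' @rdname accessors
#' @export
setGeneric("voxelOrigin", function(x) standardGeneric("voxelOrigin"))
#' @rdname accessors
#' @export
setGeneric("modality", function(x) standardGeneric("modality"))
#' @rdname accessors
#' @export
setGeneric("validMask", function(x) standardGeneric("validMask"))
#' @rdname accessors
#' @export
setGeneric("maskArray", function(x) standardGeneric("maskArray"))
#' @rdname accessors
#' @export
setGeneric("maskLabel", function(x) standardGeneric("maskLabel"))

#' @rdname accessors
setMethod("imgData", "ImageVolume", function(x) x@data)
#' @rdname accessors
setMethod("voxelSpacing", "ImageVolume", function(x) x@spacing)
#' @rdname accessors
setMethod("voxelSpacing", "RegionMask", function(x) x@spacing)
#' @rdname accessors
setMethod("voxelOrigin", "ImageVolume", function(x) x@origin)
#' @rdname accessors
setMethod("voxelOrigin", "RegionMask", function(x) x@origin)
#' @rdname accessors
setMethod("modality", "ImageVolume", function(x) x@modality)
#' @rdname accessors
setMethod("validMask", "ImageVolume", function(x) x@valid)
#' @rdname accessors
setMethod("maskArray", "RegionMask", function(x) x@mask)
#' @rdname accessors
setMethod("maskLabel", "RegionMask", function(x) x@label)

#' @describeIn accessors Array dimensions of the volume.
#' @export
setMethod("dim", "ImageVolume", function(x) dim(x@data))
#' @rdname accessors
#' @export
setMethod("dim", "RegionMask", function(x) dim(x@mask))

#' Pair accessors for VoxelPairSet
#' @param x A \linkS4class{VoxelPairSet}.
#' @name pair-accessors
NULL

#' @rdname pair-accessors
#' @export
setGeneric("suvValues", function(x) standardGeneric("suvValues"))
#' @rdname pair-accessors
#' @export
setGeneric("adcValues", function(x) standardGeneric("adcValues"))
#' @rdname pair-accessors
#' @export
setGeneric("pairCount", function(x) standardGeneric("pairCount"))

#' @rdname pair-accessors
setMethod("suvValues", "VoxelPairSet", function(x) x@suv)
#' @rdname pair-accessors
setMethod("adcValues", "VoxelPairSet", function(x) x@adc)
#' @rdname pair-accessors
setMethod("pairCount", "VoxelPairSet", function(x) length(x@suv))

setMethod("show", "ImageVolume", function(object) {
  d <- dim(object@data)
  cat(sprintf("ImageVolume [%s]  %d x %d x %d voxels\n",
              object@modality, d[1], d[2], d[3]))
  cat(sprintf("  spacing: %.4g x %.4g x %.4g mm  origin: (%.4g, %.4g, %.4g) mm\n",
              object@spacing[1], object@spacing[2], object@spacing[3],
              object@origin[1], object@origin[2], object@origin[3]))
  cat(sprintf("  range: [%.4g, %.4g]  invalid voxels: %d\n",
              min(object@data), max(object@data), sum(!object@valid)))
})

setMethod("show", "RegionMask", function(object) {
  d <- dim(object@mask)
  cat(sprintf("RegionMask [%s]  %d x %d x %d voxels, %d in mask (%.2f mL)\n",
              object@label, d[1], d[2], d[3], sum(object@mask),
              sum(object@mask) * prod(object@spacing) / 1000))
})

setMethod("show", "VoxelPairSet", function(object) {
  cat(sprintf("VoxelPairSet [%s]  n = %d pairs", object@id,
              length(object@suv)))
  if (length(object@excluded) && sum(object@excluded) > 0)
    cat(sprintf("  (excluded: %s)",
                paste(names(object@excluded), object@excluded,
                      sep = "=", collapse = ", ")))
  cat("\n")
})
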