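#' Read a 3D NIfTI-1 volume
#'
#' Decodes voxel spacing and origin from the NIfTI header affine. Only
#' axis-aligned, positively oriented single 3D scalar images are accepted;
#' 4D images and images containing non-finite voxels are rejected with a
#' diagnostic.
#'
#' @param path Path to a \code{.nii} or \code{.nii.gz} file.
#' @param modality Modality tag to attach (\code{"PET_SUV"}, \code{"ADC"},
#'   \code{"DWI"}).
#' @return An \linkS4class{ImageVolume}.
#' @seealso [writeVolume()], [readMask()]
#' @export
readVolume <- function(path, modality = "PET_SUV") {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  a <- as.array(img)
  if (length(dim(a)) == 4L && dim(a)[4] == 1L) a <- a[, , , 1, drop = TRUE]
  if (length(dim(a)) != 3L)
    stop("expected a single 3D scalar image, got ", length(dim(a)),
         " dimensions: ", path)
  nbad <- sum(!is.finite(a))
  if (nbad > 0)
    stop(sprintf("volume contains %d non-finite voxel(s): %s", nbad, path))
  aff <- RNifti::xform(img)
  rot <- aff[1:3, 1:3]
  if (any(abs(rot[row(rot) != col(rot)]) > 1e-6))
    stop("only axis-aligned (diagonal affine) volumes are supported: ", path)
  spacing <- diag(rot)
  if (any(spacing <= 0))
    stop("negative/zero axis scalings in the affine are not supported: ", path)
  ImageVolume(a, spacing = spacing, origin = aff[1:3, 4], modality = modality)
}

#' Write a 3D volume as NIfTI-1
#'
#' The header qform/sform affine encodes the voxel spacing and origin so that
#' [readVolume()] inverts the operation (data bitwise, geometry to well below
#' 1e-6 mm).
#'
#' @param volume An \linkS4class{ImageVolume}.
#' @param path Output path (\code{.nii} or \code{.nii.gz}); the parent
#'   directory must exist.
#' @return Invisibly, \code{path}.
#' @export
writeVolume <- function(volume, path) {
  stopifnot(is(volume, "ImageVolume"))
  if (!dir.exists(dirname(path)))
    stop("parent directory does not exist: ", dirname(path))
  img <- RNifti::asNifti(volume@data)
  RNifti::pixdim(img) <- volume@spacing
  aff <- diag(c(volume@spacing, 1))
  aff[1:3, 4] <- volume@origin
  RNifti::qform(img) <- structure(aff, code = 2L)
  RNifti::sform(img) <- structure(aff, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read / write region masks as 0/1 NIfTI volumes
#'
#' @param path NIfTI file of a 0/1 integer volume.
#' @param label Mask label (\code{"tumor_VOI"}, \code{"MTV"}, \code{"muscle"}).
#' @return \code{readMask}: a \linkS4class{RegionMask}.
#' @export
readMask <- function(path, label = "tumor_VOI") {
  v <- readVolume(path, modality = "PET_SUV")
  vals <- unique(as.vector(v@data))
  if (!all(vals %in% c(0, 1)))
    stop("mask file must contain only 0/1 values: ", path)
  RegionMask(v@data != 0, spacing = v@spacing, origin = v@origin,
             label = label)
}

#' @rdname readMask
#' @param mask A \linkS4class{RegionMask} to serialize.
#' @export
writeMask <- function(mask, path) {
  stopifnot(is(mask, "RegionMask"))
  v <- ImageVolume(array(as.double(mask@mask), dim(mask@mask)),
                   spacing = mask@spacing, origin = mask@origin)
  writeVolume(v, path)
}

#' Do two objects share the same voxel grid?
#'
#' @param a,b ImageVolume or RegionMask objects.
#' @param tol Tolerance in mm on spacing and origin.
#' @return Logical.
#' @export
sameGrid <- function(a, b, tol = 1e-6) {
  identical(dim(a), dim(b)) &&
    all(abs(voxelSpacing(a) - voxelSpacing(b)) <= tol) &&
    all(abs(voxelOrigin(a) - voxelOrigin(b)) <= tol)
}

# world coordinates of voxel centers along one axis (0-based index convention)
axisCoords <- function(n, spacing, origin) origin + (seq_len(n) - 1) * spacing
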