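#' Resample a volume onto the grid of another volume
#'
#' Interpolates \code{source} at the world-space voxel centers of
#' \code{target}, so that after resampling the two volumes correspond
#' voxel-for-voxel. This is how the PET volume is brought onto the ADC matrix
#' before voxel-wise comparison.
#'
#' Output voxels whose center falls outside the source extent (the bounding
#' box of source voxel centers, with a 1e-6-spacing tolerance) are flagged
#' invalid in the result's \code{valid} mask rather than zero-filled, and are
#' excluded from all downstream masked statistics and pair extraction.
#' Invalidity of source voxels propagates: a trilinear output voxel is valid
#' only if every source voxel with nonzero interpolation weight is valid.
#'
#' @param source \linkS4class{ImageVolume} to interpolate.
#' @param target \linkS4class{ImageVolume} (or \linkS4class{RegionMask})
#'   supplying the output grid.
#' @param method \code{"trilinear"} (default; exact for affine intensity
#'   fields, never extrapolates beyond the source value range) or
#'   \code{"nearest"}.
#' @return An \linkS4class{ImageVolume} on the target grid.
#' @examples
#' src <- ImageVolume(array(rnorm(8 * 8 * 8), c(8, 8, 8)), c(4.17, 4.17, 2.03))
#' tgt <- ImageVolume(array(0, c(6, 6, 4)), c(3.4, 3.4, 5), origin = c(1, 1, 1))
#' out <- resampleToGrid(src, tgt)
#' @export
resampleToGrid <- function(source, target, method = c("trilinear", "nearest")) {
  method <- match.arg(method)
  stopifnot(is(source, "ImageVolume"))
  sd3 <- dim(source@data)
  td3 <- if (is(target, "RegionMask")) dim(target@mask) else dim(target@data)
  tol <- 1e-6

  # continuous 0-based source index of each target voxel center, per axis
  ci <- lapply(1:3, function(a) {
    w <- axisCoords(td3[a], voxelSpacing(target)[a], voxelOrigin(target)[a])
    (w - source@origin[a]) / source@spacing[a]
  })
  inf <- lapply(1:3, function(a)
    ci[[a]] >= -tol & ci[[a]] <= (sd3[a] - 1) + tol)
  infield <- outer(outer(inf[[1]], inf[[2]], `&`), inf[[3]], `&`)
  if (!any(infield))
    stop("empty overlap between source and target extents")

  V <- source@data
  Vv <- array(as.double(source@valid), sd3)
  if (method == "nearest") {
    idx <- lapply(1:3, function(a)
      pmin(pmax(round(ci[[a]]), 0), sd3[a] - 1) + 1L)
    out <- V[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
    vld <- Vv[idx[[1]], idx[[2]], idx[[3]], drop = FALSE] > 0.5
  } else {
    i0 <- lapply(1:3, function(a)
      pmin(pmax(floor(ci[[a]]), 0), max(sd3[a] - 2, 0)))
    fr <- lapply(1:3, function(a)
      pmin(pmax(ci[[a]] - i0[[a]], 0), 1))
    out <- array(0, td3)
    vld <- array(0, td3)
    for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
      wx <- if (dx == 0) 1 - fr[[1]] else fr[[1]]
      wy <- if (dy == 0) 1 - fr[[2]] else fr[[2]]
      wz <- if (dz == 0) 1 - fr[[3]] else fr[[3]]
      W <- outer(outer(wx, wy), wz)
      ix <- pmin(i0[[1]] + dx, sd3[1] - 1) + 1L
      iy <- pmin(i0[[2]] + dy, sd3[2] - 1) + 1L
      iz <- pmin(i0[[3]] + dz, sd3[3] - 1) + 1L
      out <- out + W * V[ix, iy, iz, drop = FALSE]
      vld <- vld + W * Vv[ix, iy, iz, drop = FALSE]
    }
    vld <- vld > 1 - 1e-9
  }
  out[!infield] <- 0
  ImageVolume(out, spacing = voxelSpacing(target),
              origin = voxelOrigin(target), modality = source@modality,
              valid = infield & vld)
}
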