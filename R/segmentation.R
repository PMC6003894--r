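#' Segment the metabolic tumor volume by SUVmax thresholding
#'
#' Thresholds the PET volume at \code{thresholdFraction * SUVmax}, where
#' SUVmax is taken within \code{seedRegion} (the tumor VOI), and keeps the
#' 26-connected component containing the maximal voxel. Voxels exactly at the
#' threshold are included, so the maximal voxel always qualifies and the
#' result is never empty. Ties for the maximum are broken by lowest linear
#' index.
#'
#' @param pet \linkS4class{ImageVolume} in SUV units (typically already
#'   resampled to the ADC grid).
#' @param seedRegion \linkS4class{RegionMask}: non-empty region in which
#'   SUVmax (and the seed voxel) is sought.
#' @param thresholdFraction Fraction of SUVmax in (0, 1); 0.4 is the
#'   conventional PET segmentation threshold used here.
#' @param connected If \code{TRUE} (default) return the connected component
#'   containing the seed; if \code{FALSE}, all voxels at or above threshold.
#' @return A \linkS4class{RegionMask} with label \code{"MTV"}.
#' @export
segmentMTV <- function(pet, seedRegion, thresholdFraction = 0.4,
                       connected = TRUE) {
  stopifnot(is(pet, "ImageVolume"), is(seedRegion, "RegionMask"))
  if (!sameGrid(pet, seedRegion))
    stop("seed region is not aligned to the PET grid")
  if (thresholdFraction <= 0 || thresholdFraction >= 1)
    stop("thresholdFraction must lie in (0, 1)")
  sel <- seedRegion@mask & pet@valid
  if (!any(sel)) stop("seed region is empty (after validity filtering)")
  vals <- pet@data[sel]
  suvmax <- max(vals)
  seed <- which(sel & pet@data == suvmax)[1]
  if (all(pet@data[pet@valid] == suvmax))
    warning("PET volume is constant; whole connected region returned")
  above <- pet@valid & pet@data >= thresholdFraction * suvmax
  comp <- if (connected) connectedComponent3d(above, seed) else above
  RegionMask(comp, spacing = pet@spacing, origin = pet@origin, label = "MTV")
}

# 26-connected component of `above` containing linear index `seed`,
# vectorized breadth-first flood over frontier coordinate matrices
connectedComponent3d <- function(above, seed) {
  d <- dim(above)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  visited <- array(FALSE, d)
  visited[seed] <- TRUE
  frontier <- matrix(arrayInd(seed, d), ncol = 3)
  while (nrow(frontier) > 0) {
    cand <- do.call(rbind, lapply(seq_len(nrow(offs)), function(o)
      sweep(frontier, 2, offs[o, ], `+`)))
    ok <- cand[, 1] >= 1 & cand[, 1] <= d[1] &
          cand[, 2] >= 1 & cand[, 2] <= d[2] &
          cand[, 3] >= 1 & cand[, 3] <= d[3]
    cand <- cand[ok, , drop = FALSE]
    lin <- cand[, 1] + (cand[, 2] - 1L) * d[1] + (cand[, 3] - 1L) * d[1] * d[2]
    keep <- !duplicated(lin)
    lin <- lin[keep]
    cand <- cand[keep, , drop = FALSE]
    new <- above[lin] & !visited[lin]
    visited[lin[new]] <- TRUE
    frontier <- cand[new, , drop = FALSE]
  }
  visited
}

#' Volume of a mask in millilitres
#'
#' Number of mask voxels times the voxel volume (product of spacings, mm^3),
#' divided by 1000.
#'
#' @param mask A \linkS4class{RegionMask}.
#' @return Volume in mL.
#' @examples
#' m <- RegionMask(array(TRUE, c(2, 2, 2)), spacing = c(5, 5, 5),
#'                 origin = c(0, 0, 0))
#' maskVolumeMl(m)  # 8 voxels x 125 mm^3 = 1 mL
#' @export
maskVolumeMl <- function(mask) {
  stopifnot(is(mask, "RegionMask"))
  sum(mask@mask) * prod(mask@spacing) / 1000
}
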