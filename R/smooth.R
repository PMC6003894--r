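#' Separable Gaussian smoothing of a 3D field
#'
#' Convolves a 3D array with an axis-separable Gaussian kernel specified in
#' mm (truncated at 3 sigma). Kernel rows are renormalized at the array
#' edges, so constants are preserved exactly everywhere.
#'
#' @param arr 3D numeric array.
#' @param sigmaMm Gaussian SD in mm (scalar or per-axis length 3).
#' @param spacing Voxel spacing in mm, length 3.
#' @return Smoothed array of the same shape.
#' @export
gaussianSmooth3d <- function(arr, sigmaMm, spacing) {
  sigmaMm <- rep(sigmaMm, length.out = 3)
  d <- dim(arr)
  for (ax in 1:3) {
    if (sigmaMm[ax] <= 0) next
    r <- max(1L, ceiling(3 * sigmaMm[ax] / spacing[ax]))
    g <- exp(-((-r:r) * spacing[ax])^2 / (2 * sigmaMm[ax]^2))
    n <- d[ax]
    K <- matrix(0, n, n)
    for (k in -r:r) {
      i <- seq_len(n)
      j <- i + k
      ok <- j >= 1 & j <= n
      K[cbind(i[ok], j[ok])] <- g[k + r + 1]
    }
    K <- K / rowSums(K)
    perm <- c(ax, setdiff(1:3, ax))
    a2 <- aperm(arr, perm)
    dp <- dim(a2)
    a2 <- K %*% matrix(a2, dp[1], dp[2] * dp[3])
    dim(a2) <- dp
    arr <- aperm(a2, order(perm))
  }
  arr
}
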