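# small programmatic fixtures shared across test files

mkVol <- function(data, spacing = c(3.4, 3.4, 5), origin = c(0, 0, 0),
                  modality = "PET_SUV") {
  ImageVolume(data, spacing = spacing, origin = origin, modality = modality)
}

# volume with a Gaussian blob at world center `ctr` (mm), peak `amp`,
# isotropic width `sig` (mm)
blobField <- function(d, spacing, centers, amps, sig) {
  cw <- lapply(1:3, function(a) (seq_len(d[a]) - 1) * spacing[a])
  out <- array(0, d)
  for (i in seq_along(amps)) {
    sq <- lapply(1:3, function(a) (cw[[a]] - centers[[i]][a])^2)
    r2 <- outer(outer(sq[[1]], sq[[2]], `+`), sq[[3]], `+`)
    out <- out + amps[i] * exp(-r2 / (2 * sig^2))
  }
  out
}

# full-grid mask helper
fullMask <- function(vol, label = "tumor_VOI") {
  RegionMask(array(TRUE, dim(vol)), reference = vol, label = label)
}

# a 17-subject survival table with k events before 24 months and the rest
# followed beyond 24 months event-free
followupTable <- function(k, n = 17) {
  data.frame(
    time = c(seq(4, 22, length.out = k), rep(30, n - k)),
    event = c(rep(TRUE, k), rep(FALSE, n - k))
  )
}
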