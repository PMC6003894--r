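test_that("segmentMTV handles hot-voxel, uniform and threshold-edge cases", {
  d <- c(8, 8, 8)
  a <- array(0, d); a[4, 4, 4] <- 10
  pet <- mkVol(a)
  voi <- fullMask(pet)
  m <- segmentMTV(pet, voi, 0.4)
  expect_identical(sum(maskArray(m)), 1L)
  expect_true(maskArray(m)[4, 4, 4])
  expect_identical(maskLabel(m), "MTV")

  unif <- mkVol(array(3, d))
  expect_warning(mu <- segmentMTV(unif, voi, 0.4), "constant")
  expect_true(all(maskArray(mu)))

  # inclusive threshold: voxel exactly at 40% of max is kept
  b <- array(0, d); b[2, 2, 2] <- 10; b[2, 3, 2] <- 4; b[2, 4, 2] <- 3.999
  mb <- segmentMTV(mkVol(b), fullMask(pet), 0.4)
  expect_true(maskArray(mb)[2, 3, 2])
  expect_false(maskArray(mb)[2, 4, 2])
})

test_that("MTV equals a flood-fill oracle on random two-blob phantoms", {
  set.seed(5)
  d <- c(18, 18, 12); sp <- c(3, 3, 4)
  for (i in 1:25) {
    c1 <- runif(3, 0.25, 0.45) * (d - 1) * sp
    c2 <- runif(3, 0.6, 0.8) * (d - 1) * sp
    amps <- c(10, runif(1, 2, 6))  # second blob sometimes above threshold
    f <- blobField(d, sp, list(c1, c2), amps, sig = runif(1, 5, 9))
    pet <- mkVol(f, spacing = sp)
    voi <- fullMask(pet)
    got <- maskArray(segmentMTV(pet, voi, 0.4))
    above <- f >= 0.4 * max(f)
    expect_identical(got, floodFillOracle(above, which.max(f)))
  }
})

test_that("separated second blob is excluded from the connected MTV", {
  d <- c(24, 10, 10); sp <- c(2, 2, 2)
  f <- blobField(d, sp, list(c(8, 9, 9), c(38, 9, 9)), c(10, 5), sig = 4)
  expect_lt(max(f[12, , ]), 4)  # trough below the 40% threshold
  pet <- mkVol(f, spacing = sp)
  m <- maskArray(segmentMTV(pet, fullMask(pet), 0.4))
  expect_false(any(m[17:24, , ]))
  expect_identical(m, floodFillOracle(f >= 0.4 * max(f), which.max(f)))
  # without connectivity, the distant blob's super-threshold voxels remain
  mAll <- maskArray(segmentMTV(pet, fullMask(pet), 0.4, connected = FALSE))
  expect_identical(mAll, f >= 0.4 * max(f))
})

test_that("segmentMTV is monotone in the threshold fraction", {
  set.seed(6)
  d <- c(14, 14, 10); sp <- c(3.4, 3.4, 5)
  f <- blobField(d, sp, list(c(22, 22, 22), c(34, 30, 30)), c(8, 5), sig = 8)
  pet <- mkVol(f, spacing = sp)
  voi <- fullMask(pet)
  prev <- NULL
  for (fr in c(0.2, 0.4, 0.6, 0.8)) {
    cur <- maskArray(segmentMTV(pet, voi, fr))
    if (!is.null(prev)) expect_true(all(prev | !cur))  # cur subset of prev
    prev <- cur
  }
})

test_that("mask volumes: counting, empty-ish masks and digitized ellipsoid", {
  m8 <- RegionMask(array(c(rep(TRUE, 8), rep(FALSE, 19)), c(3, 3, 3)),
                   spacing = c(5, 5, 5), origin = c(0, 0, 0))
  expect_equal(maskVolumeMl(m8), 1.0)
  mus <- RegionMask(array(FALSE, c(3, 3, 3)), spacing = c(5, 5, 5),
                    origin = c(0, 0, 0), label = "muscle")
  expect_equal(maskVolumeMl(mus), 0)

  # ellipsoid semi-axes (20, 15, 10) mm on a 1 mm grid vs analytic volume
  d <- c(45, 37, 25)
  cw <- lapply(1:3, function(a) 0:(d[a] - 1))
  ctr <- (d - 1) / 2
  r2 <- outer(outer(((cw[[1]] - ctr[1]) / 20)^2,
                    ((cw[[2]] - ctr[2]) / 15)^2, `+`),
              ((cw[[3]] - ctr[3]) / 10)^2, `+`)
  ell <- RegionMask(r2 <= 1, spacing = c(1, 1, 1), origin = c(0, 0, 0))
  expect_equal(maskVolumeMl(ell), 4 / 3 * pi * 20 * 15 * 10 / 1000,
               tolerance = 0.02)
})

test_that("PET metrics match hand values and an independent masked-mean loop", {
  d <- c(6, 6, 6)
  a <- array(0, d)
  a[2:3, 2:3, 2:3] <- 10      # uniform tumor, 8 voxels
  a[5, 5, 5] <- 1.25          # muscle voxel
  pet <- mkVol(a, spacing = c(5, 5, 5))
  voi <- RegionMask(a == 10, reference = pet)
  mus <- RegionMask(array(seq_len(216) == which(a == 1.25), d),
                    reference = pet, label = "muscle")
  mtv <- segmentMTV(pet, voi, 0.4)
  pm <- computePetMetrics(pet, voi, mtv, mus)
  expect_equal(pm$SUVmax, 10)
  expect_equal(pm$SUVmean, 10)
  expect_equal(pm$MTV, 1.0)      # 8 x 125 mm^3
  expect_equal(pm$TLG, 10)
  expect_equal(pm$SUV_TM, 8)     # 10 / 1.25

  set.seed(7)
  f <- array(abs(rnorm(216)) + 0.5, d)
  petR <- mkVol(f, spacing = c(4, 4, 4))
  sel <- array(runif(216) < 0.3, d); sel[1] <- TRUE
  voiR <- RegionMask(sel, reference = petR)
  mtvR <- segmentMTV(petR, voiR, 0.4)
  pmR <- suppressWarnings(computePetMetrics(petR, voiR, mtvR))
  # voxel-by-voxel oracle
  acc <- 0; nn <- 0
  for (i in seq_len(216)) if (maskArray(mtvR)[i]) { acc <- acc + f[i]; nn <- nn + 1 }
  expect_equal(pmR$SUVmean, acc / nn, tolerance = 1e-12)
  expect_true(is.na(pmR$SUV_TM))
  expect_equal(pmR$TLG, pmR$MTV * pmR$SUVmean, tolerance = 1e-15)
})

test_that("ADC metrics: ratios, minima, non-positive exclusion, loop oracle", {
  d <- c(5, 5, 5)
  a <- array(1200, d)
  a[2:4, 2:4, 2:4] <- 900
  adc <- mkVol(a, modality = "ADC")
  voi <- RegionMask(a == 900, reference = adc)
  musArr <- array(FALSE, d); musArr[1, 1, ] <- TRUE
  mus <- RegionMask(musArr, reference = adc, label = "muscle")
  am <- computeAdcMetrics(adc, voi, mus)
  expect_equal(am$ADC_TM, 0.75)
  expect_equal(am$ADCmean, 900)

  a2 <- a; a2[3, 3, 3] <- 402.6
  am2 <- computeAdcMetrics(mkVol(a2, modality = "ADC"), voi, mus)
  expect_equal(am2$ADCmin, 402.6)

  # zero-ADC voxels inside the VOI are excluded and counted
  a3 <- a; a3[2, 2, 2] <- 0; a3[2, 3, 2] <- 0
  am3 <- computeAdcMetrics(mkVol(a3, modality = "ADC"), voi, mus)
  expect_identical(attr(am3, "nExcluded"), 2L)
  expect_equal(am3$ADCmean, mean(a3[a3 > 0 & maskArray(voi)]))
  expect_equal(am3$ADCvol, maskVolumeMl(voi))

  set.seed(8)
  f <- array(runif(125, 300, 1500), d)
  adcR <- mkVol(f, modality = "ADC")
  sel <- array(runif(125) < 0.4, d); sel[1] <- TRUE
  voiR <- RegionMask(sel, reference = adcR)
  amR <- suppressWarnings(computeAdcMetrics(adcR, voiR))
  acc <- 0; nn <- 0
  for (i in seq_len(125)) if (sel[i]) { acc <- acc + f[i]; nn <- nn + 1 }
  expect_equal(amR$ADCmean, acc / nn, tolerance = 1e-12)
})

test_that("metrics are invariant under consistent axis permutation", {
  set.seed(9)
  d <- c(8, 10, 6); sp <- c(3.4, 3.4, 5)
  f <- blobField(d, sp, list(c(12, 15, 12)), 10, sig = 8) + 0.2
  pet <- mkVol(f, spacing = sp)
  voi <- fullMask(pet)
  mtv <- segmentMTV(pet, voi, 0.4)
  pm <- suppressWarnings(computePetMetrics(pet, voi, mtv))

  perm <- c(3, 1, 2)
  petP <- mkVol(aperm(f, perm), spacing = sp[perm])
  voiP <- fullMask(petP)
  mtvP <- segmentMTV(petP, voiP, 0.4)
  pmP <- suppressWarnings(computePetMetrics(petP, voiP, mtvP))
  for (k in c("SUVmax", "SUVmean", "MTV", "TLG"))
    expect_equal(pm[[k]], pmP[[k]], tolerance = 1e-12)
})
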