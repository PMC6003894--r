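#' Specification of a synthetic PET/ADC tumor phantom
#'
#' Collects every tunable of a single two-grid phantom. Defaults follow the
#' magnitudes typical of FDG-avid cervical tumors (SUVmax around 11-13,
#' tumor ADC around 950 x 10^-6 mm^2/s, muscle ADC around 1245 so that
#' ADC_T/M is around 0.76, MTV around 33 mL) and the acquisition geometry of
#' an integrated PET/MR (PET 4.17 x 4.17 x 2.03 mm; DWI 3.4 mm in-plane,
#' 5 mm slices, b = 50/500/1000 s/mm^2).
#'
#' \code{rho} is the target voxel-level Pearson correlation between the
#' noise-free SUV and ADC fields within the tumor VOI. The generator imposes
#' it as an exact sample correlation (see [generatePhantom()]); because the
#' SUV field carries a deterministic radial uptake profile, only
#' \code{|rho| <= suvSd / sqrt(amp^2 var(profile) + suvSd^2)} (about 0.74 at
#' defaults) is attainable, except |rho| = 1 which is generated as an exact
#' affine ADC-SUV relationship.
#'
#' @param targetMtv Target metabolic tumor volume (mL) at the 40% threshold;
#'   sets the ellipsoid scale.
#' @param aspect Relative semi-axis ratios of the tumor ellipsoid (x, y, z).
#' @param peakSuv Deterministic peak SUV of the uptake profile.
#' @param bgSuv Background SUV.
#' @param suvSd SD of the stochastic SUV component inside the tumor.
#' @param suvFloor Fraction of the peak-minus-background amplitude retained
#'   at the tumor edge (keeps edge uptake well above zero so that positivity
#'   clipping almost never perturbs the imposed correlation).
#' @param tumorAdc,adcSd Mean / SD of tumor ADC (10^-6 mm^2/s).
#' @param bgAdc Background tissue ADC.
#' @param muscleAdc,muscleSuv Reference-muscle ADC and SUV.
#' @param rho Target voxel-level SUV-ADC correlation in [-1, 1].
#' @param sigmaMm Gaussian smoothness (mm) of the latent texture fields.
#' @param petNoiseSd Additive PET noise SD (SUV units).
#' @param dwiNoiseSd Additive DWI signal noise SD (signal units, S0 = 1000).
#' @param S0 Baseline DWI signal.
#' @param bScheme b-value scheme, one of (50,500,1000), (50,500,800),
#'   (50,400,600).
#' @param adcDim,adcSpacing ADC grid shape and spacing (mm).
#' @param petSpacing PET grid spacing (mm); the PET field of view is chosen
#'   to cover the ADC field of view with a margin.
#' @param muscleSemiAxes Muscle ellipsoid semi-axes (mm).
#' @param seed Optional RNG seed for [generatePhantom()].
#' @return A list of class \code{"PhantomSpec"}.
#' @export
phantomSpec <- function(targetMtv = 33, aspect = c(1, 0.85, 0.6),
                        peakSuv = 11, bgSuv = 1, suvSd = 2, suvFloor = 0.3,
                        tumorAdc = 950, adcSd = 150, bgAdc = 1400,
                        muscleAdc = 1245, muscleSuv = 0.9,
                        rho = -0.35, sigmaMm = 6,
                        petNoiseSd = 0.3, dwiNoiseSd = 10, S0 = 1000,
                        bScheme = c(50, 500, 1000),
                        adcDim = c(36, 36, 20), adcSpacing = c(3.4, 3.4, 5),
                        petSpacing = c(4.17, 4.17, 2.03),
                        muscleSemiAxes = c(11, 11, 14), seed = NULL) {
  if (abs(rho) > 1) stop("|rho| must be <= 1")
  if (targetMtv <= 0) stop("targetMtv must be positive")
  if (any(c(adcSpacing, petSpacing, aspect) <= 0))
    stop("spacings and aspect ratios must be positive")
  if (any(c(petNoiseSd, dwiNoiseSd) < 0)) stop("noise SDs must be >= 0")
  spec <- list(targetMtv = targetMtv, aspect = aspect, peakSuv = peakSuv,
               bgSuv = bgSuv, suvSd = suvSd, suvFloor = suvFloor,
               tumorAdc = tumorAdc,
               adcSd = adcSd, bgAdc = bgAdc, muscleAdc = muscleAdc,
               muscleSuv = muscleSuv, rho = rho, sigmaMm = sigmaMm,
               petNoiseSd = petNoiseSd, dwiNoiseSd = dwiNoiseSd, S0 = S0,
               bScheme = bScheme, adcDim = as.integer(adcDim),
               adcSpacing = adcSpacing, petSpacing = petSpacing,
               muscleSemiAxes = muscleSemiAxes, seed = seed)
  class(spec) <- "PhantomSpec"
  spec
}

# expected MTV/VOI volume ratio for the uptake profile
# floor + (1 - floor) * (1 - r^2): MTV is the region where the profile
# exceeds (0.4 SUVmax - bg) / amp; the stochastic texture shifts the
# realized SUVmax upward by about wPeak * suvSd (empirical maximum of the
# smooth texture over the tumor core, net of the resampling-induced
# reduction of the observed peak)
mtvVoiRatio <- function(spec, wPeak = 0.75) {
  amp <- spec$peakSuv - spec$bgSuv
  suvmax <- spec$bgSuv + amp + wPeak * spec$suvSd
  tauT <- ((0.4 * suvmax - spec$bgSuv) / amp - spec$suvFloor) /
    (1 - spec$suvFloor)
  max(1e-3, min(1, (1 - tauT)))^1.5
}

tumorSemiAxes <- function(spec) {
  voiNeeded <- spec$targetMtv / mtvVoiRatio(spec) * 1000  # mm^3
  s <- (voiNeeded * 3 / (4 * pi * prod(spec$aspect)))^(1 / 3)
  s * spec$aspect
}

#' Generate a two-grid PET/ADC tumor phantom
#'
#' Builds, on the ADC grid, an ellipsoidal tumor whose noise-free SUV field
#' is a radial uptake profile plus a smoothed Gaussian texture field, and
#' whose noise-free ADC field is a second texture field constructed (by
#' Gram-Schmidt orthogonalization against the profile and analytic
#' compensation of the profile-induced attenuation) so that the sample
#' Pearson correlation between the two noise-free fields over tumor-VOI
#' voxels equals \code{spec$rho} exactly. \code{|rho| = 1} is generated as an
#' exact affine ADC-SUV map.
#'
#' The observed ADC map is then obtained by synthesizing diffusion-weighted
#' signals from the noise-free ADC field (mono-exponential model at
#' \code{spec$bScheme}) with additive noise and refitting the map
#' ([synthesizeDwi()] + [fitAdcMap()]). The observed PET volume is rendered
#' on the coarser PET grid by sampling the world-space SUV field, plus
#' independent Gaussian noise, so that a downstream analysis genuinely
#' exercises the PET-to-ADC resampling step. A muscle reference ellipsoid
#' with its own mean SUV/ADC is placed away from the tumor.
#'
#' @param spec A \code{"PhantomSpec"} from [phantomSpec()].
#' @param seed RNG seed (defaults to \code{spec$seed}); identical seeds give
#'   bitwise-identical phantoms.
#' @return List with elements \code{pet} (PET grid), \code{adc} (fitted ADC
#'   map), \code{dwi} (list of DWI volumes), \code{suvTrue}, \code{adcTrue}
#'   (noise-free fields on the ADC grid), \code{tumorVoi}, \code{muscle}
#'   (\linkS4class{RegionMask}s on the ADC grid), and \code{truth} (realized
#'   voxel correlation of the noise-free fields, VOI volume, latent
#'   parameters).
#' @export
generatePhantom <- function(spec = phantomSpec(), seed = spec$seed) {
  stopifnot(inherits(spec, "PhantomSpec"))
  if (!is.null(seed)) set.seed(seed)
  d <- spec$adcDim
  sp <- spec$adcSpacing
  ext <- (d - 1) * sp
  center <- ext / 2
  semi <- tumorSemiAxes(spec)
  if (any(center - semi * sqrt(1.5) < 0) ||
      any(center + semi * sqrt(1.5) > ext))
    stop("tumor extends beyond the field of view; enlarge adcDim or reduce targetMtv")

  cw <- lapply(1:3, function(a) axisCoords(d[a], sp[a], 0))
  sq <- lapply(1:3, function(a) ((cw[[a]] - center[a]) / semi[a])^2)
  r2 <- outer(outer(sq[[1]], sq[[2]], `+`), sq[[3]], `+`)
  voi <- r2 <= 1
  Tprof <- pmax(0, 1 - r2)
  # transition band: 1 inside the VOI, smooth decay to 0 by r2 = 1.5, so the
  # rendered PET blob has no intensity discontinuity at the VOI boundary
  band <- pmin(pmax((1.5 - r2) / 0.5, 0), 1)

  # muscle ellipsoid: first corner position with clearance from the tumor band
  msemi <- spec$muscleSemiAxes
  corners <- list(c(0.18, 0.18, 0.5), c(0.82, 0.18, 0.5),
                  c(0.18, 0.82, 0.5), c(0.82, 0.82, 0.5))
  muscle <- NULL
  for (f in corners) {
    cm <- f * ext
    m2 <- outer(outer(((cw[[1]] - cm[1]) / msemi[1])^2,
                      ((cw[[2]] - cm[2]) / msemi[2])^2, `+`),
                ((cw[[3]] - cm[3]) / msemi[3])^2, `+`)
    mk <- m2 <= 1
    if (any(mk) && !any(mk & r2 <= 1.5)) { muscle <- mk; break }
  }
  if (is.null(muscle))
    stop("no room for the muscle reference region; tumor too large for the field of view")

  # uptake profile: 1 at the center, suvFloor at the VOI edge, continuous
  # decay to 0 across the transition band
  prof <- (1 - spec$suvFloor) * Tprof + spec$suvFloor * band

  # latent texture fields, orthogonalized over VOI voxels against {1, profile}
  u0 <- gaussianSmooth3d(array(stats::rnorm(prod(d)), d), spec$sigmaMm, sp)
  v0 <- gaussianSmooth3d(array(stats::rnorm(prod(d)), d), spec$sigmaMm, sp)
  Tv <- prof[voi]
  X <- cbind(1, Tv)
  cu <- qr.coef(qr(X), u0[voi])
  uRes <- u0[voi] - X %*% cu
  su <- stats::sd(uRes)
  uF <- (u0 - cu[1] - cu[2] * prof) / su
  X2 <- cbind(X, uF[voi])
  cv <- qr.coef(qr(X2), v0[voi])
  vRes <- v0[voi] - X2 %*% cv
  sv <- stats::sd(vRes)
  vF <- (v0 - cv[1] - cv[2] * prof - cv[3] * uF) / sv

  amp <- spec$peakSuv - spec$bgSuv
  varT <- stats::var(Tv)  # variance of the profile over VOI voxels
  aAtt <- spec$suvSd / sqrt(amp^2 * varT + spec$suvSd^2)
  exactAffine <- abs(spec$rho) == 1
  if (exactAffine) {
    wF <- uF
  } else {
    rhoL <- spec$rho / aAtt
    if (abs(rhoL) > 1)
      stop(sprintf(
        "requested correlation %.3f exceeds the attainable range (+/- %.3f) for this uptake profile",
        spec$rho, aAtt))
    wF <- rhoL * uF + sqrt(1 - rhoL^2) * vF
  }

  suvNf <- spec$bgSuv + amp * prof + spec$suvSd * wF * band
  nClipped <- sum(suvNf[voi] < 0.01)
  suvNf <- pmax(suvNf, 0.01)  # before the ADC map so |rho| = 1 stays exact
  adcNf <- spec$bgAdc + ((spec$tumorAdc - spec$bgAdc) +
                           spec$adcSd * uF) * band
  if (exactAffine) {
    z <- (suvNf[voi] - mean(suvNf[voi])) / stats::sd(suvNf[voi])
    adcNf[voi] <- spec$tumorAdc + sign(spec$rho) * spec$adcSd * z
  }
  nClipped <- nClipped + sum(adcNf[voi] < 1)
  adcNf <- pmax(adcNf, 1)
  suvNf[muscle] <- spec$muscleSuv
  adcNf[muscle] <- spec$muscleAdc

  suvTrue <- ImageVolume(suvNf, spacing = sp, origin = c(0, 0, 0),
                         modality = "PET_SUV")
  adcTrue <- ImageVolume(adcNf, spacing = sp, origin = c(0, 0, 0),
                         modality = "ADC")
  voiMask <- RegionMask(voi, spacing = sp, origin = c(0, 0, 0),
                        label = "tumor_VOI")
  muscleMask <- RegionMask(muscle, spacing = sp, origin = c(0, 0, 0),
                           label = "muscle")

  # observed ADC map via the diffusion signal model
  dwi <- synthesizeDwi(adcTrue, S0 = spec$S0, bValues = spec$bScheme,
                       noiseSd = spec$dwiNoiseSd)
  adcObs <- fitAdcMap(dwi)

  # observed PET rendered on the coarser PET grid
  psp <- spec$petSpacing
  petDim <- as.integer(ceiling((ext + 2 * psp) / psp) + 1)
  petTemplate <- ImageVolume(array(0, petDim), spacing = psp,
                             origin = -psp, modality = "PET_SUV")
  petNf <- resampleToGrid(suvTrue, petTemplate, method = "trilinear")
  petData <- petNf@data
  if (spec$petNoiseSd > 0)
    petData <- petData + stats::rnorm(length(petData), sd = spec$petNoiseSd)
  pet <- ImageVolume(pmax(petData, 0), spacing = psp, origin = -psp,
                     modality = "PET_SUV", valid = petNf@valid)

  truth <- list(rhoTarget = spec$rho,
                rhoRealized = stats::cor(suvNf[voi], adcNf[voi]),
                rhoLatent = if (exactAffine) sign(spec$rho) else rhoL,
                attainableRho = aAtt,
                voiMl = maskVolumeMl(voiMask),
                nVoiVoxels = sum(voi),
                nClipped = nClipped,
                semiAxesMm = semi)
  list(pet = pet, adc = adcObs, dwi = dwi, suvTrue = suvTrue,
       adcTrue = adcTrue, tumorVoi = voiMask, muscle = muscleMask,
       truth = truth, spec = spec)
}
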