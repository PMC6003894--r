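#' Specification of a synthetic patient cohort
#'
#' Defaults emulate a 17-patient cervical-cancer PET/MR cohort: histology mix
#' 9 squamous cell (SCCA) / 6 adenocarcinoma (AdenoCA) / 1 small cell /
#' 1 adenosquamous; grade mix 3 well / 3 moderately / 11 poorly
#' differentiated (poor grade concentrated in SCCA); treatment 14
#' chemoradiation / 3 surgery. Per-histology voxel-correlation strata center
#' the SCCA tumors at rho = -0.35 and the AdenoCA tumors at -0.068 (wider
#' spread), with draws truncated to the generator's attainable range.
#'
#' Outcomes: disease-free survival times are exponential with hazard
#' \code{lambda0 * exp(beta)} for patients whose true rho lies below the
#' cohort median (stronger SUV-ADC anticorrelation = higher risk) and
#' \code{lambda0} otherwise; censoring is uniform on
#' \code{(censorMin, censorMax)} months. \code{lambda0} is set so that the
#' marginal 2-year event-free fraction is about 0.765 under the default
#' beta = log(3); the overall-survival model uses a smaller effect.
#'
#' @param n Number of patients.
#' @param mix Named integer vector of histology counts summing to \code{n}.
#' @param gradeProps Per-histology proportions over grades
#'   (well/moderate/poor), a named list of length-3 vectors.
#' @param chemoRtFrac Fraction treated with definitive chemoradiation.
#' @param rhoStrata Named list of \code{c(mean, sd)} per histology for the
#'   target voxel correlation.
#' @param rhoRange Truncation interval for rho draws.
#' @param mtvCoupling List \code{(enabled, strength)}: when enabled, the
#'   per-patient target MTV is coupled to rho through a Gaussian copula with
#'   the given cross-patient correlation (negative strength: larger tumors
#'   have more negative rho).
#' @param mtvLogSd Log-scale SD of the per-patient target MTV around the
#'   cohort default.
#' @param outcome List: \code{lambda0}, \code{betaDfs}, \code{lambda0Os},
#'   \code{betaOs} (per-month hazards / log hazard ratios), \code{censorMin},
#'   \code{censorMax} (months).
#' @param phantom Base \code{"PhantomSpec"} used for every patient (rho,
#'   targetMtv and seed are overridden per patient).
#' @param seed Master RNG seed.
#' @return A list of class \code{"CohortSpec"}.
#' @export
cohortSpec <- function(n = 17,
                       mix = c(SCCA = 9, AdenoCA = 6, small_cell = 1,
                               adenosquamous = 1),
                       gradeProps = list(
                         SCCA = c(well = 1 / 9, moderate = 1 / 9, poor = 7 / 9),
                         AdenoCA = c(well = 2 / 6, moderate = 2 / 6, poor = 2 / 6),
                         small_cell = c(well = 0, moderate = 0, poor = 1),
                         adenosquamous = c(well = 0, moderate = 0, poor = 1)),
                       chemoRtFrac = 14 / 17,
                       rhoStrata = list(SCCA = c(mean = -0.35, sd = 0.1),
                                        AdenoCA = c(mean = -0.068, sd = 0.25),
                                        small_cell = c(mean = -0.35, sd = 0.1),
                                        adenosquamous = c(mean = -0.2, sd = 0.15)),
                       rhoRange = c(-0.7, 0.55),
                       mtvCoupling = list(enabled = FALSE, strength = -0.5),
                       mtvLogSd = 0.35,
                       outcome = list(lambda0 = 0.0058, betaDfs = log(3),
                                      lambda0Os = 0.0055, betaOs = log(2),
                                      censorMin = 24, censorMax = 60),
                       phantom = phantomSpec(), seed = 1L) {
  if (sum(mix) != n) stop("histology mix must sum to n")
  if (any(mix < 0)) stop("negative histology counts")
  if (outcome$lambda0 <= 0 || outcome$lambda0Os <= 0)
    stop("baseline hazards must be positive")
  spec <- list(n = n, mix = mix, gradeProps = gradeProps,
               chemoRtFrac = chemoRtFrac, rhoStrata = rhoStrata,
               rhoRange = rhoRange, mtvCoupling = mtvCoupling,
               mtvLogSd = mtvLogSd, outcome = outcome, phantom = phantom,
               seed = seed)
  class(spec) <- "CohortSpec"
  spec
}

#' Read a cohort specification from a YAML config file
#'
#' Keys mirror the arguments of [cohortSpec()]; missing keys keep their
#' defaults. \code{mix}, \code{rhoStrata} and \code{outcome} are given as
#' nested mappings. The cohort size is given as \code{nPatients} (a bare
#' \code{n} is a YAML 1.1 boolean and cannot be used as a key).
#'
#' @param path Path to a YAML file.
#' @return A \code{"CohortSpec"}.
#' @export
readCohortSpec <- function(path) {
  cfg <- yaml::read_yaml(path)
  args <- list()
  if (!is.null(cfg$nPatients)) args$n <- cfg$nPatients
  for (nm in c("chemoRtFrac", "rhoRange", "mtvLogSd", "seed"))
    if (!is.null(cfg[[nm]])) args[[nm]] <- cfg[[nm]]
  if (!is.null(cfg$mix)) args$mix <- unlist(cfg$mix)
  if (!is.null(cfg$rhoStrata))
    args$rhoStrata <- lapply(cfg$rhoStrata, unlist)
  if (!is.null(cfg$mtvCoupling)) args$mtvCoupling <- cfg$mtvCoupling
  if (!is.null(cfg$outcome)) {
    base <- cohortSpec()$outcome
    base[names(cfg$outcome)] <- cfg$outcome
    args$outcome <- base
  }
  if (!is.null(cfg$phantom))
    args$phantom <- do.call(phantomSpec, cfg$phantom)
  do.call(cohortSpec, args)
}

# largest-remainder allocation of n items to proportions p
allocateCounts <- function(n, p) {
  p <- p / sum(p)
  raw <- n * p
  k <- floor(raw)
  rem <- n - sum(k)
  if (rem > 0) {
    ord <- order(raw - k, decreasing = TRUE)
    k[ord[seq_len(rem)]] <- k[ord[seq_len(rem)]] + 1
  }
  k
}

# truncated normal draw by inverse-CDF
rtruncnorm1 <- function(n, mean, sd, lo, hi) {
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(plo + stats::runif(n) * (phi - plo), mean, sd)
}

#' Simulate survival outcomes for a two-group biomarker
#'
#' Exponential event times with hazard \code{lambda0} in the reference group
#' and \code{lambda0 * exp(beta)} in the high-risk group, censored uniformly
#' on \code{(censorMin, censorMax)}. Continuous draws make ties
#' probability-zero.
#'
#' @param highRisk Logical vector, one entry per subject.
#' @param lambda0 Baseline hazard per month.
#' @param beta Log hazard ratio of high-risk vs reference.
#' @param censorMin,censorMax Censoring window (months); set
#'   \code{censorMin = censorMax = Inf} for complete follow-up.
#' @return Data.frame: \code{time}, \code{event}.
#' @export
simulateOutcomes <- function(highRisk, lambda0, beta,
                             censorMin = 24, censorMax = 60) {
  n <- length(highRisk)
  tev <- stats::rexp(n, rate = lambda0 * exp(beta * as.numeric(highRisk)))
  if (is.finite(censorMax)) {
    cens <- stats::runif(n, censorMin, censorMax)
    data.frame(time = pmin(tev, cens), event = tev <= cens)
  } else {
    data.frame(time = tev, event = rep(TRUE, n))
  }
}

#' Generate a fully synthetic patient cohort
#'
#' Draws per-patient histology, grade and treatment according to the cohort
#' mix, a per-patient target voxel correlation rho from the histology
#' stratum (truncated normal), an optional MTV-coupled tumor size, survival
#' outcomes whose hazard depends on whether the patient's true rho lies
#' below the cohort median, and (optionally) a full two-grid PET/ADC phantom
#' per patient. Everything is a pure function of \code{(spec, spec$seed)}.
#'
#' @param spec A \code{"CohortSpec"} from [cohortSpec()].
#' @param phantoms Generate imaging phantoms (\code{TRUE}) or only the
#'   clinical and truth tables (\code{FALSE}).
#' @param dir Optional output directory: writes \code{clinical.csv},
#'   \code{truth.csv} and per-patient NIfTI volumes/masks
#'   (\code{<id>_pet.nii.gz}, \code{<id>_adc.nii.gz}, \code{<id>_voi.nii.gz},
#'   \code{<id>_muscle.nii.gz}).
#' @return List: \code{clinical} (id, histology, grade, treatment, dfs_time,
#'   dfs_event, os_time, os_event), \code{truth} (latent parameters per
#'   patient), \code{phantoms} (list or NULL), \code{spec}.
#' @export
generateCohort <- function(spec = cohortSpec(), phantoms = TRUE, dir = NULL) {
  stopifnot(inherits(spec, "CohortSpec"))
  if (is.null(spec$seed)) {
    spec$seed <- sample.int(2^31 - 2, 1)
    message("no seed supplied; drew master seed ", spec$seed)
  }
  set.seed(spec$seed)
  n <- spec$n
  histology <- rep(names(spec$mix), spec$mix)
  grade <- unlist(lapply(names(spec$mix), function(h) {
    k <- allocateCounts(spec$mix[[h]], spec$gradeProps[[h]])
    rep(c("well", "moderate", "poor"), k)
  }))
  nChemo <- round(spec$chemoRtFrac * n)
  treatment <- rep(c("chemoradiation", "surgery"), c(nChemo, n - nChemo))
  id <- sprintf("P%02d", seq_len(n))

  # per-patient target rho, truncated to the attainable/configured range
  base <- spec$phantom
  lo <- max(spec$rhoRange[1], -0.95)
  hi <- min(spec$rhoRange[2], 0.95)
  zRho <- stats::rnorm(n)
  rho <- vapply(seq_len(n), function(i) {
    s <- spec$rhoStrata[[histology[i]]]
    r <- stats::pnorm(zRho[i])
    plo <- stats::pnorm(lo, s[["mean"]], s[["sd"]])
    phi <- stats::pnorm(hi, s[["mean"]], s[["sd"]])
    stats::qnorm(plo + r * (phi - plo), s[["mean"]], s[["sd"]])
  }, numeric(1))

  # per-patient target MTV, optionally coupled to rho (Gaussian copula)
  if (isTRUE(spec$mtvCoupling$enabled)) {
    s <- spec$mtvCoupling$strength
    zMtv <- s * zRho + sqrt(1 - s^2) * stats::rnorm(n)
  } else {
    zMtv <- stats::rnorm(n)
  }
  targetMtv <- base$targetMtv * exp(spec$mtvLogSd * zMtv -
                                      spec$mtvLogSd^2 / 2)

  highRisk <- rho < stats::median(rho)
  oc <- spec$outcome
  dfs <- simulateOutcomes(highRisk, oc$lambda0, oc$betaDfs,
                          oc$censorMin, oc$censorMax)
  os <- simulateOutcomes(highRisk, oc$lambda0Os, oc$betaOs,
                         oc$censorMin, oc$censorMax)
  clinical <- data.frame(id = id, histology = histology, grade = grade,
                         treatment = treatment,
                         dfs_time = dfs$time, dfs_event = dfs$event,
                         os_time = os$time, os_event = os$event)

  seeds <- sample.int(2^31 - 2, n)
  phantomList <- NULL
  rhoRealized <- rep(NA_real_, n)
  voiMl <- rep(NA_real_, n)
  if (phantoms) {
    phantomList <- vector("list", n)
    for (i in seq_len(n)) {
      ps <- base
      ps$rho <- rho[i]
      ps$targetMtv <- targetMtv[i]
      ph <- generatePhantom(ps, seed = seeds[i])
      rhoRealized[i] <- ph$truth$rhoRealized
      voiMl[i] <- ph$truth$voiMl
      phantomList[[i]] <- ph
    }
    names(phantomList) <- id
  }
  truth <- data.frame(id = id, rhoTarget = rho, rhoRealized = rhoRealized,
                      targetMtv = targetMtv, voiMl = voiMl,
                      highRisk = highRisk, phantomSeed = seeds)

  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    utils::write.csv(clinical, file.path(dir, "clinical.csv"),
                     row.names = FALSE)
    utils::write.csv(truth, file.path(dir, "truth.csv"), row.names = FALSE)
    if (phantoms) {
      for (i in seq_len(n)) {
        ph <- phantomList[[i]]
        writeVolume(ph$pet, file.path(dir, paste0(id[i], "_pet.nii.gz")))
        writeVolume(ph$adc, file.path(dir, paste0(id[i], "_adc.nii.gz")))
        writeMask(ph$tumorVoi, file.path(dir, paste0(id[i], "_voi.nii.gz")))
        writeMask(ph$muscle, file.path(dir, paste0(id[i], "_muscle.nii.gz")))
      }
    }
  }
  list(clinical = clinical, truth = truth, phantoms = phantomList,
       spec = spec)
}
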