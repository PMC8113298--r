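# separable Gaussian smoothing along one axis (axis 1 of `a`), with
# edge-replication padding so a uniform volume stays uniform
.blurAxis <- function(a, sigmaVox) {
  if (sigmaVox <= 0) return(a)
  d <- dim(a)
  h <- max(1L, as.integer(ceiling(3 * sigmaVox)))
  k <- stats::dnorm(seq(-h, h), sd = sigmaVox)
  k <- k / sum(k)
  m <- matrix(a, nrow = d[1])
  padded <- rbind(m[rep(1L, h), , drop = FALSE], m,
                  m[rep(d[1], h), , drop = FALSE])
  f <- stats::filter(padded, k, sides = 2)
  array(as.numeric(f[(h + 1):(h + d[1]), ]), d)
}

# isotropic-in-mm Gaussian blur of a 3D array; FWHM in mm
.gaussianBlur3D <- function(a, spacing, fwhm) {
  if (fwhm <= 0) return(a)
  sigmaMm <- fwhm / (2 * sqrt(2 * log(2)))
  a <- .blurAxis(a, sigmaMm / spacing[1])
  a <- aperm(.blurAxis(aperm(a, c(2, 1, 3)), sigmaMm / spacing[2]),
             c(2, 1, 3))
  aperm(.blurAxis(aperm(a, c(3, 2, 1)), sigmaMm / spacing[3]),
        c(3, 2, 1))
}

# paint spheres (voxel-center membership) into `labels`; errors on
# overlap or out-of-grid spheres. Returns the updated label array.
.paintSpheres <- function(labels, spheres, spacing, origin, what) {
  d <- dim(labels)
  lo <- origin - spacing / 2
  hi <- origin + (d - 0.5) * spacing
  for (i in seq_len(nrow(spheres))) {
    ctr <- as.numeric(spheres[i, c("x", "y", "z")])
    rad <- spheres$diameter[i] / 2
    if (any(ctr - rad < lo) || any(ctr + rad > hi))
      stop(what, " ", i, " (center ", paste(format(ctr), collapse = ", "),
           " mm, diameter ", spheres$diameter[i],
           " mm) extends outside the image grid")
    ilo <- pmax(floor((ctr - rad - origin) / spacing) + 1, 1)
    ihi <- pmin(ceiling((ctr + rad - origin) / spacing) + 1, d)
    gx <- ilo[1]:ihi[1]; gy <- ilo[2]:ihi[2]; gz <- ilo[3]:ihi[3]
    wx <- origin[1] + (gx - 1) * spacing[1]
    wy <- origin[2] + (gy - 1) * spacing[2]
    wz <- origin[3] + (gz - 1) * spacing[3]
    d2 <- outer(outer((wx - ctr[1])^2, (wy - ctr[2])^2, `+`),
                (wz - ctr[3])^2, `+`)
    member <- d2 <= rad^2
    sub <- labels[gx, gy, gz, drop = FALSE]
    if (any(sub[member] > 0L))
      stop(what, " ", i, " overlaps a previously painted region")
    sub[member] <- i
    labels[gx, gy, gz] <- sub
  }
  labels
}

#' Generate a digital PET phantom
#'
#' Builds a synthetic SUV volume emulating an EARL-like whole-body PET
#' acquisition: spherical lesions and (optionally) high-uptake
#' physiological regions painted on a low-uptake background by
#' voxel-center membership, convolved with an isotropic Gaussian
#' point-spread function, plus additive Gaussian noise clipped at zero.
#' Defaults follow the emulated reconstruction: 256 x 256 in-plane
#' matrix, 3.2 x 3.2 x 2 mm voxels, 6.5 mm FWHM. Ground-truth masks are
#' the unblurred sphere voxel sets; physiological regions are tagged
#' separately so operator removal can be exercised.
#'
#' @param lesions data.frame with columns `x`, `y`, `z` (center, world
#'   mm), `diameter` (mm) and `suv` (g/mL).
#' @param physio optional data.frame in the same format (plus an
#'   optional `tag` column) for physiological high-uptake regions.
#' @param shape integer(3) grid dimensions (voxels).
#' @param spacing numeric(3) voxel size in mm.
#' @param background background SUV (g/mL).
#' @param fwhm Gaussian PSF full width at half maximum in mm (0 = no
#'   blur).
#' @param noiseSd standard deviation of additive Gaussian noise (g/mL;
#'   0 = noise free).
#' @param seed optional integer seed making the noise reproducible.
#' @param origin world mm of the first voxel center; default centers the
#'   grid on (0, 0, 0).
#' @return list with `image` ([SUVImage-class]), `truth`
#'   ([LesionSet-class] of unblurred lesion spheres, labeled in row
#'   order) and `physio` ([LesionSet-class] of physiological regions).
#' @examples
#' ph <- generatePhantom(
#'   lesions = data.frame(x = 0, y = 0, z = 0, diameter = 24, suv = 8),
#'   shape = c(32, 32, 32), fwhm = 0, noiseSd = 0)
#' matv(ph$truth)
#' @export
generatePhantom <- function(lesions,
                            physio = NULL,
                            shape = c(256, 256, 64),
                            spacing = c(3.2, 3.2, 2),
                            background = 1.0,
                            fwhm = 6.5,
                            noiseSd = 0.1,
                            seed = NULL,
                            origin = -(shape - 1) * spacing / 2) {
  stopifnot(is.data.frame(lesions),
            all(c("x", "y", "z", "diameter", "suv") %in% names(lesions)),
            all(lesions$diameter > 0), all(lesions$suv >= 0),
            background >= 0, fwhm >= 0, noiseSd >= 0)
  shape <- as.integer(shape)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (!is.null(seed)) set.seed(seed)

  truthRaw <- .paintSpheres(array(0L, shape), lesions, spacing, origin,
                            "lesion")
  physioRaw <- array(0L, shape)
  if (!is.null(physio) && nrow(physio) > 0) {
    stopifnot(all(c("x", "y", "z", "diameter", "suv") %in% names(physio)))
    physioRaw <- .paintSpheres(physioRaw, physio, spacing, origin,
                               "physiological region")
    if (any(physioRaw > 0L & truthRaw > 0L))
      stop("physiological regions overlap lesions")
  }

  arr <- array(background, shape)
  for (i in seq_len(nrow(lesions)))
    arr[truthRaw == i] <- lesions$suv[i]
  if (!is.null(physio) && nrow(physio) > 0)
    for (i in seq_len(nrow(physio)))
      arr[physioRaw == i] <- physio$suv[i]

  arr <- .gaussianBlur3D(arr, spacing, fwhm)
  if (noiseSd > 0)
    arr <- pmax(arr + stats::rnorm(length(arr), 0, noiseSd), 0)

  vv <- prod(spacing) / 1000
  mkSet <- function(raw, n) {
    counts <- if (n > 0) tabulate(raw[raw > 0L], nbins = n) else integer()
    new("LesionSet", labels = raw,
        lesions = data.frame(id = seq_len(n), voxels = as.integer(counts),
                             volume_ml = counts * vv,
                             source = rep("auto", n),
                             stringsAsFactors = FALSE),
        spacing = spacing, origin = origin)
  }
  list(image = SUVImage(array(arr, shape), spacing, origin),
       truth = mkSet(truthRaw, nrow(lesions)),
       physio = mkSet(physioRaw,
                      if (is.null(physio)) 0L else nrow(physio)))
}

#' Generate a synthetic survival cohort
#'
#' Draws a cohort of patients with per-patient tumour burden and linked
#' overall survival, emulating a metastatic-melanoma-like population:
#' each patient receives `1 + Poisson(meanLesions)` spherical lesions
#' with log-normal diameters (truncated to 8-60 mm) and uniform uptake,
#' giving an analytic true MATV; survival time is exponential with
#' hazard `log(2) / baselineMedianMonths * exp(beta * (log MATV -
#' log refMatvMl))`, censored administratively at a uniform follow-up
#' horizon. `beta = 0` decouples survival from tumour burden (null
#' cohorts for calibration checks). Default cohort size is 64 patients
#' with roughly one third alive at censoring under the defaults.
#'
#' @param n number of patients (>= 2).
#' @param seed optional integer seed.
#' @param meanLesions Poisson mean of the extra-lesion count.
#' @param diameterMeanLog,diameterSdLog log-normal parameters of lesion
#'   diameter (mm).
#' @param suvRange uniform range of lesion uptake (g/mL).
#' @param baselineMedianMonths median survival (months) at the reference
#'   MATV.
#' @param beta log-hazard coefficient on log(MATV / refMatvMl).
#' @param refMatvMl reference MATV (mL) at which the baseline hazard
#'   applies.
#' @param followupRange uniform range (months) of the administrative
#'   censoring horizon.
#' @return list with `patients` (patient_id, n_lesions, true_matv_ml),
#'   `survival` (patient_id, months, event) and `lesions` (patient_id,
#'   diameter_mm, suv).
#' @examples
#' co <- generateCohort(n = 8, seed = 1)
#' co$patients
#' @export
generateCohort <- function(n = 64, seed = NULL, meanLesions = 3,
                           diameterMeanLog = log(20),
                           diameterSdLog = 0.4,
                           suvRange = c(4, 12),
                           baselineMedianMonths = 18,
                           beta = 0.5, refMatvMl = 25,
                           followupRange = c(18, 42)) {
  stopifnot(n >= 2, meanLesions >= 0, diameterSdLog >= 0,
            length(suvRange) == 2, baselineMedianMonths > 0,
            refMatvMl > 0, length(followupRange) == 2,
            followupRange[1] > 0)
  if (!is.null(seed)) set.seed(seed)
  nl <- 1L + stats::rpois(n, meanLesions)
  lesions <- data.frame(
    patient_id = rep(seq_len(n), nl),
    diameter_mm = pmin(pmax(stats::rlnorm(sum(nl), diameterMeanLog,
                                          diameterSdLog), 8), 60))
  lesions$suv <- stats::runif(nrow(lesions), suvRange[1], suvRange[2])
  matvPer <- tapply((pi / 6) * lesions$diameter_mm^3 / 1000,
                    factor(lesions$patient_id, levels = seq_len(n)), sum)
  matvMl <- as.numeric(matvPer)
  hazard <- log(2) / baselineMedianMonths *
    exp(beta * (log(matvMl) - log(refMatvMl)))
  tDeath <- stats::rexp(n, hazard)
  tCens <- stats::runif(n, followupRange[1], followupRange[2])
  list(patients = data.frame(patient_id = seq_len(n), n_lesions = nl,
                             true_matv_ml = matvMl),
       survival = data.frame(patient_id = seq_len(n),
                             months = pmin(tDeath, tCens),
                             event = as.integer(tDeath <= tCens)),
       lesions = lesions)
}
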