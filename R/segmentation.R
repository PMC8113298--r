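#' Fixed SUV-threshold segmentation
#'
#' Includes every voxel whose SUV is greater than or equal to the
#' threshold. This realizes the SUV25 (2.5 g/mL) and SUV40 (4.0 g/mL)
#' delineation methods. The comparison is inclusive (>=) for bit-exact
#' reproducibility.
#'
#' @param image an [SUVImage-class].
#' @param threshold SUV threshold in g/mL (> 0).
#' @return A [BinaryMask-class].
#' @examples
#' a <- array(1, c(3, 3, 3)); a[2, 2, 2] <- 10
#' segmentFixed(SUVImage(a), 4.0)
#' @export
segmentFixed <- function(image, threshold) {
  stopifnot(is(image, "SUVImage"))
  if (!is.finite(threshold) || threshold <= 0)
    stop("threshold must be a positive SUV (g/mL)")
  new("BinaryMask", membership = image@values >= threshold,
      spacing = image@spacing, origin = image@origin)
}

# integer voxel offsets whose centers lie within the peak sphere
.sphereOffsets <- function(spacing, volumeMl) {
  r <- (3 * volumeMl * 1000 / (4 * pi))^(1 / 3)  # mm
  rng <- floor(r / spacing)
  off <- expand.grid(di = -rng[1]:rng[1], dj = -rng[2]:rng[2],
                     dk = -rng[3]:rng[3])
  d2 <- (off$di * spacing[1])^2 + (off$dj * spacing[2])^2 +
        (off$dk * spacing[3])^2
  as.matrix(off[d2 <= r^2, , drop = FALSE])
}

# SUVpeak with the achieving sphere-center voxel.
# Sphere centers are restricted to region voxels; sphere membership is by
# voxel-center distance <= radius; voxels falling outside the grid are
# excluded from the mean. Ties go to the smallest linear index.
.suvpeakWithCenter <- function(image, regionArr, volumeMl) {
  d <- dim(image@values)
  idx <- which(regionArr)
  if (length(idx) == 0L) stop("SUVpeak requested on an empty region")
  ijk <- arrayInd(idx, d)
  off <- .sphereOffsets(image@spacing, volumeMl)
  sums <- numeric(length(idx))
  cnts <- integer(length(idx))
  for (r in seq_len(nrow(off))) {
    ni <- ijk[, 1] + off[r, 1]
    nj <- ijk[, 2] + off[r, 2]
    nk <- ijk[, 3] + off[r, 3]
    ok <- ni >= 1L & ni <= d[1] & nj >= 1L & nj <= d[2] &
          nk >= 1L & nk <= d[3]
    lin <- (nk[ok] - 1L) * (d[1] * d[2]) + (nj[ok] - 1L) * d[1] + ni[ok]
    sums[ok] <- sums[ok] + image@values[lin]
    cnts[ok] <- cnts[ok] + 1L
  }
  means <- sums / cnts
  best <- which.max(means)
  list(value = means[best], center = ijk[best, ])
}

#' SUVpeak of a region
#'
#' SUVpeak is the maximum, over sphere centers placed at the voxel
#' centers of the region, of the mean SUV inside a sphere of
#' `peakSphereVolume` (default 1 mL, diameter ~ 12.4 mm) defined in world
#' millimetres. Sphere membership is decided by voxel-center distance;
#' for regions smaller than the sphere, out-of-region voxels contribute
#' to the mean (EANM-style behaviour).
#'
#' @param image an [SUVImage-class].
#' @param region a non-empty [BinaryMask-class] on the same grid.
#' @param config a [MethodConfig-class]; only `peakSphereVolume` is used.
#' @return SUVpeak in g/mL.
#' @export
computeSUVpeak <- function(image, region, config = methodConfig()) {
  stopifnot(is(image, "SUVImage"), is(region, "BinaryMask"))
  .checkSameGrid(image, region, "image and region")
  .suvpeakWithCenter(image, region@membership,
                     config@peakSphereVolume)$value
}

#' Detect candidate lesions
#'
#' Connected components of the voxel set above the detection threshold
#' (default 2.5 g/mL, the most inclusive of the four base thresholds).
#' These candidates are the regions inside which the adaptive methods
#' operate and on which the majority vote is evaluated.
#'
#' @param image an [SUVImage-class].
#' @param config a [MethodConfig-class].
#' @return A [LesionSet-class] of candidate regions (possibly empty).
#' @export
detectCandidates <- function(image, config = methodConfig()) {
  stopifnot(is(image, "SUVImage"))
  connectedComponents(segmentFixed(image, config@detectionThreshold),
                      config@connectivity)
}

#' Adaptive segmentation at 41% of lesion SUVmax
#'
#' Thresholds at `relativeFraction41Max` (default 0.41) of the maximum
#' SUV within the candidate region and keeps the connected component
#' containing the argmax voxel, restricted to the candidate's bounding
#' box dilated by the outer shell margin. Ties in the argmax go to the
#' smallest linear voxel index. The mask is invariant under rescaling of
#' all SUV values by any positive constant.
#'
#' @param image an [SUVImage-class].
#' @param candidate a non-empty [BinaryMask-class] candidate region.
#' @param config a [MethodConfig-class].
#' @return A [BinaryMask-class].
#' @export
segment41Max <- function(image, candidate, config = methodConfig()) {
  stopifnot(is(image, "SUVImage"), is(candidate, "BinaryMask"))
  .checkSameGrid(image, candidate, "image and candidate")
  idx <- which(candidate@membership)
  if (length(idx) == 0L) stop("41MAX requested on an empty candidate")
  vals <- image@values[idx]
  argmax <- arrayInd(idx[which.max(vals)], dim(image@values))[1, ]
  thr <- config@relativeFraction41Max * max(vals)
  outer <- config@backgroundShell[2]
  a <- (image@values >= thr) & .bboxMask(candidate@membership, outer)
  new("BinaryMask",
      membership = .componentContaining(a, argmax, config@connectivity),
      spacing = image@spacing, origin = image@origin)
}

#' Local background SUV around a region
#'
#' Mean SUV over a shell obtained by dilating the region by the outer
#' shell margin and removing its dilation by the inner margin (Chebyshev
#' voxel steps), excluding voxels that belong to any candidate lesion.
#'
#' @param image an [SUVImage-class].
#' @param region a non-empty [BinaryMask-class].
#' @param config a [MethodConfig-class]; `backgroundShell` gives the
#'   (inner, outer) dilations in voxel steps.
#' @param exclude optional [BinaryMask-class] of voxels that must not
#'   enter the background estimate (typically the union of all candidate
#'   lesions).
#' @return Mean background SUV in g/mL.
#' @export
estimateLocalBackground <- function(image, region, config = methodConfig(),
                                    exclude = NULL) {
  stopifnot(is(image, "SUVImage"), is(region, "BinaryMask"))
  .checkSameGrid(image, region, "image and region")
  r <- region@membership
  if (!any(r)) stop("background requested around an empty region")
  inner <- config@backgroundShell[1]
  outer <- config@backgroundShell[2]
  shell <- .dilateArray(r, outer) & !.dilateArray(r, inner)
  if (!is.null(exclude)) {
    .checkSameGrid(image, exclude, "image and exclude mask")
    shell <- shell & !exclude@membership
  }
  if (!any(shell))
    stop("background shell is empty; increase the outer dilation of ",
         "backgroundShell")
  mean(image@values[shell])
}

#' Background-corrected segmentation at 50% of lesion SUVpeak
#'
#' Iterates a contrast-corrected threshold: starting from the candidate
#' region, compute the region's SUVpeak P and local background B, set
#' `T = B + f * (P - B)` with `f = relativeFractionA50P` (default 0.5),
#' and update the region to the connected component of `SUV >= T` at the
#' peak location, restricted to the candidate's dilated bounding box.
#' Stops when the voxel set is unchanged or after `maxIterations`
#' iterations (keeping the last iterate, with a warning, on
#' non-convergence). If the region vanishes an empty mask is returned
#' with a warning; its MATV contribution is 0.
#'
#' @param image an [SUVImage-class].
#' @param candidate a non-empty [BinaryMask-class] candidate region.
#' @param config a [MethodConfig-class].
#' @param exclude optional [BinaryMask-class] of all candidate voxels to
#'   keep out of the background shell; defaults to the candidate itself.
#' @return A [BinaryMask-class] (possibly empty).
#' @export
segmentA50P <- function(image, candidate, config = methodConfig(),
                        exclude = candidate) {
  stopifnot(is(image, "SUVImage"), is(candidate, "BinaryMask"))
  .checkSameGrid(image, candidate, "image and candidate")
  if (!any(candidate@membership))
    stop("A50P requested on an empty candidate")
  box <- .bboxMask(candidate@membership, config@backgroundShell[2])
  region <- candidate@membership
  f <- config@relativeFractionA50P
  converged <- FALSE
  for (it in seq_len(config@maxIterations)) {
    pk <- .suvpeakWithCenter(image, region, config@peakSphereVolume)
    B <- estimateLocalBackground(
      image, new("BinaryMask", membership = region,
                 spacing = image@spacing, origin = image@origin),
      config, exclude)
    thr <- B + f * (pk$value - B)
    a <- (image@values >= thr) & box
    newRegion <- .componentContaining(a, pk$center, config@connectivity)
    if (!any(newRegion)) {
      warning("A50P region vanished during iteration ", it,
              "; returning an empty mask")
      region <- newRegion
      converged <- TRUE
      break
    }
    if (identical(newRegion, region)) {
      converged <- TRUE
      break
    }
    region <- newRegion
  }
  if (!converged)
    warning("A50P did not converge within ", config@maxIterations,
            " iterations; keeping the last iterate")
  new("BinaryMask", membership = region, spacing = image@spacing,
      origin = image@origin)
}

#' Majority-vote consensus of the four base masks
#'
#' A voxel is included when it belongs to at least `k` of the four base
#' masks (SUV25, SUV40, 41MAX, A50P). `k = 2` gives MV2, `k = 3` MV3.
#'
#' @param baseMasks list of four [BinaryMask-class] objects on one grid,
#'   in the order SUV25, SUV40, 41MAX, A50P.
#' @param k minimum number of agreeing methods (2 or 3).
#' @return A [BinaryMask-class].
#' @export
majorityVote <- function(baseMasks, k) {
  stopifnot(is.list(baseMasks), length(baseMasks) == 4L,
            k %in% c(2, 3))
  for (m in baseMasks) stopifnot(is(m, "BinaryMask"))
  for (i in 2:4) .checkSameGrid(baseMasks[[1]], baseMasks[[i]],
                                "vote ingredient masks")
  counts <- Reduce(`+`, lapply(baseMasks,
                               function(m) array(as.integer(m@membership),
                                                 dim(m@membership))))
  new("BinaryMask", membership = counts >= k,
      spacing = baseMasks[[1]]@spacing, origin = baseMasks[[1]]@origin)
}

#' Minimum-lesion-volume filter
#'
#' Removes lesions smaller than `minLesionVolume` (default 3 mL) and
#' recompacts labels deterministically. Lesions flagged
#' `source = "added"` (operator-added) are exempt; the comparison keeps
#' lesions at exactly the threshold (>=).
#'
#' @param lesions a [LesionSet-class].
#' @param config a [MethodConfig-class].
#' @return A filtered [LesionSet-class] (possibly with zero lesions).
#' @export
applyMinVolume <- function(lesions, config = methodConfig()) {
  stopifnot(is(lesions, "LesionSet"))
  df <- lesions@lesions
  if (nrow(df) == 0L) return(lesions)
  keep <- df$volume_ml >= config@minLesionVolume | df$source == "added"
  raw <- lesions@labels
  raw[raw %in% df$id[!keep]] <- 0L
  src <- character(max(df$id))
  src[df$id] <- df$source
  .lesionSetFromLabels(raw, lesions@spacing, lesions@origin, source = src)
}

# raw whole-image voxel mask of one base method (union over candidates
# for the adaptive ones)
.baseMethodArray <- function(image, method, config, candidates, detArr) {
  switch(method,
    SUV25 = image@values >= config@fixedThresholdSuv25,
    SUV40 = image@values >= config@fixedThresholdSuv40,
    `41MAX` = ,
    A50P = {
      u <- array(FALSE, dim(image@values))
      excl <- new("BinaryMask", membership = detArr,
                  spacing = image@spacing, origin = image@origin)
      for (id in candidates@lesions$id) {
        cm <- lesionMask(candidates, id)
        m <- if (method == "41MAX") segment41Max(image, cm, config)
             else segmentA50P(image, cm, config, exclude = excl)
        u <- u | m@membership
      }
      u
    },
    stop("unknown base method ", method))
}

#' Run a full segmentation method
#'
#' Executes one of the six delineation methods end to end: fixed methods
#' (SUV25, SUV40) threshold the whole volume; adaptive methods (41MAX,
#' A50P) run per candidate region and their per-candidate masks are
#' unioned; majority-vote methods (MV2, MV3) vote voxel-wise over the
#' four base masks. In every case the resulting voxel set is split into
#' connected components and the minimum-lesion-volume rule is applied
#' once at the end. A result with zero lesions is valid (MATV 0).
#'
#' @param image an [SUVImage-class].
#' @param method one of "SUV25", "SUV40", "41MAX", "A50P", "MV2", "MV3".
#' @param config a [MethodConfig-class].
#' @return A [SegmentationResult-class].
#' @examples
#' ph <- generatePhantom(
#'   lesions = data.frame(x = 0, y = 0, z = 0, diameter = 20, suv = 8),
#'   shape = c(24, 24, 24), fwhm = 0, noiseSd = 0)
#' runMethod(ph$image, "SUV40")
#' @export
runMethod <- function(image, method, config = methodConfig()) {
  stopifnot(is(image, "SUVImage"))
  method <- match.arg(method, c("SUV25", "SUV40", "41MAX", "A50P",
                                "MV2", "MV3"))
  detArr <- image@values >= config@detectionThreshold
  needsCand <- method %in% c("41MAX", "A50P", "MV2", "MV3")
  candidates <- if (needsCand) detectCandidates(image, config) else NULL

  baseNames <- if (method %in% c("MV2", "MV3"))
    c("SUV25", "SUV40", "41MAX", "A50P") else method
  arrays <- lapply(baseNames, .baseMethodArray, image = image,
                   config = config, candidates = candidates,
                   detArr = detArr)
  names(arrays) <- baseNames

  finalArr <- if (method %in% c("MV2", "MV3")) {
    k <- if (method == "MV2") 2L else 3L
    Reduce(`+`, lapply(arrays, function(a) array(as.integer(a),
                                                 dim(a)))) >= k
  } else arrays[[method]]

  lesions <- applyMinVolume(
    connectedComponents(new("BinaryMask", membership = finalArr,
                            spacing = image@spacing,
                            origin = image@origin),
                        config@connectivity),
    config)
  baseMasks <- lapply(arrays, function(a)
    new("BinaryMask", membership = a, spacing = image@spacing,
        origin = image@origin))
  new("SegmentationResult", method = method, lesions = lesions,
      baseMasks = baseMasks, audit = .emptyAudit(), config = config)
}
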