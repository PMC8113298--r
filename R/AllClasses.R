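#' @import methods
NULL

#' SUVImage: a calibrated 3D PET volume
#'
#' Container for a 3D grid of standardized uptake values (SUV, g/mL)
#' together with its voxel spacing and world origin. All segmentation and
#' quantification in this package operates on \code{SUVImage} objects.
#'
#' The coordinate convention is voxel-center based: voxel \code{(i, j, k)}
#' (1-based) has world position \code{origin + (c(i, j, k) - 1) * spacing},
#' with axis order (x, y, z) fixed throughout.
#'
#' @slot values 3D numeric array of SUV in g/mL; all finite and >= 0.
#' @slot spacing numeric(3), voxel size in mm per axis; all > 0.
#' @slot origin numeric(3), world position (mm) of the center of voxel
#'   (1, 1, 1).
#'
#' @seealso [SUVImage()] for the constructor, [voxelVolumeMl()],
#'   [worldToVoxel()]
#' @export
setClass("SUVImage",
  representation(values = "array", spacing = "numeric", origin = "numeric"))

setValidity("SUVImage", function(object) {
  v <- object@values
  if (length(dim(v)) != 3L)
    return("values must be a 3D array")
  if (any(dim(v) < 1L))
    return("grid must have at least 1 voxel per axis")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    return("spacing must be 3 positive finite numbers (mm)")
  if (length(object@origin) != 3L || any(!is.finite(object@origin)))
    return("origin must be 3 finite numbers (mm)")
  if (any(!is.finite(v)))
    return("SUV values must all be finite (no NA/NaN/Inf)")
  if (any(v < 0))
    return("SUV values must all be >= 0 g/mL")
  TRUE
})

#' Construct an SUVImage
#'
#' @param values 3D numeric array of SUV values (g/mL).
#' @param spacing numeric(3) voxel spacing in mm. Default is the
#'   EARL-like reconstruction grid of 3.2 x 3.2 x 2 mm.
#' @param origin numeric(3) world coordinates (mm) of the first voxel
#'   center.
#' @return An [SUVImage-class] object.
#' @examples
#' img <- SUVImage(array(1, c(4, 4, 4)))
#' voxelVolumeMl(img)
#' @export
SUVImage <- function(values, spacing = c(3.2, 3.2, 2), origin = c(0, 0, 0)) {
  new("SUVImage", values = values, spacing = as.numeric(spacing),
      origin = as.numeric(origin))
}

#' BinaryMask: voxel membership on an SUVImage grid
#'
#' A logical 3D grid marking a volume of interest (VOI) on the grid of a
#' parent [SUVImage-class]; carries identical spacing and origin so
#' grid-compatibility can be checked.
#'
#' @slot membership 3D logical array.
#' @slot spacing numeric(3) voxel spacing in mm.
#' @slot origin numeric(3) world origin in mm.
#' @export
setClass("BinaryMask",
  representation(membership = "array", spacing = "numeric",
                 origin = "numeric"))

setValidity("BinaryMask", function(object) {
  m <- object@membership
  if (length(dim(m)) != 3L)
    return("membership must be a 3D array")
  if (!is.logical(m))
    return("membership must be logical")
  if (any(is.na(m)))
    return("membership must not contain NA")
  if (length(object@spacing) != 3L || any(object@spacing <= 0))
    return("spacing must be 3 positive numbers (mm)")
  if (length(object@origin) != 3L || any(!is.finite(object@origin)))
    return("origin must be 3 finite numbers (mm)")
  TRUE
})

#' Construct a BinaryMask
#'
#' @param membership 3D logical array.
#' @param image optional [SUVImage-class] supplying grid metadata.
#' @param spacing,origin grid metadata, used when `image` is absent.
#' @return A [BinaryMask-class].
#' @export
BinaryMask <- function(membership, image = NULL, spacing = c(3.2, 3.2, 2),
                       origin = c(0, 0, 0)) {
  if (!is.null(image)) {
    if (!identical(dim(membership), dim(image@values)))
      stop("mask shape ", paste(dim(membership), collapse = "x"),
           " does not match image grid ",
           paste(dim(image@values), collapse = "x"))
    spacing <- image@spacing
    origin <- image@origin
  }
  new("BinaryMask", membership = membership, spacing = as.numeric(spacing),
      origin = as.numeric(origin))
}

#' LesionSet: labeled connected lesion components
#'
#' A labeled voxel grid (0 = background, k >= 1 = lesion id) plus a
#' per-lesion table with voxel counts, volumes and provenance
#' (automatically segmented vs manually added). Label ids are consecutive
#' from 1, ordered by descending volume with ties broken by the smallest
#' linear voxel index.
#'
#' @slot labels 3D integer array of lesion ids.
#' @slot lesions data.frame with columns `id`, `voxels`, `volume_ml`,
#'   `source` ("auto" or "added").
#' @slot spacing numeric(3) voxel spacing in mm.
#' @slot origin numeric(3) world origin in mm.
#' @export
setClass("LesionSet",
  representation(labels = "array", lesions = "data.frame",
                 spacing = "numeric", origin = "numeric"))

setValidity("LesionSet", function(object) {
  lab <- object@labels
  df <- object@lesions
  if (length(dim(lab)) != 3L) return("labels must be a 3D array")
  if (any(is.na(lab)) || any(lab < 0)) return("labels must be >= 0, no NA")
  need <- c("id", "voxels", "volume_ml", "source")
  if (!all(need %in% names(df)))
    return(paste("lesions table needs columns:", paste(need, collapse = ", ")))
  n <- nrow(df)
  if (n > 0 && !identical(as.integer(df$id), seq_len(n)))
    return("lesion ids must be consecutive from 1")
  present <- tabulate(lab[lab > 0L], nbins = max(n, 1L))
  if (n > 0 && !identical(as.integer(df$voxels), as.integer(present[seq_len(n)])))
    return("per-lesion voxel counts must match the label grid")
  if (n == 0 && any(lab > 0L))
    return("label grid has lesions but the table is empty")
  vv <- prod(object@spacing) / 1000
  if (n > 0 && any(abs(df$volume_ml - df$voxels * vv) > 1e-9))
    return("volume_ml must equal voxel count times voxel volume")
  if (n > 0 && !all(df$source %in% c("auto", "added")))
    return("source must be 'auto' or 'added'")
  TRUE
})

#' MethodConfig: thresholds and numeric settings of the segmentation tool
#'
#' Holds every tunable constant of the segmentation workflow. Defaults
#' follow the EANM-style threshold family: fixed SUV thresholds of 2.5 and
#' 4.0 g/mL, an adaptive threshold at 41% of lesion SUVmax, a
#' background-corrected threshold at 50% of lesion SUVpeak, and a 3 mL
#' minimum lesion volume.
#'
#' @slot fixedThresholdSuv25 SUV25 threshold (g/mL), default 2.5.
#' @slot fixedThresholdSuv40 SUV40 threshold (g/mL), default 4.0.
#' @slot relativeFraction41Max fraction of SUVmax for 41MAX, default 0.41.
#' @slot relativeFractionA50P fraction of (SUVpeak - background) for A50P,
#'   default 0.50.
#' @slot minLesionVolume minimum lesion volume (mL), default 3.
#' @slot detectionThreshold SUV (g/mL) above which connected components
#'   become candidate lesions, default 2.5.
#' @slot peakSphereVolume SUVpeak sphere volume (mL), default 1
#'   (diameter ~ 12.4 mm).
#' @slot backgroundShell integer(2): inner and outer dilation (voxel
#'   steps, Chebyshev) bounding the local-background shell, default (2, 5).
#' @slot maxIterations iteration cap for the adaptive A50P loop, default 10.
#' @slot connectivity 3D neighbourhood for connected components: 26
#'   (faces + edges + corners, default) or 6 (faces only).
#' @slot searchRadius radius (mm) used to snap a seed click to the local
#'   SUV maximum when adding lesions, default 10.
#' @export
setClass("MethodConfig",
  representation(fixedThresholdSuv25 = "numeric",
                 fixedThresholdSuv40 = "numeric",
                 relativeFraction41Max = "numeric",
                 relativeFractionA50P = "numeric",
                 minLesionVolume = "numeric",
                 detectionThreshold = "numeric",
                 peakSphereVolume = "numeric",
                 backgroundShell = "numeric",
                 maxIterations = "numeric",
                 connectivity = "numeric",
                 searchRadius = "numeric"))

setValidity("MethodConfig", function(object) {
  if (object@fixedThresholdSuv25 <= 0 || object@fixedThresholdSuv40 <= 0 ||
      object@detectionThreshold <= 0)
    return("all SUV thresholds must be > 0")
  if (object@relativeFraction41Max <= 0 || object@relativeFraction41Max >= 1 ||
      object@relativeFractionA50P <= 0 || object@relativeFractionA50P >= 1)
    return("relative fractions must lie strictly between 0 and 1")
  if (object@minLesionVolume < 0)
    return("minLesionVolume must be >= 0")
  if (object@peakSphereVolume <= 0)
    return("peakSphereVolume must be > 0")
  if (length(object@backgroundShell) != 2L ||
      object@backgroundShell[1] < 1 ||
      object@backgroundShell[1] >= object@backgroundShell[2])
    return("backgroundShell must be (inner, outer) with 1 <= inner < outer")
  if (object@maxIterations < 1)
    return("maxIterations must be >= 1")
  if (!object@connectivity %in% c(6, 26))
    return("connectivity must be 6 or 26")
  if (object@searchRadius <= 0)
    return("searchRadius must be > 0 (mm)")
  TRUE
})

#' Construct a MethodConfig
#'
#' @param fixedThresholdSuv25,fixedThresholdSuv40 fixed SUV thresholds
#'   (g/mL).
#' @param relativeFraction41Max,relativeFractionA50P adaptive fractions.
#' @param minLesionVolume minimum lesion volume (mL).
#' @param detectionThreshold candidate-detection SUV (g/mL).
#' @param peakSphereVolume SUVpeak sphere volume (mL).
#' @param backgroundShell integer(2) inner/outer shell dilations (voxels).
#' @param maxIterations adaptive iteration cap.
#' @param connectivity 26 or 6.
#' @param searchRadius lesion-addition search radius (mm).
#' @return A [MethodConfig-class].
#' @examples
#' cfg <- methodConfig()
#' cfg@minLesionVolume
#' @export
methodConfig <- function(fixedThresholdSuv25 = 2.5,
                         fixedThresholdSuv40 = 4.0,
                         relativeFraction41Max = 0.41,
                         relativeFractionA50P = 0.50,
                         minLesionVolume = 3,
                         detectionThreshold = 2.5,
                         peakSphereVolume = 1,
                         backgroundShell = c(2, 5),
                         maxIterations = 10,
                         connectivity = 26,
                         searchRadius = 10) {
  new("MethodConfig",
      fixedThresholdSuv25 = fixedThresholdSuv25,
      fixedThresholdSuv40 = fixedThresholdSuv40,
      relativeFraction41Max = relativeFraction41Max,
      relativeFractionA50P = relativeFractionA50P,
      minLesionVolume = minLesionVolume,
      detectionThreshold = detectionThreshold,
      peakSphereVolume = peakSphereVolume,
      backgroundShell = as.numeric(backgroundShell),
      maxIterations = maxIterations,
      connectivity = connectivity,
      searchRadius = searchRadius)
}

#' SegmentationResult: output of a full segmentation run
#'
#' Bundles the final [LesionSet-class] of one segmentation method with the
#' raw per-base-method voxel masks (for the majority-vote methods), the
#' configuration used, and an audit log of operator actions (removals and
#' additions of lesions).
#'
#' @slot method one of "SUV25", "SUV40", "41MAX", "A50P", "MV2", "MV3".
#' @slot lesions the final [LesionSet-class].
#' @slot baseMasks named list of [BinaryMask-class] objects: the raw
#'   (pre-filter) voxel mask per base method that entered the result.
#' @slot audit data.frame log of workflow actions (action, seed
#'   coordinates, affected label, volume delta in mL, note).
#' @slot config the [MethodConfig-class] used.
#' @export
setClass("SegmentationResult",
  representation(method = "character", lesions = "LesionSet",
                 baseMasks = "list", audit = "data.frame",
                 config = "MethodConfig"))

setValidity("SegmentationResult", function(object) {
  if (!object@method %in% c("SUV25", "SUV40", "41MAX", "A50P", "MV2", "MV3"))
    return("unknown method name")
  TRUE
})

.emptyAudit <- function() {
  data.frame(action = character(), x_mm = numeric(), y_mm = numeric(),
             z_mm = numeric(), label = integer(), delta_ml = numeric(),
             note = character(), stringsAsFactors = FALSE)
}

setMethod("show", "SUVImage", function(object) {
  d <- dim(object@values)
  cat("SUVImage:", paste(d, collapse = " x "), "voxels, spacing",
      paste(format(object@spacing), collapse = " x "), "mm\n")
  cat("  SUV range:", format(min(object@values)), "-",
      format(max(object@values)), "g/mL\n")
})

setMethod("show", "BinaryMask", function(object) {
  cat("BinaryMask:", sum(object@membership), "of",
      length(object@membership), "voxels included (",
      format(sum(object@membership) * prod(object@spacing) / 1000,
             digits = 4), "mL )\n")
})

setMethod("show", "LesionSet", function(object) {
  cat("LesionSet:", nrow(object@lesions), "lesion(s), total",
      format(sum(object@lesions$volume_ml), digits = 4), "mL\n")
  if (nrow(object@lesions) > 0)
    print(utils::head(object@lesions, 10))
})

setMethod("show", "SegmentationResult", function(object) {
  cat("SegmentationResult [", object@method, "]: ",
      nrow(object@lesions@lesions), " lesion(s), MATV ",
      format(sum(object@lesions@lesions$volume_ml), digits = 4),
      " mL\n", sep = "")
  if (nrow(object@audit) > 0)
    cat("  ", nrow(object@audit), "workflow action(s) applied\n")
})
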