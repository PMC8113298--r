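#' Quantitative biomarkers of one lesion
#'
#' Computes the standard FDG-PET lesion biomarkers over exactly the
#' lesion's voxels: metabolically active tumour volume (MATV, mL),
#' SUVmax, SUVpeak (1 mL sphere, via [computeSUVpeak()]), SUVmean and
#' total lesion glycolysis (TLG = MATV x SUVmean, g).
#'
#' @param image an [SUVImage-class].
#' @param mask a non-empty [BinaryMask-class] on the same grid.
#' @param config a [MethodConfig-class] (peak sphere volume).
#' @return A one-row data.frame with columns `voxels`, `matv_ml`,
#'   `suvmax`, `suvpeak`, `suvmean`, `tlg_g`.
#' @export
measureLesion <- function(image, mask, config = methodConfig()) {
  stopifnot(is(image, "SUVImage"), is(mask, "BinaryMask"))
  .checkSameGrid(image, mask, "image and lesion mask")
  idx <- which(mask@membership)
  if (length(idx) == 0L) stop("cannot measure an empty lesion mask")
  vals <- image@values[idx]
  vv <- voxelVolumeMl(image)
  matvMl <- length(idx) * vv
  suvmean <- mean(vals)
  data.frame(voxels = length(idx), matv_ml = matvMl,
             suvmax = max(vals),
             suvpeak = computeSUVpeak(image, mask, config),
             suvmean = suvmean, tlg_g = matvMl * suvmean)
}

#' Per-lesion biomarker table for a segmentation
#'
#' @param image an [SUVImage-class].
#' @param x a [LesionSet-class] or [SegmentationResult-class].
#' @param config a [MethodConfig-class].
#' @return data.frame with one row per lesion: `lesion_id`, `voxels`,
#'   `volume_ml`, `suvmax`, `suvpeak`, `suvmean`, `tlg_g`, `source`.
#' @export
lesionMetricsTable <- function(image, x, config = methodConfig()) {
  ls <- if (is(x, "SegmentationResult")) x@lesions else x
  stopifnot(is(ls, "LesionSet"))
  df <- ls@lesions
  if (nrow(df) == 0L)
    return(data.frame(lesion_id = integer(), voxels = integer(),
                      volume_ml = numeric(), suvmax = numeric(),
                      suvpeak = numeric(), suvmean = numeric(),
                      tlg_g = numeric(), source = character(),
                      stringsAsFactors = FALSE))
  rows <- lapply(df$id, function(id) {
    m <- measureLesion(image, lesionMask(ls, id), config)
    data.frame(lesion_id = id, voxels = m$voxels, volume_ml = m$matv_ml,
               suvmax = m$suvmax, suvpeak = m$suvpeak,
               suvmean = m$suvmean, tlg_g = m$tlg_g,
               source = df$source[df$id == id],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Per-patient biomarker summary
#'
#' Sums the per-lesion metrics into patient-level values: total MATV
#' (mL), total TLG (g), patient SUVmax (max over lesions), patient
#' SUVpeak (max of per-lesion SUVpeak) and the lesion count. A result
#' with zero lesions is valid: MATV and TLG are 0 and the SUV fields are
#' reported as `NA` (absent, not 0).
#'
#' @param result a [SegmentationResult-class] (or [LesionSet-class]).
#' @param image the [SUVImage-class] it was computed on.
#' @param config a [MethodConfig-class].
#' @return A one-row data.frame: `method`, `n_lesions`, `matv_ml`,
#'   `tlg_g`, `suvmax`, `suvpeak`.
#' @export
summarizePatient <- function(result, image, config = methodConfig()) {
  method <- if (is(result, "SegmentationResult")) result@method
            else NA_character_
  tab <- lesionMetricsTable(image, result, config)
  if (nrow(tab) == 0L)
    return(data.frame(method = method, n_lesions = 0L, matv_ml = 0,
                      tlg_g = 0, suvmax = NA_real_, suvpeak = NA_real_,
                      stringsAsFactors = FALSE))
  data.frame(method = method, n_lesions = nrow(tab),
             matv_ml = sum(tab$volume_ml), tlg_g = sum(tab$tlg_g),
             suvmax = max(tab$suvmax), suvpeak = max(tab$suvpeak),
             stringsAsFactors = FALSE)
}
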