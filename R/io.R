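#' Read an SUV-calibrated PET volume from NIfTI
#'
#' The file must already hold SUV values (g/mL); no dose/weight/decay
#' calibration is performed. Non-finite or negative voxels are rejected
#' with an error rather than clamped, to protect downstream
#' quantification.
#'
#' @param path NIfTI file (.nii or .nii.gz).
#' @return An [SUVImage-class].
#' @export
readSUVImage <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) == 4L && dim(arr)[4] == 1L)
    arr <- array(arr, dim(arr)[1:3])
  if (length(dim(arr)) != 3L)
    stop("expected a 3D volume, got dimensions ",
         paste(dim(arr), collapse = "x"))
  if (any(!is.finite(arr)))
    stop("volume contains non-finite SUV values; refusing to load")
  if (any(arr < 0))
    stop("volume contains negative SUV values; refusing to load")
  sp <- RNifti::pixdim(img)[1:3]
  orig <- as.numeric(RNifti::voxelToWorld(c(1, 1, 1), img))
  SUVImage(array(as.numeric(arr), dim(arr)), spacing = sp, origin = orig)
}

.asNiftiWithGrid <- function(arr, spacing, origin) {
  im <- RNifti::asNifti(arr)
  RNifti::pixdim(im) <- spacing
  xf <- diag(c(spacing, 1))
  xf[1:3, 4] <- origin
  RNifti::`qform<-`(im, structure(xf, code = 2L))
}

#' Write an SUVImage to NIfTI
#'
#' @param image an [SUVImage-class].
#' @param path output path (.nii or .nii.gz).
#' @return `path`, invisibly.
#' @export
writeSUVImage <- function(image, path) {
  stopifnot(is(image, "SUVImage"))
  im <- .asNiftiWithGrid(image@values, image@spacing, image@origin)
  RNifti::writeNifti(im, path)
  invisible(path)
}

#' Read a binary VOI mask from NIfTI
#'
#' Any strictly positive voxel is treated as included.
#'
#' @param path NIfTI file on the same grid as the parent image.
#' @return A [BinaryMask-class].
#' @export
readMaskNifti <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) == 4L && dim(arr)[4] == 1L)
    arr <- array(arr, dim(arr)[1:3])
  sp <- RNifti::pixdim(img)[1:3]
  orig <- as.numeric(RNifti::voxelToWorld(c(1, 1, 1), img))
  new("BinaryMask", membership = array(arr > 0, dim(arr)),
      spacing = as.numeric(sp), origin = orig)
}

#' Write a binary mask to NIfTI (unsigned 8-bit)
#'
#' @param mask a [BinaryMask-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeMaskNifti <- function(mask, path) {
  stopifnot(is(mask, "BinaryMask"))
  im <- .asNiftiWithGrid(array(as.integer(mask@membership),
                               dim(mask@membership)),
                         mask@spacing, mask@origin)
  RNifti::writeNifti(im, path, datatype = "uint8")
  invisible(path)
}

#' Write a lesion label map to NIfTI (unsigned 16-bit)
#'
#' @param lesions a [LesionSet-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeLesionLabels <- function(lesions, path) {
  stopifnot(is(lesions, "LesionSet"))
  im <- .asNiftiWithGrid(lesions@labels, lesions@spacing, lesions@origin)
  RNifti::writeNifti(im, path, datatype = "uint16")
  invisible(path)
}

#' Read a lesion label map from NIfTI
#'
#' Labels are recompacted to consecutive ids; provenance is set to
#' "auto" (NIfTI carries no provenance).
#'
#' @param path NIfTI label map.
#' @return A [LesionSet-class].
#' @export
readLesionLabels <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) == 4L && dim(arr)[4] == 1L)
    arr <- array(arr, dim(arr)[1:3])
  sp <- RNifti::pixdim(img)[1:3]
  orig <- as.numeric(RNifti::voxelToWorld(c(1, 1, 1), img))
  .lesionSetFromLabels(array(as.integer(round(arr)), dim(arr)),
                       as.numeric(sp), orig)
}

#' Read a seed-point workflow script from CSV
#'
#' The CSV replays an operator's mouse clicks headlessly. Expected header:
#' `x_mm,y_mm,z_mm[,role]` with role in {remove, add}; a missing role
#' column defaults to "remove".
#'
#' @param path CSV file.
#' @return data.frame with columns `x_mm`, `y_mm`, `z_mm`, `role`.
#' @export
readSeedScript <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("x_mm", "y_mm", "z_mm")
  if (!all(need %in% names(df)))
    stop("seed CSV must have columns x_mm, y_mm, z_mm (got: ",
         paste(names(df), collapse = ", "), ")")
  if (is.null(df$role)) df$role <- "remove"
  bad <- !df$role %in% c("remove", "add")
  if (any(bad))
    stop("seed role must be 'remove' or 'add'; offending rows: ",
         paste(which(bad), collapse = ", "))
  df[, c("x_mm", "y_mm", "z_mm", "role")]
}

#' Read a MethodConfig from JSON
#'
#' Field names mirror the [MethodConfig-class] slots; absent fields keep
#' their defaults.
#'
#' @param path JSON file.
#' @return A [MethodConfig-class].
#' @export
readMethodConfig <- function(path) {
  vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(methodConfig))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown config fields: ", paste(unknown, collapse = ", "))
  do.call(methodConfig, vals)
}
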