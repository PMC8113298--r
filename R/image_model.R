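#' @useDynLib matvseg, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

# grid-compatibility guard shared by all two-object operations
.checkSameGrid <- function(a, b, what = "objects") {
  da <- if (is(a, "SUVImage")) dim(a@values) else
        if (is(a, "LesionSet")) dim(a@labels) else dim(a@membership)
  db <- if (is(b, "SUVImage")) dim(b@values) else
        if (is(b, "LesionSet")) dim(b@labels) else dim(b@membership)
  if (!identical(da, db) ||
      any(abs(a@spacing - b@spacing) > 1e-9) ||
      any(abs(a@origin - b@origin) > 1e-6))
    stop("grid mismatch between ", what, ": shapes ",
         paste(da, collapse = "x"), " vs ", paste(db, collapse = "x"),
         ", spacing (", paste(a@spacing, collapse = ", "), ") vs (",
         paste(b@spacing, collapse = ", "), ")")
  invisible(TRUE)
}

#' Volume of one voxel in millilitres
#'
#' @param image an [SUVImage-class] (or any object carrying `gridSpacing`).
#' @return Voxel volume in mL: `prod(spacing) / 1000`.
#' @examples
#' voxelVolumeMl(SUVImage(array(0, c(2, 2, 2)), spacing = c(3.2, 3.2, 2)))
#' @export
setGeneric("voxelVolumeMl", function(image) standardGeneric("voxelVolumeMl"))

#' @rdname voxelVolumeMl
#' @export
setMethod("voxelVolumeMl", "SUVImage",
          function(image) prod(image@spacing) / 1000)

#' @rdname voxelVolumeMl
#' @export
setMethod("voxelVolumeMl", "BinaryMask",
          function(image) prod(image@spacing) / 1000)

#' @rdname voxelVolumeMl
#' @export
setMethod("voxelVolumeMl", "LesionSet",
          function(image) prod(image@spacing) / 1000)

#' Map a world-coordinate seed point to a voxel index
#'
#' Converts a point in world millimetres to the nearest voxel-center index
#' (1-based) under the package's convention
#' `world = origin + (index - 1) * spacing`.
#'
#' @param image an [SUVImage-class], [BinaryMask-class] or
#'   [LesionSet-class] supplying the grid.
#' @param seed numeric(3) world coordinates (x, y, z) in mm.
#' @return integer(3) voxel index.
#' @examples
#' img <- SUVImage(array(0, c(5, 5, 5)), spacing = c(2, 2, 2))
#' worldToVoxel(img, c(2.9, 0, 0))  # -> (2, 1, 1)
#' @export
worldToVoxel <- function(image, seed) {
  stopifnot(length(seed) == 3L, all(is.finite(seed)))
  d <- if (is(image, "SUVImage")) dim(image@values) else
       if (is(image, "LesionSet")) dim(image@labels) else
       dim(image@membership)
  idx <- as.integer(round((seed - image@origin) / image@spacing)) + 1L
  if (any(idx < 1L) || any(idx > d)) {
    lo <- image@origin - image@spacing / 2
    hi <- image@origin + (d - 0.5) * image@spacing
    stop("seed (", paste(format(seed), collapse = ", "),
         ") mm falls outside the image grid; bounds are [",
         paste(format(lo), collapse = ", "), "] to [",
         paste(format(hi), collapse = ", "), "] mm")
  }
  idx
}

#' World coordinates of a voxel center
#'
#' Inverse of [worldToVoxel()].
#' @param image object carrying grid metadata.
#' @param idx integer(3) 1-based voxel index.
#' @return numeric(3) world mm.
#' @export
voxelToWorldMm <- function(image, idx) {
  image@origin + (as.numeric(idx) - 1) * image@spacing
}

# Build a LesionSet from a raw (arbitrarily numbered) label array.
# Relabels deterministically: descending voxel count, ties broken by the
# smallest linear voxel index. `source` maps raw label -> provenance.
.lesionSetFromLabels <- function(rawLabels, spacing, origin, source = NULL) {
  d <- dim(rawLabels)
  ids <- sort(unique(rawLabels[rawLabels > 0L]))
  if (length(ids) == 0L) {
    return(new("LesionSet", labels = array(0L, d),
               lesions = data.frame(id = integer(), voxels = integer(),
                                    volume_ml = numeric(),
                                    source = character(),
                                    stringsAsFactors = FALSE),
               spacing = as.numeric(spacing), origin = as.numeric(origin)))
  }
  pos <- which(rawLabels > 0L)
  lab <- rawLabels[pos]
  counts <- tabulate(lab, nbins = max(ids))[ids]
  minidx <- vapply(split(pos, factor(lab, levels = ids)), min, numeric(1))
  ord <- order(-counts, minidx)
  newOf <- integer(max(ids))
  newOf[ids[ord]] <- seq_along(ids)
  out <- array(0L, d)
  out[pos] <- newOf[lab]
  vv <- prod(spacing) / 1000
  src <- if (is.null(source)) rep("auto", length(ids)) else source[ids]
  new("LesionSet", labels = out,
      lesions = data.frame(id = seq_along(ids),
                           voxels = as.integer(counts[ord]),
                           volume_ml = counts[ord] * vv,
                           source = src[ord],
                           stringsAsFactors = FALSE),
      spacing = as.numeric(spacing), origin = as.numeric(origin))
}

#' Label connected components of a binary mask
#'
#' Groups the `TRUE` voxels of a mask into maximal connected components
#' under a 26- (default) or 6-neighbourhood and returns them as a
#' [LesionSet-class]. Label order is deterministic: descending volume,
#' ties broken by the smallest linear voxel index. An empty mask yields a
#' LesionSet with zero lesions.
#'
#' @param mask a [BinaryMask-class].
#' @param connectivity 26 (faces, edges and corners) or 6 (faces only).
#' @return A [LesionSet-class] with `source = "auto"` for every component.
#' @examples
#' m <- array(FALSE, c(5, 5, 5)); m[1, 1, 1] <- TRUE; m[5, 5, 5] <- TRUE
#' connectedComponents(BinaryMask(m))
#' @export
connectedComponents <- function(mask, connectivity = 26) {
  stopifnot(is(mask, "BinaryMask"), connectivity %in% c(6, 26))
  m <- mask@membership
  raw <- array(.labelComponents(as.vector(m), dim(m),
                                as.integer(connectivity)), dim(m))
  .lesionSetFromLabels(raw, mask@spacing, mask@origin)
}

#' Extract one lesion of a LesionSet as a BinaryMask
#'
#' @param lesions a [LesionSet-class].
#' @param id lesion id (1-based label).
#' @return A [BinaryMask-class] covering exactly that lesion's voxels.
#' @export
lesionMask <- function(lesions, id) {
  stopifnot(is(lesions, "LesionSet"))
  if (!id %in% lesions@lesions$id)
    stop("no lesion with id ", id, " in this LesionSet")
  new("BinaryMask", membership = lesions@labels == as.integer(id),
      spacing = lesions@spacing, origin = lesions@origin)
}

#' Collapse a LesionSet to a single BinaryMask
#'
#' @param lesions a [LesionSet-class].
#' @return A [BinaryMask-class] of all labeled voxels.
#' @export
lesionUnionMask <- function(lesions) {
  stopifnot(is(lesions, "LesionSet"))
  new("BinaryMask", membership = lesions@labels > 0L,
      spacing = lesions@spacing, origin = lesions@origin)
}

# --- internal raw-array helpers (operate on logical 3D arrays) ---------

# one Chebyshev dilation step (26-neighbourhood OR of shifts)
.dilateOnce <- function(a) {
  d <- dim(a)
  out <- a
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    if (dx == 0 && dy == 0 && dz == 0) next
    sx <- max(1, 1 + dx):min(d[1], d[1] + dx)
    sy <- max(1, 1 + dy):min(d[2], d[2] + dy)
    sz <- max(1, 1 + dz):min(d[3], d[3] + dz)
    out[sx, sy, sz] <- out[sx, sy, sz] | a[sx - dx, sy - dy, sz - dz]
  }
  out
}

# dilate a logical array by `steps` voxel steps (Chebyshev ball), working
# on a cropped bounding box for speed
.dilateArray <- function(a, steps) {
  if (steps == 0 || !any(a)) return(a)
  d <- dim(a)
  w <- which(a, arr.ind = TRUE)
  lo <- pmax(apply(w, 2, min) - steps, 1)
  hi <- pmin(apply(w, 2, max) + steps, d)
  sub <- a[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  for (s in seq_len(steps)) sub <- .dilateOnce(sub)
  out <- a
  out[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- sub
  out
}

# bounding box of TRUE voxels expanded by `pad` voxels, as index ranges
.expandedBBox <- function(a, pad) {
  d <- dim(a)
  w <- which(a, arr.ind = TRUE)
  lo <- pmax(apply(w, 2, min) - pad, 1)
  hi <- pmin(apply(w, 2, max) + pad, d)
  list(x = lo[1]:hi[1], y = lo[2]:hi[2], z = lo[3]:hi[3])
}

# logical array that is TRUE inside an expanded bounding box
.bboxMask <- function(a, pad) {
  bb <- .expandedBBox(a, pad)
  out <- array(FALSE, dim(a))
  out[bb$x, bb$y, bb$z] <- TRUE
  out
}

# connected component (raw array in, raw array out) containing a voxel
.componentContaining <- function(a, idx, connectivity) {
  if (!a[idx[1], idx[2], idx[3]]) return(array(FALSE, dim(a)))
  raw <- array(.labelComponents(as.vector(a), dim(a),
                                as.integer(connectivity)), dim(a))
  raw == raw[idx[1], idx[2], idx[3]]
}
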