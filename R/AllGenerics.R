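#' Accessors for the core volumetric classes
#'
#' Small accessor generics so user code never touches slots directly:
#' `suvValues()` returns the SUV array of an image, `maskArray()` the
#' logical grid of a mask, `lesionLabels()` / `lesionTable()` the label
#' grid and per-lesion table of a [LesionSet-class] or
#' [SegmentationResult-class], `gridSpacing()` / `gridOrigin()` the grid
#' metadata of any of them, and `matv()` the total metabolically active
#' tumour volume (mL).
#'
#' @param x an object of one of the package's classes.
#' @return See the individual descriptions above.
#' @examples
#' img <- SUVImage(array(1, c(3, 3, 3)))
#' gridSpacing(img)
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("suvValues", function(x) standardGeneric("suvValues"))

#' @rdname accessors
#' @export
setMethod("suvValues", "SUVImage", function(x) x@values)

#' @rdname accessors
#' @export
setGeneric("maskArray", function(x) standardGeneric("maskArray"))

#' @rdname accessors
#' @export
setMethod("maskArray", "BinaryMask", function(x) x@membership)

#' @rdname accessors
#' @export
setGeneric("lesionLabels", function(x) standardGeneric("lesionLabels"))

#' @rdname accessors
#' @export
setMethod("lesionLabels", "LesionSet", function(x) x@labels)

#' @rdname accessors
#' @export
setMethod("lesionLabels", "SegmentationResult",
          function(x) x@lesions@labels)

#' @rdname accessors
#' @export
setGeneric("lesionTable", function(x) standardGeneric("lesionTable"))

#' @rdname accessors
#' @export
setMethod("lesionTable", "LesionSet", function(x) x@lesions)

#' @rdname accessors
#' @export
setMethod("lesionTable", "SegmentationResult", function(x) x@lesions@lesions)

#' @rdname accessors
#' @export
setGeneric("gridSpacing", function(x) standardGeneric("gridSpacing"))

#' @rdname accessors
#' @export
setMethod("gridSpacing", "SUVImage", function(x) x@spacing)

#' @rdname accessors
#' @export
setMethod("gridSpacing", "BinaryMask", function(x) x@spacing)

#' @rdname accessors
#' @export
setMethod("gridSpacing", "LesionSet", function(x) x@spacing)

#' @rdname accessors
#' @export
setGeneric("gridOrigin", function(x) standardGeneric("gridOrigin"))

#' @rdname accessors
#' @export
setMethod("gridOrigin", "SUVImage", function(x) x@origin)

#' @rdname accessors
#' @export
setMethod("gridOrigin", "BinaryMask", function(x) x@origin)

#' @rdname accessors
#' @export
setMethod("gridOrigin", "LesionSet", function(x) x@origin)

#' @rdname accessors
#' @export
setGeneric("matv", function(x) standardGeneric("matv"))

#' @rdname accessors
#' @export
setMethod("matv", "LesionSet", function(x) sum(x@lesions$volume_ml))

#' @rdname accessors
#' @export
setMethod("matv", "SegmentationResult", function(x) matv(x@lesions))

#' @rdname accessors
#' @export
setGeneric("segMethod", function(x) standardGeneric("segMethod"))

#' @rdname accessors
#' @export
setMethod("segMethod", "SegmentationResult", function(x) x@method)

#' @rdname accessors
#' @export
setGeneric("auditLog", function(x) standardGeneric("auditLog"))

#' @rdname accessors
#' @export
setMethod("auditLog", "SegmentationResult", function(x) x@audit)
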