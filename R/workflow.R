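#' Remove the lesion under a seed click
#'
#' Deletes the lesion whose label contains the seed voxel; used to strip
#' regions of physiologically high uptake (bladder, kidneys, myocardium,
#' brain) from an automatic segmentation with a single replayable
#' "click". A seed landing on background leaves the result unchanged
#' with a warning.
#'
#' @param result a [SegmentationResult-class].
#' @param seed numeric(3) world coordinates (mm).
#' @return The updated [SegmentationResult-class]; the audit log gains
#'   one row.
#' @export
removeComponent <- function(result, seed) {
  stopifnot(is(result, "SegmentationResult"))
  ls <- result@lesions
  vox <- worldToVoxel(ls, seed)
  lab <- ls@labels[vox[1], vox[2], vox[3]]
  if (lab == 0L) {
    warning("seed (", paste(format(seed), collapse = ", "),
            ") mm lies on background; nothing removed")
    result@audit <- rbind(result@audit, data.frame(
      action = "remove", x_mm = seed[1], y_mm = seed[2], z_mm = seed[3],
      label = 0L, delta_ml = 0, note = "seed on background",
      stringsAsFactors = FALSE))
    return(result)
  }
  df <- ls@lesions
  vol <- df$volume_ml[df$id == lab]
  raw <- ls@labels
  raw[raw == lab] <- 0L
  src <- character(max(df$id))
  src[df$id] <- df$source
  result@lesions <- .lesionSetFromLabels(raw, ls@spacing, ls@origin,
                                         source = src)
  result@audit <- rbind(result@audit, data.frame(
    action = "remove", x_mm = seed[1], y_mm = seed[2], z_mm = seed[3],
    label = as.integer(lab), delta_ml = -vol, note = "",
    stringsAsFactors = FALSE))
  result
}

# voxels (linear indices) whose centers lie within `radius` mm of voxel v
.voxelsWithinRadius <- function(d, spacing, v, radius) {
  rng <- floor(radius / spacing)
  off <- expand.grid(di = -rng[1]:rng[1], dj = -rng[2]:rng[2],
                     dk = -rng[3]:rng[3])
  d2 <- (off$di * spacing[1])^2 + (off$dj * spacing[2])^2 +
        (off$dk * spacing[3])^2
  off <- off[d2 <= radius^2, , drop = FALSE]
  ni <- v[1] + off$di; nj <- v[2] + off$dj; nk <- v[3] + off$dk
  ok <- ni >= 1L & ni <= d[1] & nj >= 1L & nj <= d[2] &
        nk >= 1L & nk <= d[3]
  sort((nk[ok] - 1L) * (d[1] * d[2]) + (nj[ok] - 1L) * d[1] + ni[ok])
}

#' Add a missed lesion at a seed click
#'
#' Snaps the seed to the local SUV maximum within `searchRadius`
#' (default 10 mm), then delineates a new lesion there by the result's
#' own method rule: fixed methods take the connected component above the
#' fixed threshold, adaptive methods run one adaptive pass on the
#' detection-threshold component, and majority-vote methods vote over
#' the four local masks. The minimum-volume filter is NOT applied (added
#' lesions are precisely those the automatic pass missed, e.g. lesions
#' < 3 mL); the lesion is flagged `source = "added"`. Voxels already
#' labeled are not double-counted, so re-adding a segmented lesion is a
#' no-op.
#'
#' @param result a [SegmentationResult-class].
#' @param image the [SUVImage-class] the result was computed on.
#' @param seed numeric(3) world coordinates (mm).
#' @param config a [MethodConfig-class]; defaults to the result's own.
#' @return The updated [SegmentationResult-class].
#' @export
addLesion <- function(result, image, seed, config = result@config) {
  stopifnot(is(result, "SegmentationResult"), is(image, "SUVImage"))
  v <- worldToVoxel(image, seed)
  d <- dim(image@values)
  near <- .voxelsWithinRadius(d, image@spacing, v, config@searchRadius)
  hot <- near[image@values[near] >= config@detectionThreshold]
  if (length(hot) == 0L)
    stop("no addable lesion at seed (", paste(format(seed), collapse = ", "),
         ") mm: no voxel above the detection threshold (",
         config@detectionThreshold, " g/mL) within ", config@searchRadius,
         " mm")
  peakLin <- hot[which.max(image@values[hot])]
  peak <- arrayInd(peakLin, d)[1, ]
  detArr <- image@values >= config@detectionThreshold

  localFixed <- function(thr) {
    a <- image@values >= thr
    .componentContaining(a, peak, config@connectivity)
  }
  localAdaptive <- function(fun) {
    cand <- new("BinaryMask",
                membership = .componentContaining(detArr, peak,
                                                  config@connectivity),
                spacing = image@spacing, origin = image@origin)
    fun(cand)@membership
  }
  buildLocal <- function(method) {
    switch(method,
      SUV25 = localFixed(config@fixedThresholdSuv25),
      SUV40 = localFixed(config@fixedThresholdSuv40),
      `41MAX` = localAdaptive(function(cm)
        segment41Max(image, cm, config)),
      A50P = localAdaptive(function(cm)
        segmentA50P(image, cm, config,
                    exclude = new("BinaryMask", membership = detArr,
                                  spacing = image@spacing,
                                  origin = image@origin))))
  }
  localArr <- if (result@method %in% c("MV2", "MV3")) {
    k <- if (result@method == "MV2") 2L else 3L
    arrays <- lapply(c("SUV25", "SUV40", "41MAX", "A50P"), buildLocal)
    voted <- Reduce(`+`, lapply(arrays, function(a)
      array(as.integer(a), dim(a)))) >= k
    .componentContaining(voted, peak, config@connectivity)
  } else buildLocal(result@method)

  note <- ""
  ls <- result@lesions
  newVox <- localArr & ls@labels == 0L
  if (!any(localArr)) {
    warning("the ", result@method, " rule produced no voxels at the seed; ",
            "nothing added")
    note <- "method rule yielded empty lesion"
  } else if (!any(newVox)) {
    note <- "lesion already segmented"
  }
  if (!any(newVox)) {
    result@audit <- rbind(result@audit, data.frame(
      action = "add", x_mm = seed[1], y_mm = seed[2], z_mm = seed[3],
      label = 0L, delta_ml = 0, note = note, stringsAsFactors = FALSE))
    return(result)
  }
  df <- ls@lesions
  newId <- if (nrow(df) == 0L) 1L else max(df$id) + 1L
  raw <- ls@labels
  raw[newVox] <- newId
  src <- character(newId)
  if (nrow(df) > 0L) src[df$id] <- df$source
  src[newId] <- "added"
  result@lesions <- .lesionSetFromLabels(raw, ls@spacing, ls@origin,
                                         source = src)
  delta <- sum(newVox) * prod(ls@spacing) / 1000
  result@audit <- rbind(result@audit, data.frame(
    action = "add", x_mm = seed[1], y_mm = seed[2], z_mm = seed[3],
    label = as.integer(newId), delta_ml = delta, note = note,
    stringsAsFactors = FALSE))
  result
}

#' Replay a workflow script of seed clicks
#'
#' Applies an ordered list of remove/add actions (the headless
#' equivalent of the operator's mouse clicks), producing the
#' fully corrected total VOI. The audit log records every action with
#' its seed, the affected label and the MATV delta; an action that
#' errors aborts the replay with its index reported.
#'
#' @param result a [SegmentationResult-class].
#' @param image the [SUVImage-class] the result was computed on.
#' @param script data.frame with columns `x_mm`, `y_mm`, `z_mm`, `role`
#'   (role in "remove"/"add"), e.g. from [readSeedScript()].
#' @param config a [MethodConfig-class]; defaults to the result's own.
#' @return The updated [SegmentationResult-class].
#' @export
applyScript <- function(result, image, script, config = result@config) {
  stopifnot(is.data.frame(script),
            all(c("x_mm", "y_mm", "z_mm", "role") %in% names(script)))
  for (i in seq_len(nrow(script))) {
    seed <- as.numeric(script[i, c("x_mm", "y_mm", "z_mm")])
    result <- tryCatch(
      if (script$role[i] == "remove") removeComponent(result, seed)
      else addLesion(result, image, seed, config),
      error = function(e)
        stop("workflow script action ", i, " (", script$role[i],
             ") failed: ", conditionMessage(e), call. = FALSE))
  }
  result
}
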