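#' ZStackField: one high-content imaging field
#'
#' Container for a single field of view as acquired on a high-content
#' imager: a single nuclear-stain (DAPI) plane plus a spot-channel (GFP)
#' z-stack, with pixel and z calibration. Images are stored as plain
#' numeric matrices in arbitrary intensity units; the stack is a
#' height x width x planes array ordered by z.
#'
#' @slot nuclearPlane numeric matrix, the nuclear-stain plane.
#' @slot spotStack 3-d numeric array; `spotStack[, , i]` is plane `i`.
#' @slot pixelSizeUm positive scalar, lateral pixel size in micrometres.
#' @slot zSpacingUm positive scalar, spacing between planes in micrometres.
#'
#' @seealso [generateField()], [analyzeField()]
#' @export
setClass("ZStackField",
  representation(
    nuclearPlane = "matrix",
    spotStack = "array",
    pixelSizeUm = "numeric",
    zSpacingUm = "numeric"
  )
)

setValidity("ZStackField", function(object) {
  msg <- character()
  d <- dim(object@spotStack)
  if (length(d) != 3L)
    msg <- c(msg, "spotStack must be a 3-d array (rows x cols x planes)")
  else if (!identical(dim(object@nuclearPlane), d[1:2]))
    msg <- c(msg, "nuclearPlane and spotStack plane dimensions differ")
  if (length(object@pixelSizeUm) != 1L || object@pixelSizeUm <= 0)
    msg <- c(msg, "pixelSizeUm must be a positive scalar")
  if (length(object@zSpacingUm) != 1L || object@zSpacingUm <= 0)
    msg <- c(msg, "zSpacingUm must be a positive scalar")
  if (length(msg)) msg else TRUE
})

#' Construct a ZStackField
#'
#' @param nuclearPlane numeric matrix.
#' @param spotStack 3-d numeric array with the same first two dimensions.
#' @param pixelSizeUm lateral calibration, um/px.
#' @param zSpacingUm plane spacing, um.
#' @return A [ZStackField-class] object.
#' @export
ZStackField <- function(nuclearPlane, spotStack, pixelSizeUm, zSpacingUm) {
  new("ZStackField",
    nuclearPlane = nuclearPlane, spotStack = spotStack,
    pixelSizeUm = as.numeric(pixelSizeUm), zSpacingUm = as.numeric(zSpacingUm))
}

#' FieldGroundTruth: generator ground truth for one field
#'
#' Records the true nuclei (ellipses) and nucleoli (Gaussian spots) that a
#' synthetic field was rendered from, for validating segmentation and
#' detection. Coordinates are continuous pixel positions in R's 1-based
#' convention (`x` = column, `y` = row); on JSON export they are shifted
#' to the 0-based convention documented in [writeField()].
#'
#' @slot nuclei data.frame with columns `nucleus`, `x`, `y`,
#'   `semiMajorPx`, `semiMinorPx`, `thetaRad`.
#' @slot nucleoli data.frame with columns `nucleus`, `x`, `y`,
#'   `radiusPx`, `amplitude`.
#' @slot focalPlaneIndex integer, 1-based index of the in-focus plane.
#' @export
setClass("FieldGroundTruth",
  representation(
    nuclei = "data.frame",
    nucleoli = "data.frame",
    focalPlaneIndex = "integer"
  )
)

setValidity("FieldGroundTruth", function(object) {
  msg <- character()
  need_n <- c("nucleus", "x", "y", "semiMajorPx", "semiMinorPx", "thetaRad")
  need_s <- c("nucleus", "x", "y", "radiusPx", "amplitude")
  if (!all(need_n %in% names(object@nuclei)))
    msg <- c(msg, "nuclei data.frame is missing required columns")
  if (!all(need_s %in% names(object@nucleoli)))
    msg <- c(msg, "nucleoli data.frame is missing required columns")
  if (length(object@focalPlaneIndex) != 1L || object@focalPlaneIndex < 1L)
    msg <- c(msg, "focalPlaneIndex must be a single index >= 1")
  if (nrow(object@nucleoli) &&
      !all(object@nucleoli$nucleus %in% object@nuclei$nucleus))
    msg <- c(msg, "every nucleolus must reference an existing nucleus")
  if (length(msg)) msg else TRUE
})

#' LabelMap: integer-labelled segmentation mask
#'
#' A segmentation result shared by the nuclei and nucleolus stages:
#' an integer matrix in which 0 is background and objects carry the
#' consecutive labels 1..L.
#'
#' @slot map integer matrix; 0 = background, labels consecutive from 1.
#' @export
setClass("LabelMap", representation(map = "matrix"))

setValidity("LabelMap", function(object) {
  m <- object@map
  if (!is.numeric(m)) return("map must be a numeric/integer matrix")
  if (any(m < 0)) return("labels must be non-negative")
  labs <- sort(unique(as.integer(m[m > 0])))
  L <- length(labs)
  if (L > 0 && !identical(labs, seq_len(L)))
    return("labels must be consecutive 1..L")
  TRUE
})

#' Construct a LabelMap
#'
#' @param map integer matrix, 0 = background, labels consecutive 1..L.
#' @return A [LabelMap-class] object.
#' @export
LabelMap <- function(map) {
  storage.mode(map) <- "integer"
  new("LabelMap", map = map)
}

# ---- accessors -------------------------------------------------------------

#' @describeIn ZStackField-class the nuclear-stain plane matrix.
#' @param object a `ZStackField`.
#' @export
setGeneric("nuclearPlane", function(object) standardGeneric("nuclearPlane"))
#' @export
setMethod("nuclearPlane", "ZStackField", function(object) object@nuclearPlane)

#' @describeIn ZStackField-class the spot-channel z-stack array.
#' @export
setGeneric("spotStack", function(object) standardGeneric("spotStack"))
#' @export
setMethod("spotStack", "ZStackField", function(object) object@spotStack)

#' @describeIn ZStackField-class lateral pixel size, um/px.
#' @export
setGeneric("pixelSize", function(object) standardGeneric("pixelSize"))
#' @export
setMethod("pixelSize", "ZStackField", function(object) object@pixelSizeUm)

#' @describeIn ZStackField-class z spacing, um.
#' @export
setGeneric("zSpacing", function(object) standardGeneric("zSpacing"))
#' @export
setMethod("zSpacing", "ZStackField", function(object) object@zSpacingUm)

#' @describeIn LabelMap-class the underlying integer matrix.
#' @param object a `LabelMap`.
#' @export
setGeneric("labelMatrix", function(object) standardGeneric("labelMatrix"))
#' @export
setMethod("labelMatrix", "LabelMap", function(object) object@map)

#' @describeIn LabelMap-class number of labelled objects.
#' @export
setGeneric("nLabels", function(object) standardGeneric("nLabels"))
#' @export
setMethod("nLabels", "LabelMap", function(object) max(object@map, 0L))

#' @describeIn FieldGroundTruth-class the true nuclei table.
#' @param object a `FieldGroundTruth`.
#' @export
setGeneric("truthNuclei", function(object) standardGeneric("truthNuclei"))
#' @export
setMethod("truthNuclei", "FieldGroundTruth", function(object) object@nuclei)

#' @describeIn FieldGroundTruth-class the true nucleoli table.
#' @export
setGeneric("truthNucleoli", function(object) standardGeneric("truthNucleoli"))
#' @export
setMethod("truthNucleoli", "FieldGroundTruth", function(object) object@nucleoli)

#' @describeIn FieldGroundTruth-class 1-based index of the in-focus plane.
#' @export
setGeneric("focalPlane", function(object) standardGeneric("focalPlane"))
#' @export
setMethod("focalPlane", "FieldGroundTruth", function(object) object@focalPlaneIndex)

# ---- show methods ----------------------------------------------------------

setMethod("show", "ZStackField", function(object) {
  d <- dim(object@spotStack)
  cat("ZStackField:", d[1], "x", d[2], "px,", d[3], "planes\n")
  cat("  pixel size:", object@pixelSizeUm, "um/px; z spacing:",
      object@zSpacingUm, "um\n")
  cat("  nuclear plane intensity range: [",
      signif(min(object@nuclearPlane), 4), ", ",
      signif(max(object@nuclearPlane), 4), "]\n", sep = "")
})

setMethod("show", "FieldGroundTruth", function(object) {
  cat("FieldGroundTruth:", nrow(object@nuclei), "nuclei,",
      nrow(object@nucleoli), "nucleoli; focal plane",
      object@focalPlaneIndex, "\n")
})

setMethod("show", "LabelMap", function(object) {
  cat("LabelMap:", nrow(object@map), "x", ncol(object@map), "px,",
      nLabels(object), "objects\n")
})
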