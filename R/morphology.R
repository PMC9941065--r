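# R-level surface over the compiled morphological primitives. These are
# the pieces of the spot detector that general-purpose image packages do
# not provide in marker-controlled form.

.as_matrix <- function(x) {
  if (is(x, "Image")) x <- EBImage::imageData(x)
  if (!is.matrix(x)) x <- as.matrix(x)
  storage.mode(x) <- "double"
  x
}

#' Grayscale reconstruction by dilation
#'
#' Iteratively dilates `marker` while constraining it under `mask` until
#' stability (Vincent's hybrid raster/queue algorithm, 8-connectivity).
#' The workhorse behind [hMaxima()] and [regionalMaxima()].
#'
#' @param marker numeric matrix; clamped to `<= mask` elementwise.
#' @param mask numeric matrix of identical dimensions.
#' @return Reconstructed numeric matrix.
#' @export
reconstructByDilation <- function(marker, mask) {
  cpp_reconstruct_dilation(.as_matrix(marker), .as_matrix(mask))
}

#' H-maxima transform
#'
#' Suppresses all intensity maxima of depth less than `h`:
#' `reconstructByDilation(img - h, img)`. Its regional maxima are the
#' candidate spots of depth at least `h`.
#'
#' @param img numeric matrix.
#' @param h positive depth, in the image's intensity units.
#' @return Transformed matrix.
#' @export
hMaxima <- function(img, h) {
  if (!is.numeric(h) || length(h) != 1L || h <= 0)
    stop("h must be a single positive number")
  img <- .as_matrix(img)
  cpp_reconstruct_dilation(img - h, img)
}

#' Regional maxima
#'
#' Connected plateaus with no strictly greater 8-neighbour. Exact
#' (plateau flood fill), no epsilon.
#'
#' @param img numeric matrix.
#' @return Logical matrix marking maxima pixels.
#' @export
regionalMaxima <- function(img) {
  cpp_regional_maxima(.as_matrix(img))
}

#' Label connected components
#'
#' 8-connected components of a logical mask, labelled consecutively.
#'
#' @param mask logical matrix.
#' @return Integer matrix of labels (0 = background).
#' @export
labelConnected <- function(mask) {
  if (is(mask, "Image")) mask <- EBImage::imageData(mask)
  storage.mode(mask) <- "logical"
  cpp_label8(mask)
}

#' Marker-controlled watershed
#'
#' Floods `priority` (lower values first) from labelled `markers`,
#' restricted to `mask`; each reachable pixel receives the label of the
#' marker whose flood arrives first, with FIFO tie-breaking, so the
#' result is deterministic.
#'
#' @param priority numeric matrix; the topographic surface.
#' @param markers integer matrix of seed labels (0 = none).
#' @param mask logical matrix restricting the flood.
#' @return Integer matrix of labels.
#' @export
watershedFromMarkers <- function(priority, markers, mask) {
  if (is(markers, "Image")) markers <- EBImage::imageData(markers)
  storage.mode(markers) <- "integer"
  if (is(mask, "Image")) mask <- EBImage::imageData(mask)
  storage.mode(mask) <- "logical"
  cpp_watershed_flood(.as_matrix(priority), markers, mask)
}

# Relabel an integer matrix so used labels become consecutive 1..L.
.relabel <- function(m) {
  labs <- sort(unique(as.integer(m[m > 0])))
  if (!length(labs)) {
    storage.mode(m) <- "integer"
    return(m)
  }
  lut <- integer(max(labs))
  lut[labs] <- seq_along(labs)
  out <- m
  out[m > 0] <- lut[m[m > 0]]
  storage.mode(out) <- "integer"
  out
}

# Odd-sized disc brush of (approximately) the requested radius.
.disc <- function(radius) {
  size <- 2L * as.integer(ceiling(radius)) + 1L
  EBImage::makeBrush(size, shape = "disc")
}

# EBImage grayscale morphology operates on the [0, 1] display scale;
# these wrappers rescale arbitrary non-negative intensities around the
# call so morphology is exact on raw camera units.
.grayDilate <- function(img, brush) {
  img <- .as_matrix(img)
  s <- max(img)
  if (s <= 0) return(img)
  .as_matrix(EBImage::dilate(img / s, brush)) * s
}

.whiteTopHat <- function(img, brush) {
  img <- .as_matrix(img)
  s <- max(img)
  if (s <= 0) return(img * 0)
  .as_matrix(EBImage::whiteTopHat(img / s, brush)) * s
}
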