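# File interfaces: 16-bit TIFF images (single nuclear plane, multi-page
# z-stack, label masks), JSON ground truth, and the fraction-table CSV
# dialect.

# Scale an intensity matrix into [0,1] for 16-bit TIFF storage; warns on
# saturation.
.to_tiff16 <- function(img, max_value = 65535) {
  if (any(img > max_value))
    warning("intensities above ", max_value, " clipped on TIFF export")
  pmin(pmax(img, 0), max_value) / max_value
}

#' Write a field and its ground truth to disk
#'
#' Writes `nuclear.tif` (single-page), `spots.tif` (multi-page, plane
#' order = z order), both 16-bit unsigned with intensities clipped at
#' 65535, and `truth.json`. JSON coordinates are 0-based with
#' `x` = column and `y` = row; the focal plane index is 0-based too.
#'
#' @param field a [ZStackField-class].
#' @param dir output directory (created if needed).
#' @param truth optional [FieldGroundTruth-class] to write alongside.
#' @return Invisibly, the output directory.
#' @export
writeField <- function(field, dir, truth = NULL) {
  if (!is(field, "ZStackField")) stop("field must be a ZStackField")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tiff::writeTIFF(.to_tiff16(nuclearPlane(field)),
                  file.path(dir, "nuclear.tif"), bits.per.sample = 16L)
  st <- spotStack(field)
  planes <- lapply(seq_len(dim(st)[3]), function(i) .to_tiff16(st[, , i]))
  tiff::writeTIFF(planes, file.path(dir, "spots.tif"), bits.per.sample = 16L)
  meta <- list(pixel_size_um = pixelSize(field), z_spacing_um = zSpacing(field))
  if (!is.null(truth)) {
    nuc <- truthNuclei(truth)
    sp <- truthNucleoli(truth)
    meta$truth <- list(
      focal_plane_index = focalPlane(truth) - 1L,
      nuclei = data.frame(nucleus = nuc$nucleus, x = nuc$x - 1, y = nuc$y - 1,
                          semi_major_px = nuc$semiMajorPx,
                          semi_minor_px = nuc$semiMinorPx,
                          theta_rad = nuc$thetaRad),
      nucleoli = data.frame(nucleus = sp$nucleus, x = sp$x - 1, y = sp$y - 1,
                            radius_px = sp$radiusPx, amplitude = sp$amplitude)
    )
  }
  jsonlite::write_json(meta, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(dir)
}

#' Read a field written by [writeField()]
#'
#' Restores intensities on the original scale (TIFF samples times
#' 65535).
#'
#' @param dir directory containing `nuclear.tif`, `spots.tif`,
#'   `truth.json`.
#' @return A [ZStackField-class].
#' @export
readField <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "truth.json"),
                              simplifyVector = TRUE)
  nuclear <- tiff::readTIFF(file.path(dir, "nuclear.tif")) * 65535
  planes <- tiff::readTIFF(file.path(dir, "spots.tif"), all = TRUE)
  stack <- array(0, dim = c(dim(planes[[1]]), length(planes)))
  for (i in seq_along(planes)) stack[, , i] <- planes[[i]] * 65535
  ZStackField(nuclear, stack, meta$pixel_size_um, meta$z_spacing_um)
}

#' Write a label map as 16-bit TIFF
#'
#' Labels are stored as raw 16-bit sample values.
#'
#' @param labels a [LabelMap-class].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
writeLabelMap <- function(labels, path) {
  if (!is(labels, "LabelMap")) stop("labels must be a LabelMap")
  if (nLabels(labels) > 65535) stop("more than 65535 labels")
  tiff::writeTIFF(labelMatrix(labels) / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a label map written by [writeLabelMap()]
#'
#' @param path TIFF path.
#' @return A [LabelMap-class].
#' @export
readLabelMap <- function(path) {
  LabelMap(round(tiff::readTIFF(path) * 65535))
}

#' Write a fraction table as CSV
#'
#' Columns `fraction`, `condition`, `replicate`, `value`, `unit`.
#'
#' @param table fraction table data.frame.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
writeFractionTable <- function(table, path) {
  .check_fraction_table(table)
  write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' Read a fraction table CSV
#'
#' @param path CSV path.
#' @return Validated fraction table data.frame.
#' @export
readFractionTable <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  .check_fraction_table(tab)
  tab
}

#' Read a DEG table CSV
#'
#' Columns `gene_id`, `log2fc`, `fdr`.
#'
#' @param path CSV path.
#' @return Validated DEG table data.frame.
#' @export
readDegTable <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  .check_deg_table(tab)
  tab
}
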