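# High-content nucleolar-hypertrophy pipeline: watershed segmentation of
# nuclear-stain nuclei, best-focus plane selection in the spot-channel
# z-stack, top-hat + H-maxima nucleolus detection, and per-nucleus
# morphometry.

#' Detection parameters for the nucleolar pipeline
#'
#' @param smoothing_sigma_px Gaussian smoothing applied before nuclear
#'   thresholding, px.
#' @param min_nucleus_area_px objects below this area are discarded and
#'   its implied radius `sqrt(area/pi)` sets the minimum separation of
#'   watershed markers.
#' @param tophat_radius_px disc radius of the white top-hat structuring
#'   element; about twice the expected nucleolus radius in px.
#' @param h_depth depth of the H-maxima transform, intensity units;
#'   `NULL` (default) uses 10% of the focused plane's robust dynamic
#'   range (1st to 99.9th percentile of the top-hat input plane).
#' @param min_spot_area_px nucleolus objects below this area are dropped.
#' @param exclude_border_nuclei drop nuclei touching the field border
#'   (partial nuclei bias counts).
#' @return A list of class `detectionParams`.
#' @export
detectionParams <- function(smoothing_sigma_px = 2,
                            min_nucleus_area_px = 1500,
                            tophat_radius_px = 11,
                            h_depth = NULL,
                            min_spot_area_px = 20,
                            exclude_border_nuclei = TRUE) {
  if (smoothing_sigma_px < 0) stop("smoothing_sigma_px must be non-negative")
  if (min_nucleus_area_px <= 0) stop("min_nucleus_area_px must be positive")
  if (tophat_radius_px <= 0) stop("tophat_radius_px must be positive")
  if (!is.null(h_depth) && h_depth <= 0) stop("h_depth must be positive")
  if (min_spot_area_px <= 0) stop("min_spot_area_px must be positive")
  structure(list(smoothing_sigma_px = smoothing_sigma_px,
                 min_nucleus_area_px = min_nucleus_area_px,
                 tophat_radius_px = tophat_radius_px,
                 h_depth = h_depth,
                 min_spot_area_px = min_spot_area_px,
                 exclude_border_nuclei = exclude_border_nuclei),
            class = "detectionParams")
}

.check_image <- function(img) {
  img <- .as_matrix(img)
  if (any(img < 0)) stop("image must be non-negative")
  img
}

#' Segment nuclei with a marker-controlled watershed
#'
#' Gaussian smoothing, global Otsu threshold, hole filling, removal of
#' objects below `min_nucleus_area_px`, Euclidean distance transform,
#' markers at distance maxima separated by at least
#' `sqrt(min_nucleus_area_px / pi)`, marker-controlled watershed on the
#' negated distance map restricted to the foreground, optional removal
#' of border-touching labels, and consecutive relabelling.
#'
#' @param nuclear_plane 2-d non-negative numeric matrix (DAPI channel).
#' @param params a [detectionParams()].
#' @return A [LabelMap-class] of nuclei.
#' @export
segmentNuclei <- function(nuclear_plane, params = detectionParams()) {
  img <- .check_image(nuclear_plane)
  empty <- LabelMap(matrix(0L, nrow(img), ncol(img)))
  sm <- if (params$smoothing_sigma_px > 0) {
    .as_matrix(EBImage::gblur(img, sigma = params$smoothing_sigma_px))
  } else img
  rng <- range(sm)
  if (diff(rng) == 0) return(empty)
  norm <- (sm - rng[1]) / diff(rng)
  mask <- norm > EBImage::otsu(EBImage::Image(norm))
  mask <- .as_matrix(EBImage::fillHull(mask)) > 0
  lab0 <- cpp_label8(mask)
  if (max(lab0) == 0) return(empty)
  areas <- tabulate(lab0[lab0 > 0], nbins = max(lab0))
  keep <- which(areas >= params$min_nucleus_area_px)
  if (!length(keep)) return(empty)
  mask <- matrix(lab0 %in% keep & mask, nrow(mask), ncol(mask))
  d <- .as_matrix(EBImage::distmap(mask))
  minsep <- sqrt(params$min_nucleus_area_px / pi)
  # light smoothing of the distance map merges the spurious twin ridge
  # maxima that boundary aliasing creates on eccentric nuclei
  ds <- .as_matrix(EBImage::gblur(d, sigma = 2))
  dil <- .grayDilate(ds, .disc(minsep))
  peaks <- (ds >= dil - 1e-6 * max(ds)) & mask & (d > 0)
  markers <- cpp_label8(peaks)
  seg <- cpp_watershed_flood(-d, markers, mask)
  if (isTRUE(params$exclude_border_nuclei)) {
    border <- unique(c(seg[1, ], seg[nrow(seg), ], seg[, 1], seg[, ncol(seg)]))
    seg[seg %in% border[border > 0]] <- 0L
  }
  LabelMap(.relabel(seg))
}

#' Focus functional: normalised variance of the Laplacian
#'
#' Variance of the 4-neighbour-Laplacian-filtered plane divided by the
#' squared mean intensity. Strictly decreasing under Gaussian blurring
#' of a structured image, which makes it a valid best-focus criterion
#' for a defocus series.
#'
#' @param plane numeric matrix.
#' @return Non-negative scalar; 0 for a constant plane.
#' @export
focusMetric <- function(plane) {
  plane <- .as_matrix(plane)
  mu <- mean(plane)
  if (mu <= 0) return(0)
  kern <- matrix(c(0, 1, 0, 1, -4, 1, 0, 1, 0), 3, 3)
  lap <- .as_matrix(EBImage::filter2(plane, kern))
  var(as.numeric(lap)) / mu^2
}

#' Select the best-focused plane of a z-stack
#'
#' Returns the 1-based index of the plane maximising [focusMetric()];
#' ties break to the lowest index.
#'
#' @param spot_zstack 3-d array (rows x cols x planes) or a
#'   [ZStackField-class].
#' @return Integer plane index.
#' @export
selectBestFocusPlane <- function(spot_zstack) {
  if (is(spot_zstack, "ZStackField")) spot_zstack <- spotStack(spot_zstack)
  d <- dim(spot_zstack)
  if (is.null(d) || length(d) != 3 || d[3] < 1)
    stop("spot_zstack must be a non-empty 3-d array")
  scores <- vapply(seq_len(d[3]),
                   function(i) focusMetric(spot_zstack[, , i]), numeric(1))
  which.max(scores)  # which.max takes the first maximum: lowest-index tie-break
}

#' Detect nucleoli on the focused plane
#'
#' White top-hat with a disc structuring element isolates bright
#' structures smaller than the element; the H-maxima transform with
#' depth `h_depth` suppresses shallow maxima and its regional maxima
#' seed a marker-controlled watershed of the negated top-hat image,
#' restricted to pixels with top-hat value at least `h_depth` (plus the
#' marker plateaus). Objects below `min_spot_area_px` are removed and
#' each object is assigned to the nucleus containing its centroid;
#' objects whose centroid falls outside every nucleus are discarded.
#'
#' @param focused_plane numeric matrix, the selected spot-channel plane.
#' @param nuclei a [LabelMap-class] of segmented nuclei (same shape).
#' @param params a [detectionParams()].
#' @return List with `spots` (a [LabelMap-class]) and `records`, a
#'   data.frame with one row per retained nucleolus: `label`, `nucleus`,
#'   `areaPx`, `meanIntensity` (on the original plane),
#'   `meanTophatIntensity` (background-corrected), `x`, `y` (centroid,
#'   1-based pixel coordinates).
#' @export
detectNucleoli <- function(focused_plane, nuclei, params = detectionParams()) {
  img <- .as_matrix(focused_plane)
  if (!is(nuclei, "LabelMap")) stop("nuclei must be a LabelMap")
  nmap <- labelMatrix(nuclei)
  if (!identical(dim(img), dim(nmap)))
    stop("focused_plane and nuclei label map must have the same shape")
  empty <- list(
    spots = LabelMap(matrix(0L, nrow(img), ncol(img))),
    records = data.frame(label = integer(), nucleus = integer(),
                         areaPx = numeric(), meanIntensity = numeric(),
                         meanTophatIntensity = numeric(),
                         x = numeric(), y = numeric())
  )
  th <- .whiteTopHat(img, .disc(params$tophat_radius_px))
  h <- params$h_depth
  if (is.null(h)) {
    q <- quantile(img, c(0.01, 0.999), names = FALSE)
    h <- 0.10 * diff(q)
  }
  if (h <= 0) return(empty)
  hm <- cpp_reconstruct_dilation(th - h, th)
  maxima <- cpp_regional_maxima(hm) & (th >= h)
  markers <- cpp_label8(maxima)
  if (max(markers) == 0) return(empty)
  support <- (th >= h) | (markers > 0)
  seg <- cpp_watershed_flood(-th, markers, support)
  L <- max(seg)
  areas <- tabulate(seg[seg > 0], nbins = L)
  recs <- list()
  out <- matrix(0L, nrow(img), ncol(img))
  next_label <- 0L
  for (l in seq_len(L)) {
    if (areas[l] < params$min_spot_area_px) next
    idx <- which(seg == l)
    rows <- (idx - 1) %% nrow(img) + 1
    cols <- (idx - 1) %/% nrow(img) + 1
    cy <- mean(rows); cx <- mean(cols)
    parent <- nmap[round(cy), round(cx)]
    if (parent == 0) next
    next_label <- next_label + 1L
    out[idx] <- next_label
    recs[[next_label]] <- data.frame(
      label = next_label, nucleus = as.integer(parent),
      areaPx = areas[l],
      meanIntensity = mean(img[idx]),
      meanTophatIntensity = mean(th[idx]),
      x = cx, y = cy
    )
  }
  if (!next_label) return(empty)
  list(spots = LabelMap(out), records = do.call(rbind, recs))
}

#' Per-nucleus nucleolar morphometry
#'
#' One row per nucleus label (including nuclei with no nucleoli, whose
#' mean fields are `NA`): nucleolus count, mean nucleolus area (px^2 and,
#' when a pixel size is given, um^2) and mean nucleolus intensity.
#'
#' @param nuclei a [LabelMap-class] of nuclei.
#' @param records the `records` data.frame from [detectNucleoli()].
#' @param pixel_size_um optional lateral calibration for um^2 areas.
#' @return data.frame with columns `nucleus`, `nNucleoli`,
#'   `meanNucleolusArea`, `meanNucleolusAreaUm2`, `meanNucleolusIntensity`.
#' @export
summarizePerNucleus <- function(nuclei, records, pixel_size_um = NULL) {
  if (!is(nuclei, "LabelMap")) stop("nuclei must be a LabelMap")
  L <- nLabels(nuclei)
  if (nrow(records) && !all(records$nucleus %in% seq_len(L)))
    stop("records reference nucleus labels absent from the label map")
  out <- data.frame(nucleus = seq_len(L), nNucleoli = 0L,
                    meanNucleolusArea = NA_real_,
                    meanNucleolusAreaUm2 = NA_real_,
                    meanNucleolusIntensity = NA_real_)
  if (nrow(records)) {
    agg_n <- tapply(records$label, records$nucleus, length)
    agg_a <- tapply(records$areaPx, records$nucleus, mean)
    agg_i <- tapply(records$meanIntensity, records$nucleus, mean)
    ids <- as.integer(names(agg_n))
    out$nNucleoli[ids] <- as.integer(agg_n)
    out$meanNucleolusArea[ids] <- as.numeric(agg_a)
    out$meanNucleolusIntensity[ids] <- as.numeric(agg_i)
    if (!is.null(pixel_size_um))
      out$meanNucleolusAreaUm2 <- out$meanNucleolusArea * pixel_size_um^2
  }
  out
}

#' Run the full single-field pipeline
#'
#' Segments nuclei on the nuclear plane, selects the best-focused
#' spot-channel plane, detects nucleoli on it and summarises per
#' nucleus.
#'
#' @param field a [ZStackField-class].
#' @param params a [detectionParams()].
#' @return List with `nuclei` (LabelMap), `focusIndex`, `spots`
#'   (LabelMap), `records` and `summary` (per-nucleus data.frame).
#' @export
analyzeField <- function(field, params = detectionParams()) {
  if (!is(field, "ZStackField")) stop("field must be a ZStackField")
  nuclei <- segmentNuclei(nuclearPlane(field), params)
  k <- selectBestFocusPlane(field)
  det <- detectNucleoli(spotStack(field)[, , k], nuclei, params)
  list(nuclei = nuclei, focusIndex = k, spots = det$spots,
       records = det$records,
       summary = summarizePerNucleus(nuclei, det$records,
                                     pixel_size_um = pixelSize(field)))
}

#' Pool per-nucleus summaries into per-well summaries
#'
#' Wells are the replicate unit: nuclei from all fields of a well are
#' pooled, the nucleolus count is averaged over all nuclei, and area and
#' intensity are averaged over nucleoli-bearing nuclei only.
#'
#' @param nucleus_table data.frame of per-nucleus rows with columns
#'   `well`, `treatment`, `nNucleoli`, `meanNucleolusArea`,
#'   `meanNucleolusIntensity` (as produced by [summarizePerNucleus()]
#'   plus well/treatment annotations).
#' @return data.frame with one row per well: `well`, `treatment`,
#'   `nNuclei`, `meanNucleoliPerNucleus`, `meanNucleolusArea`,
#'   `meanNucleolusIntensity`.
#' @export
aggregatePlate <- function(nucleus_table) {
  need <- c("well", "treatment", "nNucleoli")
  if (!all(need %in% names(nucleus_table)))
    stop("nucleus_table must carry well, treatment and nNucleoli columns")
  if (anyNA(nucleus_table$well) || anyNA(nucleus_table$treatment))
    stop("every nucleus must be mapped to a well and a treatment")
  wt <- unique(nucleus_table[, c("well", "treatment")])
  if (anyDuplicated(wt$well))
    stop("a well is mapped to more than one treatment")
  rows <- lapply(seq_len(nrow(wt)), function(i) {
    sub <- nucleus_table[nucleus_table$well == wt$well[i], ]
    bearing <- sub[sub$nNucleoli > 0, ]
    data.frame(
      well = wt$well[i], treatment = wt$treatment[i],
      nNuclei = nrow(sub),
      meanNucleoliPerNucleus = mean(sub$nNucleoli),
      meanNucleolusArea = if (nrow(bearing))
        mean(bearing$meanNucleolusArea) else NA_real_,
      meanNucleolusIntensity = if (nrow(bearing) &&
          "meanNucleolusIntensity" %in% names(bearing))
        mean(bearing$meanNucleolusIntensity) else NA_real_
    )
  })
  do.call(rbind, rows)
}

#' Compare treatments on a per-well metric by one-way ANOVA
#'
#' Wells are replicates; the chosen per-well metric is compared between
#' treatments with [oneWayAnova()].
#'
#' @param well_summary data.frame from [aggregatePlate()].
#' @param metric column of `well_summary` to compare
#'   (default `"meanNucleoliPerNucleus"`).
#' @return An [oneWayAnova()] result.
#' @export
compareTreatments <- function(well_summary,
                              metric = "meanNucleoliPerNucleus") {
  if (!metric %in% names(well_summary)) stop("unknown metric '", metric, "'")
  groups <- split(well_summary[[metric]], well_summary$treatment)
  oneWayAnova(groups)
}
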