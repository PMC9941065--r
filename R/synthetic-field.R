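# Ground-truthed synthetic microscopy fields emulating the high-content
# acquisition: a single nuclear-stain plane plus a spot-channel z-stack
# (10 um at 1 um increments -> 11 planes by default) with a
# Poisson-Gaussian camera noise model.

#' Configuration for a synthetic imaging field
#'
#' Collects and validates the parameters of [generateField()]. Defaults
#' emulate a 40x high-content acquisition of adherent carcinoma cells:
#' 0.16 um/px, round-ish nuclei of 4.5-6 um radius (9-12 um diameter), a
#' Poisson number of bright nucleoli per nucleus, an 11-plane z-stack at 1 um spacing with
#' mid-stack focus, defocus blur growing linearly with distance from the
#' focal plane, and shot plus read noise.
#'
#' @param width_px,height_px positive integer field dimensions.
#' @param pixel_size_um lateral calibration, um/px.
#' @param n_nuclei non-negative integer count of nuclei to place.
#' @param nucleus_radius_um_range `(lo, hi)` semi-major axis range, um.
#' @param nucleoli_per_nucleus_mean Poisson rate of nucleoli per nucleus.
#' @param nucleolus_radius_um_range `(lo, hi)` spot radius range, um; the
#'   upper bound must stay below the nucleus radius lower bound so spots
#'   fit inside nuclei.
#' @param nucleus_background_intensity fill intensity of nuclei
#'   (arbitrary units) in both channels.
#' @param nucleolus_amplitude additive peak amplitude of a nucleolar spot
#'   over the nucleus background.
#' @param n_planes number of z planes.
#' @param z_spacing_um spacing between planes, um.
#' @param focal_plane_index 1-based index of the in-focus plane.
#' @param defocus_blur_um_per_um added Gaussian blur standard deviation
#'   (um) per um of defocus distance.
#' @param photon_gain photons per intensity unit for the Poisson shot
#'   noise stage.
#' @param read_noise_sd standard deviation of additive Gaussian read
#'   noise, intensity units.
#' @param seed integer seed; equal config and seed give bit-identical
#'   fields and truth.
#' @return A validated list of class `fieldConfig`.
#' @examples
#' cfg <- fieldConfig(n_nuclei = 3, seed = 7)
#' @export
fieldConfig <- function(width_px = 256L, height_px = 256L,
                        pixel_size_um = 0.16,
                        n_nuclei = 5L,
                        nucleus_radius_um_range = c(4.5, 6),
                        nucleoli_per_nucleus_mean = 2,
                        nucleolus_radius_um_range = c(0.6, 1.2),
                        nucleus_background_intensity = 500,
                        nucleolus_amplitude = 2000,
                        n_planes = 11L,
                        z_spacing_um = 1,
                        focal_plane_index = 6L,
                        defocus_blur_um_per_um = 0.5,
                        photon_gain = 1,
                        read_noise_sd = 10,
                        seed = 1L) {
  cfg <- list(
    width_px = as.integer(width_px), height_px = as.integer(height_px),
    pixel_size_um = pixel_size_um,
    n_nuclei = as.integer(n_nuclei),
    nucleus_radius_um_range = as.numeric(nucleus_radius_um_range),
    nucleoli_per_nucleus_mean = nucleoli_per_nucleus_mean,
    nucleolus_radius_um_range = as.numeric(nucleolus_radius_um_range),
    nucleus_background_intensity = nucleus_background_intensity,
    nucleolus_amplitude = nucleolus_amplitude,
    n_planes = as.integer(n_planes),
    z_spacing_um = z_spacing_um,
    focal_plane_index = as.integer(focal_plane_index),
    defocus_blur_um_per_um = defocus_blur_um_per_um,
    photon_gain = photon_gain,
    read_noise_sd = read_noise_sd,
    seed = as.integer(seed)
  )
  with(cfg, {
    if (width_px <= 0 || height_px <= 0) stop("field dimensions must be positive")
    if (pixel_size_um <= 0) stop("pixel_size_um must be positive")
    if (n_nuclei < 0) stop("n_nuclei must be non-negative")
    if (nucleoli_per_nucleus_mean < 0) stop("nucleoli rate must be non-negative")
    if (length(nucleus_radius_um_range) != 2 ||
        any(nucleus_radius_um_range <= 0) ||
        diff(nucleus_radius_um_range) < 0)
      stop("nucleus_radius_um_range must be positive (lo, hi) with lo <= hi")
    if (length(nucleolus_radius_um_range) != 2 ||
        any(nucleolus_radius_um_range <= 0) ||
        diff(nucleolus_radius_um_range) < 0)
      stop("nucleolus_radius_um_range must be positive (lo, hi) with lo <= hi")
    if (nucleolus_radius_um_range[2] >= nucleus_radius_um_range[1])
      stop("nucleolus radius upper bound must be below nucleus radius lower bound")
    if (nucleus_background_intensity <= 0 || nucleolus_amplitude <= 0)
      stop("intensities must be positive")
    if (n_planes <= 0) stop("n_planes must be positive")
    if (z_spacing_um <= 0) stop("z_spacing_um must be positive")
    if (focal_plane_index < 1 || focal_plane_index > n_planes)
      stop("focal_plane_index out of range [1, n_planes]")
    if (defocus_blur_um_per_um < 0) stop("defocus blur rate must be non-negative")
    if (photon_gain <= 0) stop("photon_gain must be positive")
    if (read_noise_sd < 0) stop("read_noise_sd must be non-negative")
  })
  class(cfg) <- "fieldConfig"
  cfg
}

# Sample the ground truth (nucleus ellipses, nucleolus spots) for a
# config. Called inside the seeded stream; all truth draws happen before
# any pixel noise draw, so truth-only and full generation agree.
.sampleTruth <- function(cfg) {
  px <- cfg$pixel_size_um
  nuc <- data.frame(nucleus = integer(), x = numeric(), y = numeric(),
                    semiMajorPx = numeric(), semiMinorPx = numeric(),
                    thetaRad = numeric())
  spots <- data.frame(nucleus = integer(), x = numeric(), y = numeric(),
                      radiusPx = numeric(), amplitude = numeric())
  if (cfg$n_nuclei > 0) {
    for (i in seq_len(cfg$n_nuclei)) {
      placed <- FALSE
      for (try in seq_len(2000L)) {
        a_um <- runif(1, cfg$nucleus_radius_um_range[1],
                      cfg$nucleus_radius_um_range[2])
        ratio <- runif(1, 0.7, 1.0)
        a <- a_um / px
        b <- a * ratio
        theta <- runif(1, 0, pi)
        cx <- runif(1, 1 + a, cfg$width_px - a)
        cy <- runif(1, 1 + a, cfg$height_px - a)
        # disjoint placement via bounding circles of the semi-major axes
        ok <- TRUE
        if (nrow(nuc)) {
          dd <- sqrt((nuc$x - cx)^2 + (nuc$y - cy)^2)
          ok <- all(dd > nuc$semiMajorPx + a)
        }
        if (ok) {
          nuc <- rbind(nuc, data.frame(nucleus = i, x = cx, y = cy,
                                       semiMajorPx = a, semiMinorPx = b,
                                       thetaRad = theta))
          placed <- TRUE
          break
        }
      }
      if (!placed)
        stop("could not place ", cfg$n_nuclei, " disjoint nuclei; ",
             "reduce n_nuclei or nucleus radii")
      k <- rpois(1, cfg$nucleoli_per_nucleus_mean)
      if (k > 0) {
        ni <- nuc[nrow(nuc), ]
        placed_spots <- spots[0, ]
        for (j in seq_len(k)) {
          r_um <- runif(1, cfg$nucleolus_radius_um_range[1],
                        cfg$nucleolus_radius_um_range[2])
          r <- r_um / px
          # uniform in the ellipse shrunk to keep the spot interior;
          # nucleoli are kept disjoint (centres >= sum of radii apart)
          # when space allows, as real nucleoli are
          for (try in seq_len(50L)) {
            rr <- sqrt(runif(1)) * 0.8
            phi <- runif(1, 0, 2 * pi)
            ex <- rr * ni$semiMajorPx * cos(phi)
            ey <- rr * ni$semiMinorPx * sin(phi)
            sx <- ni$x + ex * cos(ni$thetaRad) - ey * sin(ni$thetaRad)
            sy <- ni$y + ex * sin(ni$thetaRad) + ey * cos(ni$thetaRad)
            if (!nrow(placed_spots)) break
            dd <- sqrt((placed_spots$x - sx)^2 + (placed_spots$y - sy)^2)
            if (all(dd >= placed_spots$radiusPx + r)) break
          }
          placed_spots <- rbind(placed_spots,
                                data.frame(nucleus = i, x = sx, y = sy,
                                           radiusPx = r,
                                           amplitude = cfg$nucleolus_amplitude))
        }
        spots <- rbind(spots, placed_spots)
      }
    }
  }
  new("FieldGroundTruth", nuclei = nuc, nucleoli = spots,
      focalPlaneIndex = cfg$focal_plane_index)
}

# Render the filled-ellipse nucleus mask image for a truth table.
.renderNuclei <- function(truth, cfg, value = 1) {
  img <- matrix(0, cfg$height_px, cfg$width_px)
  nuc <- truthNuclei(truth)
  for (i in seq_len(nrow(nuc))) {
    n <- nuc[i, ]
    rad <- ceiling(n$semiMajorPx) + 1
    xs <- max(1, floor(n$x - rad)):min(cfg$width_px, ceiling(n$x + rad))
    ys <- max(1, floor(n$y - rad)):min(cfg$height_px, ceiling(n$y + rad))
    dx <- outer(rep(1, length(ys)), xs - n$x)
    dy <- outer(ys - n$y, rep(1, length(xs)))
    u <- dx * cos(n$thetaRad) + dy * sin(n$thetaRad)
    v <- -dx * sin(n$thetaRad) + dy * cos(n$thetaRad)
    inside <- (u / n$semiMajorPx)^2 + (v / n$semiMinorPx)^2 <= 1
    sub <- img[ys, xs, drop = FALSE]
    sub[inside] <- value
    img[ys, xs] <- sub
  }
  img
}

# Add truncated Gaussian spots (sigma = radius/2, support 3 sigma).
.renderSpots <- function(img, truth) {
  spots <- truthNucleoli(truth)
  for (i in seq_len(nrow(spots))) {
    s <- spots[i, ]
    sigma <- s$radiusPx / 2
    rad <- ceiling(3 * sigma)
    xs <- max(1, floor(s$x - rad)):min(ncol(img), ceiling(s$x + rad))
    ys <- max(1, floor(s$y - rad)):min(nrow(img), ceiling(s$y + rad))
    dx2 <- outer(rep(1, length(ys)), (xs - s$x)^2)
    dy2 <- outer((ys - s$y)^2, rep(1, length(xs)))
    g <- s$amplitude * exp(-(dx2 + dy2) / (2 * sigma^2))
    g[sqrt(dx2 + dy2) > 3 * sigma] <- 0
    img[ys, xs] <- img[ys, xs] + g
  }
  img
}

.applyNoise <- function(img, cfg) {
  g <- cfg$photon_gain
  noisy <- if (is.finite(g)) {
    rpois(length(img), lambda = pmax(img, 0) * g) / g
  } else {
    as.numeric(img)  # photon_gain = Inf: shot-noise-free rendering
  }
  if (cfg$read_noise_sd > 0)
    noisy <- noisy + rnorm(length(img), sd = cfg$read_noise_sd)
  matrix(pmax(noisy, 0), nrow(img), ncol(img))
}

#' Generate a synthetic imaging field with ground truth
#'
#' Renders one field from a [fieldConfig()]: filled-ellipse nuclei on the
#' nuclear plane; on the spot channel, the same nucleus background plus
#' additive Gaussian nucleolar spots (sigma = radius/2, truncated at
#' 3 sigma), rendered in focus on the focal plane and blurred on every
#' other plane by a Gaussian kernel of standard deviation
#' `defocus_blur_um_per_um * |z - z_focal|` (converted to pixels). Each
#' plane then receives Poisson shot noise (at `photon_gain`) followed by
#' additive Gaussian read noise, clamped at zero. All randomness flows
#' from a single seeded stream, with ground-truth draws preceding noise
#' draws, so equal `(config, seed)` give bit-identical output and
#' [generateFieldTruth()] reproduces the identical truth.
#'
#' @param config a [fieldConfig()].
#' @return List with `field` (a [ZStackField-class]) and `truth`
#'   (a [FieldGroundTruth-class]).
#' @examples
#' out <- generateField(fieldConfig(n_nuclei = 2, seed = 3))
#' out$field
#' out$truth
#' @export
generateField <- function(config) {
  if (!inherits(config, "fieldConfig")) stop("config must be a fieldConfig")
  withr::with_seed(config$seed, {
    truth <- .sampleTruth(config)
    base_nuc <- .renderNuclei(truth, config,
                              value = config$nucleus_background_intensity)
    base_spot <- .renderSpots(base_nuc, truth)
    stack <- array(0, dim = c(config$height_px, config$width_px,
                              config$n_planes))
    for (i in seq_len(config$n_planes)) {
      dz_um <- abs(i - config$focal_plane_index) * config$z_spacing_um
      sigma_px <- config$defocus_blur_um_per_um * dz_um / config$pixel_size_um
      plane <- if (sigma_px > 0) {
        .as_matrix(EBImage::gblur(base_spot, sigma = sigma_px))
      } else {
        base_spot
      }
      stack[, , i] <- .applyNoise(plane, config)
    }
    nuclear <- .applyNoise(base_nuc, config)
    list(
      field = ZStackField(nuclear, stack, config$pixel_size_um,
                          config$z_spacing_um),
      truth = truth
    )
  })
}

#' Generate only the ground truth of a synthetic field
#'
#' Draws the same nuclei and nucleoli as [generateField()] under the same
#' seed, without rendering pixels. Useful for statistical properties of
#' the downstream summaries where the imaging stages are not under test.
#'
#' @param config a [fieldConfig()].
#' @return A [FieldGroundTruth-class].
#' @export
generateFieldTruth <- function(config) {
  if (!inherits(config, "fieldConfig")) stop("config must be a fieldConfig")
  withr::with_seed(config$seed, .sampleTruth(config))
}

#' Render the nucleus label mask implied by a ground truth
#'
#' Rasterises the truth ellipses into a [LabelMap-class] (labels follow
#' the truth nucleus ids, which are consecutive). Used to validate
#' segmentation against truth by intersection-over-union.
#'
#' @param truth a [FieldGroundTruth-class].
#' @param config the [fieldConfig()] the truth came from (for dimensions).
#' @return A [LabelMap-class].
#' @export
truthLabelMap <- function(truth, config) {
  img <- matrix(0L, config$height_px, config$width_px)
  nuc <- truthNuclei(truth)
  for (i in seq_len(nrow(nuc))) {
    n <- nuc[i, ]
    one <- .renderNuclei(
      new("FieldGroundTruth", nuclei = nuc[i, , drop = FALSE],
          nucleoli = truthNucleoli(truth)[0, ],
          focalPlaneIndex = truth@focalPlaneIndex),
      config, value = 1)
    img[one > 0] <- n$nucleus
  }
  LabelMap(img)
}
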