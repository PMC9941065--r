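test_that("a blank field yields an empty label map", {
  expect_identical(nLabels(segmentNuclei(matrix(0, 64, 64))), 0L)
  expect_error(segmentNuclei(matrix(-1, 8, 8)), "non-negative")
})

test_that("synthetic nuclei are segmented one-to-one with IoU >= 0.7", {
  cfg <- fieldConfig(seed = 1L)
  out <- generateField(cfg)
  seg <- segmentNuclei(nuclearPlane(out$field))
  expect_identical(nLabels(seg), nrow(truthNuclei(out$truth)))
  truth_map <- labelMatrix(truthLabelMap(out$truth, cfg))
  seg_map <- labelMatrix(seg)
  for (t in seq_len(max(truth_map))) {
    tm <- truth_map == t
    # the segmented label overlapping this truth nucleus most
    lab <- as.integer(names(which.max(table(seg_map[tm & seg_map > 0]))))
    sm <- seg_map == lab
    iou <- sum(tm & sm) / sum(tm | sm)
    expect_gte(iou, 0.7)
  }
})

test_that("two touching disks are split along the neck", {
  img <- matrix(0, 90, 120)
  for (cx in c(45, 80)) {
    dx2 <- outer(rep(1, 90), (seq_len(120) - cx)^2)
    dy2 <- outer((seq_len(90) - 45)^2, rep(1, 120))
    img[dx2 + dy2 <= 25^2] <- 500
  }
  params <- detectionParams(min_nucleus_area_px = 700,
                            exclude_border_nuclei = FALSE)
  seg <- segmentNuclei(img, params)
  expect_identical(nLabels(seg), 2L)
})

test_that("best-focus selection follows the contract", {
  one <- array(runif(64), dim = c(8, 8, 1))
  expect_identical(selectBestFocusPlane(one), 1L)
  flat <- array(rep(matrix(runif(64), 8, 8), 3), dim = c(8, 8, 3))
  expect_identical(selectBestFocusPlane(flat), 1L)  # tie -> lowest index
  expect_error(selectBestFocusPlane(array(0, dim = c(4, 4, 0))), "non-empty")
  # noise-free synthetic stack: exact recovery of the focal plane
  for (k in c(2L, 6L, 10L)) {
    out <- generateField(fieldConfig(seed = 21L, focal_plane_index = k,
                                     photon_gain = Inf, read_noise_sd = 0))
    expect_identical(selectBestFocusPlane(out$field), k)
  }
})

test_that("focus selection is robust to default noise within one plane", {
  hits <- 0L
  n_fields <- 100L
  for (s in seq_len(n_fields)) {
    out <- generateField(fieldConfig(seed = s, focal_plane_index = 4L))
    hits <- hits + (abs(selectBestFocusPlane(out$field) - 4L) <= 1L)
  }
  expect_gte(hits / n_fields, 0.95)
})

test_that("a single Gaussian spot is detected with accurate centroid", {
  img <- matrix(100, 128, 128)
  nuc <- matrix(0L, 128, 128)
  dx2 <- outer(rep(1, 128), (seq_len(128) - 64)^2)
  dy2 <- outer((seq_len(128) - 64)^2, rep(1, 128))
  nuc[dx2 + dy2 <= 40^2] <- 1L
  spot <- 1000 * exp(-((dx2 + dy2)) / (2 * 3^2))
  det <- detectNucleoli(img + spot, LabelMap(nuc),
                        detectionParams(h_depth = 200, min_spot_area_px = 4))
  expect_identical(nrow(det$records), 1L)
  expect_lt(sqrt((det$records$x - 64)^2 + (det$records$y - 64)^2), 2)
  expect_identical(det$records$nucleus, 1L)
  # constant image: nothing above any depth
  none <- detectNucleoli(matrix(7, 32, 32), LabelMap(matrix(0L, 32, 32)),
                         detectionParams(h_depth = 1))
  expect_identical(nrow(none$records), 0L)
  expect_error(detectNucleoli(matrix(0, 4, 4), LabelMap(matrix(0L, 5, 5))),
               "shape")
})

test_that("detection recovers ground truth with F1 >= 0.90 at default SNR", {
  counts <- c(tp = 0L, fp = 0L, fn = 0L)
  n_nuclei <- 0L
  s <- 0L
  while (n_nuclei < 100L) {
    s <- s + 1L
    out <- generateField(fieldConfig(seed = s))
    res <- analyzeField(out$field)
    n_nuclei <- n_nuclei + nLabels(res$nuclei)
    counts <- counts + match_detections(res$records, truthNucleoli(out$truth))
  }
  expect_gte(f1_from_counts(counts), 0.90)
})

test_that("every nucleolus record lies inside its parent nucleus label", {
  for (s in c(2L, 13L)) {
    out <- generateField(fieldConfig(seed = s))
    res <- analyzeField(out$field)
    m <- labelMatrix(res$nuclei)
    for (i in seq_len(nrow(res$records))) {
      expect_identical(m[round(res$records$y[i]), round(res$records$x[i])],
                       res$records$nucleus[i])
    }
  }
})

test_that("label maps are invariant to additive intensity offsets", {
  out <- generateField(fieldConfig(seed = 4L))
  plane <- spotStack(out$field)[, , 6]
  seg1 <- segmentNuclei(nuclearPlane(out$field))
  seg2 <- segmentNuclei(nuclearPlane(out$field) + 250)
  expect_identical(labelMatrix(seg1), labelMatrix(seg2))
  p <- detectionParams(h_depth = 300)
  d1 <- detectNucleoli(plane, seg1, p)
  d2 <- detectNucleoli(plane + 250, seg1, p)
  expect_identical(labelMatrix(d1$spots), labelMatrix(d2$spots))
  expect_equal(d2$records$meanIntensity - d1$records$meanIntensity,
               rep(250, nrow(d1$records)))
  # the top-hat itself ignores the offset, so background-corrected
  # intensities agree
  expect_equal(d1$records$meanTophatIntensity, d2$records$meanTophatIntensity,
               tolerance = 1e-8)
})

test_that("raising the H-maxima depth never adds objects", {
  out <- generateField(fieldConfig(seed = 4L))
  res <- analyzeField(out$field)
  plane <- spotStack(out$field)[, , res$focusIndex]
  prev <- Inf
  for (h in c(100, 300, 800, 1200, 1600, 2200)) {
    n <- nrow(detectNucleoli(plane, res$nuclei,
                             detectionParams(h_depth = h))$records)
    expect_lte(n, prev)
    prev <- n
  }
})

test_that("the pipeline is deterministic", {
  out <- generateField(fieldConfig(seed = 6L))
  a <- analyzeField(out$field)
  b <- analyzeField(out$field)
  expect_identical(labelMatrix(a$nuclei), labelMatrix(b$nuclei))
  expect_identical(a$records, b$records)
  expect_identical(a$summary, b$summary)
})

test_that("per-nucleus summaries follow the counting and averaging rules", {
  nuc <- matrix(0L, 10, 10)
  nuc[1:5, 1:5] <- 1L
  nuc[6:10, 6:10] <- 2L
  recs <- data.frame(label = 1:3, nucleus = c(1L, 1L, 1L),
                     areaPx = c(10, 20, 30),
                     meanIntensity = c(100, 200, 300),
                     meanTophatIntensity = c(90, 190, 290),
                     x = c(2, 3, 4), y = c(2, 3, 4))
  s <- summarizePerNucleus(LabelMap(nuc), recs)
  expect_identical(s$nNucleoli, c(3L, 0L))
  expect_equal(s$meanNucleolusArea[1], 20)
  expect_equal(s$meanNucleolusIntensity[1], 200)
  expect_true(is.na(s$meanNucleolusArea[2]))
  expect_true(is.na(s$meanNucleolusIntensity[2]))
  bad <- recs
  bad$nucleus <- c(1L, 1L, 7L)
  expect_error(summarizePerNucleus(LabelMap(nuc), bad), "absent")
})

test_that("plate aggregation pools nuclei within wells", {
  one <- data.frame(well = "w1", treatment = "ctrl",
                    nNucleoli = c(1L, 2L), meanNucleolusArea = c(10, 30),
                    meanNucleolusIntensity = c(5, 15))
  ws <- aggregatePlate(one)
  expect_identical(nrow(ws), 1L)
  expect_equal(ws$meanNucleoliPerNucleus, 1.5)
  expect_equal(ws$meanNucleolusArea, 20)

  # two fields pooled: counts {1,2} and {3} -> mean 2.0
  two <- data.frame(well = "w1", treatment = "ctrl",
                    nNucleoli = c(1L, 2L, 3L),
                    meanNucleolusArea = c(10, 30, 20),
                    meanNucleolusIntensity = c(5, 15, 10))
  expect_equal(aggregatePlate(two)$meanNucleoliPerNucleus, 2)

  bad <- one
  bad$treatment <- NA
  expect_error(aggregatePlate(bad), "mapped")
})

test_that("treatment effects on nucleolus counts are recovered", {
  # truth-level plate, 200+ nuclei per arm: estimated means within 10%
  plate <- simulatePlate(rates = c(control = 2, treated = 4),
                         wells_per_treatment = 4L, fields_per_well = 2L,
                         base_config = fieldConfig(n_nuclei = 30L,
                                                   width_px = 600L,
                                                   height_px = 600L),
                         measure = "truth", seed = 1L)
  ws <- aggregatePlate(plate)
  expect_identical(nrow(ws), 8L)
  mc <- mean(ws$meanNucleoliPerNucleus[ws$treatment == "control"])
  mt <- mean(ws$meanNucleoliPerNucleus[ws$treatment == "treated"])
  expect_lt(abs(mc - 2) / 2, 0.10)
  expect_lt(abs(mt - 4) / 4, 0.10)
  res <- compareTreatments(ws)
  expect_lt(res$p, 0.01)
  expect_identical(res$df_between, 1L)
  expect_identical(res$df_within, 6L)
})
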