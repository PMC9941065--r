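test_that("field generation is deterministic per (config, seed)", {
  cfg <- fieldConfig(n_nuclei = 3L, seed = 11L)
  a <- generateField(cfg)
  b <- generateField(cfg)
  expect_identical(nuclearPlane(a$field), nuclearPlane(b$field))
  expect_identical(spotStack(a$field), spotStack(b$field))
  expect_identical(truthNuclei(a$truth), truthNuclei(b$truth))
  expect_identical(truthNucleoli(a$truth), truthNucleoli(b$truth))
  # truth-only generation reproduces the same truth
  expect_identical(truthNuclei(generateFieldTruth(cfg)), truthNuclei(a$truth))
})

test_that("an empty field is noise-only with empty truth", {
  cfg <- fieldConfig(n_nuclei = 0L, seed = 5L)
  out <- generateField(cfg)
  expect_identical(nrow(truthNuclei(out$truth)), 0L)
  expect_identical(nrow(truthNucleoli(out$truth)), 0L)
  # pure noise: no pixel anywhere near the nucleus fill level
  expect_lt(max(nuclearPlane(out$field)),
            cfg$nucleus_background_intensity / 2)
})

test_that("field config invariants are enforced", {
  expect_error(fieldConfig(focal_plane_index = 12L), "out of range")
  expect_error(fieldConfig(width_px = 0), "positive")
  expect_error(fieldConfig(nucleolus_radius_um_range = c(1, 5)), "below")
  expect_error(fieldConfig(read_noise_sd = -1), "non-negative")
})

test_that("nucleolus counts follow the configured Poisson rate", {
  # distributional oracle: the total count over nuclei is a sum of
  # independent Poisson draws, so across seeds the mean is n * rate
  rate <- 3
  n_nuclei <- 5L
  totals <- vapply(1:200, function(s) {
    nrow(truthNucleoli(generateFieldTruth(
      fieldConfig(n_nuclei = n_nuclei, nucleoli_per_nucleus_mean = rate,
                  seed = s))))
  }, numeric(1))
  expected <- n_nuclei * rate
  se <- sqrt(expected / 200)
  expect_lt(abs(mean(totals) - expected), 4 * se)
})

test_that("every nucleolus lies inside its parent nucleus", {
  for (s in 1:5) {
    truth <- generateFieldTruth(fieldConfig(seed = s,
                                            nucleoli_per_nucleus_mean = 4))
    nuc <- truthNuclei(truth)
    sp <- truthNucleoli(truth)
    for (i in seq_len(nrow(sp))) {
      parent <- nuc[nuc$nucleus == sp$nucleus[i], ]
      expect_true(inside_ellipse(sp$x[i], sp$y[i], parent))
    }
    # and inside the rasterised mask of the same truth
    cfg <- fieldConfig(seed = s, nucleoli_per_nucleus_mean = 4)
    m <- labelMatrix(truthLabelMap(truth, cfg))
    for (i in seq_len(nrow(sp))) {
      expect_identical(m[round(sp$y[i]), round(sp$x[i])],
                       as.integer(sp$nucleus[i]))
    }
  }
})

test_that("the noise-free focal plane maximises a contrast functional", {
  cfg <- fieldConfig(seed = 9L, focal_plane_index = 3L,
                     photon_gain = Inf, read_noise_sd = 0)
  out <- generateField(cfg)
  scores <- vapply(seq_len(cfg$n_planes), function(i)
    focusMetric(spotStack(out$field)[, , i]), numeric(1))
  expect_identical(which.max(scores), 3L)
  expect_true(all(scores[-3] < scores[3]))
})

test_that("assay generation honours presets and the noise-free limit", {
  p <- assayPreset("pp242-incorporation")
  expect_equal(p$multipliers$pp242[["cytosol"]], 0.80)
  expect_equal(p$multipliers$pp242[["CMX"]], 1.50)
  expect_identical(p$n_replicates, 5L)

  p0 <- assayPreset("pp242-incorporation", cv = 0)
  tab <- generateAssay(p0, seed = 1)
  for (i in seq_len(nrow(tab))) {
    expect_equal(tab$value[i],
                 p0$means[[tab$fraction[i]]] *
                   p0$multipliers[[tab$condition[i]]][[tab$fraction[i]]])
  }

  split0 <- generateAssay(assayPreset("fraction-split", cv = 0), seed = 1)
  pct <- fractionPercentages(split0)
  expect_equal(pct$meanPercent[pct$fraction == "cytosol"], 70)

  expect_error(assayPreset("fraction-split", cv = -0.1), "non-negative")
  expect_error(assayPreset("no-such-preset"), "unknown preset")
})

test_that("assay values are positive and deterministic per seed", {
  p <- assayPreset("18S-ratio", cv = 0.8)  # heavy noise forces redraws
  tab <- generateAssay(p, seed = 3)
  expect_true(all(tab$value > 0))
  expect_identical(tab, generateAssay(p, seed = 3))
})

test_that("DEG universe reproduces the configured Venn regions exactly", {
  cfg <- degSimConfig(1000, 200, 180, overlap_count = 168, seed = 2)
  sets <- generateDegUniverse(cfg)
  expect_length(sets$universe, 1000)
  expect_length(sets$rna_up, 200)
  expect_length(sets$ribo_up, 180)
  expect_length(intersect(sets$rna_up, sets$ribo_up), 168)
  expect_identical(sets, generateDegUniverse(cfg))

  full <- generateDegUniverse(degSimConfig(50, 10, 10, overlap_count = 10))
  expect_identical(full$rna_up, full$ribo_up)

  disj <- generateDegUniverse(degSimConfig(50, 10, 10, overlap_count = 0))
  expect_length(intersect(disj$rna_up, disj$ribo_up), 0)

  expect_error(degSimConfig(100, 10, 5, overlap_count = 8), "exceeds")
  expect_error(degSimConfig(10, 8, 8, overlap_count = 2), "universe")

  # fraction parameterisation matches the overlap arithmetic
  cfg2 <- degSimConfig(1000, 200, 180,
                       fraction_transcribed_not_translated = 0.16)
  expect_identical(cfg2$overlap_count, 168L)
})
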