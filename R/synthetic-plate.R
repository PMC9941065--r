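# Whole-plate simulation: several wells per treatment, several fields
# per well, with the treatment acting on the nucleoli-per-nucleus rate.

#' Simulate a multi-well plate of synthetic fields
#'
#' Generates `wells_per_treatment` wells for each treatment and
#' `fields_per_well` fields per well, with the treatment's effect
#' entering through the Poisson nucleoli-per-nucleus rate. Per-field
#' seeds are drawn from one stream seeded by `seed`, so the whole plate
#' is reproducible.
#'
#' With `measure = "image"` every field is rendered and pushed through
#' the full pipeline ([analyzeField()]); with `measure = "truth"` the
#' per-nucleus summaries are read off the generator's ground truth
#' (count = true nucleolus count, area = mean true pi r^2, intensity =
#' mean true amplitude), which isolates the downstream well-level
#' statistics from the imaging stages.
#'
#' @param rates named numeric vector: nucleoli-per-nucleus rate per
#'   treatment, e.g. `c(control = 2, treated = 4)`.
#' @param wells_per_treatment wells (replicates) per treatment.
#' @param fields_per_well fields of view per well.
#' @param base_config a [fieldConfig()] used as the template for every
#'   field (its rate and seed are overridden).
#' @param params a [detectionParams()] for `measure = "image"`.
#' @param measure `"image"` (full pipeline) or `"truth"` (ground truth).
#' @param seed integer plate seed.
#' @return data.frame of per-nucleus rows with `well`, `treatment`,
#'   `field`, `nucleus`, `nNucleoli`, `meanNucleolusArea`,
#'   `meanNucleolusIntensity`; feed to [aggregatePlate()].
#' @export
simulatePlate <- function(rates = c(control = 2, treated = 4),
                          wells_per_treatment = 4L,
                          fields_per_well = 2L,
                          base_config = fieldConfig(),
                          params = detectionParams(),
                          measure = c("image", "truth"),
                          seed = 1L) {
  measure <- match.arg(measure)
  if (is.null(names(rates)) || any(!nzchar(names(rates))))
    stop("rates must be a named vector (one rate per treatment)")
  n_fields <- length(rates) * wells_per_treatment * fields_per_well
  field_seeds <- withr::with_seed(as.integer(seed),
                                  sample.int(.Machine$integer.max, n_fields))
  rows <- list()
  fs <- 0L
  for (tr in names(rates)) {
    for (w in seq_len(wells_per_treatment)) {
      well_id <- paste0(tr, "_w", w)
      for (f in seq_len(fields_per_well)) {
        fs <- fs + 1L
        cfg <- base_config
        cfg$nucleoli_per_nucleus_mean <- rates[[tr]]
        cfg$seed <- field_seeds[fs]
        per_nuc <- if (measure == "image") {
          out <- generateField(cfg)
          analyzeField(out$field, params)$summary
        } else {
          truth <- generateFieldTruth(cfg)
          .truthSummary(truth, cfg)
        }
        if (nrow(per_nuc)) {
          per_nuc$well <- well_id
          per_nuc$treatment <- tr
          per_nuc$field <- fs
          rows[[length(rows) + 1L]] <- per_nuc
        }
      }
    }
  }
  do.call(rbind, rows)
}

# Per-nucleus summary straight from ground truth (no pixels).
.truthSummary <- function(truth, cfg) {
  nuc <- truthNuclei(truth)
  spots <- truthNucleoli(truth)
  out <- data.frame(nucleus = nuc$nucleus, nNucleoli = 0L,
                    meanNucleolusArea = NA_real_,
                    meanNucleolusAreaUm2 = NA_real_,
                    meanNucleolusIntensity = NA_real_)
  if (nrow(spots)) {
    cnt <- tapply(spots$radiusPx, spots$nucleus, length)
    ar <- tapply(pi * spots$radiusPx^2, spots$nucleus, mean)
    am <- tapply(spots$amplitude, spots$nucleus, mean)
    ids <- match(as.integer(names(cnt)), out$nucleus)
    out$nNucleoli[ids] <- as.integer(cnt)
    out$meanNucleolusArea[ids] <- as.numeric(ar)
    out$meanNucleolusAreaUm2[ids] <- as.numeric(ar) * cfg$pixel_size_um^2
    out$meanNucleolusIntensity[ids] <- as.numeric(am)
  }
  out
}
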