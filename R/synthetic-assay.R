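# Synthetic tabular assay data (protein concentrations, scintillation
# counts, RT-PCR abundances) with the effect sizes the fractionation
# experiments report, for exercising the quantification statistics.

#' Registered assay presets
#'
#' Returns a fully specified assay preset by name, or builds a custom
#' one. A preset defines per-fraction baseline means, per-condition
#' multipliers, a coefficient of variation and a replicate count.
#'
#' Registered presets:
#' \describe{
#'   \item{`"pp242-incorporation"`}{Radiolabel incorporation (cpm) in the
#'     cytosol and cytomatrix under control and mTOR-inhibitor (pp242)
#'     conditions: treatment multiplies the cytosol by 0.80 (a 20%
#'     decrease) and the CMX by 1.50 (a 50% increase); CV 0.05, n = 5.}
#'   \item{`"fraction-split"`}{Protein amounts per fraction with true
#'     shares 70% cytosol, 15% CMX, 15% nuclear; CV 0.03, n = 6.}
#'   \item{`"18S-ratio"`}{Relative 18S rRNA abundance with a true
#'     cytosol:CMX ratio of 1.8:1; CV 0.05, n = 3.}
#' }
#'
#' @param name preset name, or any string when all parts are supplied.
#' @param means named numeric vector of per-fraction baseline means.
#' @param multipliers named list: per condition, a named numeric vector
#'   of per-fraction multipliers.
#' @param cv non-negative coefficient of variation of the multiplicative
#'   Gaussian noise.
#' @param n_replicates positive integer replicates per cell.
#' @param unit measurement unit label carried into the table.
#' @return A list of class `assayPreset`.
#' @examples
#' assayPreset("pp242-incorporation")
#' @export
assayPreset <- function(name, means = NULL, multipliers = NULL, cv = NULL,
                        n_replicates = NULL, unit = NULL) {
  preset <- switch(name,
    "pp242-incorporation" = list(
      name = name,
      means = c(cytosol = 10000, CMX = 3000),
      multipliers = list(
        control = c(cytosol = 1.00, CMX = 1.00),
        pp242 = c(cytosol = 0.80, CMX = 1.50)
      ),
      cv = 0.05, n_replicates = 5L, unit = "cpm"
    ),
    "fraction-split" = list(
      name = name,
      means = c(cytosol = 700, CMX = 150, nuclear = 150),
      multipliers = list(control = c(cytosol = 1, CMX = 1, nuclear = 1)),
      cv = 0.03, n_replicates = 6L, unit = "ug_protein"
    ),
    "18S-ratio" = list(
      name = name,
      means = c(cytosol = 1.8, CMX = 1.0),
      multipliers = list(control = c(cytosol = 1, CMX = 1)),
      cv = 0.05, n_replicates = 3L, unit = "relative_abundance"
    ),
    {
      if (is.null(means) || is.null(multipliers))
        stop("unknown preset '", name,
             "'; supply means and multipliers for a custom preset")
      list(name = name, means = means, multipliers = multipliers,
           cv = if (is.null(cv)) 0.05 else cv,
           n_replicates = if (is.null(n_replicates)) 5L else
             as.integer(n_replicates),
           unit = if (is.null(unit)) "au" else unit)
    }
  )
  # explicit arguments override registered defaults
  if (!is.null(means)) preset$means <- means
  if (!is.null(multipliers)) preset$multipliers <- multipliers
  if (!is.null(cv)) preset$cv <- cv
  if (!is.null(n_replicates)) preset$n_replicates <- as.integer(n_replicates)
  if (!is.null(unit)) preset$unit <- unit
  if (preset$cv < 0) stop("cv must be non-negative")
  if (preset$n_replicates < 1) stop("n_replicates must be positive")
  if (any(preset$means <= 0)) stop("means must be positive")
  for (m in preset$multipliers) {
    if (!all(names(m) %in% names(preset$means)))
      stop("multiplier fractions must match the preset means")
    if (any(m <= 0)) stop("multipliers must be positive")
  }
  class(preset) <- "assayPreset"
  preset
}

#' Generate a synthetic fraction table from a preset
#'
#' For every fraction and condition, draws `n_replicates` values as
#' `mean * multiplier * (1 + eps)` with `eps ~ N(0, cv)`; non-positive
#' draws are redrawn (not clipped) so means stay unbiased. The result is
#' a long-format table with columns `fraction`, `condition`,
#' `replicate`, `value`, `unit`.
#'
#' @param preset an [assayPreset()] or a preset name.
#' @param seed integer seed; equal `(preset, seed)` give identical tables.
#' @return A `data.frame` fraction table.
#' @examples
#' tab <- generateAssay("fraction-split", seed = 1)
#' head(tab)
#' @export
generateAssay <- function(preset, seed = 1L) {
  if (is.character(preset)) preset <- assayPreset(preset)
  if (!inherits(preset, "assayPreset")) stop("preset must be an assayPreset")
  withr::with_seed(as.integer(seed), {
    rows <- list()
    for (cond in names(preset$multipliers)) {
      mult <- preset$multipliers[[cond]]
      for (fr in names(mult)) {
        mu <- preset$means[[fr]] * mult[[fr]]
        vals <- numeric(preset$n_replicates)
        for (r in seq_len(preset$n_replicates)) {
          repeat {
            v <- mu * (1 + rnorm(1, sd = preset$cv))
            if (v > 0) break
          }
          vals[r] <- v
        }
        rows[[length(rows) + 1L]] <- data.frame(
          fraction = fr, condition = cond,
          replicate = seq_len(preset$n_replicates),
          value = vals, unit = preset$unit
        )
      }
    }
    do.call(rbind, rows)
  })
}
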