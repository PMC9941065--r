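# Quantification statistics for fractionation and incorporation assays:
# per-fraction percentages, percent change under treatment, abundance
# ratios, one-way ANOVA and the confirmatory two-group t-test.

.check_fraction_table <- function(table) {
  need <- c("fraction", "condition", "replicate", "value")
  if (!all(need %in% names(table)))
    stop("fraction table needs columns: ", paste(need, collapse = ", "))
  if (any(table$value <= 0)) stop("fraction table values must be positive")
  key <- paste(table$fraction, table$condition, table$replicate)
  if (anyDuplicated(key))
    stop("(fraction, condition, replicate) must be unique")
  invisible(table)
}

#' Per-fraction percentages of total
#'
#' For each replicate, each fraction's value is divided by the replicate
#' total (so per-replicate percentages sum to 100); the mean, SD and SE
#' across replicates are reported per fraction.
#'
#' @param table long-format fraction table (columns `fraction`,
#'   `condition`, `replicate`, `value`).
#' @param condition condition to analyse; default the only one present.
#' @return data.frame with `fraction`, `meanPercent`, `sdPercent`,
#'   `sePercent`, `nReplicates`.
#' @examples
#' tab <- generateAssay("fraction-split", seed = 1)
#' fractionPercentages(tab)
#' @export
fractionPercentages <- function(table, condition = NULL) {
  .check_fraction_table(table)
  if (is.null(condition)) {
    condition <- unique(table$condition)
    if (length(condition) != 1)
      stop("several conditions present; specify one")
  }
  sub <- table[table$condition == condition, ]
  if (!nrow(sub)) stop("condition '", condition, "' not present")
  fractions <- sort(unique(sub$fraction))
  reps <- sort(unique(sub$replicate))
  pct <- matrix(NA_real_, length(reps), length(fractions),
                dimnames = list(reps, fractions))
  for (i in seq_along(reps)) {
    ri <- sub[sub$replicate == reps[i], ]
    if (!setequal(ri$fraction, fractions))
      stop("replicate ", reps[i], " is missing a fraction")
    tot <- sum(ri$value)
    pct[i, ri$fraction] <- 100 * ri$value / tot
  }
  data.frame(
    fraction = fractions,
    meanPercent = colMeans(pct),
    sdPercent = apply(pct, 2, sd),
    sePercent = apply(pct, 2, sd) / sqrt(length(reps)),
    nReplicates = length(reps),
    row.names = NULL
  )
}

#' Percent change of a fraction between conditions
#'
#' `100 * (mean_treated - mean_control) / mean_control`, using group
#' means (the bar-plot arithmetic), signed: a 0.8x treatment effect
#' reads -20, a 1.5x effect +50.
#'
#' @param table long-format fraction table.
#' @param fraction fraction to compare.
#' @param control_condition,treated_condition condition labels.
#' @return Signed percent change (scalar).
#' @examples
#' tab <- generateAssay("pp242-incorporation", seed = 1)
#' percentChange(tab, "cytosol", "control", "pp242")
#' @export
percentChange <- function(table, fraction, control_condition,
                          treated_condition) {
  .check_fraction_table(table)
  a <- table$value[table$fraction == fraction &
                     table$condition == control_condition]
  b <- table$value[table$fraction == fraction &
                     table$condition == treated_condition]
  if (!length(a) || !length(b))
    stop("both conditions must be present for fraction '", fraction, "'")
  100 * (mean(b) - mean(a)) / mean(a)
}

#' Abundance ratio between two fractions
#'
#' Ratio of group means `mean(fraction_a) / mean(fraction_b)` within one
#' condition (e.g. the cytosol:CMX 18S rRNA ratio).
#'
#' @param table long-format fraction table.
#' @param fraction_a,fraction_b fraction labels (numerator, denominator).
#' @param condition condition to analyse; default the only one present.
#' @return Ratio (scalar).
#' @examples
#' tab <- generateAssay("18S-ratio", seed = 1)
#' abundanceRatio(tab, "cytosol", "CMX")
#' @export
abundanceRatio <- function(table, fraction_a, fraction_b, condition = NULL) {
  .check_fraction_table(table)
  if (is.null(condition)) {
    condition <- unique(table$condition)
    if (length(condition) != 1)
      stop("several conditions present; specify one")
  }
  sub <- table[table$condition == condition, ]
  a <- sub$value[sub$fraction == fraction_a]
  b <- sub$value[sub$fraction == fraction_b]
  if (!length(a) || !length(b)) stop("both fractions must be present")
  mean(a) / mean(b)
}

#' One-way ANOVA
#'
#' Classic fixed-effects one-way ANOVA: `F = MSB / MSW` with
#' `df = (k - 1, N - k)`, p from the upper tail of the F distribution
#' (delegated to `stats::oneway.test(var.equal = TRUE)`). Degenerate
#' inputs are handled explicitly: zero within-group variance with
#' non-zero between-group variance gives `F = Inf, p = 0` with a
#' warning; all-identical data are an error.
#'
#' @param groups list of two or more numeric vectors, each of length at
#'   least two. Names become group labels.
#' @return List of class `cytophaseAnova` with `F`, `df_between`,
#'   `df_within`, `p`, `group_means`.
#' @examples
#' oneWayAnova(list(a = c(1, 2, 3), b = c(2, 3, 4), c = c(3, 4, 5)))
#' @export
oneWayAnova <- function(groups) {
  if (!is.list(groups) || length(groups) < 2)
    stop("need at least two groups")
  if (any(vapply(groups, length, 1L) < 2))
    stop("every group needs at least two observations")
  k <- length(groups)
  N <- sum(lengths(groups))
  means <- vapply(groups, mean, numeric(1))
  grand <- mean(unlist(groups))
  ssb <- sum(lengths(groups) * (means - grand)^2)
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  if (ssw == 0 && ssb == 0)
    stop("all observations identical; ANOVA undefined")
  res <- if (ssw == 0) {
    warning("zero within-group variance; F is infinite")
    list(F = Inf, p = 0)
  } else {
    x <- unlist(groups, use.names = FALSE)
    g <- factor(rep(seq_len(k), lengths(groups)))
    ow <- oneway.test(x ~ g, var.equal = TRUE)
    list(F = unname(ow$statistic), p = unname(ow$p.value))
  }
  structure(list(F = res$F, df_between = k - 1L, df_within = N - k,
                 p = res$p, group_means = means),
            class = "cytophaseAnova")
}

#' @export
print.cytophaseAnova <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.4g, p = %.4g\n",
              x$df_between, x$df_within, x$F, x$p))
  cat("Group means:\n")
  print(x$group_means)
  invisible(x)
}

#' Two-group t-test (Welch by default)
#'
#' Welch's t statistic with Welch-Satterthwaite degrees of freedom
#' (robust to unequal variances), or the pooled-variance Student test
#' with `pooled = TRUE`. Delegated to `stats::t.test()`; both samples
#' constant with equal means is an explicit error.
#'
#' @param a,b numeric samples, each of length at least two.
#' @param pooled use the equal-variance (pooled) statistic.
#' @return List with `t`, `df`, `p`.
#' @export
welchTTest <- function(a, b, pooled = FALSE) {
  if (length(a) < 2 || length(b) < 2)
    stop("both samples need at least two observations")
  if (sd(a) == 0 && sd(b) == 0)
    stop("both samples constant; t statistic undefined")
  res <- t.test(a, b, var.equal = pooled)
  list(t = unname(res$statistic), df = unname(res$parameter),
       p = unname(res$p.value))
}
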