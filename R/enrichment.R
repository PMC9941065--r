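# DEG significance filter, hypergeometric over-representation analysis
# with Benjamini-Hochberg adjustment, and the RNA-seq/Ribo-seq Venn
# concordance computations.

.check_deg_table <- function(table) {
  need <- c("gene_id", "log2fc", "fdr")
  if (!all(need %in% names(table)))
    stop("DEG table needs columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(table$gene_id)) stop("gene_ids must be unique")
  if (any(table$fdr < 0 | table$fdr > 1)) stop("fdr must lie in [0, 1]")
  invisible(table)
}

#' Call differentially expressed genes
#'
#' Applies the significance rule: a gene is up if its fold change
#' exceeds `fc_threshold` (`2^log2fc > fc_threshold`) and its FDR is
#' strictly below `fdr_threshold`; down analogously with `2^(-log2fc)`.
#' Both inequalities are strict.
#'
#' @param table data.frame with columns `gene_id`, `log2fc`, `fdr`.
#' @param fc_threshold positive linear fold-change threshold
#'   (default 1.5).
#' @param fdr_threshold FDR cutoff (default 0.05).
#' @return List with character vectors `up` and `down` (always
#'   disjoint).
#' @examples
#' tab <- data.frame(gene_id = c("A", "B"), log2fc = c(0.6, -1),
#'                   fdr = c(0.04, 0.2))
#' callDegs(tab)
#' @export
callDegs <- function(table, fc_threshold = 1.5, fdr_threshold = 0.05) {
  .check_deg_table(table)
  if (fc_threshold <= 0 || fdr_threshold <= 0)
    stop("thresholds must be positive")
  sig <- table$fdr < fdr_threshold
  list(
    up = table$gene_id[sig & 2^table$log2fc > fc_threshold],
    down = table$gene_id[sig & 2^(-table$log2fc) > fc_threshold]
  )
}

#' Hypergeometric over-representation test for one gene set
#'
#' Upper-tail hypergeometric probability `P(X >= k)` of observing at
#' least `k` query genes inside the set, with the set and the query both
#' intersected with the declared universe first. Computed with
#' `stats::phyper` (numerically safe tail).
#'
#' @param query character vector of query gene ids.
#' @param gene_set character vector of set member ids.
#' @param universe character vector, the genes tested (must be
#'   non-empty).
#' @return List with `k` (overlap), `K` (set size in universe),
#'   `n` (query size in universe), `N` (universe size), `p`.
#' @examples
#' u <- as.character(1:10)
#' hypergeometricOra(u[1:3], u[1:4], u)
#' @export
hypergeometricOra <- function(query, gene_set, universe) {
  universe <- unique(universe)
  if (!length(universe)) stop("universe must be non-empty")
  query <- intersect(unique(query), universe)
  gs <- intersect(unique(gene_set), universe)
  N <- length(universe)
  K <- length(gs)
  n <- length(query)
  k <- length(intersect(query, gs))
  p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  list(k = k, K = K, n = n, N = N, p = p)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment: `q(i) = min_{j >= i} p(j) * m / j` over the
#' rank order, clipped at 1, returned in the input order (delegates to
#' `stats::p.adjust(method = "BH")` after validating the inputs).
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return Adjusted q-values in the input order.
#' @export
bhAdjust <- function(p) {
  if (!is.numeric(p)) stop("p must be numeric")
  if (any(is.na(p)) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Gene-set collection
#'
#' Bundles named gene sets with the declared universe. Sets may contain
#' ids outside the universe; [runOra()] intersects with the universe
#' before sizing and reports how many ids were dropped.
#'
#' @param sets named list of character vectors.
#' @param universe character vector of tested gene ids.
#' @return A list of class `geneSetCollection`.
#' @export
geneSetCollection <- function(sets, universe) {
  if (!length(sets) || is.null(names(sets)) || any(!nzchar(names(sets))))
    stop("sets must be a non-empty named list")
  if (!length(universe)) stop("universe must be non-empty")
  structure(list(sets = sets, universe = unique(universe)),
            class = "geneSetCollection")
}

#' Read a GMT gene-set file
#'
#' Tab-separated: set name, description, member ids.
#'
#' @param path path to a `.gmt` file.
#' @return Named list of character vectors.
#' @export
readGmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' Over-representation analysis across a collection
#'
#' Runs [hypergeometricOra()] for every set in the collection, adjusts
#' across all sets with [bhAdjust()], and returns results sorted by p
#' ascending with ties broken by set name.
#'
#' @param query character vector of query gene ids (non-empty).
#' @param collection a [geneSetCollection()].
#' @return data.frame with columns `set`, `k`, `K`, `n`, `N`, `p`, `q`.
#' @export
runOra <- function(query, collection) {
  if (!length(query)) stop("query must be non-empty")
  if (!inherits(collection, "geneSetCollection"))
    stop("collection must be a geneSetCollection")
  dropped <- sum(vapply(collection$sets, function(s)
    length(setdiff(s, collection$universe)), numeric(1)))
  if (dropped > 0)
    message(dropped, " set member id(s) outside the universe were dropped")
  rows <- lapply(names(collection$sets), function(nm) {
    r <- hypergeometricOra(query, collection$sets[[nm]], collection$universe)
    data.frame(set = nm, k = r$k, K = r$K, n = r$n, N = r$N, p = r$p)
  })
  out <- do.call(rbind, rows)
  out$q <- bhAdjust(out$p)
  out[order(out$p, out$set), , drop = FALSE]
}

#' RNA-seq/Ribo-seq Venn concordance
#'
#' Region counts of the two-set Venn diagram plus the share of
#' transcriptionally upregulated genes lacking a ribosome-footprint
#' call. The denominator is `|rna_up|` by default; `"union"` divides by
#' the union size instead (the choice is exposed because printed
#' summary fractions do not pin it down).
#'
#' @param rna_up,ribo_up character vectors of upregulated gene ids from
#'   RNA-seq and Ribo-seq over a shared id space.
#' @param denominator `"rna"` (default) or `"union"`.
#' @return List with `rna_only`, `common`, `ribo_only` (counts) and
#'   `fraction_transcribed_not_translated`; 0 with a warning when the
#'   denominator set is empty.
#' @examples
#' vennConcordance(letters[1:10], letters[3:12])
#' @export
vennConcordance <- function(rna_up, ribo_up,
                            denominator = c("rna", "union")) {
  denominator <- match.arg(denominator)
  rna_up <- unique(rna_up)
  ribo_up <- unique(ribo_up)
  common <- length(intersect(rna_up, ribo_up))
  rna_only <- length(setdiff(rna_up, ribo_up))
  ribo_only <- length(setdiff(ribo_up, rna_up))
  denom <- switch(denominator,
                  rna = length(rna_up),
                  union = rna_only + common + ribo_only)
  frac <- if (denom == 0) {
    warning("empty denominator set; fraction reported as 0")
    0
  } else rna_only / denom
  list(rna_only = rna_only, common = common, ribo_only = ribo_only,
       fraction_transcribed_not_translated = frac)
}
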