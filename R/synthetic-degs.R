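# Synthetic DEG universes with controlled RNA-seq/Ribo-seq overlap
# structure, emulating the Venn comparisons of up/downregulated
# transcript sets between transcriptome and translatome.

#' Configuration for a synthetic DEG universe
#'
#' Either `overlap_count` or `fraction_transcribed_not_translated` must
#' be given; the fraction `f` sets `overlap_count =
#' round(n_rna_up * (1 - f))`.
#'
#' @param universe_size positive integer, number of genes tested.
#' @param n_rna_up non-negative count of transcriptionally upregulated
#'   genes (RNA-seq calls).
#' @param n_ribo_up non-negative count of translationally upregulated
#'   genes (Ribo-seq calls).
#' @param overlap_count genes called up by both assays.
#' @param fraction_transcribed_not_translated alternative to
#'   `overlap_count`: share of RNA-seq-up genes lacking a Ribo-seq call.
#' @param seed integer seed.
#' @return A validated list of class `degSimConfig`.
#' @export
degSimConfig <- function(universe_size, n_rna_up, n_ribo_up,
                         overlap_count = NULL,
                         fraction_transcribed_not_translated = NULL,
                         seed = 1L) {
  if (is.null(overlap_count)) {
    if (is.null(fraction_transcribed_not_translated))
      stop("supply overlap_count or fraction_transcribed_not_translated")
    f <- fraction_transcribed_not_translated
    if (f < 0 || f > 1) stop("fraction must lie in [0, 1]")
    overlap_count <- round(n_rna_up * (1 - f))
  }
  cfg <- list(universe_size = as.integer(universe_size),
              n_rna_up = as.integer(n_rna_up),
              n_ribo_up = as.integer(n_ribo_up),
              overlap_count = as.integer(overlap_count),
              seed = as.integer(seed))
  with(cfg, {
    if (universe_size < 1) stop("universe_size must be positive")
    if (n_rna_up < 0 || n_ribo_up < 0 || overlap_count < 0)
      stop("counts must be non-negative")
    if (overlap_count > min(n_rna_up, n_ribo_up))
      stop("overlap_count exceeds min(n_rna_up, n_ribo_up)")
    if (n_rna_up > universe_size || n_ribo_up > universe_size ||
        n_rna_up + n_ribo_up - overlap_count > universe_size)
      stop("counts exceed the universe size")
  })
  class(cfg) <- "degSimConfig"
  cfg
}

#' Generate a gene universe with controlled RNA/Ribo overlap
#'
#' Draws gene ids without replacement so that the Venn region sizes
#' (RNA-only, shared, Ribo-only) match the configuration exactly;
#' deterministic per seed.
#'
#' @param config a [degSimConfig()].
#' @return List with character vectors `universe`, `rna_up`, `ribo_up`.
#' @examples
#' cfg <- degSimConfig(1000, 200, 180, overlap_count = 168, seed = 1)
#' sets <- generateDegUniverse(cfg)
#' length(intersect(sets$rna_up, sets$ribo_up))  # 168
#' @export
generateDegUniverse <- function(config) {
  if (!inherits(config, "degSimConfig")) stop("config must be a degSimConfig")
  withr::with_seed(config$seed, {
    universe <- sprintf("g%05d", seq_len(config$universe_size))
    shared <- sample(universe, config$overlap_count)
    rest <- setdiff(universe, shared)
    rna_only <- sample(rest, config$n_rna_up - config$overlap_count)
    rest <- setdiff(rest, rna_only)
    ribo_only <- sample(rest, config$n_ribo_up - config$overlap_count)
    list(universe = universe,
         rna_up = sort(c(shared, rna_only)),
         ribo_up = sort(c(shared, ribo_only)))
  })
}
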