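five_gene_fixture <- data.frame(
  gene_id = c("A", "B", "C", "D", "E"),
  log2fc = c(0.60, 0.50, -1.00, 2.00, 0.00),
  fdr = c(0.04, 0.01, 0.049, 0.050, 1.0)
)

test_that("the DEG filter applies strict fold-change and FDR thresholds", {
  res <- callDegs(five_gene_fixture)
  expect_identical(res$up, "A")     # 2^0.6 = 1.516 > 1.5, fdr 0.04 < 0.05
  expect_identical(res$down, "C")   # 2^1 = 2 > 1.5, fdr 0.049 < 0.05
  # B fails fold change (1.41), D fails the strict FDR, E fails both

  empty <- callDegs(five_gene_fixture[0, ])
  expect_length(empty$up, 0)
  expect_length(empty$down, 0)

  # threshold-degenerate case: fc = 1 calls every significant non-flat gene
  loose <- callDegs(five_gene_fixture, fc_threshold = 1)
  expect_setequal(c(loose$up, loose$down), c("A", "B", "C"))

  bad <- five_gene_fixture
  bad$fdr[1] <- 1.5
  expect_error(callDegs(bad), "\\[0, 1\\]")
  dup <- rbind(five_gene_fixture, five_gene_fixture[1, ])
  expect_error(callDegs(dup), "unique")
})

test_that("up and down calls are always disjoint", {
  withr::with_seed(12, {
    for (rep in 1:10) {
      tab <- data.frame(gene_id = sprintf("g%03d", 1:100),
                        log2fc = rnorm(100, sd = 1.5),
                        fdr = runif(100))
      res <- callDegs(tab)
      expect_length(intersect(res$up, res$down), 0)
    }
  })
})

test_that("hypergeometric tail matches exhaustive enumeration", {
  # worked example: N = 10, K = 4, n = 3, k = 2 -> 40/120 = 1/3
  u <- sprintf("u%02d", 1:10)
  res <- hypergeometricOra(c(u[1:2], u[5]), u[1:4], u)
  expect_identical(res$k, 2L)
  expect_equal(res$p, 1 / 3)

  # exhaustive small-instance oracle over every (N <= 12, K, n, k)
  for (N in 2:12) {
    ids <- sprintf("g%02d", 1:N)
    for (K in 0:N) {
      for (n in 0:N) {
        for (k in max(0, K + n - N):min(K, n)) {
          query <- c(ids[seq_len(k)],
                     if (n > k) ids[K + seq_len(n - k)])
          got <- hypergeometricOra(query, ids[seq_len(K)], ids)
          expect_identical(got$k, as.integer(k))
          expect_equal(got$p, enum_hyper_tail(k, K, n, N), tolerance = 1e-12)
        }
      }
    }
  }
})

test_that("hypergeometric edge cases", {
  u <- letters[1:10]
  expect_equal(hypergeometricOra(u[5:7], u[1:2], u)$p, 1)  # k = 0
  full <- hypergeometricOra(u, u[1:4], u)
  expect_identical(full$k, full$K)
  expect_equal(full$p, 1)
  expect_error(hypergeometricOra("a", "a", character(0)), "non-empty")
})

test_that("BH adjustment matches step-up hand computations", {
  expect_equal(bhAdjust(0.02), 0.02)
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bhAdjust(c(0.05, 0.05, 0.05)), c(0.05, 0.05, 0.05))
  # input order restored
  expect_equal(bhAdjust(c(0.03, 0.01, 0.02)), c(0.03, 0.03, 0.03))
  # q >= p and monotone in rank order
  withr::with_seed(7, {
    p <- runif(20)
    q <- bhAdjust(p)
    expect_true(all(q >= p))
    o <- order(p)
    expect_true(all(diff(q[o]) >= -1e-12))
    expect_true(all(q <= 1))
  })
  expect_error(bhAdjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("collection-level ORA ranks a spiked set first", {
  cfg <- degSimConfig(500, 60, 50, overlap_count = 40, seed = 4)
  sets <- generateDegUniverse(cfg)
  query <- sets$rna_up
  spiked <- withr::with_seed(10, sample(query, 30))
  collection <- geneSetCollection(
    sets = list(
      spiked = spiked,
      random1 = sprintf("g%05d", 1:40),
      random2 = sprintf("g%05d", 201:260)
    ),
    universe = sets$universe
  )
  res <- runOra(query, collection)
  expect_identical(res$set[1], "spiked")
  expect_true(all(res$q >= res$p))
  expect_equal(res$q, bhAdjust(res$p))  # rows already sorted by p

  # a single-set collection has q = p
  single <- runOra(query, geneSetCollection(list(s = spiked), sets$universe))
  expect_equal(single$q, single$p)

  # a set disjoint from the universe: K = 0, k = 0, p = 1
  disjoint <- geneSetCollection(list(out = c("x1", "x2")), sets$universe)
  suppressMessages(resd <- runOra(query, disjoint))
  expect_identical(resd$K, 0L)
  expect_identical(resd$k, 0L)
  expect_equal(resd$p, 1)
})

test_that("ORA p-values are invariant to relabelling gene ids", {
  cfg <- degSimConfig(200, 30, 25, overlap_count = 20, seed = 6)
  sets <- generateDegUniverse(cfg)
  collection <- geneSetCollection(
    list(a = sets$ribo_up, b = sets$universe[1:50]), sets$universe)
  res1 <- runOra(sets$rna_up, collection)
  relabel <- setNames(sprintf("new%05d", seq_along(sets$universe)),
                      sets$universe)
  collection2 <- geneSetCollection(
    list(a = unname(relabel[sets$ribo_up]),
         b = unname(relabel[sets$universe[1:50]])),
    unname(relabel[sets$universe]))
  res2 <- runOra(unname(relabel[sets$rna_up]), collection2)
  expect_equal(res1$p, res2$p)
  expect_equal(res1$k, res2$k)
})

test_that("Venn concordance computes region counts and the lost fraction", {
  same <- vennConcordance(letters[1:5], letters[1:5])
  expect_equal(same$fraction_transcribed_not_translated, 0)
  expect_identical(same$common, 5L)

  disj <- vennConcordance(letters[1:5], letters[6:10])
  expect_equal(disj$fraction_transcribed_not_translated, 1)

  cfg <- degSimConfig(1000, 200, 180, overlap_count = 168, seed = 1)
  sets <- generateDegUniverse(cfg)
  v <- vennConcordance(sets$rna_up, sets$ribo_up)
  expect_identical(v$rna_only, 32L)
  expect_identical(v$common, 168L)
  expect_identical(v$ribo_only, 12L)
  expect_equal(v$fraction_transcribed_not_translated, 0.16)

  expect_warning(z <- vennConcordance(character(0), letters[1:3]), "empty")
  expect_equal(z$fraction_transcribed_not_translated, 0)
})

test_that("GMT files round-trip through the reader", {
  path <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("setA\tdesc\tg1\tg2\tg3", "setB\tdesc\tg2\tg4"), path)
  sets <- readGmt(path)
  expect_identical(sets$setA, c("g1", "g2", "g3"))
  expect_identical(sets$setB, c("g2", "g4"))
})
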