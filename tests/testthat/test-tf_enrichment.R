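test_that("promoter windows reflect strand orientation and biotype", {
  genes <- data.frame(gene_id = c("plus", "minus", "linc"),
                      chrom = "chr1",
                      start = c(5000, 4000, 20000),
                      end = c(6000, 5001, 21000),
                      strand = c("+", "-", "+"),
                      biotype = c("protein_coding", "protein_coding", "lincRNA"),
                      stringsAsFactors = FALSE)
  ann <- toy_annotation(genes, c(chr1 = 50000))   # TSS: 5000 (+), 5000 (-)
  w <- promoter_windows(ann, upstream = 1000, downstream = 0)
  expect_setequal(w$gene_id, c("plus", "minus"))  # lincRNA filtered out
  wp <- w[w$gene_id == "plus", ]
  wm <- w[w$gene_id == "minus", ]
  expect_equal(c(wp$start, wp$end), c(4000, 5000))
  expect_equal(c(wm$start, wm$end), c(5001, 6001)) # reflected on forward axis
  w_all <- promoter_windows(ann, biotype = NULL)
  expect_equal(nrow(w_all), 3)
})

test_that("random peaks conserve count and widths and are seed-stable", {
  peaks <- data.frame(chrom = "chrA",
                      start = c(0, 100, 5000), end = c(300, 600, 5200))
  sizes <- c(chrA = 100000, chrB = 50000)
  r1 <- random_peaks(peaks, sizes, seed = 4)
  expect_equal(nrow(r1), 3)
  expect_equal(sort(r1$end - r1$start), sort(peaks$end - peaks$start))
  expect_true(all(r1$end <= sizes[r1$chrom]))
  expect_identical(random_peaks(peaks, sizes, seed = 4), r1)
  expect_error(random_peaks(data.frame(chrom = "c", start = 0, end = 2e5),
                            sizes, seed = 1), "wider than every chromosome")
})

test_that("null placement hits promoters at the binomial-expected rate", {
  ann <- make_genome(40, 2e6, seed = 2, lincRNA_fraction = 0)
  windows <- promoter_windows(ann)
  peaks <- data.frame(chrom = "chr1", start = seq(0, by = 350, length.out = 30))
  peaks$end <- peaks$start + 300
  hits <- 0
  n_trials <- 0
  for (seed in 1:50) {
    rp <- random_peaks(peaks, ann$chrom_sizes, seed = seed)
    hits <- hits + sum(vapply(seq_len(nrow(rp)), function(i) {
      any(iv_overlaps_test(rp$start[i], rp$end[i], windows$start, windows$end))
    }, logical(1)))
    n_trials <- n_trials + nrow(rp)
  }
  # P(single peak hits any 1-kb window) with width adjustment
  w <- 300
  p_hit <- sum(windows$end - windows$start + w - 1) / (ann$chrom_sizes[[1]] - w + 1)
  expected <- n_trials * p_hit
  sd3 <- 3 * sqrt(n_trials * p_hit * (1 - p_hit))
  expect_lt(abs(hits - expected), sd3)
})

test_that("promoter hit counting uses half-open >=1 bp overlap per gene", {
  windows <- data.frame(gene_id = c("g1", "g2"), chrom = "chr1",
                        start = c(1000, 5000), end = c(2000, 6000),
                        strand = "+", stringsAsFactors = FALSE)
  inside <- data.frame(chrom = "chr1", start = 1200, end = 1300)
  expect_equal(unname(overlap_counts(inside, windows, c("g1", "g2"))), c(1, 1))
  touching <- data.frame(chrom = "chr1", start = 2000, end = 2100)
  expect_equal(unname(overlap_counts(touching, windows, c("g1", "g2"))[1]), 0)
})

test_that("two peaks in one promoter count once; missing windows warn", {
  windows <- data.frame(gene_id = "g1", chrom = "chr1",
                        start = 1000, end = 2000, strand = "+",
                        stringsAsFactors = FALSE)
  two <- data.frame(chrom = "chr1", start = c(1100, 1500), end = c(1200, 1600))
  expect_equal(unname(overlap_counts(two, windows, "g1")), c(1, 0))
  expect_warning(res <- overlap_counts(two, windows, c("g1", "ghost")),
                 "without a promoter window")
  expect_equal(unname(res), c(1, 0))
})

test_that("one-sided Fisher matches enumeration, the library test and edge cases", {
  r <- fisher_one_sided(matrix(c(5, 1, 5, 9), 2, 2))
  expect_equal(r$p_one_sided, 2730 / 38760, tolerance = 1e-12)
  expect_equal(r$odds, 9)
  expect_equal(r$intersection_size, 5)

  r2 <- fisher_one_sided(matrix(c(10, 0, 0, 10), 2, 2))
  expect_equal(r2$p_one_sided, 1 / choose(20, 10), tolerance = 1e-15)
  expect_equal(r2$odds, Inf)

  expect_equal(fisher_one_sided(c(0, 10, 5, 5))$p_one_sided, 1)
  expect_error(fisher_one_sided(c(-1, 2, 3, 4)), "negative")

  # exhaustive enumeration oracle over all tables with N <= 40
  worst <- 0
  for (N in c(5, 12, 23, 40)) {
    for (a in 0:N) for (b in 0:(N - a)) for (c in 0:(N - a - b)) {
      d <- N - a - b - c
      got <- fisher_one_sided(c(a, b, c, d))$p_one_sided
      worst <- max(worst, abs(got - oracle_fisher_p(a, b, c, d)))
    }
  }
  expect_lt(worst, 1e-12)

  # cross-check against the standard implementation on random tables
  set.seed(8)
  for (i in 1:25) {
    tb <- matrix(rpois(4, 8), 2, 2)
    expect_equal(fisher_one_sided(tb)$p_one_sided,
                 fisher.test(tb, alternative = "greater")$p.value,
                 tolerance = 1e-10)
  }
})

test_that("one-sided p-values are super-uniform under the null", {
  set.seed(19)
  ps <- replicate(1000, {
    a <- rbinom(1, 30, 0.3)
    c <- rbinom(1, 30, 0.3)
    fisher_one_sided(c(a, 30 - a, c, 30 - c))$p_one_sided
  })
  for (alpha in c(0.05, 0.01)) {
    slack <- 2 * sqrt(alpha * (1 - alpha) / 1000)
    expect_lte(mean(ps <= alpha), alpha + slack)
  }
})

test_that("enrichment flags the top-right scatter area", {
  res <- list(
    up = fisher_one_sided(c(40, 10, 5, 45)),
    flat = fisher_one_sided(c(10, 40, 10, 40)))
  tab <- enrichment_scatter(res, odds_min = 2, logp_min = 3)
  expect_true(tab$enriched[tab$tf == "up"])
  expect_false(tab$enriched[tab$tf == "flat"])
  all_in <- enrichment_scatter(res, odds_min = 0, logp_min = 0)
  expect_true(all(all_in$enriched))
  p1 <- enrichment_scatter(list(x = fisher_one_sided(c(0, 10, 0, 10))),
                           odds_min = 0, logp_min = 0.5)
  expect_false(p1$enriched)
})

test_that("a planted enriched TF separates from background binding", {
  ann <- make_genome(80, 3e6, seed = 13, lincRNA_fraction = 0)
  windows <- promoter_windows(ann)
  gene_set <- windows$gene_id[1:25]
  gs <- windows[windows$gene_id %in% gene_set, ]
  set.seed(99)
  hit_idx <- sample(nrow(gs), 20)   # peaks in 80% of gene-set promoters
  planted <- data.frame(chrom = gs$chrom[hit_idx],
                        start = gs$start[hit_idx] + 100)
  planted$end <- planted$start + 200
  r <- tf_promoter_enrichment(planted, ann, gene_set, seed = 7)
  expect_gte(r$odds, 2)
  expect_gte(-log10(r$p_one_sided), 3)
})
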