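# SNP-matching baseline: key computation, pool expansion, the matched test.

dist_bin_oracle <- function(d, breaks = c(1000, 2000, 5000, 1e4, 2e4, 1e5)) {
  sum(d > breaks) + 1L
}

toy_genes <- function() {
  as_gene_table(data.frame(
    chrom = c("chr1", "chr1", "chr2"), strand = c("+", "-", "+"),
    tx_start = c(10000, 60000, 5000), tx_end = c(20000, 90000, 9000),
    exon_starts = c("10000", "60000", "5000"),
    exon_ends = c("20000", "90000", "9000"),
    name = c("gA", "gB", "gC"), stringsAsFactors = FALSE))
}

test_that("match keys bin GEN, MAF, TSS and TES as specified", {
  genes <- toy_genes()
  v <- data.frame(chrom = c("chr1", "chr1", "chr1", "chr3"),
                  pos = c(10300, 9700, 15000, 100),
                  maf = c(0.07, 0.02, 0.49, 0.12),
                  stringsAsFactors = FALSE)
  k <- compute_match_key(v, genes = genes,
                         active_axes = c("gen", "maf", "tss", "tes"))
  # 300 bp from the nearest TSS (gA at 10000): first bin
  expect_equal(k$tss[1], 1L)
  expect_equal(k$tss[2], 1L)
  # maf 0.07 lands in the second 5% bin [0.05, 0.10)
  expect_equal(k$maf, c(2L, 1L, 10L, 3L))
  expect_equal(k$gen, c(TRUE, FALSE, TRUE, FALSE))
  # chromosome without genes: sentinel terminal bins
  expect_equal(k$tss[4], 7L)
  expect_equal(k$tes[4], 7L)
  # TES of the gene with the nearest TSS: gA TES at 19999
  expect_equal(k$tes[3], dist_bin_oracle(19999 - 15000))
})

test_that("match keys equal a brute-force nearest-TSS/TES scan on random variants", {
  genes <- toy_genes()
  tss <- c(10000, 89999, 5000)
  tes <- c(19999, 60000, 8999)
  gchrom <- c("chr1", "chr1", "chr2")
  withr::with_seed(53, {
    v <- data.frame(chrom = sample(c("chr1", "chr2"), 40, replace = TRUE),
                    pos = sample.int(120000, 40), maf = runif(40, 0, 0.5),
                    stringsAsFactors = FALSE)
  })
  k <- compute_match_key(v, genes = genes,
                         active_axes = c("gen", "tss", "tes"))
  for (i in seq_len(nrow(v))) {
    on_chr <- which(gchrom == v$chrom[i])
    dists <- abs(v$pos[i] - tss[on_chr])
    j <- on_chr[which.min(dists)]
    expect_equal(k$tss[i], dist_bin_oracle(min(dists),
                                           c(500, 2000, 5000, 1e4, 2e4, 1e5)))
    expect_equal(k$tes[i], dist_bin_oracle(abs(v$pos[i] - tes[j])))
  }
})

test_that("pools expand along the LD axis only, by the 20-candidate rule", {
  # 19 panel variants at ld 3, 5 more at ld 4: widened pool of 24
  panel_keys <- data.frame(ld = c(rep(3L, 19), rep(4L, 5), rep(9L, 30)),
                           key = "all", stringsAsFactors = FALSE)
  pools <- annoshift:::build_match_pools(panel_keys)
  cand <- annoshift:::match_candidates(pools, "all", 3L, 20, "rs1")
  expect_length(cand, 24L)
  # a pool that can never reach 20 errors out naming the SNP
  small <- data.frame(ld = rep(1L, 7), key = "all", stringsAsFactors = FALSE)
  expect_error(
    annoshift:::match_candidates(annoshift:::build_match_pools(small),
                                 "all", 1L, 20, "rs77"),
    "rs77")
  # fixed axes never relax: an unseen key is an error
  expect_error(annoshift:::match_candidates(pools, "other", 1L, 20, "rs9"),
               "rs9")
})

test_that("matched sets are seed-reproducible and avoid within-set reuse", {
  panel_keys <- data.frame(ld = rep(c(2L, 3L), each = 25), key = "all",
                           stringsAsFactors = FALSE)
  test_keys <- data.frame(ld = rep(2L, 10), key = "all",
                          stringsAsFactors = FALSE)
  a <- sample_matched_set(test_keys, panel_keys, seed = 5)
  b <- sample_matched_set(test_keys, panel_keys, seed = 5)
  expect_identical(a, b)
  expect_equal(anyDuplicated(a), 0L)
  c2 <- sample_matched_set(test_keys, panel_keys, seed = 6)
  expect_false(identical(a, c2))
})

test_that("self-matching panels and degenerate annotations give p near 1", {
  g <- test_genome("default")
  ld <- genome_ld(g)
  withr::with_seed(59, {
    sub <- sample(nrow(g$panel$variants), 40)
  })
  # keep (chrom, pos) order so the subset panel preserves row alignment
  sub <- sub[order(g$panel$variants$chrom[sub], g$panel$variants$pos[sub])]
  ids <- g$panel$variants$id[sub]
  # panel restricted to the test SNPs themselves (single shared key):
  # every null set is a permutation of the test set, so p = 1 exactly
  pk <- data.frame(key = "all", stringsAsFactors = FALSE)[rep(1, 40), , drop = FALSE]
  ov <- annoshift:::panel_overlap_vector(g$panel, ld,
                                         annoshift:::track_index(g$tracks$x))
  spanel <- hap_panel(g$panel$variants[sub, ], g$panel$hap[, sub])
  # proxies outside the subset are irrelevant here; drop them so indices
  # stay within the subset panel
  sld <- list(proxies = rep(list(integer(0)), 40), r2 = rep(list(numeric(0)), 40),
              ld_count = ld$ld_count[sub], r2_threshold = 0.8, window = 1e4)
  r <- matching_test(ids, spanel, g$tracks$x, n_sets = 50,
                     active_axes = "maf", ld = sld,
                     panel_keys = pk, panel_overlap = ov[sub],
                     min_candidates = 20, seed = 3)
  expect_equal(r$p_value, 1)

  # annotation covering everything, or nothing: p = 1 either way
  whole <- merge_track(annot_track(g$chromosomes$chrom,
                                   rep(0, nrow(g$chromosomes)),
                                   g$chromosomes$length))
  r2 <- matching_test(ids, spanel, whole, n_sets = 30, active_axes = "maf",
                      ld = sld, panel_keys = pk, seed = 4)
  expect_equal(r2$p_value, 1)
  expect_equal(r2$observed_overlap, 1)
  none <- merge_track(annot_track("chrZ", 0, 1))
  r3 <- matching_test(ids, spanel, none, n_sets = 30, active_axes = "maf",
                      ld = sld, panel_keys = pk, seed = 5)
  expect_equal(r3$p_value, 1)
  expect_equal(r3$observed_overlap, 0)
})
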