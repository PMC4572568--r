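# LD computation, proxy expansion, independence pruning, tag selection.

test_that("r_squared matches the Pearson-correlation oracle and its symmetries", {
  a <- c(rep(1, 10), rep(0, 10))
  expect_equal(r_squared(a, a), 1)
  expect_equal(r_squared(a, 1 - a), 1)  # allele relabeling is sign-free

  # haplotype counts AB=4, Ab=1, aB=1, ab=4
  x <- c(rep(1, 5), rep(0, 5))
  y <- c(rep(1, 4), 0, 1, rep(0, 4))
  expect_equal(r_squared(x, y), cor(x, y)^2)
  expect_equal(r_squared(x, y), r_squared(y, x))

  withr::with_seed(4, {
    for (i in 1:20) {
      u <- rbinom(30, 1, 0.5); w <- rbinom(30, 1, 0.4)
      if (var(u) == 0 || var(w) == 0) next
      expect_equal(r_squared(u, w), cor(u, w)^2)
      expect_equal(r_squared(1 - u, w), r_squared(u, w))
    }
  })
  expect_error(r_squared(rep(1, 10), rbinom(10, 1, 0.5)), "monomorphic")
})

test_that("expand_proxies recovers a planted perfect-LD block exactly", {
  # 50 variants: one 5-variant perfect block among independent singletons
  panel <- planted_panel(c(rep(1, 20), 5, rep(1, 25)), seed = 9)
  block_ids <- panel$variants$id[21:25]
  # exhaustive pairwise oracle
  oracle <- sapply(seq_len(50), function(j) {
    if (panel$variants$id[j] == block_ids[2]) return(TRUE)
    r2 <- cor(panel$hap[, block_ids[2]], panel$hap[, j])^2
    r2 > 0.8
  })
  ps <- expand_proxies(block_ids[2], panel, r2_threshold = 0.8, window = 1e6)
  expect_setequal(ps$proxies$id, panel$variants$id[oracle])
  expect_setequal(ps$proxies$id, block_ids)
  expect_equal(ps$proxies$r2[ps$proxies$id == block_ids[2]], 1)
})

test_that("proxy expansion has strict-threshold and monotone-subset semantics", {
  panel <- planted_panel(c(3, rep(1, 10)), seed = 2)
  lone <- panel$variants$id[10]
  expect_equal(nrow(expand_proxies(lone, panel)$proxies), 1L)

  # threshold 0 with strict > still excludes r2 == 0 variants
  two <- hap_panel(data.frame(id = c("a", "b"), chrom = "chr1",
                              pos = c(0, 10), stringsAsFactors = FALSE),
                   cbind(c(1, 1, 0, 0), c(1, 0, 1, 0)))
  expect_equal(expand_proxies("a", two, r2_threshold = 0)$proxies$id, "a")

  # higher threshold yields a subset
  p1 <- expand_proxies(panel$variants$id[2], panel, r2_threshold = 0.2)
  p2 <- expand_proxies(panel$variants$id[2], panel, r2_threshold = 0.9)
  expect_true(all(p2$proxies$id %in% p1$proxies$id))
})

test_that("bulk ld_index agrees with per-variant expand_proxies", {
  panel <- planted_panel(c(4, 1, 3, 1, 1, 2), n_hap = 30, seed = 21)
  ld <- ld_index(panel, r2_threshold = 0.8, window = 1e5, chunk = 5L)
  for (i in seq_len(nrow(panel$variants))) {
    ps <- expand_proxies(panel$variants$id[i], panel,
                         r2_threshold = 0.8, window = 1e5)
    got <- sort(panel$variants$id[ld$proxies[[i]]])
    want <- sort(setdiff(ps$proxies$id, panel$variants$id[i]))
    expect_equal(got, want)
  }
})

test_that("prune_independent output satisfies both constraints", {
  # two variants 50 kb apart: one survives
  p <- planted_panel(2, spacing = 5e4, seed = 5)
  kept <- prune_independent(p$variants$id, p, seed = 1)
  expect_length(kept, 1L)

  # different chromosomes, r2 = 0: all survive
  v <- data.frame(id = c("a", "b"), chrom = c("chr1", "chr2"), pos = c(0, 0))
  withr::with_seed(8, {
    h <- cbind(rbinom(30, 1, .5), rbinom(30, 1, .5))
  })
  p2 <- hap_panel(v, h)
  expect_setequal(prune_independent(c("a", "b"), p2, seed = 1), c("a", "b"))

  # chain of 5 correlated variants 60 kb apart: survivors verified
  # pairwise-valid by an oracle re-check of both constraints
  p3 <- planted_panel(5, spacing = 6e4, seed = 6)
  kept3 <- prune_independent(p3$variants$id, p3, seed = 3)
  pos <- p3$variants$pos[match(kept3, p3$variants$id)]
  if (length(pos) > 1) {
    d <- diff(sort(pos))
    expect_true(all(d >= 1e5))
    cmb <- combn(seq_along(kept3), 2)
    for (k in seq_len(ncol(cmb))) {
      r2 <- r_squared(p3$hap[, kept3[cmb[1, k]]], p3$hap[, kept3[cmb[2, k]]])
      expect_lte(r2, 0.1 + 1e-12)
    }
  }
  expect_equal(prune_independent(character(0), p3), character(0))
})

test_that("prune_independent removes correlated pairs beyond the distance rule", {
  # plant perfect LD between two variants 200 kb apart
  withr::with_seed(12, h <- rbinom(40, 1, 0.5))
  p <- hap_panel(data.frame(id = c("a", "b"), chrom = "chr1",
                            pos = c(0, 2e5), stringsAsFactors = FALSE),
                 cbind(h, h))
  expect_length(prune_independent(c("a", "b"), p, seed = 4), 1L)
})

test_that("select_best_tag picks the argmax tag with stated fallback", {
  # block of 3 perfect proxies + weaker neighbours
  withr::with_seed(13, {
    h <- rbinom(50, 1, 0.5)
    flip1 <- ifelse(runif(50) < 0.02, 1 - h, h)   # strong tag
    flip2 <- ifelse(runif(50) < 0.25, 1 - h, h)   # weak tag
    indep <- rbinom(50, 1, 0.5)
  })
  p <- hap_panel(data.frame(id = c("f", "t1", "t2", "u"), chrom = "chr1",
                            pos = c(1000, 2000, 3000, 4000),
                            stringsAsFactors = FALSE),
                 cbind(h, flip1, flip2, indep))
  # functional variant available as its own tag
  expect_equal(select_best_tag("f", c("f", "t1"), p, r2_min = 0.8)$id, "f")
  # best among candidates, verified against the exhaustive r2 oracle
  r2s <- c(t1 = cor(h, flip1)^2, t2 = cor(h, flip2)^2)
  best <- select_best_tag("f", c("t1", "t2"), p, r2_min = 0.5)
  expect_equal(best$id, names(which.max(r2s)))
  expect_equal(best$r2, unname(max(r2s)))
  # fallback when nothing reaches the threshold
  fb <- select_best_tag("f", "u", p, r2_min = 0.8, fallback = TRUE)
  expect_equal(fb$id, "f")
  expect_true(fb$is_self)
  nt <- select_best_tag("f", "u", p, r2_min = 0.8, fallback = FALSE)
  expect_true(is.na(nt$id))
})

test_that("variants absent from the panel raise lookup errors", {
  p <- planted_panel(c(2, 1), seed = 1)
  expect_error(expand_proxies("nope", p), "not found")
})
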