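# The circular-shifting null: overlap predicate, interval rotation,
# Monte Carlo enrichment test, overlap scores.

test_that("locus overlap respects half-open interval semantics", {
  expect_true(locus_overlaps(make_locus(10, 5, c(5, 7))))
  expect_false(locus_overlaps(make_locus(10, 7, c(5, 7))))
  # random loci against the per-base membership oracle
  withr::with_seed(23, {
    for (i in 1:30) {
      L <- sample(20:60, 1)
      lo <- make_locus(L, sample.int(L, 3) - 1,
                       as.vector(t(cbind(s <- sort(sample.int(L - 5, 2)), s + 3))))
      oracle <- any(cover_intervals(lo$x_intervals, L)[lo$snp_pos + 1])
      expect_equal(locus_overlaps(lo), oracle)
    }
  })
})

test_that("shift_intervals rotates, wraps, and conserves covered bases", {
  m <- cbind(8, 10)
  expect_equal(unname(shift_intervals(m, 0, 10)), unname(cbind(8, 10)))
  expect_equal(unname(shift_intervals(m, 3, 10)), unname(cbind(1, 3)))
  # boundary-crossing interval splits into two pieces
  sp <- shift_intervals(cbind(7, 9), 2, 10)
  expect_equal(unname(sp), unname(rbind(c(0, 1), c(9, 10))))
  expect_error(shift_intervals(m, 10, 10), "out of range")
  expect_error(shift_intervals(m, -1, 10), "out of range")

  withr::with_seed(29, {
    for (i in 1:30) {
      L <- sample(15:80, 1)
      s <- sort(sample.int(L - 4, 3))
      m <- merge_track(annot_track("c", s, pmin(s + sample.int(4, 3), L)))
      m <- cbind(m$start, m$end)
      k <- sample.int(L, 1) - 1
      sh <- shift_intervals(m, k, L)
      # conservation and per-base rotation oracle
      expect_equal(sum(sh[, 2] - sh[, 1]), sum(m[, 2] - m[, 1]))
      expect_equal(cover_intervals(sh, L), rotate_cover(cover_intervals(m, L), k))
    }
  })
})

test_that("the offset-set evaluation equals explicitly shifting intervals", {
  withr::with_seed(37, {
    for (i in 1:20) {
      L <- sample(10:50, 1)
      n_snp <- sample.int(3, 1)
      s <- sort(sample.int(max(L - 6, 2), 2))
      lo <- make_locus(L, sample.int(L, n_snp) - 1,
                       as.vector(t(cbind(s, pmin(s + sample.int(5, 2), L)))))
      member <- annoshift:::points_in_bounds(0:(L - 1),
                                             annoshift:::overlap_offsets(lo)$bounds)
      explicit <- vapply(0:(L - 1), function(k) {
        sh <- shift_intervals(lo$x_intervals, k, L)
        any(cover_intervals(sh, L)[lo$snp_pos + 1])
      }, logical(1))
      expect_equal(member, explicit)
      expect_equal(locus_overlap_probability(lo), mean(explicit))
    }
  })
})

test_that("degenerate loci give the stated saturated and empty results", {
  # every locus fully covered: observed 1, all null 1, p 1, delta 0
  sat <- lapply(1:3, function(i) make_locus(10, c(2, 5), c(0, 10)))
  r <- enrichment_test(sat, n_iterations = 200, seed = 1)
  expect_equal(r$observed_overlap, 1)
  expect_true(all(r$null_overlaps == 1))
  expect_equal(r$p_value, 1)
  expect_equal(r$delta_overlap, 0)
  expect_equal(unname(r$overlap_scores), rep(1, 3))

  # no annotation anywhere: observed 0, p 1, delta 0
  emp <- lapply(1:3, function(i) make_locus(10, c(2, 5), NULL))
  r2 <- enrichment_test(emp, n_iterations = 200, seed = 1)
  expect_equal(r2$observed_overlap, 0)
  expect_equal(r2$p_value, 1)
  expect_equal(r2$delta_overlap, 0)
  expect_length(r2$overlap_scores, 0)

  expect_error(enrichment_test(list()), "at least one locus")
})

test_that("Monte Carlo p matches exhaustive joint-offset enumeration", {
  # 3 loci of length 10, one SNP, one length-2 interval each: per-locus
  # null overlap probability 2/10
  loci <- list(make_locus(10, 4, c(4, 6)),
               make_locus(10, 0, c(5, 7)),
               make_locus(10, 9, c(2, 4)))
  p_loc <- vapply(loci, locus_overlap_probability, numeric(1))
  expect_equal(p_loc, rep(0.2, 3))

  obs <- sum(vapply(loci, locus_overlaps, logical(1)))
  # exhaustive enumeration over all 10^3 joint offsets
  p_exact <- enumerate_joint_p(loci, obs)
  # analytic product law (Poisson-binomial tail)
  dist <- exact_count_distribution(p_loc)
  p_analytic <- sum(dist[(obs + 1):length(dist)])
  expect_equal(p_exact, p_analytic)

  r <- enrichment_test(loci, n_iterations = 10000, seed = 11)
  se <- sqrt(p_exact * (1 - p_exact) / 10000)
  expect_lt(abs(r$p_value - p_exact), 3 * se)
})

test_that("overlap scores estimate the per-locus chance and converge", {
  lo <- make_locus(10, 3, c(3, 5))  # overlaps observed; chance 0.2
  r <- enrichment_test(list(lo), n_iterations = 10000, seed = 3)
  expect_equal(names(r$overlap_scores), "L")
  expect_lt(abs(r$overlap_scores[["L"]] - 0.2), 3 * sqrt(0.2 * 0.8 / 10000))

  # a locus not overlapping in the observed data is excluded from the report
  lo2 <- make_locus(10, 8, c(3, 5))
  r2 <- enrichment_test(list(lo, lo2), n_iterations = 100, seed = 3)
  expect_equal(names(r2$overlap_scores), "L")
})

test_that("results are reproducible from the seed and report p correctly", {
  loci <- lapply(1:4, function(i) make_locus(30, c(3, 10) + i, c(5, 9, 20, 23)))
  a <- enrichment_test(loci, n_iterations = 500, seed = 99)
  b <- enrichment_test(loci, n_iterations = 500, seed = 99)
  expect_identical(a$null_overlaps, b$null_overlaps)
  expect_identical(a$p_value, b$p_value)

  # zero extreme iterations render as "<1/n"
  hot <- lapply(1:8, function(i) make_locus(1000, 500, c(499, 502)))
  r <- enrichment_test(hot, n_iterations = 1000, seed = 1)
  expect_equal(r$p_value, 0)
  expect_match(r$p_report, "^<1e-03$")
  # the add-one estimator stays strictly positive
  r2 <- enrichment_test(hot, n_iterations = 1000, seed = 1, add_one = TRUE)
  expect_equal(r2$p_value, 1 / 1001)
})

test_that("null p-values are stochastically valid on a null synthetic design", {
  withr::with_seed(41, {
    ps <- vapply(1:60, function(i) {
      loci <- lapply(1:25, function(j) {
        L <- 200
        s <- sort(sample.int(L - 10, 4))
        make_locus(L, sample.int(L, 3) - 1,
                   as.vector(t(cbind(s, s + sample.int(8, 4)))),
                   id = sprintf("l%d", j))
      })
      enrichment_test(loci, n_iterations = 200)$p_value
    }, numeric(1))
  })
  # empirical type-I error at 0.05 must not exceed nominal + 3 SE
  expect_lte(mean(ps < 0.05), 0.05 + 3 * sqrt(0.05 * 0.95 / 60))
})
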