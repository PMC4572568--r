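# Shared fixtures and brute-force oracles. Everything is generated in code;
# expensive genomes are memoized for the duration of the suite.

# --- per-base oracles ------------------------------------------------------

# Boolean coverage of [0, n) by a track restricted to one chromosome.
cover_vector <- function(track, chrom, n) {
  v <- logical(n)
  d <- track[track$chrom == chrom, , drop = FALSE]
  for (i in seq_len(nrow(d))) {
    s <- max(d$start[i], 0) + 1
    e <- min(d$end[i], n)
    if (s <= e) v[s:e] <- TRUE
  }
  v
}

# Coverage of [0, n) by a relative-interval matrix.
cover_intervals <- function(m, n) {
  v <- logical(n)
  for (i in seq_len(nrow(m))) {
    s <- m[i, 1] + 1; e <- m[i, 2]
    if (s <= e) v[s:e] <- TRUE
  }
  v
}

# Rotate a coverage vector by +offset (per-base circular shift oracle).
rotate_cover <- function(v, offset) {
  n <- length(v)
  if (offset == 0) v else c(v[(n - offset + 1):n], v[1:(n - offset)])
}

random_track <- function(n_intervals, max_pos = 1e4, max_len = 50,
                         chroms = "chr1") {
  s <- sample.int(max_pos - max_len, n_intervals, replace = TRUE) - 1
  len <- sample.int(max_len, n_intervals, replace = TRUE)
  annot_track(sample(chroms, n_intervals, replace = TRUE), s, s + len)
}

# --- hand-built loci -------------------------------------------------------

make_locus <- function(length, snp_pos, x_intervals, id = "L",
                       chrom = "chr1", window_start = 0) {
  structure(list(index_id = id, chrom = chrom,
                 window_start = window_start,
                 window_end = window_start + length,
                 length = length, snp_pos = sort(snp_pos),
                 index_pos = snp_pos[1], n_proxies = length(snp_pos),
                 x_intervals = if (is.null(x_intervals)) {
                   matrix(numeric(0), ncol = 2)
                 } else {
                   m <- matrix(x_intervals, ncol = 2, byrow = TRUE)
                   m[order(m[, 1]), , drop = FALSE]
                 }),
            class = "shift_locus")
}

# Exact per-locus overlap probabilities by brute force: for every offset,
# rotate the coverage vector and check SNP membership.
brute_overlap_by_offset <- function(locus) {
  v <- cover_intervals(locus$x_intervals, locus$length)
  vapply(0:(locus$length - 1), function(k) {
    any(rotate_cover(v, k)[locus$snp_pos + 1])
  }, logical(1))
}

# Exact null distribution of the overlap count across loci: product law over
# independent per-locus offset draws (Poisson-binomial convolution).
exact_count_distribution <- function(p_locus) {
  dist <- 1
  for (p in p_locus) dist <- convolve_bernoulli(dist, p)
  dist  # dist[k + 1] = P(count == k)
}

convolve_bernoulli <- function(dist, p) {
  out <- c(dist * (1 - p), 0) + c(0, dist * p)
  out
}

# Exhaustive joint-offset enumeration of P(count >= observed) for <= 3 loci.
enumerate_joint_p <- function(loci, observed_count) {
  per <- lapply(loci, brute_overlap_by_offset)
  grid <- expand.grid(lapply(per, function(v) seq_along(v)))
  counts <- rowSums(mapply(function(v, col) v[col], per,
                           as.list(grid)))
  mean(counts >= observed_count)
}

# --- toy haplotype panels --------------------------------------------------

# Panel with planted perfect-LD blocks: `block_sizes[i]` variants share one
# haplotype column; blocks are mutually independent.
planted_panel <- function(block_sizes, n_hap = 40, spacing = 100,
                          chrom = "chr1", start = 1000, seed = 1) {
  withr::with_seed(seed, {
    cols <- list(); pos <- numeric(0)
    at <- start
    for (b in seq_along(block_sizes)) {
      h <- stats::rbinom(n_hap, 1, 0.5)
      while (sum(h) %in% c(0, n_hap)) h <- stats::rbinom(n_hap, 1, 0.5)
      for (j in seq_len(block_sizes[b])) {
        cols[[length(cols) + 1L]] <- h
        pos <- c(pos, at)
        at <- at + spacing
      }
      at <- at + 10 * spacing
    }
    hap_panel(data.frame(id = sprintf("s%02d", seq_along(pos)),
                         chrom = chrom, pos = pos,
                         stringsAsFactors = FALSE),
              do.call(cbind, cols))
  })
}

# --- memoized simulation genomes ------------------------------------------

.genome_cache <- new.env(parent = emptyenv())

test_genome <- function(key = c("default", "coloc", "confounded")) {
  key <- match.arg(key)
  if (is.null(.genome_cache[[key]])) {
    cfg <- switch(key,
      default = sim_config(seed = 42),
      coloc = sim_config(seed = 5,
                         colocalization = list(anchor_frac = 0.9, jitter = 200)),
      confounded = sim_config(seed = 77, block_density_dispersion = 1))
    .genome_cache[[key]] <- simulate_genome(cfg)
  }
  .genome_cache[[key]]
}

# Spaced draw from an arbitrary candidate pool (used for the LD-confounded
# matching designs, where sets are deliberately biased toward high LD).
draw_spaced <- function(panel, pool, n, seed, min_spacing = 1e5) {
  v <- panel$variants
  withr::with_seed(seed, {
    ord <- sample(pool)
    acc <- integer(0); accpos <- list()
    for (i in ord) {
      ch <- v$chrom[i]
      if (is.null(accpos[[ch]]) || !any(abs(accpos[[ch]] - v$pos[i]) <= min_spacing)) {
        acc <- c(acc, i)
        accpos[[ch]] <- c(accpos[[ch]], v$pos[i])
        if (length(acc) == n) break
      }
    }
  })
  stopifnot(length(acc) == n)
  v$id[acc]
}
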