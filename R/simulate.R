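#' Simulation configuration
#'
#' Parameters of the synthetic genome used for power, type-I-error and
#' causal-proportion studies: a desk-scale stand-in for a phased reference
#' panel plus functional annotation tracks. Defaults describe the study
#' conditions used throughout the package: a 40-Mb genome over 20
#' chromosomes, 40,000 variants on 100 phased haplotypes arranged in 20-kb
#' LD blocks with target within-block r-squared 0.9, one annotation covering
#' 16% of the genome with lognormal interval sizes (median 500 bp), 1,500
#' genes, and SNP sets of 200 loci spaced more than 100 kb apart.
#'
#' @param genome_length Total genome size in bp.
#' @param n_chromosomes Number of equally sized chromosomes.
#' @param n_variants Number of panel variants.
#' @param n_haplotypes Number of phased haplotypes.
#' @param ld_block_length LD block size in bp; variants within a block are
#'   correlated, blocks are independent.
#' @param within_block_r2 Target pairwise r-squared inside a block (the
#'   copy-with-mutation flip probability is derived from it).
#' @param block_density_dispersion Lognormal sd of the per-block variant
#'   density multiplier; 0 gives homogeneous density, larger values create
#'   blocks with very different LD proxy counts (used to build
#'   LD-confounded panels).
#' @param annotation_density Target fraction of the genome covered by the
#'   tested annotation.
#' @param annotation_size_law List `(median, dispersion)`: interval lengths
#'   are lognormal with this median and log-sd.
#' @param colocalization Optional rule for a second track `y` placed
#'   relative to the first: list with `anchor_frac` (fraction of y intervals
#'   anchored near x intervals), `jitter` (max |offset| in bp between
#'   anchored centres), and optional `density` / `size_law` (default: same
#'   as x).
#' @param n_genes Number of synthetic transcripts.
#' @param array_fraction Fraction of panel variants available as array tags.
#' @param n_loci_per_set Default number of loci per simulated SNP set.
#' @param causal_fraction Default proportion of loci whose causal variant
#'   lies inside the annotation.
#' @param tag_r2_min Default tag selection threshold.
#' @param min_spacing Minimum spacing between index SNPs of a set (bp).
#' @param seed Genome seed (realization is fully reproducible from it).
#' @return A validated `sim_config`.
#' @export
sim_config <- function(genome_length = 4e7,
                       n_chromosomes = 20,
                       n_variants = 4e4,
                       n_haplotypes = 100,
                       ld_block_length = 5e3,
                       within_block_r2 = 0.9,
                       block_density_dispersion = 0,
                       annotation_density = 0.16,
                       annotation_size_law = list(median = 500, dispersion = 0.5),
                       colocalization = NULL,
                       n_genes = 1500,
                       array_fraction = 0.6,
                       n_loci_per_set = 200,
                       causal_fraction = 0,
                       tag_r2_min = 0.8,
                       min_spacing = 1e5,
                       seed = 1) {
  cfg <- as.list(environment())
  stopifnot(genome_length >= 1, n_chromosomes >= 1, n_variants >= 2,
            n_haplotypes >= 4, ld_block_length >= 1,
            within_block_r2 > 0, within_block_r2 <= 1,
            block_density_dispersion >= 0,
            annotation_density >= 0, annotation_density <= 1,
            annotation_size_law$median >= 1, annotation_size_law$dispersion >= 0,
            array_fraction > 0, array_fraction <= 1,
            n_loci_per_set >= 1, causal_fraction >= 0, causal_fraction <= 1,
            tag_r2_min >= 0, tag_r2_min <= 1, min_spacing >= 0)
  if (annotation_density > 0 &&
      annotation_size_law$median > genome_length * annotation_density) {
    stopf("infeasible annotation density/size combination")
  }
  structure(cfg, class = "sim_config")
}

#' Generate a synthetic genome
#'
#' Realizes a `sim_config`: panel variants with phased haplotypes arranged
#' in LD blocks (a founder haplotype per block copied with a per-site flip
#' probability tuned so that pairwise within-block r-squared hits the
#' target), an annotation track `x` placed independently of the variants
#' (plus an optional colocalized track `y`), a synthetic transcript table,
#' and an array-like tag subset. Fully reproducible from `config$seed`.
#'
#' @param config A `sim_config`.
#' @return A `sim_genome`: list with `config`, `chromosomes` (data frame
#'   `chrom`, `length`), `panel` (`hap_panel`), `tracks` (named list of
#'   `annot_track`), `genes` (`gene_table`), `array_ids`, and internal
#'   caches.
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed_opt(config$seed, {
    chrom_len <- floor(config$genome_length / config$n_chromosomes)
    chroms <- data.frame(chrom = sprintf("chr%d", seq_len(config$n_chromosomes)),
                         length = chrom_len, stringsAsFactors = FALSE)
    panel <- simulate_panel(config, chroms)
    tracks <- list(x = simulate_track(config, chroms, "x"))
    if (!is.null(config$colocalization)) {
      tracks$y <- simulate_coloc_track(config, chroms, tracks$x)
    }
    genes <- simulate_genes(config, chroms)
    array_ids <- sort(sample(panel$variants$id,
                             round(config$array_fraction * nrow(panel$variants))))
  })
  structure(list(config = config, chromosomes = chroms, panel = panel,
                 tracks = tracks, genes = genes, array_ids = array_ids,
                 cache = new.env(parent = emptyenv())),
            class = "sim_genome")
}

#' @export
print.sim_genome <- function(x, ...) {
  cov <- vapply(x$tracks, function(t) covered_bases(t), numeric(1L))
  cat(sprintf(
    paste0("sim_genome (seed %s): %s bp on %d chromosomes, %d variants x %d ",
           "haplotypes\n  tracks: %s\n  genes: %d, array variants: %d\n"),
    format(x$config$seed), format(x$config$genome_length, big.mark = ","),
    nrow(x$chromosomes), nrow(x$panel$variants), nrow(x$panel$hap),
    paste(sprintf("%s (%.1f%%)", names(x$tracks),
                  100 * cov / x$config$genome_length), collapse = ", "),
    nrow(x$genes), length(x$array_ids)))
  invisible(x)
}

simulate_panel <- function(config, chroms) {
  blocks <- do.call(rbind, lapply(seq_len(nrow(chroms)), function(ci) {
    bs <- seq(0, chroms$length[ci] - 1, by = config$ld_block_length)
    data.frame(chrom = chroms$chrom[ci], start = bs,
               end = pmin(bs + config$ld_block_length, chroms$length[ci]),
               stringsAsFactors = FALSE)
  }))
  nb <- nrow(blocks)
  w <- (blocks$end - blocks$start) *
    stats::rlnorm(nb, 0, config$block_density_dispersion)
  counts <- stats::rmultinom(1L, config$n_variants, w / sum(w))[, 1L]
  # haplotypes per block: founder assignment copied with per-site flips.
  # With founder frequency q and flip probability eps, the pairwise
  # correlation is a(1-k)/(1-k*a) with a = (1-2*eps)^2, k = (2q-1)^2, so
  # eps is solved per block to hit the target r2 at that block's q.
  nh <- config$n_haplotypes
  pos_l <- vector("list", nb)
  hap_l <- vector("list", nb)
  for (b in seq_len(nb)) {
    m <- counts[b]
    if (m == 0L) next
    pos_l[[b]] <- sort(sample.int(blocks$end[b] - blocks$start[b], m)) - 1L +
      blocks$start[b]
    q <- stats::runif(1, 0.15, 0.85)
    k <- (2 * q - 1)^2
    cc <- sqrt(config$within_block_r2)
    a <- cc / (1 - k * (1 - cc))
    eps <- (1 - sqrt(a)) / 2
    founder <- stats::rbinom(nh, 1L, q)
    flips <- matrix(stats::rbinom(nh * m, 1L, eps), nrow = nh)
    h <- (founder + flips) %% 2L
    # keep every variant polymorphic in the sample
    mono <- which(colSums(h) %in% c(0L, nh))
    for (j in mono) h[sample.int(nh, 1L), j] <- 1L - h[sample.int(nh, 1L), j]
    mono <- which(colSums(h) %in% c(0L, nh))
    for (j in mono) h[1L, j] <- 1L - h[1L, j]
    hap_l[[b]] <- h
  }
  keep <- which(counts > 0L)
  chrom <- rep(blocks$chrom[keep], counts[keep])
  pos <- unlist(pos_l[keep])
  hap <- do.call(cbind, hap_l[keep])
  # unique positions per chromosome (duplicates would be zero-distance pairs)
  dup <- duplicated(paste(chrom, pos))
  chrom <- chrom[!dup]; pos <- pos[!dup]; hap <- hap[, !dup, drop = FALSE]
  ids <- sprintf("v%06d", seq_along(pos))
  hap_panel(data.frame(id = ids, chrom = chrom, pos = pos,
                       stringsAsFactors = FALSE), hap)
}

# Independent placement: draw lognormal interval lengths and uniform starts
# until the merged track reaches the target coverage (within 10% relative).
simulate_track <- function(config, chroms, name,
                           density = config$annotation_density,
                           size_law = config$annotation_size_law) {
  if (density == 0) {
    return(annot_track(character(0), numeric(0), numeric(0), name = name))
  }
  target <- density * sum(chroms$length)
  meanlog <- log(size_law$median)
  acc <- NULL
  covered <- 0
  while (covered < target) {
    need <- target - covered
    n <- max(50L, ceiling(need / size_law$median))
    len <- pmax(1, round(stats::rlnorm(n, meanlog, size_law$dispersion)))
    ci <- sample.int(nrow(chroms), n, replace = TRUE,
                     prob = chroms$length / sum(chroms$length))
    start <- floor(stats::runif(n) * (chroms$length[ci] - len))
    ok <- start >= 0
    new <- data.frame(chrom = chroms$chrom[ci[ok]], start = start[ok],
                      end = start[ok] + len[ok], stringsAsFactors = FALSE)
    acc <- if (is.null(acc)) new else rbind(acc, new)
    mt <- merge_track(annot_track(acc$chrom, acc$start, acc$end))
    covered <- sum(mt$end - mt$start)
  }
  attr(mt, "track_name") <- name
  mt
}

# Track colocalizing with `anchor_track`: a fraction of intervals are
# centred near anchor interval centres (uniform jitter), the rest are
# independent; placement continues to the target density.
simulate_coloc_track <- function(config, chroms, anchor_track) {
  rule <- config$colocalization
  density <- if (!is.null(rule$density)) rule$density else config$annotation_density
  size_law <- if (!is.null(rule$size_law)) rule$size_law else config$annotation_size_law
  target <- density * sum(chroms$length)
  meanlog <- log(size_law$median)
  centers <- (anchor_track$start + anchor_track$end) / 2
  clen_map <- stats::setNames(chroms$length, chroms$chrom)
  acc <- NULL
  covered <- 0
  while (covered < target) {
    need <- target - covered
    n <- max(50L, ceiling(need / size_law$median))
    len <- pmax(1, round(stats::rlnorm(n, meanlog, size_law$dispersion)))
    anchored <- stats::runif(n) < rule$anchor_frac
    chrom <- character(n)
    start <- numeric(n)
    na <- sum(anchored)
    if (na > 0L) {
      ai <- sample.int(length(centers), na, replace = TRUE)
      ctr <- centers[ai] + stats::runif(na, -rule$jitter, rule$jitter)
      chrom[anchored] <- anchor_track$chrom[ai]
      start[anchored] <- round(ctr - len[anchored] / 2)
    }
    if (na < n) {
      ci <- sample.int(nrow(chroms), n - na, replace = TRUE,
                       prob = chroms$length / sum(chroms$length))
      chrom[!anchored] <- chroms$chrom[ci]
      start[!anchored] <- floor(stats::runif(n - na) *
                                  (chroms$length[ci] - len[!anchored]))
    }
    end <- start + len
    start <- pmax(start, 0)
    end <- pmin(end, clen_map[chrom])
    ok <- start < end
    new <- data.frame(chrom = chrom[ok], start = start[ok], end = end[ok],
                      stringsAsFactors = FALSE)
    acc <- if (is.null(acc)) new else rbind(acc, new)
    mt <- merge_track(annot_track(acc$chrom, acc$start, acc$end))
    covered <- sum(mt$end - mt$start)
  }
  attr(mt, "track_name") <- "y"
  mt
}

simulate_genes <- function(config, chroms) {
  n <- config$n_genes
  len <- pmax(2000, round(stats::rlnorm(n, log(8000), 0.6)))
  ci <- sample.int(nrow(chroms), n, replace = TRUE,
                   prob = chroms$length / sum(chroms$length))
  start <- floor(stats::runif(n) * pmax(chroms$length[ci] - len, 1))
  end <- pmin(start + len, chroms$length[ci])
  strand <- sample(c("+", "-"), n, replace = TRUE)
  nex <- sample(2:5, n, replace = TRUE)
  ex <- lapply(seq_len(n), function(i) {
    # random internal cut points; alternate exon/intron pieces
    k <- 2L * nex[i] - 1L
    cuts <- sort(sample.int(end[i] - start[i] - 1L, k - 1L))
    bounds <- c(0, cuts, end[i] - start[i]) + start[i]
    es <- bounds[seq(1L, k, by = 2L)]
    ee <- bounds[seq(2L, k + 1L, by = 2L)]
    list(starts = es, ends = ee)
  })
  as_gene_table(data.frame(
    chrom = chroms$chrom[ci], strand = strand, tx_start = start, tx_end = end,
    exon_starts = vapply(ex, function(e) paste(e$starts, collapse = ","), ""),
    exon_ends = vapply(ex, function(e) paste(e$ends, collapse = ","), ""),
    name = sprintf("g%04d", seq_len(n)), stringsAsFactors = FALSE))
}

# Cached logical mask of panel variants present on the synthetic array.
genome_array_mask <- function(genome) {
  if (is.null(genome$cache$array_mask)) {
    genome$cache$array_mask <-
      genome$panel$variants$id %in% genome$array_ids
  }
  genome$cache$array_mask
}

# Cached membership of every panel variant in a named track.
genome_track_membership <- function(genome, track_name) {
  key <- paste0("member_", track_name)
  if (is.null(genome$cache[[key]])) {
    v <- genome$panel$variants
    tidx <- track_index(genome$tracks[[track_name]])
    member <- logical(nrow(v))
    for (chr in names(tidx)) {
      ci <- tidx[[chr]]
      vi <- which(v$chrom == chr)
      member[vi] <- points_in_bounds(v$pos[vi],
                                     as.vector(rbind(ci$start, ci$end)))
    }
    genome$cache[[key]] <- member
  }
  genome$cache[[key]]
}

#' Cached LD index of a simulated genome
#'
#' Computes (once per genome and threshold) the [ld_index()] of the genome's
#' panel with a search window of two LD blocks -- ample, since blocks are
#' independent by construction -- and caches it on the genome object.
#'
#' @param genome A `sim_genome`.
#' @param r2_threshold Strict r-squared threshold (default 0.8).
#' @return An `ld_index`.
#' @export
genome_ld <- function(genome, r2_threshold = 0.8) {
  key <- sprintf("ld_%g", r2_threshold)
  if (is.null(genome$cache[[key]])) {
    genome$cache[[key]] <- ld_index(genome$panel, r2_threshold = r2_threshold,
                                    window = 2 * genome$config$ld_block_length)
  }
  genome$cache[[key]]
}

#' Draw a simulated functional SNP set
#'
#' Selects `n_loci` causal variants -- a `causal_fraction` share from inside
#' the given annotation category and the rest from outside it (category
#' `"any"` ignores the annotation entirely, giving sets with no causal
#' relationship to it). Each causal variant is reported either directly
#' (`tag_r2_min = NULL`) or via its best array tag at r-squared >=
#' `tag_r2_min` (falling back to the variant itself when no tag qualifies).
#' Accepted index SNPs are spaced more than `min_spacing` bp apart.
#'
#' @param genome A `sim_genome`.
#' @param category Track name (e.g. `"x"`), `"outside"` (complement of
#'   `"x"`), or `"any"`.
#' @param n_loci Number of loci (default from the config).
#' @param causal_fraction Share of causal variants inside the category
#'   track (default from the config; ignored for `"any"`/`"outside"`).
#' @param tag_r2_min Tag threshold, or `NULL` to report causal variants
#'   directly.
#' @param seed RNG seed.
#' @param min_spacing Minimum index spacing in bp (default from config).
#' @return List with `snps` (data frame `id`, `chrom`, `pos` of index SNPs)
#'   and `truth` (per-locus record: causal id/position, whether it lies in
#'   the annotation, tag r-squared).
#' @export
draw_functional_set <- function(genome, category = "x",
                                n_loci = genome$config$n_loci_per_set,
                                causal_fraction = genome$config$causal_fraction,
                                tag_r2_min = genome$config$tag_r2_min,
                                seed = NULL,
                                min_spacing = genome$config$min_spacing) {
  v <- genome$panel$variants
  in_x <- genome_track_membership(genome, "x")
  if (category == "any") {
    pool_in <- integer(0)
    pool_out <- seq_len(nrow(v))
    causal_fraction <- 0
  } else if (category == "outside") {
    pool_in <- integer(0)
    pool_out <- which(!in_x)
    causal_fraction <- 0
  } else {
    if (is.null(genome$tracks[[category]])) stopf("unknown category '%s'", category)
    in_cat <- genome_track_membership(genome, category)
    pool_in <- which(in_cat)
    pool_out <- which(!in_cat)
  }
  n_in <- round(causal_fraction * n_loci)
  n_out <- n_loci - n_in
  if (n_in > 0 && length(pool_in) == 0L) {
    stopf("no panel variants inside category '%s'", category)
  }
  if (!is.null(tag_r2_min)) {
    ld_tag <- genome_ld(genome, tag_r2_min)
    in_array <- genome_array_mask(genome)
  }
  with_seed_opt(seed, {
    ord_in <- sample(pool_in)
    ord_out <- sample(pool_out)
    want <- sample(rep(c(TRUE, FALSE), c(n_in, n_out)))
    accepted <- integer(n_loci)
    tag_r2s <- numeric(n_loci)
    causal <- integer(n_loci)
    acc_pos <- list()  # per chrom positions of accepted indices
    ptr_in <- 1L; ptr_out <- 1L
    for (k in seq_len(n_loci)) {
      repeat {
        if (want[k]) {
          if (ptr_in > length(ord_in)) stopf(
            "genome too small to draw %d spaced loci (inside pool exhausted)", n_loci)
          cand <- ord_in[ptr_in]; ptr_in <- ptr_in + 1L
        } else {
          if (ptr_out > length(ord_out)) stopf(
            "genome too small to draw %d spaced loci (outside pool exhausted)", n_loci)
          cand <- ord_out[ptr_out]; ptr_out <- ptr_out + 1L
        }
        if (is.null(tag_r2_min)) {
          tj <- cand; tr2 <- 1
        } else if (in_array[cand]) {
          # the functional variant is itself on the array: perfect tag
          tj <- cand; tr2 <- 1
        } else {
          js <- ld_tag$proxies[[cand]]
          sel <- which(in_array[js])
          if (length(sel)) {
            r2s <- ld_tag$r2[[cand]][sel]
            d <- abs(v$pos[js[sel]] - v$pos[cand])
            pick <- sel[order(-r2s, d, v$pos[js[sel]])[1L]]
            tj <- js[pick]
            tr2 <- ld_tag$r2[[cand]][pick]
          } else {
            # no qualifying tag: report the functional variant itself
            tj <- cand; tr2 <- 1
          }
        }
        chrom <- v$chrom[tj]; pos <- v$pos[tj]
        near <- acc_pos[[chrom]]
        if (is.null(near) || !any(abs(near - pos) <= min_spacing)) {
          accepted[k] <- tj
          tag_r2s[k] <- tr2
          causal[k] <- cand
          acc_pos[[chrom]] <- c(near, pos)
          break
        }
      }
    }
  })
  truth <- data.frame(index_id = v$id[accepted], causal_id = v$id[causal],
                      causal_chrom = v$chrom[causal],
                      causal_pos = v$pos[causal],
                      causal_in_annotation = in_x[causal],
                      tag_r2 = tag_r2s, stringsAsFactors = FALSE)
  list(snps = v[accepted, c("id", "chrom", "pos")], truth = truth)
}

#' Run the shifting pipeline on a simulated SNP set
#'
#' Convenience wrapper: proxy expansion against the genome's haplotype
#' panel (cached LD index), locus construction from the tested track's
#' median interval size, and the (optionally stratified) enrichment test.
#'
#' @param genome A `sim_genome`.
#' @param index_ids Index SNP ids (e.g. from [draw_functional_set()]).
#' @param track Tested track name in `genome$tracks`, or an `annot_track`.
#' @param n_iterations,seed,add_one Passed to the test.
#' @param stratify_by Optional stratifying track (name or `annot_track`).
#' @param r2_threshold Proxy expansion threshold (default 0.8).
#' @return An `enrich_result`.
#' @export
shift_test_set <- function(genome, index_ids, track = "x",
                           n_iterations = 1000, seed = NULL,
                           stratify_by = NULL, r2_threshold = 0.8,
                           add_one = FALSE) {
  xtr <- if (is.character(track)) genome$tracks[[track]] else track
  stopifnot(!is.null(xtr))
  ld <- genome_ld(genome, r2_threshold)
  loci <- build_loci(index_ids, genome$panel, xtr, ld = ld)
  if (is.null(stratify_by)) {
    enrichment_test(loci, n_iterations = n_iterations, seed = seed,
                    add_one = add_one)
  } else {
    ytr <- if (is.character(stratify_by)) genome$tracks[[stratify_by]] else stratify_by
    stopifnot(!is.null(ytr))
    y_name <- if (is.character(stratify_by)) stratify_by else attr(ytr, "track_name")
    stratified_test(loci, ytr, n_iterations = n_iterations, seed = seed,
                    add_one = add_one, y_name = y_name)
  }
}
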