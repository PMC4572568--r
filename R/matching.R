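# SNP-matching baseline enrichment test. Null SNP sets are sampled from a
# background panel (e.g. array content) matched to the tested SNPs on a
# configurable combination of axes: gene overlap (GEN), 5%-wide MAF bins,
# distance-to-nearest-TSS bins, distance-to-TES bins (TES of the gene with
# the nearest TSS), and the number of SNPs in LD.

TSS_BREAKS <- c(500, 2000, 5000, 1e4, 2e4, 1e5)
TES_BREAKS <- c(1000, 2000, 5000, 1e4, 2e4, 1e5)

dist_bin <- function(d, breaks) {
  # d <= breaks[1] -> 1, ..., d > last break (or no gene, d = Inf) -> length+1
  b <- findInterval(d, breaks + 0.5) + 1L
  b[is.infinite(d)] <- length(breaks) + 1L
  b
}

#' Matching keys for variants
#'
#' Computes, for each variant, the bin on every requested matching axis:
#' `gen` (inside a gene transcript), `maf` (5%-wide frequency bins),
#' `tss` / `tes` (distance bins at 0.5/2/5/10/20/100 kb and 1/2/5/10/20/100
#' kb respectively; variants on a chromosome without genes fall in the
#' terminal ">100 kb" bin), and `ld` (number of LD proxies at the working
#' r-squared threshold).
#'
#' @param variants Data frame with `chrom`, `pos` and (for the `maf` axis)
#'   `maf`.
#' @param genes A `gene_table` (needed for `gen`, `tss`, `tes`).
#' @param ld_count Integer vector of per-variant LD proxy counts (needed for
#'   the `ld` axis).
#' @param active_axes Character subset of
#'   `c("gen", "maf", "tss", "tes", "ld")`.
#' @return Data frame of bin columns, one row per variant, plus a `key`
#'   column concatenating all axes except `ld` (the expandable axis).
#' @export
compute_match_key <- function(variants, genes = NULL, ld_count = NULL,
                              active_axes = c("gen", "maf", "tss", "tes", "ld")) {
  active_axes <- match.arg(active_axes, several.ok = TRUE)
  n <- nrow(variants)
  out <- data.frame(row.names = seq_len(n))
  if (any(c("gen", "tss", "tes") %in% active_axes) && is.null(genes)) {
    stopf("gene table required for axes gen/tss/tes")
  }
  if (!is.null(genes)) {
    tss <- gene_tss(genes)
    tes <- gene_tes(genes)
    gene_bounds <- track_index(annot_track(genes$chrom, genes$tx_start, genes$tx_end))
    nearest <- nearest_tss(variants, genes, tss, tes)
  }
  if ("gen" %in% active_axes) {
    gen <- logical(n)
    for (chr in names(gene_bounds)) {
      ci <- gene_bounds[[chr]]
      vi <- which(variants$chrom == chr)
      gen[vi] <- points_in_bounds(variants$pos[vi],
                                  as.vector(rbind(ci$start, ci$end)))
    }
    out$gen <- gen
  }
  if ("maf" %in% active_axes) {
    if (is.null(variants$maf)) stopf("variants need a maf column for the maf axis")
    out$maf <- pmin(floor(variants$maf / 0.05), 9) + 1L
  }
  if ("tss" %in% active_axes) out$tss <- dist_bin(nearest$tss_dist, TSS_BREAKS)
  if ("tes" %in% active_axes) out$tes <- dist_bin(nearest$tes_dist, TES_BREAKS)
  if ("ld" %in% active_axes) {
    if (is.null(ld_count)) stopf("ld_count required for the ld axis")
    out$ld <- as.integer(ld_count)
  }
  fixed <- setdiff(names(out), "ld")
  out$key <- if (length(fixed)) {
    do.call(paste, c(out[fixed], sep = "|"))
  } else {
    rep("all", n)
  }
  out
}

# Distance to nearest TSS and to the TES of that same gene.
nearest_tss <- function(variants, genes, tss, tes) {
  td <- rep(Inf, nrow(variants))
  ed <- rep(Inf, nrow(variants))
  for (chr in unique(variants$chrom)) {
    gi <- which(genes$chrom == chr)
    vi <- which(variants$chrom == chr)
    if (!length(gi) || !length(vi)) next
    o <- order(tss[gi])
    gpos <- tss[gi][o]
    gtes <- tes[gi][o]
    p <- variants$pos[vi]
    k <- findInterval(p, gpos)
    lo <- pmax(k, 1L)
    hi <- pmin(k + 1L, length(gpos))
    dlo <- abs(p - gpos[lo])
    dhi <- abs(p - gpos[hi])
    pick <- ifelse(k < 1L, hi, ifelse(k >= length(gpos), lo,
                                      ifelse(dlo <= dhi, lo, hi)))
    td[vi] <- abs(p - gpos[pick])
    ed[vi] <- abs(p - gtes[pick])
  }
  list(tss_dist = td, tes_dist = ed)
}

# Pools of panel variants grouped by fixed-axes key, ordered by LD bin,
# ready for the ">= 20 candidates, expand to the nearest LD bins" rule.
build_match_pools <- function(panel_keys) {
  has_ld <- "ld" %in% names(panel_keys)
  idx <- seq_len(nrow(panel_keys))
  pools <- split(idx, panel_keys$key)
  lapply(pools, function(i) {
    if (has_ld) {
      o <- order(panel_keys$ld[i])
      list(idx = i[o], ld = panel_keys$ld[i][o])
    } else {
      list(idx = i, ld = NULL)
    }
  })
}

# Candidates for one test SNP: same fixed key; if the ld axis is active,
# start from the exact LD bin and widen symmetrically (+/- 1, +/- 2, ...)
# until at least `min_candidates` are available. Other axes never relax.
match_candidates <- function(pools, key, ld_bin, min_candidates, snp_id) {
  pool <- pools[[key]]
  if (is.null(pool)) {
    stopf("no background variants match SNP %s (key %s)", snp_id, key)
  }
  if (is.null(pool$ld)) {
    cand <- pool$idx
    if (length(cand) < min_candidates) {
      stopf("only %d matched background variants for SNP %s (key %s); need %d",
            length(cand), snp_id, key, min_candidates)
    }
    return(cand)
  }
  width <- 0L
  max_width <- max(abs(range(pool$ld) - ld_bin))
  repeat {
    sel <- pool$ld >= ld_bin - width & pool$ld <= ld_bin + width
    if (sum(sel) >= min_candidates || width >= max_width) break
    width <- width + 1L
  }
  cand <- pool$idx[sel]
  if (length(cand) < min_candidates) {
    stopf("only %d matched background variants for SNP %s (key %s, ld bin %d) after exhausting LD bins; need %d",
          length(cand), snp_id, key, ld_bin, min_candidates)
  }
  cand
}

#' Sample one matched null SNP set
#'
#' Draws, for each test SNP, one background-panel variant uniformly from its
#' matched candidate pool (see [compute_match_key()]); pools smaller than
#' `min_candidates` are widened along the LD axis only. Sampling is without
#' replacement within the set.
#'
#' @param test_keys Key data frame for the test SNPs (from
#'   [compute_match_key()]).
#' @param panel_keys Key data frame for the background panel.
#' @param min_candidates Minimum pool size before sampling (default 20).
#' @param seed RNG seed.
#' @param test_ids Optional ids used in error messages.
#' @return Integer vector of panel row indices, one per test SNP.
#' @export
sample_matched_set <- function(test_keys, panel_keys, min_candidates = 20,
                               seed = NULL, test_ids = NULL) {
  pools <- build_match_pools(panel_keys)
  with_seed_opt(seed, draw_matched(test_keys, pools, min_candidates, test_ids))
}

draw_matched <- function(test_keys, pools, min_candidates, test_ids = NULL) {
  n <- nrow(test_keys)
  if (is.null(test_ids)) test_ids <- paste0("snp", seq_len(n))
  has_ld <- "ld" %in% names(test_keys)
  out <- integer(n)
  used <- integer(0)
  for (i in seq_len(n)) {
    cand <- match_candidates(pools, test_keys$key[i],
                             if (has_ld) test_keys$ld[i] else NA_integer_,
                             min_candidates, test_ids[i])
    avail <- setdiff(cand, used)
    if (!length(avail)) {
      stopf("matched pool for SNP %s exhausted within this null set", test_ids[i])
    }
    pick <- avail[sample.int(length(avail), 1L)]
    out[i] <- pick
    used <- c(used, pick)
  }
  out
}

#' Matching-based enrichment test
#'
#' Baseline test contrasting the observed number of test loci overlapping
#' the annotation (a locus overlaps when the SNP or any of its LD proxies
#' lies in the annotation, exactly as in the shifting test) with the counts
#' in `n_sets` matched null SNP sets. `p = (# null sets with overlap count
#' >= observed) / n_sets`.
#'
#' @param test_ids Ids of the tested SNPs (present in `panel`).
#' @param panel A `hap_panel` holding the background variants (the tested
#'   SNPs must be part of it).
#' @param x_track Tested annotation.
#' @param genes `gene_table` for the gene-based axes (may be `NULL` if none
#'   of `gen`/`tss`/`tes` is active).
#' @param n_sets Number of matched null sets (default 1000).
#' @param active_axes Matching axes, subset of
#'   `c("gen", "maf", "tss", "tes", "ld")`.
#' @param ld Precomputed [ld_index()] for the panel (computed at
#'   `r2_threshold` if missing).
#' @param r2_threshold Working LD threshold (default 0.8).
#' @param min_candidates Minimum matched-pool size (default 20).
#' @param seed RNG seed.
#' @param panel_keys Optional precomputed [compute_match_key()] table for
#'   the whole panel (recomputed otherwise); useful when running many tests
#'   against the same panel.
#' @param panel_overlap Optional precomputed logical overlap vector for the
#'   panel (from the same `ld` and `x_track`).
#' @return A `match_result`: list with `observed_count`,
#'   `observed_overlap`, `null_counts`, `p_value`, `delta_overlap`,
#'   `n_sets`, `active_axes`, `seed`.
#' @export
matching_test <- function(test_ids, panel, x_track, genes = NULL,
                          n_sets = 1000, active_axes = c("gen", "maf", "tss", "tes", "ld"),
                          ld = NULL, r2_threshold = 0.8, min_candidates = 20,
                          seed = NULL, panel_keys = NULL, panel_overlap = NULL) {
  if (is.null(ld)) ld <- ld_index(panel, r2_threshold = r2_threshold)
  v <- panel$variants
  ti <- panel_lookup(panel, test_ids)
  ov <- if (is.null(panel_overlap)) {
    panel_overlap_vector(panel, ld, track_index(x_track))
  } else {
    panel_overlap
  }
  keys <- if (is.null(panel_keys)) {
    compute_match_key(v, genes = genes, ld_count = ld$ld_count,
                      active_axes = active_axes)
  } else {
    panel_keys
  }
  pools <- build_match_pools(keys)
  test_keys <- keys[ti, , drop = FALSE]
  obs_count <- sum(ov[ti])
  seeds <- derive_seeds(seed, n_sets)
  null_counts <- vapply(seq_len(n_sets), function(s) {
    idx <- with_seed_opt(seeds[s],
                         draw_matched(test_keys, pools, min_candidates,
                                      test_ids))
    sum(ov[idx])
  }, numeric(1L))
  structure(list(
    n_test = length(ti),
    observed_count = obs_count,
    observed_overlap = obs_count / length(ti),
    null_counts = null_counts,
    p_value = mean(null_counts >= obs_count),
    delta_overlap = (obs_count - mean(null_counts)) / length(ti),
    n_sets = n_sets, active_axes = active_axes, seed = seed
  ), class = "match_result")
}

# TRUE for panel variants whose "locus" (the variant plus its LD proxies)
# touches the annotation.
panel_overlap_vector <- function(panel, ld, tidx) {
  v <- panel$variants
  self_in <- logical(nrow(v))
  for (chr in names(tidx)) {
    ci <- tidx[[chr]]
    vi <- which(v$chrom == chr)
    self_in[vi] <- points_in_bounds(v$pos[vi],
                                    as.vector(rbind(ci$start, ci$end)))
  }
  vapply(seq_len(nrow(v)), function(i) {
    self_in[i] || any(self_in[ld$proxies[[i]]])
  }, logical(1L))
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf(
    paste0("SNP-matching enrichment test (axes: %s)\n",
           "  observed overlapping loci: %d / %s (%.4f)\n",
           "  null sets: %d; delta-overlap: %+.4f; p-value: %s\n"),
    paste(x$active_axes, collapse = ","),
    x$observed_count, format(x$n_test),
    x$observed_overlap, x$n_sets, x$delta_overlap,
    format(x$p_value, digits = 4)))
  invisible(x)
}
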