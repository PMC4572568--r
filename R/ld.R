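#' Haplotype panels
#'
#' A `hap_panel` couples a variant table (`id`, `chrom`, `pos`, `maf`) with a
#' phased haplotype matrix (haplotypes in rows, variants in columns, 0/1
#' alleles). Positions are 0-based. All LD quantities are computed from the
#' haplotype matrix.
#'
#' @param variants Data frame with columns `id`, `chrom`, `pos` (and
#'   optionally `maf`; recomputed from the haplotypes when absent).
#' @param haplotypes Integer/numeric 0-1 matrix, one column per variant, in
#'   the same order as `variants`.
#' @return A `hap_panel` object.
#' @export
hap_panel <- function(variants, haplotypes) {
  stopifnot(is.data.frame(variants),
            all(c("id", "chrom", "pos") %in% names(variants)),
            is.matrix(haplotypes), ncol(haplotypes) == nrow(variants),
            nrow(haplotypes) >= 2L, all(haplotypes %in% c(0, 1)))
  if (anyDuplicated(variants$id)) stopf("duplicate variant id in panel")
  if (any(variants$pos < 0)) stopf("negative variant position in panel")
  o <- order(variants$chrom, variants$pos)
  variants <- variants[o, , drop = FALSE]
  haplotypes <- haplotypes[, o, drop = FALSE]
  f <- colMeans(haplotypes)
  variants$maf <- pmin(f, 1 - f)
  rownames(variants) <- NULL
  colnames(haplotypes) <- variants$id
  structure(list(variants = variants, hap = haplotypes),
            class = "hap_panel")
}

#' @export
print.hap_panel <- function(x, ...) {
  cat(sprintf("hap_panel: %d variants x %d haplotypes on %d chromosome(s)\n",
              nrow(x$variants), nrow(x$hap), length(unique(x$variants$chrom))))
  invisible(x)
}

panel_lookup <- function(panel, ids) {
  i <- match(ids, panel$variants$id)
  if (anyNA(i)) stopf("variant(s) not found in panel: %s",
                      paste(utils::head(ids[is.na(i)], 3L), collapse = ", "))
  i
}

#' Squared allelic correlation between two loci
#'
#' Computes the standard LD measure
#' \eqn{r^2 = (p_{AB} - p_A p_B)^2 / (p_A(1-p_A)\,p_B(1-p_B))}
#' from two phased binary haplotype vectors.
#'
#' @param a,b Binary vectors of equal length (>= 2), one entry per haplotype.
#' @return r-squared in `[0, 1]`.
#' @export
r_squared <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2L)
  pa <- mean(a); pb <- mean(b)
  va <- pa * (1 - pa); vb <- pb * (1 - pb)
  if (va == 0 || vb == 0) stopf("r_squared(): LD undefined at a monomorphic locus")
  (mean(a * b) - pa * pb)^2 / (va * vb)
}

# Vectorized r^2 of panel column `i` against columns `js`.
r_squared_cols <- function(panel, i, js) {
  x <- panel$hap[, i]
  px <- mean(x)
  vx <- px * (1 - px)
  if (vx == 0) stopf("r_squared(): LD undefined at a monomorphic locus (%s)",
                     panel$variants$id[i])
  H <- panel$hap[, js, drop = FALSE]
  p <- colMeans(H)
  v <- p * (1 - p)
  pab <- colMeans(H * x)
  r2 <- (pab - px * p)^2 / (vx * v)
  r2[v == 0] <- NA_real_
  r2
}

#' Expand an index variant to its LD proxies
#'
#' Returns the index variant together with every panel variant within
#' `window` bp whose r-squared with the index strictly exceeds
#' `r2_threshold` (the conventional r2 > 0.8 reference-panel expansion).
#'
#' @param index_id Variant identifier present in the panel.
#' @param panel A `hap_panel`.
#' @param r2_threshold Strict lower r-squared bound (default 0.8).
#' @param window Search window in bp on each side of the index (default 1 Mb).
#' @return A `proxy_set`: list with `index` (one-row data frame) and
#'   `proxies` (data frame `id`, `chrom`, `pos`, `maf`, `r2`, index included
#'   with r2 = 1).
#' @export
expand_proxies <- function(index_id, panel, r2_threshold = 0.8, window = 1e6) {
  i <- panel_lookup(panel, index_id)
  v <- panel$variants
  cand <- which(v$chrom == v$chrom[i] & abs(v$pos - v$pos[i]) <= window)
  cand <- setdiff(cand, i)
  keep <- integer(0)
  r2 <- numeric(0)
  if (length(cand)) {
    r2c <- r_squared_cols(panel, i, cand)
    sel <- which(!is.na(r2c) & r2c > r2_threshold)
    keep <- cand[sel]
    r2 <- r2c[sel]
  }
  proxies <- rbind(
    cbind(v[i, c("id", "chrom", "pos", "maf")], r2 = 1),
    cbind(v[keep, c("id", "chrom", "pos", "maf")], r2 = r2)
  )
  proxies <- proxies[order(proxies$pos), , drop = FALSE]
  rownames(proxies) <- NULL
  structure(list(index = v[i, c("id", "chrom", "pos", "maf")],
                 proxies = proxies, r2_threshold = r2_threshold),
            class = "proxy_set")
}

#' @export
print.proxy_set <- function(x, ...) {
  cat(sprintf("proxy_set: index %s (%s:%s), %d variant(s) at r2 > %g\n",
              x$index$id, x$index$chrom,
              format(x$index$pos, scientific = FALSE, big.mark = ","),
              nrow(x$proxies), x$r2_threshold))
  invisible(x)
}

#' Bulk LD adjacency for a whole panel
#'
#' Computes, for every panel variant, the indices of its LD proxies
#' (r-squared strictly above `r2_threshold`, within `window` bp) using
#' chunked cross-products over the haplotype matrix. Used to precompute LD
#' counts for the matching baseline and to speed up locus construction.
#'
#' @inheritParams expand_proxies
#' @param chunk Number of variants per cross-product block.
#' @return An `ld_index`: list with `proxies` (list of integer vectors,
#'   excluding self), `r2` (matching r-squared vectors) and `ld_count`
#'   (integer vector).
#' @export
ld_index <- function(panel, r2_threshold = 0.8, window = 1e5, chunk = 1500L) {
  v <- panel$variants
  n <- nrow(v)
  H <- panel$hap
  nh <- nrow(H)
  p <- colMeans(H)
  vv <- p * (1 - p)
  proxies <- vector("list", n)
  r2list <- vector("list", n)
  for (chr in unique(v$chrom)) {
    idx <- which(v$chrom == chr)
    pos <- v$pos[idx]
    lo <- 1L
    while (lo <= length(idx)) {
      hi <- min(lo + chunk - 1L, length(idx))
      # widen both sides so every pair within `window` of a row in [lo, hi]
      # appears in this block's columns
      hi_ext <- hi
      while (hi_ext < length(idx) && pos[hi_ext + 1L] - pos[hi] <= window) {
        hi_ext <- hi_ext + 1L
      }
      lo_ext <- lo
      while (lo_ext > 1L && pos[lo] - pos[lo_ext - 1L] <= window) {
        lo_ext <- lo_ext - 1L
      }
      cols <- idx[lo_ext:hi_ext]
      Hc <- H[, cols, drop = FALSE]
      pab <- crossprod(Hc) / nh
      pc <- p[cols]
      num <- (pab - tcrossprod(pc))^2
      den <- tcrossprod(vv[cols]^0.5)^2
      r2m <- num / den
      posc <- v$pos[cols]
      row_off <- lo - lo_ext  # rows [lo, hi] sit at offset row_off in cols
      for (a0 in seq_len(hi - lo + 1L)) {
        a <- a0 + row_off
        ga <- cols[a]
        near <- which(abs(posc - posc[a]) <= window & seq_along(cols) != a)
        if (length(near)) {
          r2a <- r2m[a, near]
          sel <- which(!is.na(r2a) & r2a > r2_threshold)
          proxies[[ga]] <- cols[near][sel]
          r2list[[ga]] <- unname(r2a[sel])
        } else {
          proxies[[ga]] <- integer(0)
          r2list[[ga]] <- numeric(0)
        }
      }
      lo <- hi + 1L
    }
  }
  structure(list(proxies = proxies, r2 = r2list,
                 ld_count = lengths(proxies), r2_threshold = r2_threshold,
                 window = window),
            class = "ld_index")
}

# proxy_set from a precomputed ld_index (fast path used by the simulator).
proxy_set_from_index <- function(panel, ld, i) {
  v <- panel$variants
  js <- ld$proxies[[i]]
  proxies <- rbind(
    cbind(v[i, c("id", "chrom", "pos", "maf")], r2 = 1),
    cbind(v[js, c("id", "chrom", "pos", "maf")], r2 = ld$r2[[i]])
  )
  proxies <- proxies[order(proxies$pos), , drop = FALSE]
  rownames(proxies) <- NULL
  structure(list(index = v[i, c("id", "chrom", "pos", "maf")],
                 proxies = proxies, r2_threshold = ld$r2_threshold),
            class = "proxy_set")
}

#' Prune a variant set to approximate independence
#'
#' Walks over same-chromosome variant pairs in position order and, whenever a
#' pair lies closer than `min_distance` bp or has r-squared above `r2_max`,
#' removes one member chosen at random (seeded). The surviving set satisfies
#' both constraints pairwise.
#'
#' @param ids Variant identifiers (present in the panel).
#' @param panel A `hap_panel`.
#' @param r2_max Maximum tolerated pairwise r-squared (strict; default 0.1).
#' @param min_distance Minimum same-chromosome distance in bp (default 100 kb).
#' @param ld_window r-squared is computed for pairs within this distance;
#'   more distant pairs are treated as uncorrelated (default 1 Mb).
#' @param seed RNG seed for the random member choice.
#' @return Character vector of surviving variant ids (position order).
#' @export
prune_independent <- function(ids, panel, r2_max = 0.1, min_distance = 1e5,
                              ld_window = 1e6, seed = NULL) {
  if (length(ids) == 0L) return(character(0))
  i <- panel_lookup(panel, ids)
  v <- panel$variants[i, , drop = FALSE]
  o <- order(v$chrom, v$pos)
  i <- i[o]; v <- v[o, , drop = FALSE]
  alive <- rep(TRUE, nrow(v))
  with_seed_opt(seed, {
    for (a in seq_len(nrow(v) - 1L)) {
      if (!alive[a]) next
      b <- a + 1L
      while (b <= nrow(v) && v$chrom[b] == v$chrom[a] &&
             v$pos[b] - v$pos[a] <= max(min_distance, ld_window)) {
        if (alive[b]) {
          d <- v$pos[b] - v$pos[a]
          viol <- d < min_distance
          if (!viol && d <= ld_window) {
            viol <- r_squared_cols(panel, i[a], i[b]) > r2_max
          }
          if (isTRUE(viol)) {
            drop <- if (stats::runif(1) < 0.5) a else b
            alive[drop] <- FALSE
            if (drop == a) break
          }
        }
        b <- b + 1L
      }
    }
  })
  v$id[alive]
}

#' Select the best tag for a functional variant
#'
#' Among candidate tag variants within `window` bp, returns the one with the
#' greatest r-squared, provided it reaches `r2_min`; ties are broken by
#' smallest distance to the functional variant, then smallest position. When
#' no candidate qualifies and `fallback` is `TRUE`, the functional variant
#' itself is returned (the sequencing-study convention); with `fallback =
#' FALSE`, `NA_character_` signals "no tag".
#'
#' @param functional_id Identifier of the functional variant.
#' @param tag_ids Identifiers of candidate tags (e.g. array content).
#' @param panel A `hap_panel` containing all of them.
#' @param r2_min Minimum r-squared for a usable tag (>= comparison;
#'   typically 0.5 or 0.8).
#' @param window Candidate search window in bp (default 1 Mb).
#' @param fallback Return the functional variant itself when no tag
#'   qualifies (default `TRUE`).
#' @return List with `id` (tag id or `NA`), `r2`, and `is_self`.
#' @export
select_best_tag <- function(functional_id, tag_ids, panel, r2_min = 0.8,
                            window = 1e6, fallback = TRUE) {
  fi <- panel_lookup(panel, functional_id)
  v <- panel$variants
  ti <- panel_lookup(panel, tag_ids)
  ti <- ti[v$chrom[ti] == v$chrom[fi] & abs(v$pos[ti] - v$pos[fi]) <= window]
  best <- NULL
  if (length(ti)) {
    self <- ti == fi
    r2 <- numeric(length(ti))
    r2[self] <- 1
    if (any(!self)) r2[!self] <- r_squared_cols(panel, fi, ti[!self])
    ok <- which(!is.na(r2) & r2 >= r2_min)
    if (length(ok)) {
      d <- abs(v$pos[ti[ok]] - v$pos[fi])
      ord <- order(-r2[ok], d, v$pos[ti[ok]])
      pick <- ok[ord[1L]]
      best <- list(id = v$id[ti[pick]], r2 = unname(r2[pick]),
                   is_self = ti[pick] == fi)
    }
  }
  if (is.null(best)) {
    if (fallback) {
      best <- list(id = v$id[fi], r2 = 1, is_self = TRUE)
    } else {
      best <- list(id = NA_character_, r2 = NA_real_, is_self = NA)
    }
  }
  best
}
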