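#' Shiftable loci
#'
#' A `shift_locus` is the unit of the shifting test: the genomic window
#' spanned by an index variant's LD proxies, extended by twice the median
#' size of the tested annotation on each side so that a shift can always move
#' the local annotation fully on or off the SNPs, with SNP positions and
#' (after [attach_annotation()]) annotation intervals stored in locus-relative
#' 0-based coordinates.
#'
#' @name shift_locus
NULL

#' Define a locus from a proxy set
#'
#' The window is `[min proxy pos - 2 * median_x, max proxy pos +
#' 2 * median_x + 1)`, clipped at coordinate 0. This guarantees a window
#' length of at least `4 * median_x + 1`, so even a single-SNP locus admits
#' both overlap and non-overlap states under circular shifting.
#'
#' @param proxyset A `proxy_set` (see [expand_proxies()]).
#' @param median_x Median size (bp) of the tested annotation (>= 1),
#'   see [median_size()].
#' @return A `shift_locus` (annotation not yet attached).
#' @export
define_locus <- function(proxyset, median_x) {
  stopifnot(inherits(proxyset, "proxy_set"), median_x >= 1)
  locus_from_positions(proxyset$index$id, proxyset$index$chrom,
                       proxyset$proxies$pos, proxyset$index$pos, median_x)
}

locus_from_positions <- function(index_id, chrom, pos, index_pos, median_x) {
  ws <- max(min(pos) - 2 * median_x, 0)
  we <- max(pos) + 2 * median_x + 1
  structure(list(index_id = index_id,
                 chrom = chrom,
                 window_start = ws, window_end = we,
                 length = we - ws,
                 snp_pos = sort(pos) - ws,
                 index_pos = index_pos - ws,
                 n_proxies = length(pos),
                 x_intervals = NULL),
            class = "shift_locus")
}

#' Attach the tested annotation to a locus
#'
#' Intersects a merged annotation track with the locus window and stores the
#' result in locus-relative coordinates; intervals straddling the window are
#' clipped at its edges.
#'
#' @param locus A `shift_locus`.
#' @param track A merged `annot_track`, or a `track_chrom_index` built from
#'   one (see the internal fast path used when attaching many loci).
#' @return The locus with `x_intervals` set (two-column matrix, may be empty).
#' @export
attach_annotation <- function(locus, track) {
  tidx <- if (inherits(track, "track_chrom_index")) track else track_index(track)
  locus$x_intervals <- clip_to_window(tidx, locus$chrom,
                                      locus$window_start, locus$window_end)
  locus
}

#' @export
print.shift_locus <- function(x, ...) {
  cat(sprintf(
    "shift_locus %s: %s:[%s, %s) length %s, %d SNP(s), %s annotation interval(s)\n",
    x$index_id, x$chrom,
    format(x$window_start, scientific = FALSE, big.mark = ","),
    format(x$window_end, scientific = FALSE, big.mark = ","),
    format(x$length, scientific = FALSE, big.mark = ","),
    length(x$snp_pos),
    if (is.null(x$x_intervals)) "unattached" else nrow(x$x_intervals)))
  invisible(x)
}

#' Build loci for a set of index variants
#'
#' Convenience pipeline: expand proxies for each index variant (or use
#' supplied `proxy_set`s), define windows from the annotation's median
#' interval size, and attach the annotation.
#'
#' @param index_ids Character vector of index variant ids, or a list of
#'   `proxy_set` objects (e.g. from [read_proxy_table()]).
#' @param panel A `hap_panel` (ignored when `index_ids` is a list of proxy
#'   sets).
#' @param track The tested annotation (`annot_track`); merged internally.
#' @param r2_threshold,window Passed to [expand_proxies()].
#' @param median_x Median annotation size; computed from `track` if `NULL`.
#' @param ld Optional precomputed [ld_index()] for fast proxy lookup.
#' @return List of `shift_locus` objects.
#' @export
build_loci <- function(index_ids, panel = NULL, track, r2_threshold = 0.8,
                       window = 1e6, median_x = NULL, ld = NULL) {
  track <- if (is_merged(track)) track else merge_track(track)
  if (is.null(median_x)) median_x <- median_size(track)
  tidx <- track_index(track)
  if (is.list(index_ids) && all(vapply(index_ids, inherits, TRUE, "proxy_set"))) {
    psets <- index_ids
  } else {
    stopifnot(inherits(panel, "hap_panel"))
    if (!is.null(ld)) {
      # fast path: loci straight from the precomputed LD adjacency
      ii <- panel_lookup(panel, index_ids)
      v <- panel$variants
      return(lapply(ii, function(i) {
        pos <- c(v$pos[i], v$pos[ld$proxies[[i]]])
        attach_annotation(locus_from_positions(v$id[i], v$chrom[i], pos,
                                               v$pos[i], median_x), tidx)
      }))
    }
    psets <- lapply(index_ids, expand_proxies, panel = panel,
                    r2_threshold = r2_threshold, window = window)
  }
  lapply(psets, function(ps) attach_annotation(define_locus(ps, median_x), tidx))
}
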