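#' Segment a locus by a stratifying annotation
#'
#' Fragments the locus window wherever the stratifying annotation Y starts or
#' ends, then concatenates the fragments (in genomic order) into two
#' segments: one holding all bases covered by Y and one holding the
#' complement. Tested-annotation intervals are split at fragment boundaries
#' ("an X site partially overlapping Y is split") and remapped, as are SNP
#' positions; Y intervals are half-open, so a SNP exactly at a Y end belongs
#' to the complement. The remapping is invertible via `frag_map`.
#'
#' @param locus A `shift_locus` with attached tested annotation.
#' @param y_track The stratifying annotation: a merged `annot_track` or a
#'   `track_chrom_index`.
#' @return A `segmented_locus`: list with `locus_id`, `segments` (named list
#'   `y` / `ybar`, each with `length`, `snp_pos`, `x_intervals` in segment
#'   coordinates) and `frag_map` (data frame `orig_start`, `orig_end`,
#'   `segment`, `seg_offset`).
#' @export
segment_locus <- function(locus, y_track) {
  if (is.null(locus$x_intervals)) stopf("locus %s has no attached annotation",
                                        locus$index_id)
  tidx <- if (inherits(y_track, "track_chrom_index")) y_track else track_index(y_track)
  L <- locus$length
  y <- clip_to_window(tidx, locus$chrom, locus$window_start, locus$window_end)

  # fragments in genomic order, labelled y / ybar
  cuts <- sort(unique(c(0, L, as.vector(y))))
  fs <- cuts[-length(cuts)]
  fe <- cuts[-1L]
  in_y <- points_in_bounds(fs, bounds_of(y))
  lab <- ifelse(in_y, "y", "ybar")
  seg_off <- numeric(length(fs))
  for (g in c("y", "ybar")) {
    i <- lab == g
    seg_off[i] <- cumsum(c(0, (fe - fs)[i]))[seq_len(sum(i))]
  }
  frag_map <- data.frame(orig_start = fs, orig_end = fe, segment = lab,
                         seg_offset = seg_off, stringsAsFactors = FALSE)

  seg <- lapply(c(y = "y", ybar = "ybar"), function(g) {
    i <- which(lab == g)
    len <- sum((fe - fs)[i])
    # SNPs whose fragment has this label
    fi <- findInterval(locus$snp_pos, fs)
    sn <- which(lab[fi] == g)
    snp <- locus$snp_pos[sn] - fs[fi[sn]] + seg_off[fi[sn]]
    # X pieces: intersect each X interval with each fragment of this label
    xs <- matrix(numeric(0), ncol = 2L)
    if (nrow(locus$x_intervals) && length(i)) {
      pieces <- lapply(i, function(f) {
        s <- pmax(locus$x_intervals[, 1L], fs[f])
        e <- pmin(locus$x_intervals[, 2L], fe[f])
        k <- s < e
        if (!any(k)) return(NULL)
        cbind(s[k] - fs[f] + seg_off[f], e[k] - fs[f] + seg_off[f])
      })
      pieces <- do.call(rbind, pieces)
      if (!is.null(pieces) && nrow(pieces)) {
        xs <- pieces[order(pieces[, 1L]), , drop = FALSE]
      }
    }
    list(length = len, snp_pos = sort(snp), x_intervals = xs)
  })
  structure(list(locus_id = locus$index_id, segments = seg,
                 frag_map = frag_map, locus_length = L),
            class = "segmented_locus")
}

# Map a segment-relative position back to locus coordinates (inverse of the
# segmentation remapping; used for audits).
unmap_position <- function(seglocus, segment, pos) {
  fm <- seglocus$frag_map
  fm <- fm[fm$segment == segment, , drop = FALSE]
  i <- findInterval(pos, fm$seg_offset)
  fm$orig_start[i] + (pos - fm$seg_offset[i])
}

# Overlap-offset sets of the two segments of a segmented locus.
segment_offset_sets <- function(seglocus) {
  lapply(seglocus$segments, function(s) {
    if (s$length < 1 || nrow(s$x_intervals) == 0L || length(s$snp_pos) == 0L) {
      return(list(bounds = numeric(0), measure = 0, length = max(s$length, 1)))
    }
    overlap_offsets(list(length = s$length, snp_pos = s$snp_pos,
                         x_intervals = s$x_intervals))
  })
}

#' Stratified local-shifting enrichment test
#'
#' Tests enrichment of the attached annotation X while controlling for a
#' colocalizing annotation Y. Each locus is segmented by Y
#' (see [segment_locus()]); per iteration, X is circularly shifted within the
#' Y-segment and the complement segment independently (each with its own
#' uniform offset), and a locus counts as overlapping when any SNP overlaps
#' shifted X in either segment. Observed overlap, p-value, delta-overlap and
#' overlap scores are defined exactly as in [enrichment_test()]. With an
#' empty Y the null law reduces to the unstratified test.
#'
#' @inheritParams enrichment_test
#' @param y_track The stratifying annotation (`annot_track`; merged
#'   internally).
#' @param y_name Label for the stratifying track in the result (defaults to
#'   the track's name attribute).
#' @return An `enrich_result` with an extra `stratified_on` field.
#' @export
stratified_test <- function(loci, y_track, n_iterations = 1000, seed = NULL,
                            add_one = FALSE, y_name = NULL) {
  check_loci(loci)
  if (!inherits(y_track, "track_chrom_index")) {
    if (is.null(y_name)) y_name <- attr(y_track, "track_name")
    y_track <- track_index(merge_track(y_track))
  }
  if (is.null(y_name)) y_name <- "Y"
  obs <- vapply(loci, locus_overlaps, logical(1L))
  segsets <- lapply(loci, function(l) segment_offset_sets(segment_locus(l, y_track)))
  n_loci <- length(loci)
  hits <- matrix(FALSE, nrow = n_iterations, ncol = n_loci)
  with_seed_opt(seed, {
    for (j in seq_len(n_loci)) {
      h <- rep(FALSE, n_iterations)
      for (oo in segsets[[j]]) {
        if (oo$measure == 0) next
        if (oo$measure >= oo$length) { h <- rep(TRUE, n_iterations); next }
        k <- sample.int(oo$length, n_iterations, replace = TRUE) - 1L
        h <- h | points_in_bounds(k, oo$bounds)
      }
      hits[, j] <- h
    }
  })
  finish_result(loci, obs, hits, n_iterations, seed, add_one,
                extra = list(stratified_on = y_name))
}
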