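#' Annotation tracks
#'
#' An `annot_track` is a data frame of genomic intervals with columns `chrom`,
#' `start`, `end` and (optionally) `summit`, using the BED convention
#' throughout: coordinates are 0-based and half-open, so an interval covers
#' bases `start, ..., end - 1` and a point variant at position `p` overlaps it
#' iff `start <= p < end`. Intervals are kept sorted by `(chrom, start)`.
#'
#' @param chrom Character vector of chromosome labels.
#' @param start,end Numeric vectors of 0-based half-open interval bounds.
#' @param summit Optional numeric vector of absolute summit positions
#'   (`NA` where absent); must satisfy `start <= summit < end`.
#' @param name Optional track label, stored as an attribute.
#' @return An `annot_track` (a sorted data frame).
#' @examples
#' annot_track(c("chr1", "chr1"), c(10, 100), c(20, 150))
#' @export
annot_track <- function(chrom, start, end, summit = NULL, name = NULL) {
  n <- length(start)
  if (length(chrom) == 1L) chrom <- rep(chrom, n)
  stopifnot(length(chrom) == n, length(end) == n)
  df <- data.frame(chrom = as.character(chrom), start = as.numeric(start),
                   end = as.numeric(end), stringsAsFactors = FALSE)
  if (!is.null(summit)) {
    stopifnot(length(summit) == n)
    df$summit <- as.numeric(summit)
  }
  validate_track(df)
  df <- df[order(df$chrom, df$start, df$end), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("annot_track", "data.frame")
  attr(df, "track_name") <- name
  df
}

validate_track <- function(df) {
  bad <- which(!(df$start < df$end) | df$start < 0 |
                 is.na(df$start) | is.na(df$end))
  if (length(bad)) {
    stopf("invalid interval coordinates (start >= end or negative) at record %d: %s:%s-%s",
          bad[1L], df$chrom[bad[1L]], format(df$start[bad[1L]], scientific = FALSE),
          format(df$end[bad[1L]], scientific = FALSE))
  }
  if (!is.null(df$summit)) {
    ok <- is.na(df$summit) | (df$start <= df$summit & df$summit < df$end)
    if (any(!ok)) {
      b <- which(!ok)[1L]
      stopf("summit outside its interval at record %d (%s:%s-%s, summit %s)",
            b, df$chrom[b], df$start[b], df$end[b], df$summit[b])
    }
  }
  invisible(df)
}

as_track <- function(x) {
  if (inherits(x, "annot_track")) return(x)
  stopifnot(is.data.frame(x), all(c("chrom", "start", "end") %in% names(x)))
  annot_track(x$chrom, x$start, x$end, summit = x[["summit"]])
}

#' @export
print.annot_track <- function(x, ...) {
  nm <- attr(x, "track_name")
  cat(sprintf("annot_track%s: %d intervals on %d chromosome(s), %s bp covered\n",
              if (is.null(nm)) "" else paste0(" '", nm, "'"),
              nrow(x), length(unique(x$chrom)),
              format(sum(x$end - x$start), big.mark = ",")))
  NextMethod()
}

#' Merge overlapping and adjacent intervals of a track
#'
#' Returns the minimal sorted set of disjoint intervals covering exactly the
#' same bases. Touching intervals are merged, as they are indistinguishable
#' for point-overlap queries. Summits do not survive merging.
#'
#' @param track An `annot_track` (or data frame coercible to one).
#' @return A merged `annot_track`.
#' @examples
#' merge_track(annot_track("chr1", c(10, 15), c(20, 30)))
#' @export
merge_track <- function(track) {
  track <- as_track(track)
  if (nrow(track) == 0L) return(track)
  parts <- lapply(split(track, track$chrom), function(d) {
    # IRanges is 1-based closed; BED start+1 converts. reduce() merges
    # overlapping and adjacent ranges by default.
    red <- IRanges::reduce(IRanges::IRanges(start = d$start + 1, end = d$end))
    data.frame(chrom = d$chrom[1L], start = IRanges::start(red) - 1,
               end = IRanges::end(red), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, parts)
  res <- annot_track(out$chrom, out$start, out$end,
                     name = attr(track, "track_name"))
  attr(res, "merged") <- TRUE
  res
}

is_merged <- function(track) isTRUE(attr(track, "merged"))

#' Union of several annotation tracks
#'
#' A base is covered in the result iff it is covered in any input track
#' (e.g. consolidating per-cell-type open-chromatin tracks into one).
#'
#' @param tracks A list of `annot_track` objects (at least one).
#' @param name Optional label for the resulting track.
#' @return A merged `annot_track`.
#' @export
union_tracks <- function(tracks, name = NULL) {
  if (!is.list(tracks) || length(tracks) == 0L ||
      inherits(tracks, "data.frame")) {
    stopf("union_tracks() expects a non-empty list of tracks")
  }
  tracks <- lapply(tracks, as_track)
  all <- do.call(rbind, lapply(tracks, function(t) t[c("chrom", "start", "end")]))
  merge_track(annot_track(all$chrom, all$start, all$end, name = name))
}

#' Fixed-width windows around peak summits
#'
#' Replaces each interval by a window of `2 * flank + 1` bases centred on its
#' summit (the summit base plus `flank` bases on each side), clips at
#' coordinate 0, and merges the result.
#'
#' @param track An `annot_track` whose every interval carries a summit.
#' @param flank Flank size in base pairs (default 100, i.e. 201-bp windows).
#' @return A merged `annot_track` of summit windows.
#' @export
summit_windows <- function(track, flank = 100) {
  track <- as_track(track)
  stopifnot(flank >= 0)
  if (is.null(track$summit) || anyNA(track$summit)) {
    b <- if (is.null(track$summit)) 1L else which(is.na(track$summit))[1L]
    stopf("summit_windows(): record %d (%s:%s-%s) has no summit",
          b, track$chrom[b], format(track$start[b], scientific = FALSE),
          format(track$end[b], scientific = FALSE))
  }
  merge_track(annot_track(track$chrom,
                          pmax(track$summit - flank, 0),
                          track$summit + flank + 1,
                          name = attr(track, "track_name")))
}

#' Median interval size of a track
#'
#' The median width (bp) of the track's intervals; for an even count the
#' lower of the two central values is returned, keeping the result a pure
#' integer base-pair count.
#'
#' @param track A merged `annot_track` with at least one interval.
#' @return Median interval width in base pairs.
#' @export
median_size <- function(track) {
  track <- as_track(track)
  if (nrow(track) == 0L) stopf("median_size(): empty track")
  len <- sort(track$end - track$start)
  n <- length(len)
  len[[if (n %% 2L == 0L) n %/% 2L else (n + 1L) %/% 2L]]
}

# Fast per-chromosome lookup index for a *merged* track: sorted start/end
# vectors per chromosome, for binary-search clipping in hot loops.
track_index <- function(track) {
  track <- as_track(track)
  if (!is_merged(track)) track <- merge_track(track)
  idx <- lapply(split(track[c("start", "end")], track$chrom),
                function(d) list(start = d$start, end = d$end))
  structure(idx, class = "track_chrom_index")
}

# Intervals of an indexed track intersected with [ws, we) on `chrom`,
# returned clipped and shifted to window-relative coordinates.
clip_to_window <- function(tidx, chrom, ws, we) {
  ci <- tidx[[chrom]]
  if (is.null(ci)) return(matrix(numeric(0), ncol = 2L))
  # first interval with end > ws; last interval with start < we
  i1 <- findInterval(ws, ci$end) + 1L
  i2 <- findInterval(we - 1, ci$start)
  if (i1 > i2) return(matrix(numeric(0), ncol = 2L))
  s <- pmax(ci$start[i1:i2], ws) - ws
  e <- pmin(ci$end[i1:i2], we) - ws
  cbind(start = s, end = e)
}

# Covered bases of a track within [from, to) on one chromosome -- used by
# the simulator to measure realized annotation density.
covered_bases <- function(track, chrom = NULL) {
  track <- merge_track(as_track(track))
  if (!is.null(chrom)) track <- track[track$chrom %in% chrom, , drop = FALSE]
  sum(track$end - track$start)
}
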