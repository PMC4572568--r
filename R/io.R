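# File formats: variant maps, BED / narrowPeak tracks, result tables.

#' Read an index-variant map
#'
#' Tab-delimited with header columns `id`, `chrom`, `pos`. Positions are
#' 0-based by default; pass `one_based = TRUE` for 1-based input (positions
#' are decremented on read). Duplicated ids and malformed rows are errors.
#'
#' @param path File path.
#' @param one_based Interpret positions as 1-based (default `FALSE`).
#' @return Data frame `id`, `chrom`, `pos` (0-based).
#' @export
read_snpmap <- function(path, one_based = FALSE) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(id = "character", chrom = "character"))
  need <- c("id", "chrom", "pos")
  miss <- setdiff(need, names(df))
  if (length(miss)) stopf("snpmap missing column(s): %s", paste(miss, collapse = ", "))
  pos <- suppressWarnings(as.numeric(df$pos))
  bad <- which(is.na(pos) | pos != floor(pos) | (pos < if (one_based) 1 else 0))
  if (length(bad)) {
    stopf("snpmap %s: invalid position '%s' at line %d", path,
          df$pos[bad[1L]], bad[1L] + 1L)
  }
  if (anyDuplicated(df$id)) {
    stopf("snpmap %s: duplicate id '%s'", path, df$id[anyDuplicated(df$id)])
  }
  data.frame(id = df$id, chrom = df$chrom,
             pos = pos - if (one_based) 1 else 0,
             stringsAsFactors = FALSE)
}

#' Write an index-variant map
#'
#' @param snps Data frame `id`, `chrom`, `pos` (0-based).
#' @param path Output path.
#' @param one_based Write positions 1-based.
#' @export
write_snpmap <- function(snps, path, one_based = FALSE) {
  out <- snps[c("id", "chrom", "pos")]
  if (one_based) out$pos <- out$pos + 1
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a BED track
#'
#' BED3/BED6 via rtracklayer; coordinates come back in the package's 0-based
#' half-open convention (identical to the bytes on disk).
#'
#' @param path BED path.
#' @param name Optional track label.
#' @return An `annot_track`.
#' @export
read_bed <- function(path, name = NULL) {
  df <- as.data.frame(rtracklayer::import(path, format = "BED"))
  annot_track(as.character(df$seqnames), df$start - 1, df$end,
              name = if (is.null(name)) basename(path) else name)
}

#' Read a narrowPeak track
#'
#' BED6+4; field 10 is the summit offset from the interval start (-1 when
#' absent). Summits are stored as absolute positions.
#'
#' @inheritParams read_bed
#' @return An `annot_track` with a `summit` column (`NA` where the file has
#'   -1).
#' @export
read_narrowpeak <- function(path, name = NULL) {
  extra <- c(signalValue = "numeric", pValue = "numeric", qValue = "numeric",
             peak = "integer")
  df <- as.data.frame(rtracklayer::import(path, format = "BED",
                                          extraCols = extra))
  start0 <- df$start - 1
  summit <- ifelse(df$peak < 0, NA_real_, start0 + df$peak)
  annot_track(as.character(df$seqnames), start0, df$end, summit = summit,
              name = if (is.null(name)) basename(path) else name)
}

#' Write a track as BED3
#'
#' @param track An `annot_track`.
#' @param path Output path.
#' @export
write_bed <- function(track, path) {
  track <- as_track(track)
  gr <- GenomicRanges::GRanges(track$chrom,
                               IRanges::IRanges(start = track$start + 1,
                                                end = track$end))
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Write enrichment results
#'
#' Writes `<prefix>.summary.tsv` (one row: locus count, observed overlap,
#' mean null overlap, delta-overlap, p-value, iteration count, seed) and
#' `<prefix>.loci.tsv` (per observed-overlapping locus: id and overlap
#' score, sorted ascending by score so the loci driving the enrichment come
#' first). Reruns with the same inputs and seed produce byte-identical
#' files. A p-value of zero counts is rendered `<1/n` (e.g. `<1e-04`).
#'
#' @param result An `enrich_result`.
#' @param prefix Output path prefix.
#' @return Invisibly, the two file paths.
#' @export
write_results <- function(result, prefix) {
  stopifnot(inherits(result, "enrich_result"))
  sum_path <- paste0(prefix, ".summary.tsv")
  loci_path <- paste0(prefix, ".loci.tsv")
  summary <- data.frame(
    n_loci = result$n_loci,
    observed_overlap = sprintf("%.6f", result$observed_overlap),
    mean_null_overlap = sprintf("%.6f", mean(result$null_overlaps)),
    delta_overlap = sprintf("%.6f", result$delta_overlap),
    p_value = result$p_report,
    n_iterations = result$n_iterations,
    seed = if (is.null(result$seed)) NA_integer_ else result$seed,
    stringsAsFactors = FALSE)
  if (!is.null(result$stratified_on)) summary$stratified_on <- result$stratified_on
  utils::write.table(summary, sum_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  sc <- sort(result$overlap_scores)
  loci <- data.frame(index_id = names(sc),
                     overlap_score = sprintf("%.6f", sc),
                     stringsAsFactors = FALSE)
  utils::write.table(loci, loci_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(summary = sum_path, loci = loci_path))
}
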