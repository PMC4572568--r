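#' Read a transcript table
#'
#' Reads a tab-delimited transcript table with columns `chrom`, `strand`,
#' `tx_start`, `tx_end`, `exon_starts`, `exon_ends`, `name` (extra columns are
#' kept). Exon columns are comma-separated 0-based half-open coordinates, as
#' in UCSC gene tables.
#'
#' @param path Path to the table.
#' @return A `gene_table` data frame.
#' @export
read_gene_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom", "strand", "tx_start", "tx_end", "name")
  miss <- setdiff(need, names(df))
  if (length(miss)) stopf("gene table missing column(s): %s", paste(miss, collapse = ", "))
  as_gene_table(df)
}

#' Validate and sort a transcript table built in memory
#'
#' @param df Data frame with at least `chrom`, `strand`, `tx_start`,
#'   `tx_end`, `name` (plus `exon_starts` / `exon_ends` for exon-based
#'   features).
#' @return A `gene_table`.
#' @export
as_gene_table <- function(df) {
  stopifnot(all(df$tx_start < df$tx_end), all(df$strand %in% c("+", "-")))
  df <- df[order(df$chrom, df$tx_start), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("gene_table", "data.frame")
  df
}

parse_exons <- function(genes) {
  sl <- function(x) lapply(strsplit(as.character(x), ","), as.numeric)
  list(starts = sl(genes$exon_starts), ends = sl(genes$exon_ends))
}

# Strand-aware transcription start/end site, as 0-based base positions.
gene_tss <- function(genes) ifelse(genes$strand == "+", genes$tx_start, genes$tx_end - 1)
gene_tes <- function(genes) ifelse(genes$strand == "+", genes$tx_end - 1, genes$tx_start)

#' Derive feature tracks from a transcript table
#'
#' Builds merged annotation tracks for whole gene bodies, exons, introns,
#' promoters (the first `promoter_upstream` bp upstream of the TSS,
#' strand-aware), and first/last-exon UTR proxies (the transcript table
#' carries no CDS bounds, so the 5'/3' terminal exons stand in for UTRs).
#'
#' @param genes A `gene_table`.
#' @param feature One of `"gene"`, `"exon"`, `"intron"`, `"promoter"`,
#'   `"utr5"`, `"utr3"`.
#' @param promoter_upstream Promoter length in bp upstream of the TSS
#'   (default 500).
#' @return A merged `annot_track`.
#' @export
gene_features <- function(genes,
                          feature = c("gene", "exon", "intron", "promoter",
                                      "utr5", "utr3"),
                          promoter_upstream = 500) {
  feature <- match.arg(feature)
  if (feature == "gene") {
    return(merge_track(annot_track(genes$chrom, genes$tx_start, genes$tx_end,
                                   name = "gene")))
  }
  if (feature == "promoter") {
    plus <- genes$strand == "+"
    s <- ifelse(plus, pmax(genes$tx_start - promoter_upstream, 0), genes$tx_end)
    e <- ifelse(plus, genes$tx_start, genes$tx_end + promoter_upstream)
    keep <- s < e
    return(merge_track(annot_track(genes$chrom[keep], s[keep], e[keep],
                                   name = "promoter")))
  }
  ex <- parse_exons(genes)
  if (feature == "exon") {
    chrom <- rep(genes$chrom, lengths(ex$starts))
    return(merge_track(annot_track(chrom, unlist(ex$starts), unlist(ex$ends),
                                   name = "exon")))
  }
  if (feature %in% c("utr5", "utr3")) {
    first <- feature == "utr5"
    pick <- function(v, plus) if (xor(plus, !first)) v[[1L]] else v[[length(v)]]
    plus <- genes$strand == "+"
    s <- mapply(function(v, p) pick(v, p), ex$starts, plus)
    e <- mapply(function(v, p) pick(v, p), ex$ends, plus)
    return(merge_track(annot_track(genes$chrom, s, e, name = feature)))
  }
  # introns: gene bodies minus exons, per transcript
  ints <- mapply(function(es, ee) {
    if (length(es) < 2L) return(NULL)
    cbind(ee[-length(ee)], es[-1L])
  }, ex$starts, ex$ends, SIMPLIFY = FALSE)
  chrom <- rep(genes$chrom, vapply(ints, function(m) if (is.null(m)) 0L else nrow(m), 0L))
  m <- do.call(rbind, ints)
  if (is.null(m) || nrow(m) == 0L) {
    return(annot_track(character(0), numeric(0), numeric(0), name = "intron"))
  }
  keep <- m[, 1L] < m[, 2L]
  merge_track(annot_track(chrom[keep], m[keep, 1L], m[keep, 2L], name = "intron"))
}
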