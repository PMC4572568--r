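# Readers for LD inputs: phased VCF haplotypes and precomputed proxy tables.

#' Read a phased VCF into a haplotype panel
#'
#' Reads a VCF restricted to bi-allelic SNV records with phased genotypes
#' (`0|1`-style GT), applying the conventional reference-panel filters: at
#' least `min_mac` copies of the minor allele, and a minor-allele-frequency
#' floor. Positions are converted to 0-based.
#'
#' @param path VCF path (plain text or bgzip).
#' @param min_mac Minimum minor-allele count (default 5).
#' @param min_maf Minimum minor-allele frequency (default 0, i.e. only the
#'   count filter).
#' @return A `hap_panel`.
#' @export
read_vcf_panel <- function(path, min_mac = 5, min_maf = 0) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(vcf)
  biallelic <- !grepl(",", fix$ALT) & nchar(fix$REF) == 1L & nchar(fix$ALT) == 1L
  phased <- apply(gt, 1L, function(r) all(grepl("^[01]\\|[01]$", r)))
  keep <- which(biallelic & phased)
  if (length(keep) == 0L) stopf("no phased bi-allelic records in %s", path)
  gt <- gt[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]
  h1 <- matrix(as.integer(substr(gt, 1L, 1L)), nrow = nrow(gt))
  h2 <- matrix(as.integer(substr(gt, 3L, 3L)), nrow = nrow(gt))
  hap <- rbind(t(h1), t(h2))  # haplotypes x variants
  mac <- pmin(colSums(hap), nrow(hap) - colSums(hap))
  maf <- mac / nrow(hap)
  keep2 <- mac >= min_mac & maf >= min_maf
  if (!any(keep2)) stopf("no variants pass MAC/MAF filters in %s", path)
  ids <- fix$ID
  noid <- is.na(ids) | ids == "."
  ids[noid] <- paste0(fix$CHROM[noid], ":", fix$POS[noid])
  hap_panel(data.frame(id = ids[keep2], chrom = fix$CHROM[keep2],
                       pos = as.numeric(fix$POS[keep2]) - 1,
                       stringsAsFactors = FALSE),
            hap[, keep2, drop = FALSE])
}

#' Read a precomputed proxy table
#'
#' Alternative to haplotype input: a tab-delimited table with columns
#' `index_id`, `proxy_id`, `proxy_chrom`, `proxy_pos`, `r2` (0-based
#' positions). Each index variant must appear as its own proxy with r2 = 1;
#' if absent, a row is synthesized from the matching `proxy` record when one
#' exists, otherwise reading fails.
#'
#' @param path Table path.
#' @param r2_threshold Proxies at or below this r-squared are dropped
#'   (strict `>`; default 0.8).
#' @return Named list of `proxy_set` objects, one per index variant.
#' @export
read_proxy_table <- function(path, r2_threshold = 0.8) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("index_id", "proxy_id", "proxy_chrom", "proxy_pos", "r2")
  miss <- setdiff(need, names(df))
  if (length(miss)) stopf("proxy table missing column(s): %s",
                          paste(miss, collapse = ", "))
  df <- df[df$r2 > r2_threshold | df$index_id == df$proxy_id, , drop = FALSE]
  out <- lapply(split(df, df$index_id), function(d) {
    self <- d[d$proxy_id == d$index_id[1L], , drop = FALSE]
    if (nrow(self) == 0L) {
      stopf("proxy table: index %s has no self row (r2 = 1)", d$index_id[1L])
    }
    proxies <- data.frame(id = d$proxy_id, chrom = d$proxy_chrom,
                          pos = as.numeric(d$proxy_pos),
                          maf = NA_real_, r2 = d$r2,
                          stringsAsFactors = FALSE)
    proxies <- proxies[order(proxies$pos), , drop = FALSE]
    rownames(proxies) <- NULL
    structure(list(index = data.frame(id = self$index_id[1L],
                                      chrom = self$proxy_chrom[1L],
                                      pos = as.numeric(self$proxy_pos[1L]),
                                      maf = NA_real_,
                                      stringsAsFactors = FALSE),
                   proxies = proxies, r2_threshold = r2_threshold),
              class = "proxy_set")
  })
  out
}
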