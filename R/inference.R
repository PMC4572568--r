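#' Power / type-I-error study over causal fractions
#'
#' For each causal fraction, simulates `n_sets` SNP sets on the given
#' genome, runs the chosen enrichment test, and records the share of sets
#' rejected at each alpha level. At fraction 0 this is a type-I-error
#' calibration; at higher fractions, power.
#'
#' @param genome A `sim_genome`.
#' @param fractions Numeric vector of causal fractions in `[0, 1]`.
#' @param n_sets Simulated sets per fraction.
#' @param n_iterations Shifting iterations (or matched null sets) per test.
#' @param alpha_levels Significance levels (default `c(0.05, 0.001)`).
#' @param method `"shifting"` or `"matching"`.
#' @param axes Matching axes when `method = "matching"`.
#' @param set_size Loci per set (default from the config).
#' @param tag_r2_min Tag threshold (`NULL` = report causal variants
#'   directly).
#' @param seed Root seed; per-set seeds are derived from it.
#' @return Data frame `fraction`, `alpha`, `rejection_rate`, `n_sets`, plus
#'   a `"deltas"` attribute holding the per-set delta-overlap values.
#' @export
power_study <- function(genome, fractions, n_sets = 100, n_iterations = 1000,
                        alpha_levels = c(0.05, 0.001),
                        method = c("shifting", "matching"),
                        axes = c("gen", "maf", "tss", "tes", "ld"),
                        set_size = genome$config$n_loci_per_set,
                        tag_r2_min = genome$config$tag_r2_min,
                        seed = NULL) {
  method <- match.arg(method)
  stopifnot(length(fractions) >= 1)
  if (method == "matching") {
    ld <- genome_ld(genome)
    panel_keys <- compute_match_key(genome$panel$variants, genes = genome$genes,
                                    ld_count = ld$ld_count, active_axes = axes)
    panel_overlap <- panel_overlap_vector(genome$panel, ld,
                                          track_index(genome$tracks$x))
  }
  seeds <- matrix(derive_seeds(seed, 2L * length(fractions) * n_sets),
                  ncol = 2L)
  rows <- list()
  deltas <- list()
  si <- 0L
  for (f in fractions) {
    p <- numeric(n_sets)
    d <- numeric(n_sets)
    for (s in seq_len(n_sets)) {
      si <- si + 1L
      set <- draw_functional_set(genome, category = if (f > 0) "x" else "any",
                                 n_loci = set_size, causal_fraction = f,
                                 tag_r2_min = tag_r2_min,
                                 seed = seeds[si, 1L])
      res <- if (method == "shifting") {
        shift_test_set(genome, set$snps$id, n_iterations = n_iterations,
                       seed = seeds[si, 2L])
      } else {
        matching_test(set$snps$id, genome$panel, genome$tracks$x,
                      genes = genome$genes, n_sets = n_iterations,
                      active_axes = axes, ld = ld,
                      panel_keys = panel_keys, panel_overlap = panel_overlap,
                      seed = seeds[si, 2L])
      }
      p[s] <- res$p_value
      d[s] <- res$delta_overlap
    }
    rows[[length(rows) + 1L]] <- data.frame(
      fraction = f, alpha = alpha_levels,
      rejection_rate = vapply(alpha_levels, function(a) mean(p < a), 0),
      n_sets = n_sets)
    deltas[[length(deltas) + 1L]] <- data.frame(fraction = f, delta = d)
  }
  out <- do.call(rbind, rows)
  attr(out, "deltas") <- do.call(rbind, deltas)
  out
}

#' Reference delta-overlap distribution over causal-fraction increments
#'
#' Simulates `n_sets_per_increment` SNP sets at every causal-fraction
#' increment and records each set's delta-overlap. This table is the
#' costly half of [infer_causal_proportion()]; computing it once and
#' passing it as `reference` lets several observed values be inverted
#' against the same genome.
#'
#' @inheritParams power_study
#' @param increments Causal fractions to scan (default 0 to 0.45 in steps
#'   of 0.03).
#' @param n_sets_per_increment Sets per increment (default 100).
#' @return Data frame `fraction`, `delta`.
#' @export
delta_reference <- function(genome, increments = seq(0, 0.45, by = 0.03),
                            n_sets_per_increment = 100,
                            set_size = genome$config$n_loci_per_set,
                            n_iterations = 1000,
                            tag_r2_min = genome$config$tag_r2_min,
                            seed = NULL) {
  ps <- power_study(genome, fractions = increments,
                    n_sets = n_sets_per_increment,
                    n_iterations = n_iterations, set_size = set_size,
                    tag_r2_min = tag_r2_min, seed = seed)
  attr(ps, "deltas")
}

#' Infer the proportion of causal variants inside the annotation
#'
#' Inverts an observed delta-overlap against simulation: SNP sets are
#' simulated across a grid of true causal fractions, sets whose
#' delta-overlap falls within `tolerance` of the observed value are
#' retained, and the retained sets' true fractions form a probability
#' distribution whose mean and central 95% interval are reported.
#'
#' @param observed_delta Observed delta-overlap, on the proportion scale
#'   (e.g. 0.0317 for a 3.17-percentage-point excess).
#' @param genome A `sim_genome` (ignored if `reference` is supplied).
#' @param set_size Loci per simulated set.
#' @param increments Causal-fraction grid.
#' @param tolerance Half-width of the delta acceptance band, proportion
#'   scale (default 0.002, i.e. 0.2 percentage points).
#' @param n_sets_per_increment Simulated sets per grid point (default 100).
#' @param n_iterations Shifting iterations per set.
#' @param tag_r2_min Tag threshold.
#' @param seed RNG seed (used only when building the reference).
#' @param reference Optional precomputed [delta_reference()] table.
#' @return List with `mean`, `ci` (2.5% / 97.5% quantiles of retained true
#'   fractions), `n_retained`, and the `reference` table (for reuse).
#' @export
infer_causal_proportion <- function(observed_delta, genome = NULL,
                                    set_size = NULL,
                                    increments = seq(0, 0.45, by = 0.03),
                                    tolerance = 0.002,
                                    n_sets_per_increment = 100,
                                    n_iterations = 1000,
                                    tag_r2_min = NULL,
                                    seed = NULL,
                                    reference = NULL) {
  if (is.null(reference)) {
    stopifnot(inherits(genome, "sim_genome"))
    if (is.null(set_size)) set_size <- genome$config$n_loci_per_set
    if (is.null(tag_r2_min)) tag_r2_min <- genome$config$tag_r2_min
    reference <- delta_reference(genome, increments = increments,
                                 n_sets_per_increment = n_sets_per_increment,
                                 set_size = set_size,
                                 n_iterations = n_iterations,
                                 tag_r2_min = tag_r2_min, seed = seed)
  }
  keep <- abs(reference$delta - observed_delta) <= tolerance
  if (!any(keep)) {
    stopf(paste0("no simulated set has delta-overlap within %.4g of %.4g; ",
                 "widen `tolerance` or extend `increments`"),
          tolerance, observed_delta)
  }
  fr <- reference$fraction[keep]
  list(mean = mean(fr),
       ci = unname(stats::quantile(fr, c(0.025, 0.975))),
       n_retained = sum(keep),
       reference = reference)
}
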