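# Internal helpers shared across modules.

#' @importFrom withr with_seed
NULL

# Evaluate `expr` under `seed` without disturbing the caller's RNG state.
# seed = NULL means "use the current RNG stream".
with_seed_opt <- function(seed, expr) {
  if (is.null(seed)) {
    force(expr)
  } else {
    withr::with_seed(as.integer(seed), expr)
  }
}

# Derive `n` independent sub-seeds (< 2^31) from a root seed.
derive_seeds <- function(seed, n) {
  with_seed_opt(seed, sample.int(.Machine$integer.max - 1L, n))
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) length(x) == 1L && is.numeric(x) && !is.na(x) && x == floor(x)

# Membership of integer points `p` in a union of disjoint, sorted half-open
# intervals given as an interleaved boundary vector c(s1, e1, s2, e2, ...).
# findInterval counts boundaries <= p, so an odd count means p is inside.
points_in_bounds <- function(p, bounds) {
  if (length(bounds) == 0L) return(rep(FALSE, length(p)))
  findInterval(p, bounds) %% 2L == 1L
}

# Union of half-open integer intervals given as vectors of starts/ends.
# Returns a two-column matrix (start, end), sorted, disjoint; adjacent
# intervals are merged (indistinguishable for point queries).
union_intervals <- function(start, end) {
  if (length(start) == 0L) return(matrix(numeric(0), ncol = 2L))
  o <- order(start, end)
  start <- start[o]; end <- end[o]
  cme <- cummax(end)
  new_run <- c(TRUE, start[-1L] > cme[-length(cme)])
  grp <- cumsum(new_run)
  cbind(start = start[new_run], end = tapply(end, grp, max))
}

# Interleave a (start, end) matrix into a flat boundary vector.
bounds_of <- function(m) {
  if (is.null(m) || nrow(m) == 0L) return(numeric(0))
  as.vector(t(m))
}
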