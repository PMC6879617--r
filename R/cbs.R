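# Circular binary segmentation on a per-exon copy-ratio vector.
#
# The profile is treated as circularly closed: the maximal two-segment
# statistic |S_j - S_i| / sqrt(L (n - L)) over split pairs (i, j) of the
# centered partial sums S is compared against its permutation null
# (default 1,000 within-segment permutations, alpha 0.01, with early
# stopping once significance is impossible).  A significant top-level
# split separates the arc (i, j] from its wrapped complement, which stays
# a single segment; both arcs are then refined recursively as linear
# sequences.  The minimum segment width is 2 exons.  Deterministic for a
# fixed RNG state.

cbs_max_stat <- function(x, min_width) {
  n <- length(x)
  S <- c(0, cumsum(x - mean(x)))
  idx <- 0:n
  L <- outer(idx, idx, function(i, j) j - i)
  valid <- L >= min_width & L <= n - min_width
  if (!any(valid)) return(list(stat = 0, i = NA_integer_, j = NA_integer_))
  W <- sqrt(pmax(L * (n - L), 1))
  stat <- abs(outer(S, S, function(a, b) b - a)) / W
  stat[!valid] <- -Inf
  k <- which.max(stat)
  j <- (k - 1) %/% (n + 1)   # column (0-based)
  i <- (k - 1) %% (n + 1)    # row (0-based)
  list(stat = stat[k], i = i, j = j, valid = valid, W = W)
}

cbs_perm_p <- function(x, obs, nperm, alpha, valid, W) {
  exceed <- 0L
  stop_at <- ceiling(alpha * (nperm + 1))
  for (p in seq_len(nperm)) {
    xp <- sample(x)
    Sp <- c(0, cumsum(xp - mean(xp)))
    statp <- abs(outer(Sp, Sp, function(a, b) b - a)) / W
    statp[!valid] <- -Inf
    if (max(statp) >= obs - 1e-12) {
      exceed <- exceed + 1L
      if (exceed >= stop_at) {
        # p-value already certain to exceed alpha
        return(1)
      }
    }
  }
  (1 + exceed) / (1 + nperm)
}

cbs_test_split <- function(x, alpha, nperm, min_width) {
  n <- length(x)
  if (n < 2 * min_width) return(NULL)
  ms <- cbs_max_stat(x, min_width)
  if (!is.finite(ms$stat) || ms$stat <= 0) return(NULL)
  p <- cbs_perm_p(x, ms$stat, nperm, alpha, ms$valid, ms$W)
  if (p > alpha) return(NULL)
  ms
}

# recursive refinement of a linear (non-wrapping) arc; returns integer
# breakpoints (positions after which a boundary falls)
cbs_breakpoints_linear <- function(x, alpha, nperm, min_width) {
  n <- length(x)
  ms <- cbs_test_split(x, alpha, nperm, min_width)
  if (is.null(ms)) return(integer(0))
  cuts <- c(ms$i, ms$j)
  cuts <- cuts[cuts > 0 & cuts < n]
  out <- cuts
  bounds <- c(0, sort(cuts), n)
  for (k in seq_len(length(bounds) - 1)) {
    piece <- seq(bounds[k] + 1, bounds[k + 1])
    sub <- cbs_breakpoints_linear(x[piece], alpha, nperm, min_width)
    out <- c(out, piece[1] - 1 + sub)
  }
  sort(unique(out))
}

cbs_assign_linear <- function(x, alpha, nperm, min_width) {
  cuts <- cbs_breakpoints_linear(x, alpha, nperm, min_width)
  findInterval(seq_along(x) - 1, c(0, cuts))
}

# full circular segmentation: integer segment id per position, numbered by
# first occurrence
cbs_assign <- function(x, alpha = 0.01, nperm = 1000, min_width = 2) {
  n <- length(x)
  ms <- cbs_test_split(x, alpha, nperm, min_width)
  if (is.null(ms)) return(rep(1L, n))
  arc <- (ms$i + 1):ms$j
  rest <- c(if (ms$j < n) (ms$j + 1):n, if (ms$i > 0) 1:ms$i)
  ids_arc <- cbs_assign_linear(x[arc], alpha, nperm, min_width)
  ids_rest <- cbs_assign_linear(x[rest], alpha, nperm, min_width)
  assignment <- integer(n)
  assignment[arc] <- ids_arc
  assignment[rest] <- ids_rest + max(ids_arc)
  match(assignment, unique(assignment))
}
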