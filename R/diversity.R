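#' Rarefy a count vector without replacement
#'
#' Draws a multivariate-hypergeometric subsample of exactly `depth` reads,
#' i.e. sampling reads without replacement, matching mothur's subsampling
#' semantics. Implemented by sequential univariate hypergeometric draws, so
#' it is exact and fast regardless of total depth.
#'
#' @param counts non-negative integer count vector (one sample).
#' @param depth target depth; must not exceed `sum(counts)` (a shallow
#'   sample is never silently kept).
#' @param seed optional integer seed; when NULL the current RNG stream is
#'   used (the iteration drivers manage seeding).
#' @return integer vector of the same length summing exactly to `depth`.
#' @examples
#' rarefyCounts(c(10, 0, 0), 4)          # c(4, 0, 0)
#' rarefyCounts(c(50, 50), 20, seed = 1) # sums to 20
#' @export
rarefyCounts <- function(counts, depth, seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  if (any(counts < 0)) stop("negative counts")
  total <- sum(counts)
  if (depth > total)
    stop(sprintf("depth (%g) exceeds sample total (%g)", depth, total))
  if (depth == total) return(as.integer(counts))
  out <- integer(length(counts))
  need <- as.integer(depth)
  remaining <- total
  for (j in seq_along(counts)) {
    if (need == 0L) break
    nj <- counts[j]
    remaining <- remaining - nj
    x <- if (remaining == 0) need else stats::rhyper(1, nj, remaining, need)
    out[j] <- x
    need <- need - x
  }
  names(out) <- names(counts)
  out
}

#' Alpha diversity of one count vector
#'
#' With proportions `p_i = n_i / N`: Simpson concentration `D = sum p_i^2`,
#' Gini-Simpson diversity `1 - D`, observed richness `S_obs` (number of
#' positive counts), and Simpson evenness `E_D = (1/D) / S_obs`. The
#' plug-in `p^2` form is used (no finite-sample correction) -- after
#' rarefaction to a common depth the bias is shared across samples; the
#' unbiased `n(n-1)` form is available via `correction = "unbiased"`.
#'
#' @param counts count vector with at least one positive entry.
#' @param correction `"plugin"` (default) or `"unbiased"`
#'   (`D = sum n_i (n_i - 1) / (N (N - 1))`).
#' @return named list with `S_obs`, `E_D`, `one_minus_D`.
#' @examples
#' alphaMetrics(c(1, 3))  # D = 0.625, 1 - D = 0.375, E_D = 0.8
#' @export
alphaMetrics <- function(counts, correction = c("plugin", "unbiased")) {
  correction <- match.arg(correction)
  N <- sum(counts)
  if (N <= 0) stop("all-zero count vector")
  s_obs <- sum(counts > 0)
  D <- if (correction == "plugin") {
    sum((counts / N)^2)
  } else {
    if (N < 2) 1 else sum(counts * (counts - 1)) / (N * (N - 1))
  }
  list(S_obs = as.integer(s_obs), E_D = (1 / D) / s_obs, one_minus_D = 1 - D)
}

# counter-based per-iteration seed: results are independent of iteration
# order and of how many iterations other stages consumed.
.iterSeed <- function(seed, iter) {
  as.integer((as.double(seed) * 7919 + iter * 104729) %% 2147483647)
}

#' Mean rarefied alpha diversity over iterations
#'
#' Each iteration independently rarefies every sample to `depth` and
#' computes the three alpha metrics; the per-sample arithmetic means over
#' all iterations are returned. Deterministic given `seed` (per-iteration
#' seeds are derived by a counter scheme).
#'
#' @param table an [OtuTable-class].
#' @param depth subsampling depth; at most the smallest sample total.
#' @param iterations number of independent rarefactions.
#' @param seed integer master seed.
#' @param correction passed to [alphaMetrics()].
#' @return data.frame with one row per sample: `sample`, `S_obs`, `E_D`,
#'   `one_minus_D`.
#' @export
meanRarefiedAlpha <- function(table, depth, iterations = 1000, seed,
                              correction = "plugin") {
  m <- otuCounts(table)
  if (depth > min(rowSums(m)))
    stop("depth exceeds the smallest sample total")
  acc <- matrix(0, nrow(m), 3,
                dimnames = list(rownames(m), c("S_obs", "E_D", "one_minus_D")))
  for (it in seq_len(iterations)) {
    set.seed(.iterSeed(seed, it))
    for (i in seq_len(nrow(m))) {
      a <- alphaMetrics(rarefyCounts(m[i, ], depth), correction = correction)
      acc[i, ] <- acc[i, ] + c(a$S_obs, a$E_D, a$one_minus_D)
    }
  }
  acc <- acc / iterations
  data.frame(sample = rownames(m), acc, row.names = NULL,
             check.names = FALSE)
}

#' Mean rarefied Bray-Curtis dissimilarity matrix
#'
#' Each iteration rarefies every sample to a common `depth` and computes
#' Bray-Curtis dissimilarity
#' `BC(x, y) = 1 - 2 sum min(x_i, y_i) / (sum x + sum y)` on the rarefied
#' pair; the element-wise mean over iterations is returned.
#'
#' @inheritParams meanRarefiedAlpha
#' @return symmetric numeric matrix with zero diagonal, entries in [0, 1],
#'   sample ids as dimnames.
#' @export
meanBrayCurtis <- function(table, depth, iterations = 1000, seed) {
  m <- otuCounts(table)
  if (depth > min(rowSums(m)))
    stop("depth exceeds the smallest sample total")
  acc <- matrix(0, nrow(m), nrow(m),
                dimnames = list(rownames(m), rownames(m)))
  for (it in seq_len(iterations)) {
    set.seed(.iterSeed(seed, it))
    rf <- t(vapply(seq_len(nrow(m)),
                   function(i) rarefyCounts(m[i, ], depth),
                   integer(ncol(m))))
    stopifnot(all(rowSums(rf) == depth))
    acc <- acc + as.matrix(vegan::vegdist(rf, method = "bray"))
  }
  acc / iterations
}
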