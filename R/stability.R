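#' Best-match Jaccard similarity of two partitions
#'
#' For every reference module `R`, the maximum over candidate clusters `C`
#' of `|R intersect C| / |R union C|`. Both partitions must cover the same
#' OTU universe. The unassigned (`"grey"` / `0`) pool is excluded from the
#' candidate side by default, so a reference module is never "matched" by
#' the leftover pool; set `include_unassigned = TRUE` to allow it. The
#' measure is invariant to OTU order and to candidate cluster labels.
#'
#' @param reference,candidate partitions as named vectors (OTU -> label);
#'   `"grey"`, `"0"` and `0` denote unassigned.
#' @param include_unassigned logical; treat the candidate unassigned pool
#'   as a matchable cluster.
#' @return named numeric vector, one Jaccard value per reference module.
#' @examples
#' ref <- c(a = "m1", b = "m1", c = "m1")
#' cand <- c(a = "x", b = "x", c = "y")
#' bestMatchJaccard(ref, cand)  # m1 = 2/3
#' @export
bestMatchJaccard <- function(reference, candidate,
                             include_unassigned = FALSE) {
  if (is.null(names(reference)) || is.null(names(candidate)))
    stop("partitions must be named by OTU id")
  if (!setequal(names(reference), names(candidate)))
    stop("partitions are over different OTU universes")
  candidate <- candidate[names(reference)]
  unassigned <- function(v) v %in% c("grey", "0") | v == 0
  ref_labs <- unique(reference[!unassigned(reference)])
  cand_labs <- unique(candidate)
  if (!include_unassigned)
    cand_labs <- cand_labs[!unassigned(cand_labs)]
  out <- stats::setNames(numeric(length(ref_labs)), ref_labs)
  for (rl in ref_labs) {
    R <- names(reference)[reference == rl]
    best <- 0
    for (cl in cand_labs) {
      C <- names(candidate)[candidate == cl]
      j <- length(intersect(R, C)) / length(union(R, C))
      if (j > best) best <- j
    }
    out[as.character(rl)] <- best
  }
  out
}

#' Bootstrap clusterwise Jaccard stability of modules
#'
#' Re-derives modules on `B` bootstrap resamples of the **samples** (with
#' replacement) using identical network parameters, and records for each
#' reference module the best-match Jaccard similarity against the
#' re-derived partition. Resampling samples rather than OTUs makes the
#' score reflect robustness to which snows were collected. A module whose
#' Jaccard falls below `dissolution_threshold` in a replicate counts as
#' dissolved there (threshold 0.5 is the conventional choice). OTUs with
#' zero variance in a replicate are dropped for that replicate only and
#' count as unassigned in the candidate partition. Deterministic given
#' `seed`.
#'
#' @param h samples x OTUs matrix ([hellingerTransform()] output).
#' @param beta,mode adjacency parameters (see [softAdjacency()]).
#' @param min_module_size,cut,min_gap module-detection parameters
#'   (see [detectModules()]).
#' @param B number of bootstrap replicates (>= 1).
#' @param seed integer master seed.
#' @param reference optional reference [ModuleSet-class]; when NULL the
#'   modules detected on the full data with the same parameters are used.
#' @param dissolution_threshold Jaccard below which a module counts as
#'   dissolved (default 0.5).
#' @param resample internal hook: a `function(n)` returning the replicate's
#'   sample indices (default: `sample(n, replace = TRUE)`).
#' @return a [StabilityReport-class].
#' @export
bootstrapStability <- function(h, beta = 4, mode = "unsigned",
                               min_module_size = 5, cut = "dynamic",
                               min_gap = 0.2, B = 100, seed,
                               reference = NULL,
                               dissolution_threshold = 0.5,
                               resample = NULL) {
  h <- as.matrix(h)
  n <- nrow(h)
  if (B < 1) stop("B must be >= 1")
  if (n < 5) stop("need at least 5 samples to resample")
  if (missing(seed)) stop("'seed' is required")
  if (is.null(resample))
    resample <- function(n) sample.int(n, replace = TRUE)
  runDetect <- function(hh) {
    a <- suppressWarnings(softAdjacency(hh, beta = beta, mode = mode))
    dropped <- attr(a, "excluded")
    ms <- detectModules(tomSimilarity(a), min_module_size = min_module_size,
                        cut = cut, min_gap = min_gap)
    lab <- moduleLabels(ms)
    if (length(dropped))
      lab <- c(lab, stats::setNames(rep("grey", length(dropped)), dropped))
    lab[colnames(h)]
  }
  if (is.null(reference)) {
    ref_lab <- runDetect(h)
  } else {
    ref_lab <- moduleLabels(reference)[colnames(h)]
  }
  names(ref_lab) <- colnames(h)
  ref_mods <- setdiff(unique(ref_lab), "grey")
  if (!length(ref_mods)) stop("reference partition has no modules")
  jac <- matrix(NA_real_, B, length(ref_mods),
                dimnames = list(NULL, ref_mods))
  for (b in seq_len(B)) {
    set.seed(.iterSeed(seed, b))
    idx <- resample(n)
    cand <- runDetect(h[idx, , drop = FALSE])
    names(cand) <- colnames(h)
    jac[b, ] <- bestMatchJaccard(ref_lab, cand)[ref_mods]
  }
  sz <- table(ref_lab)[ref_mods]
  tab <- data.frame(module = ref_mods, size = as.integer(sz),
                    mean_jaccard = colMeans(jac),
                    dissolved_fraction =
                      colMeans(jac < dissolution_threshold),
                    stringsAsFactors = FALSE)
  tab <- tab[order(-tab$size), , drop = FALSE]
  rownames(tab) <- NULL
  new("StabilityReport", stability = tab, B = as.integer(B),
      seed = as.integer(seed),
      dissolutionThreshold = dissolution_threshold)
}
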