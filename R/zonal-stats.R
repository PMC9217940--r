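#' Wilcoxon rank-sum (Mann-Whitney) test with median-difference effect size
#'
#' Two-sided test of a location difference between two independent groups.
#' The exact null distribution is used when `n1 + n2 <= 20` and there are
#' no ties; otherwise a normal approximation with tie correction and
#' continuity correction. The reported statistic `S` is the centered rank
#' sum of group 1, `S = W1 - n1 (N + 1) / 2`, so its sign follows the
#' group order: with groups ordered (Rockies, Cascades), positive values
#' indicate larger values in the Rockies. The effect size is the median
#' difference `MD = median(x) - median(y)`.
#'
#' @param x,y numeric values of group 1 and group 2 (both non-empty).
#' @param mode `"auto"` (exact when feasible), `"exact"`, or `"normal"`.
#' @return list of class `"wocnaTest"`: `statistic_S`, `p_value`,
#'   `median_difference`, `n_used`, `method`.
#' @examples
#' rankSumTest(c(1, 2, 3), c(4, 5, 6))  # exact two-sided p = 0.1
#' @export
rankSumTest <- function(x, y, mode = c("auto", "exact", "normal")) {
  mode <- match.arg(mode)
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (!length(x) || !length(y)) stop("both groups must be non-empty")
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  all_v <- c(x, y)
  r <- rank(all_v)
  ties <- as.vector(table(all_v))
  has_ties <- any(ties > 1)
  W1 <- sum(r[seq_len(n1)])
  U <- W1 - n1 * (n1 + 1) / 2
  S <- W1 - n1 * (N + 1) / 2
  exact <- switch(mode,
                  auto = N <= 20 && !has_ties,
                  exact = TRUE,
                  normal = FALSE)
  if (exact && has_ties) {
    warning("ties present; falling back to the normal approximation")
    exact <- FALSE
  }
  if (exact) {
    p <- 2 * min(stats::pwilcox(U, n1, n2),
                 1 - stats::pwilcox(U - 1, n1, n2))
    method <- "exact rank-sum"
  } else {
    mu <- n1 * n2 / 2
    sig2 <- n1 * n2 / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    cc <- sign(U - mu) * 0.5
    z <- if (sig2 > 0) (U - mu - cc) / sqrt(sig2) else 0
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal approximation (tie- and continuity-corrected)"
  }
  structure(list(statistic_S = S, p_value = min(p, 1),
                 median_difference = stats::median(x) - stats::median(y),
                 n_used = N, method = method),
            class = "wocnaTest")
}

#' Wilcoxon signed-rank test on paired differences
#'
#' Exact zeros are dropped before ranking (Wilcoxon's original procedure);
#' absolute differences are ranked with average ranks for ties. The
#' reported statistic uses the half-sum-of-signed-ranks convention
#' `S = (W+ - W-) / 2 = W+ - n(n+1)/4`, so `|S| <= n(n+1)/4`; for 9
#' untied positive differences `S = 22.5`. The exact two-sided p-value is
#' obtained from the `2^n` sign-pattern distribution when `n <= 25` and the
#' absolute differences are untied; otherwise a normal approximation with
#' tie-corrected variance is used. Two-sided p-values are capped at 1.
#'
#' @param differences numeric vector of paired differences; at least one
#'   must be non-zero.
#' @param mode `"auto"`, `"exact"`, or `"normal"`.
#' @return list of class `"wocnaTest"`: `statistic_S`, `p_value`,
#'   `median_difference` (median of the non-zero differences), `n_used`
#'   (non-zero pairs), `method`.
#' @examples
#' signedRankTest(1:9)            # S = 22.5, p = 0.00390625
#' signedRankTest(c(1, -2, 3))    # S = 1, exact p = 0.75
#' @export
signedRankTest <- function(differences,
                           mode = c("auto", "exact", "normal")) {
  mode <- match.arg(mode)
  d <- differences[!is.na(differences)]
  d <- d[d != 0]
  if (!length(d)) stop("all differences are zero")
  n <- length(d)
  r <- rank(abs(d))
  ties <- as.vector(table(abs(d)))
  has_ties <- any(ties > 1)
  Wpos <- sum(r[d > 0])
  S <- Wpos - n * (n + 1) / 4
  exact <- switch(mode,
                  auto = n <= 25 && !has_ties,
                  exact = TRUE,
                  normal = FALSE)
  if (exact && has_ties) {
    warning("tied |differences|; falling back to the normal approximation")
    exact <- FALSE
  }
  if (exact) {
    p <- 2 * min(stats::psignrank(Wpos, n),
                 1 - stats::psignrank(Wpos - 1, n))
    method <- "exact signed-rank"
  } else {
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- if (sig2 > 0) S / sqrt(sig2) else 0
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal approximation (tie-corrected)"
  }
  structure(list(statistic_S = S, p_value = min(p, 1),
                 median_difference = stats::median(d), n_used = n,
                 method = method),
            class = "wocnaTest")
}

#' @export
print.wocnaTest <- function(x, ...) {
  cat(sprintf("%s: S = %g, p = %g, MD = %g, n = %d\n",
              x$method, x$statistic_S, x$p_value, x$median_difference,
              x$n_used))
  invisible(x)
}

#' Taxonomic roll-up with low-abundance grouping
#'
#' Aggregates counts by lineage at the chosen rank and computes relative
#' abundances; taxa whose share of the total count falls below `threshold`
#' are merged into a single `"remainder"` column, so every row still sums
#' to 1. With `scope = "per_group"` the rows are region x zone groups
#' (abundances relative to each group's total); with `scope = "per_total"`
#' a single row over all samples is returned.
#'
#' @param table an [OtuTable-class] with complete taxonomy.
#' @param rank one of kingdom, phylum, class, order, family, genus, species.
#' @param threshold relative-abundance fraction in `[0, 1)` below which a
#'   taxon (by total RA) is grouped into the remainder.
#' @param scope `"per_group"` or `"per_total"`.
#' @return data.frame, rows = groups, columns = retained taxa (decreasing
#'   total abundance) plus `"remainder"` when non-empty; attributes `rank`
#'   and `threshold`.
#' @export
taxonRollup <- function(table, rank = "family", threshold = 0.01,
                        scope = c("per_group", "per_total")) {
  scope <- match.arg(scope)
  if (!rank %in% TAX_RANKS)
    stop("unknown rank: ", rank, " (use one of ",
         paste(TAX_RANKS, collapse = ", "), ")")
  stopifnot(threshold >= 0, threshold < 1)
  m <- otuCounts(table)
  taxon <- taxonomyTable(table)[[rank]]
  agg <- t(rowsum(t(m), group = taxon))      # samples x taxa
  total_ra <- colSums(agg) / sum(agg)
  keep <- names(sort(total_ra[total_ra >= threshold], decreasing = TRUE))
  if (scope == "per_total") {
    groups <- factor(rep("all", nrow(m)))
  } else {
    sm <- sampleData(table)
    groups <- factor(paste(sm$region, sm$zone, sep = "."))
  }
  by_group <- rowsum(agg, group = groups)    # groups x taxa
  ra <- sweep(by_group, 1, rowSums(by_group), "/")
  out <- as.data.frame(ra[, keep, drop = FALSE], check.names = FALSE)
  remainder <- 1 - rowSums(out)
  if (length(keep) < ncol(ra)) out$remainder <- remainder
  attr(out, "rank") <- rank
  attr(out, "threshold") <- threshold
  out
}

#' Paired zone screening with signed-rank tests
#'
#' For each zone pair and each target (an environmental feature or a taxon
#' at a chosen rank), forms within-bloom paired differences
#' `value(zone1) - value(zone2)` and runs [signedRankTest()]. Taxon values
#' are per-sample relative abundances within the table's own counts (so a
#' lineage-specific table yields within-lineage RA). Blooms missing either
#' zone are excluded; `n_used` reports the pairs actually tested. Raw
#' p-values are reported by default; `p_adjust = "BH"` adds a
#' Benjamini-Hochberg column.
#'
#' @param table an [OtuTable-class] with `zone` and `bloom_id` metadata.
#' @param targets character vector of targets: feature names when
#'   `env` is supplied and `data = "env"`, else taxon names at `rank`.
#' @param pairs character vector of zone pairs, e.g. `c("M-P","M-A","P-A")`.
#' @param data `"taxa"` or `"env"`.
#' @param env an [EnvTable-class] (required when `data = "env"`).
#' @param rank taxonomy rank for taxon targets.
#' @param p_adjust `"none"` (default) or `"BH"`.
#' @return data.frame with columns `target`, `zone1`, `zone2`, `MD`, `S`,
#'   `p`, `n_used` (and `p_adj` when requested), sorted as given.
#' @export
zonePairScreen <- function(table, targets, pairs = c("M-P", "M-A", "P-A"),
                           data = c("taxa", "env"), env = NULL,
                           rank = "species", p_adjust = c("none", "BH")) {
  data <- match.arg(data)
  p_adjust <- match.arg(p_adjust)
  sm <- sampleData(table)
  if (any(is.na(sm$zone)) || any(is.na(sm$bloom_id)))
    stop("zone and bloom_id metadata are required for zone screening")
  if (data == "env") {
    if (is.null(env)) stop("env table required when data = 'env'")
    vals <- envData(env)[rownames(sm), , drop = FALSE]
  } else {
    ra <- relativeAbundance(table)
    taxon <- taxonomyTable(table)[[rank]]
    vals <- as.data.frame(t(rowsum(t(ra), group = taxon)),
                          check.names = FALSE)
  }
  missing_t <- setdiff(targets, colnames(vals))
  if (length(missing_t))
    stop("unknown target(s): ", paste(missing_t, collapse = ", "))
  rows <- list()
  for (pr in pairs) {
    zz <- strsplit(pr, "-", fixed = TRUE)[[1]]
    if (length(zz) != 2 || !all(zz %in% c("M", "P", "A")))
      stop("invalid zone pair: ", pr)
    for (tg in targets) {
      v <- vals[[tg]]
      v1 <- tapply(ifelse(sm$zone == zz[1], v, NA), sm$bloom_id,
                   function(u) if (all(is.na(u))) NA else sum(u, na.rm = TRUE))
      v2 <- tapply(ifelse(sm$zone == zz[2], v, NA), sm$bloom_id,
                   function(u) if (all(is.na(u))) NA else sum(u, na.rm = TRUE))
      ok <- !is.na(v1) & !is.na(v2)
      dd <- v1[ok] - v2[ok]
      if (!length(dd) || all(dd == 0)) {
        rows[[length(rows) + 1L]] <-
          data.frame(target = tg, zone1 = zz[1], zone2 = zz[2],
                     MD = stats::median(v1[ok]) - stats::median(v2[ok]),
                     S = 0, p = 1, n_used = 0L, stringsAsFactors = FALSE)
        next
      }
      tst <- signedRankTest(dd)
      rows[[length(rows) + 1L]] <-
        data.frame(target = tg, zone1 = zz[1], zone2 = zz[2],
                   MD = stats::median(v1[ok]) - stats::median(v2[ok]),
                   S = tst$statistic_S, p = tst$p_value,
                   n_used = tst$n_used, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (p_adjust == "BH") out$p_adj <- stats::p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  out
}
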