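#' Hellinger transformation of a count table
#'
#' Per sample, the square root of relative abundance:
#' `h_ij = sqrt(n_ij / N_i)`. Each row of the result has unit squared
#' norm, the transform downweights rare OTUs relative to abundant ones,
#' and it is invariant to multiplying a sample's counts by a constant.
#' This transformed matrix is the input to the correlation network.
#'
#' @param x an [OtuTable-class] or a numeric matrix with samples as rows.
#' @return numeric matrix of the same shape.
#' @examples
#' hellingerTransform(matrix(c(1, 4, 4), 1, dimnames = list("s1", NULL)))
#' @export
hellingerTransform <- function(x) {
  m <- if (is(x, "OtuTable")) otuCounts(x) else as.matrix(x)
  tot <- rowSums(m)
  if (any(tot == 0)) {
    bad <- rownames(m)[tot == 0]
    stop("all-zero sample(s): ",
         paste(if (is.null(bad)) which(tot == 0) else bad, collapse = ", "))
  }
  sqrt(sweep(m, 1, tot, "/"))
}

#' Kendall tau-b correlation with a two-sided p-value
#'
#' Tie-corrected tau-b from the concordant/discordant pair counts. The
#' p-value is exact (complete enumeration of rank permutations) when
#' `n <= 8` and neither vector has ties; otherwise a normal approximation
#' with the tie-corrected variance of the S statistic is used. Pairs with
#' a missing value in either vector are removed first (pairwise deletion).
#' A constant vector leaves tau undefined: the result is flagged and its
#' tau/p are `NA` so downstream consumers can exclude it.
#'
#' @param x,y numeric vectors of equal length (>= 3 after missing-pair
#'   removal).
#' @param p_mode `"auto"`, `"exact"`, or `"normal"`.
#' @return list: `tau`, `p`, `n` (pairs used), `flagged` (logical).
#' @examples
#' kendallTau(1:4, c(1, 3, 2, 4))  # tau = 2/3
#' @export
kendallTau <- function(x, y, p_mode = c("auto", "exact", "normal")) {
  p_mode <- match.arg(p_mode)
  ok <- !(is.na(x) | is.na(y))
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3)
    return(list(tau = NA_real_, p = NA_real_, n = n, flagged = TRUE))
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(tau = NA_real_, p = NA_real_, n = n, flagged = TRUE))
  S <- .kendallS(x, y)
  tx <- as.vector(table(x)); ty <- as.vector(table(y))
  n0 <- n * (n - 1) / 2
  n1 <- sum(tx * (tx - 1) / 2)
  n2 <- sum(ty * (ty - 1) / 2)
  tau <- S / sqrt((n0 - n1) * (n0 - n2))
  has_ties <- n1 > 0 || n2 > 0
  exact <- switch(p_mode,
                  auto = n <= 8 && !has_ties,
                  exact = TRUE,
                  normal = FALSE)
  if (exact && (has_ties || n > 8)) {
    warning("exact p requires n <= 8 and no ties; using normal approximation")
    exact <- FALSE
  }
  if (exact) {
    perms <- .allPermutations(n)
    ys <- sort(y)
    Sp <- apply(perms, 1, function(idx) .kendallS(x, ys[idx]))
    p <- mean(abs(Sp) >= abs(S) - 1e-12)
  } else {
    v0 <- n * (n - 1) * (2 * n + 5)
    vt <- sum(tx * (tx - 1) * (2 * tx + 5))
    vu <- sum(ty * (ty - 1) * (2 * ty + 5))
    v1 <- sum(tx * (tx - 1)) * sum(ty * (ty - 1)) / (2 * n * (n - 1))
    v2 <- sum(tx * (tx - 1) * (tx - 2)) * sum(ty * (ty - 1) * (ty - 2)) /
      (9 * n * (n - 1) * (n - 2))
    varS <- (v0 - vt - vu) / 18 + v1 + v2
    z <- if (varS > 0) S / sqrt(varS) else 0
    p <- 2 * stats::pnorm(-abs(z))
  }
  list(tau = tau, p = min(p, 1), n = n, flagged = FALSE)
}

# S = (#concordant - #discordant) over all pairs; ties contribute 0.
.kendallS <- function(x, y) {
  dx <- sign(outer(x, x, "-"))
  dy <- sign(outer(y, y, "-"))
  sum((dx * dy)[upper.tri(dx)])
}

#' Soft-thresholded correlation adjacency
#'
#' Pearson correlation of Hellinger-transformed OTU profiles raised to a
#' soft power: unsigned `a_ij = |cor|^beta`, signed
#' `a_ij = ((1 + cor) / 2)^beta`. Zero-variance OTU columns cannot be
#' correlated and are excluded with a warning; their ids are recorded in
#' the `"excluded"` attribute.
#'
#' @param h numeric matrix, samples x OTUs (typically
#'   [hellingerTransform()] output).
#' @param beta soft power, >= 1 (default 4, a mid-range choice for OTU-scale networks).
#' @param mode `"unsigned"` (default) or `"signed"`.
#' @param cor_method correlation underlying the adjacency: `"pearson"`
#'   (default) or `"kendall"` (tau-b).
#' @return symmetric matrix in [0, 1] with unit diagonal; attributes
#'   `beta`, `mode`, `excluded`.
#' @export
softAdjacency <- function(h, beta = 4, mode = c("unsigned", "signed"),
                          cor_method = c("pearson", "kendall")) {
  mode <- match.arg(mode)
  cor_method <- match.arg(cor_method)
  if (beta < 1) stop("beta must be >= 1")
  h <- as.matrix(h)
  sds <- apply(h, 2, stats::sd)
  excluded <- colnames(h)[sds == 0]
  if (length(excluded)) {
    warning("excluding zero-variance OTU column(s): ",
            paste(excluded, collapse = ", "))
    h <- h[, sds > 0, drop = FALSE]
  }
  r <- stats::cor(h, method = cor_method)
  a <- if (mode == "unsigned") abs(r)^beta else ((1 + r) / 2)^beta
  a <- pmin(pmax(a, 0), 1)
  diag(a) <- 1
  attr(a, "beta") <- beta
  attr(a, "mode") <- mode
  attr(a, "excluded") <- excluded
  a
}

#' Pick a soft power by scale-free topology fit
#'
#' For each candidate power, builds the adjacency, computes the
#' connectivity `k_i = sum_j a_ij - 1`, bins `k`, and regresses
#' `log10(frequency)` on `log10(mean k)` over occupied bins. The signed
#' fit index is `-sign(slope) * R^2` (scale-free networks have a negative
#' slope). The smallest power reaching `target_fit` is chosen; if none
#' does, the best-fitting power is returned with flag `"unverified"`, as
#' is a single-element candidate list.
#'
#' @param h samples x OTUs matrix ([hellingerTransform()] output).
#' @param powers candidate soft powers.
#' @param target_fit signed R^2 to reach (default 0.8).
#' @param n_bins number of connectivity bins (default 10).
#' @param mode adjacency mode, see [softAdjacency()].
#' @return list: `beta` (chosen power), `fit_table` (data.frame `power`,
#'   `signed_R2`, `mean_k`, `n_bins`), `flag` (`""` or `"unverified"`).
#' @export
pickSoftPower <- function(h, powers = c(1:10, seq(12, 20, 2)),
                          target_fit = 0.8, n_bins = 10,
                          mode = "unsigned") {
  rows <- lapply(powers, function(b) {
    a <- suppressWarnings(softAdjacency(h, beta = b, mode = mode))
    k <- rowSums(a) - 1
    brk <- seq(min(k), max(k), length.out = n_bins + 1)
    bin <- cut(k, breaks = brk, include.lowest = TRUE)
    freq <- as.vector(table(bin)) / length(k)
    kmean <- tapply(k, bin, mean)
    use <- freq > 0 & !is.na(kmean) & kmean > 0
    if (sum(use) < 3)
      return(data.frame(power = b, signed_R2 = NA_real_, mean_k = mean(k),
                        n_bins = sum(use)))
    fit <- stats::lm(log10(freq[use]) ~ log10(kmean[use]))
    r2 <- summary(fit)$r.squared
    slope <- stats::coef(fit)[2]
    data.frame(power = b, signed_R2 = -sign(slope) * r2, mean_k = mean(k),
               n_bins = sum(use))
  })
  ft <- do.call(rbind, rows)
  rownames(ft) <- NULL
  if (length(powers) < 2)
    return(list(beta = powers[1], fit_table = ft, flag = "unverified"))
  hit <- which(!is.na(ft$signed_R2) & ft$signed_R2 >= target_fit)
  if (length(hit)) {
    list(beta = ft$power[hit[1]], fit_table = ft, flag = "")
  } else {
    best <- which.max(ft$signed_R2)
    warning("no candidate power reached the target scale-free fit")
    list(beta = ft$power[best], fit_table = ft, flag = "unverified")
  }
}

#' Topological overlap matrix
#'
#' `TOM_ij = (sum_{u != i,j} a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)`
#' with connectivity `k_i = sum_{j != i} a_ij`, and `TOM_ii = 1`. Values
#' stay in [0, 1] for adjacencies in [0, 1]; high overlap means two OTUs
#' are connected to the same neighbourhood, the similarity the module
#' clustering operates on (via dissimilarity `1 - TOM`).
#'
#' @param adj symmetric adjacency in [0, 1] with unit diagonal
#'   (see [softAdjacency()]).
#' @return symmetric matrix in [0, 1] with unit diagonal; carries over the
#'   `beta`/`mode` attributes.
#' @export
tomSimilarity <- function(adj) {
  a <- as.matrix(adj)
  if (!isSymmetric(unname(a), tol = 1e-8)) stop("adjacency must be symmetric")
  if (any(a < -1e-12 | a > 1 + 1e-12)) stop("adjacency must lie in [0, 1]")
  A <- a
  diag(A) <- 0
  L <- A %*% A                       # sum_u a_iu a_uj, u != i (a_ii = 0)
  k <- rowSums(A)
  denom <- outer(k, k, pmin) + 1 - A
  tom <- (L + A) / denom
  diag(tom) <- 1
  tom <- pmin(pmax(tom, 0), 1)
  dimnames(tom) <- dimnames(a)
  attr(tom, "beta") <- attr(adj, "beta")
  attr(tom, "mode") <- attr(adj, "mode")
  tom
}

#' Detect modules by average-linkage clustering of topological overlap
#'
#' Clusters OTUs by average-linkage hierarchical clustering on the
#' dissimilarity `1 - TOM`, then cuts the dendrogram either statically at
#' a fixed height or with a basic gap-splitting dynamic cut. In the
#' dynamic cut a branch with at least `min_module_size` members qualifies
#' as a module when it is separated from the rest of the tree by a
#' merge-height gap of at least `min_gap` times the dendrogram's height
#' range. The gap is measured straggler-tolerantly: single leaves or small
#' side-branches (fewer than `min_module_size` members in total) joining
#' the branch on its way up do not close the gap -- the gap ends where the
#' branch meets a competing group of at least `min_module_size` members.
#' Among nested qualifying branches the most inclusive one wins, and only
#' the qualifying branch's own members are assigned (late stragglers stay
#' unassigned). OTUs in no accepted branch get the reserved `"grey"`
#' label; in structureless data no branch shows a gap and (almost)
#' everything stays grey. Labels are ordered by module size and mapped to
#' a stable colour alias table; the procedure is fully deterministic (no
#' RNG).
#'
#' @param tom TOM similarity matrix (see [tomSimilarity()]).
#' @param min_module_size minimum OTUs per module (>= 2).
#' @param cut `"dynamic"` (default) or a numeric height in (0, 1) for a
#'   static [stats::cutree()] cut.
#' @param min_gap minimum branch separation for the dynamic cut, as a
#'   fraction of the dendrogram height range (default 0.2).
#' @return a [ModuleSet-class] (eigen-OTUs empty until [eigenOtus()]).
#' @export
detectModules <- function(tom, min_module_size = 5, cut = "dynamic",
                          min_gap = 0.2) {
  if (min_module_size < 2) stop("min_module_size must be >= 2")
  tom <- as.matrix(tom)
  n <- nrow(tom)
  if (n < 2 * min_module_size)
    stop("need at least 2 * min_module_size OTUs")
  otus <- rownames(tom)
  if (is.null(otus)) otus <- paste0("otu", seq_len(n))
  d <- stats::as.dist(1 - tom)
  hc <- stats::hclust(d, method = "average")
  if (is.numeric(cut)) {
    raw <- stats::cutree(hc, h = cut)
  } else if (identical(cut, "dynamic")) {
    raw <- .gapCut(hc, min_module_size, min_gap)
  } else {
    stop("cut must be 'dynamic' or a numeric height")
  }
  sizes <- table(raw[raw != 0])
  keep <- names(sizes)[sizes >= min_module_size]
  lab <- rep("grey", n)
  if (length(keep)) {
    first_member <- vapply(keep, function(k) min(which(raw == k)), 1L)
    ord <- keep[order(-as.integer(sizes[keep]), first_member)]
    for (i in seq_along(ord)) lab[raw == ord[i]] <- paste0("M", i)
  }
  names(lab) <- otus
  labs <- if (length(keep)) paste0("M", seq_along(keep)) else character(0)
  colors <- stats::setNames(.MODULE_COLORS[seq_along(labs)], labs)
  new("ModuleSet", moduleOf = lab,
      eigenOtus = matrix(numeric(0), 0, 0),
      varExplained = stats::setNames(numeric(0), character(0)),
      colors = colors, flags = character(0))
}

.MODULE_COLORS <- c("turquoise", "blue", "brown", "yellow", "green", "red",
                    "black", "pink", "magenta", "purple", "greenyellow",
                    "tan", "salmon", "cyan", "midnightblue", "lightcyan",
                    paste0("extra", 1:200))

# Basic gap-splitting tree cut. Returns integer labels, 0 = unassigned.
# A branch's gap runs from its own merge height to the height at which it
# meets a competing group of >= min_size members (small stragglers joining
# in between are ignored); branches with gap >= min_gap * height range
# qualify, the most inclusive qualifying branches win, and only branch
# members (not absorbed stragglers) are assigned.
.gapCut <- function(hc, min_size, min_gap) {
  n <- length(hc$order)
  n_nodes <- nrow(hc$merge)
  members <- vector("list", n_nodes)
  size <- integer(n_nodes)
  for (k in seq_len(n_nodes)) {
    kids <- hc$merge[k, ]
    mem <- integer(0)
    for (ch in kids)
      mem <- c(mem, if (ch < 0) -ch else members[[ch]])
    members[[k]] <- mem
    size[k] <- length(mem)
  }
  parent <- rep(NA_integer_, n_nodes)
  for (k in seq_len(n_nodes)) {
    kids <- hc$merge[k, ]
    for (ch in kids[kids > 0]) parent[ch] <- k
  }
  rng <- max(hc$height) - min(hc$height)
  if (rng <= 0) return(integer(n))
  ext_height <- rep(NA_real_, n_nodes)
  for (v in seq_len(n_nodes)) {
    if (size[v] < min_size) next
    cur <- v
    repeat {
      a <- parent[cur]
      if (is.na(a)) {               # reached the root
        ext_height[v] <- hc$height[n_nodes]
        break
      }
      if (size[a] - size[v] >= min_size) {
        ext_height[v] <- hc$height[a]
        break
      }
      cur <- a
    }
  }
  gap <- ext_height - hc$height
  candidate <- !is.na(gap) & gap >= min_gap * rng & size >= min_size
  # bottom-up selection: a qualifying branch absorbs a single nested
  # qualifying sub-branch (the inclusive branch wins), but yields when it
  # unites two or more disjoint qualifying branches -- a separable union
  # is a set of modules, not one
  n_cand <- integer(n_nodes)     # disjoint candidates at or below the node
  chosen_below <- vector("list", n_nodes)
  for (k in seq_len(n_nodes)) {
    kids <- hc$merge[k, ][hc$merge[k, ] > 0]
    kid_cand <- sum(n_cand[kids])
    kid_chosen <- as.integer(unlist(chosen_below[kids]))
    if (candidate[k] && kid_cand < 2) {
      n_cand[k] <- 1L
      chosen_below[[k]] <- k
    } else {
      n_cand[k] <- kid_cand
      chosen_below[[k]] <- kid_chosen
    }
  }
  chosen <- chosen_below[[n_nodes]]
  lab <- integer(n)
  for (i in seq_along(chosen)) lab[members[[chosen[i]]]] <- i
  lab
}

#' Compute eigen-OTUs for a module set
#'
#' Per module, the first principal component of the column-standardized
#' member profiles: scores are scaled to unit variance and sign-oriented so
#' that the mean correlation with the member profiles is non-negative
#' (ties broken toward a positive first-loading sum). `varExplained`
#' records the fraction of standardized member variance the component
#' captures. Singleton modules return their own standardized profile and
#' are flagged, as are modules whose orientation is ambiguous (mean member
#' correlation near zero, e.g. two anti-correlated halves forced into one
#' module).
#'
#' @param h samples x OTUs matrix ([hellingerTransform()] output).
#' @param modules a [ModuleSet-class] from [detectModules()].
#' @return the `ModuleSet` with `eigenOtus`, `varExplained` and `flags`
#'   filled in.
#' @export
eigenOtus <- function(h, modules) {
  h <- as.matrix(h)
  lab <- moduleLabels(modules)
  stopifnot(all(names(lab) %in% colnames(h)))
  labs <- names(moduleSizes(modules))
  labs <- labs[labs != "grey"]
  scores <- matrix(NA_real_, length(labs), nrow(h),
                   dimnames = list(labs, rownames(h)))
  ve <- stats::setNames(rep(NA_real_, length(labs)), labs)
  flags <- character(0)
  for (md in labs) {
    mem <- names(lab)[lab == md]
    X <- h[, mem, drop = FALSE]
    Xs <- scale(X)
    Xs[, attr(Xs, "scaled:scale") == 0] <- 0
    if (length(mem) == 1L) {
      sc <- as.numeric(Xs)
      ve[md] <- 1
      flags <- c(flags, md)
    } else {
      sv <- svd(Xs)
      sc <- sv$u[, 1] * sv$d[1]
      ve[md] <- sv$d[1]^2 / sum(sv$d^2)
      cors <- suppressWarnings(stats::cor(sc, X))
      mc <- mean(cors, na.rm = TRUE)
      if (is.na(mc)) mc <- 0
      if (mc < 0 || (mc == 0 && sum(sv$v[, 1]) < 0)) {
        sc <- -sc
        mc <- -mc
      }
      if (abs(mc) < 0.1) flags <- c(flags, md)
    }
    s <- stats::sd(sc)
    if (s > 0) sc <- sc / s
    scores[md, ] <- sc
  }
  new("ModuleSet", moduleOf = lab, eigenOtus = scores, varExplained = ve,
      colors = modules@colors, flags = unique(c(modules@flags, flags)))
}

#' Kendall-tau correlation of modules with traits and focal OTUs
#'
#' Correlates every module eigen-OTU with every environmental feature
#' and/or every focal OTU profile (typically relative abundances of
#' user-selected highly abundant OTUs), using [kendallTau()] with pairwise
#' missing-value removal. Cells with fewer than 3 complete pairs are `NA`.
#'
#' @param modules a [ModuleSet-class] with eigen-OTUs computed.
#' @param env an [EnvTable-class] or NULL.
#' @param focal numeric matrix (samples x focal OTUs) or NULL.
#' @return list with elements `env` and/or `otu`, each a
#'   [CorrelationHeatmap-class].
#' @export
moduleCorrelations <- function(modules, env = NULL, focal = NULL) {
  E <- eigenOtuScores(modules)
  if (!nrow(E)) stop("modules have no eigen-OTUs; run eigenOtus() first")
  corBlock <- function(vars) {
    vars <- as.matrix(vars)
    stopifnot(nrow(vars) == ncol(E))
    tau <- p <- matrix(NA_real_, nrow(E), ncol(vars),
                       dimnames = list(rownames(E), colnames(vars)))
    for (i in seq_len(nrow(E))) {
      for (j in seq_len(ncol(vars))) {
        kt <- kendallTau(E[i, ], vars[, j])
        if (!kt$flagged) {
          tau[i, j] <- kt$tau
          p[i, j] <- kt$p
        }
      }
    }
    new("CorrelationHeatmap", tau = tau, p = p)
  }
  out <- list()
  if (!is.null(env)) {
    d <- envData(env)
    d <- d[colnames(E), , drop = FALSE]
    out$env <- corBlock(d)
  }
  if (!is.null(focal)) {
    focal <- as.matrix(focal)
    out$otu <- corBlock(focal[colnames(E), , drop = FALSE])
  }
  out
}

#' Classical MDS embedding of the topological overlap structure
#'
#' Torgerson (classical) multidimensional scaling on the dissimilarity
#' `1 - TOM`: coordinates are centered and the axes ordered by eigenvalue.
#' When `k` exceeds the configuration's rank the trailing axes are filled
#' with zeros and a warning is raised.
#'
#' @param tom TOM similarity matrix.
#' @param k number of output dimensions (>= 1).
#' @return numeric matrix (OTUs x k) of coordinates.
#' @export
mdsEmbed <- function(tom, k = 2) {
  stopifnot(k >= 1)
  tom <- as.matrix(tom)
  n <- nrow(tom)
  d <- stats::as.dist(1 - tom)
  k_eff <- min(k, n - 1)
  cmd <- suppressWarnings(stats::cmdscale(d, k = k_eff))
  if (ncol(cmd) < k) {
    warning(sprintf("requested %d axes, configuration supports %d; ",
                    k, ncol(cmd)), "trailing axes zero-filled")
    cmd <- cbind(cmd, matrix(0, n, k - ncol(cmd)))
  }
  rownames(cmd) <- rownames(tom)
  colnames(cmd) <- paste0("MDS", seq_len(ncol(cmd)))
  cmd
}
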