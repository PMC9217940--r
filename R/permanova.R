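#' Gower-center a distance matrix
#'
#' Computes `G = -1/2 * J * D^2 * J` with `J = I - 11'/n` the centering
#' projector, the inner-product matrix underlying distance-based ANOVA and
#' classical MDS. `G` is symmetric and its rows sum to zero.
#'
#' @param dist symmetric non-negative matrix (or `dist`) with zero diagonal.
#' @return symmetric matrix with zero row sums.
#' @export
gowerCenter <- function(dist) {
  D <- as.matrix(dist)
  if (!isSymmetric(unname(D), tol = 1e-8))
    stop("distance matrix must be symmetric")
  n <- nrow(D)
  A <- -0.5 * D^2
  rm_ <- rowMeans(A)
  G <- A - outer(rm_, rep(1, n)) - outer(rep(1, n), rm_) + mean(A)
  (G + t(G)) / 2
}

#' Single-covariate PerMANOVA on a distance matrix
#'
#' Permutational multivariate analysis of variance with one covariate at a
#' time (plus an implicit intercept), the design used when reporting one
#' DF = 1 row per environmental feature. With `G` the Gower-centered
#' matrix and `H` the hat matrix of the centered covariate:
#' `pseudo-F = [tr(HGH) / 1] / [tr((I-H) G (I-H)) / (N - 2)]`,
#' `R^2 = tr(HGH) / tr(G)`. Significance is assessed by permuting the
#' sample labels of the covariate; the reported p uses the add-one rule
#' `p = (1 + #{F_perm >= F_obs}) / (1 + n_permutations)`, so it is never
#' exactly zero. With `permutations = "exact"` all `n!` label permutations
#' are enumerated and `p = #{F_perm >= F_obs} / n!` (the identity
#' permutation is part of the enumeration). Negative eigenvalue mass of
#' non-Euclidean (e.g. Bray-Curtis) matrices is retained in the traces, as
#' in common adonis practice.
#'
#' Continuous covariates are z-scored before building the design (a
#' no-op in exact arithmetic; stabilizes floating point); factors and
#' two-level characters are encoded as 0/1 indicators.
#'
#' @param dist distance matrix (or `dist`) over the samples.
#' @param covariate numeric or categorical vector, one value per sample;
#'   samples with missing values are dropped (and counted in the result).
#' @param permutations integer number of random permutations (default
#'   9999) or `"exact"` for complete enumeration (n <= 8).
#' @param seed integer seed for the permutation stream.
#' @return list of class `"permanovaResult"`: `pseudo_F`, `R2`, `p_value`,
#'   `df_model`, `df_residual`, `n_permutations`, `n_used`, `n_dropped`.
#' @export
permanovaSingle <- function(dist, covariate, permutations = 9999, seed = 1) {
  D <- as.matrix(dist)
  ok <- !is.na(covariate)
  n_dropped <- sum(!ok)
  D <- D[ok, ok, drop = FALSE]
  covariate <- covariate[ok]
  n <- nrow(D)
  if (n < 3) stop("need at least 3 samples with covariate values")
  if (is.character(covariate)) covariate <- factor(covariate)
  if (is.factor(covariate)) {
    if (nlevels(droplevels(covariate)) != 2)
      stop("categorical covariates must have exactly 2 levels ",
           "(single-column design)")
    xx <- as.numeric(droplevels(covariate)) - 1
  } else {
    xx <- as.numeric(covariate)
  }
  if (stats::sd(xx) == 0) stop("constant covariate: pseudo-F is undefined")
  xx <- as.numeric(scale(xx))
  G <- gowerCenter(D)
  trG <- sum(diag(G))

  fstat <- function(xs) {
    xc <- xs - mean(xs)
    ssm <- as.numeric(crossprod(xc, G %*% xc)) / sum(xc^2)
    ssr <- trG - ssm
    (ssm / 1) / (ssr / (n - 2))
  }
  F_obs <- fstat(xx)
  ss_model <- as.numeric(crossprod(xx - mean(xx), G %*% (xx - mean(xx)))) /
    sum((xx - mean(xx))^2)

  if (identical(permutations, "exact")) {
    if (n > 8) stop("exact enumeration limited to n <= 8")
    perms <- .allPermutations(n)
    Fp <- apply(perms, 1, function(idx) fstat(xx[idx]))
    p <- mean(Fp >= F_obs - 1e-12)
    n_perm <- nrow(perms)
  } else {
    set.seed(as.integer(seed))
    n_perm <- as.integer(permutations)
    X <- vapply(seq_len(n_perm), function(b) xx[sample.int(n)],
                numeric(n))
    Xc <- sweep(X, 2, colMeans(X), "-")
    ssm <- colSums(Xc * (G %*% Xc)) / colSums(Xc^2)
    Fp <- ssm / ((trG - ssm) / (n - 2))
    p <- (1 + sum(Fp >= F_obs - 1e-12)) / (1 + n_perm)
  }
  structure(list(pseudo_F = F_obs, R2 = ss_model / trG, p_value = p,
                 df_model = 1L, df_residual = n - 2L,
                 n_permutations = n_perm, n_used = n,
                 n_dropped = n_dropped),
            class = "permanovaResult")
}

#' @export
print.permanovaResult <- function(x, ...) {
  cat(sprintf(
    "PerMANOVA: DF = %d, pseudo-F = %.4g, R2 = %.4g, Prob > F = %.4g (%d permutations, n = %d)\n",
    x$df_model, x$pseudo_F, x$R2, x$p_value, x$n_permutations, x$n_used))
  invisible(x)
}

# all permutations of 1..n as a matrix (n! rows); n kept small by callers
.allPermutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- .allPermutations(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  row <- 1L
  for (pos in seq_len(n)) {
    for (r in seq_len(nrow(sub))) {
      v <- sub[r, ]
      out[row, ] <- append(v, n, after = pos - 1L)
      row <- row + 1L
    }
  }
  out
}

#' PerMANOVA screen over a covariate table
#'
#' Runs [permanovaSingle()] for each covariate in turn against one distance
#' matrix, the tabulation used for distance-based environmental screens
#' (one DF = 1 row per feature).
#'
#' @param dist distance matrix over samples.
#' @param covariates data.frame of covariates (rows aligned with `dist`).
#' @param permutations,seed passed to [permanovaSingle()].
#' @return data.frame with one row per covariate: `covariate`, `DF`,
#'   `pseudo_F`, `R2`, `p`, sorted by increasing p.
#' @export
permanovaScreen <- function(dist, covariates, permutations = 9999,
                            seed = 1) {
  rows <- lapply(colnames(covariates), function(cv) {
    r <- permanovaSingle(dist, covariates[[cv]],
                         permutations = permutations, seed = seed)
    data.frame(covariate = cv, DF = r$df_model, pseudo_F = r$pseudo_F,
               R2 = r$R2, p = r$p_value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$p), , drop = FALSE]
}
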