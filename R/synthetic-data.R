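#' SyntheticTruth: ground truth of a generated community
#'
#' Records everything the generator planted, so every downstream stage can
#' be scored against a known answer.
#'
#' @slot moduleOf named integer vector, OTU -> planted module label
#'   (0 = unstructured noise).
#' @slot loadings named numeric, per-OTU factor loading (0 for noise OTUs).
#' @slot envDriver data.frame with columns `feature`, `module`, `alpha`:
#'   which latent module factor drives which environmental feature, and how
#'   strongly.
#' @slot zoneFold named numeric multiplicative density gradient applied to
#'   the algal OTUs (names `A`, `P`, `M`).
#' @slot algalOtus character, ids of the OTUs carrying the zone gradient.
#' @slot regionEffect named numeric, per-OTU log-scale offset applied in
#'   the second region (non-zero only for noise fungal OTUs).
#' @slot seed integer; the seed fully determines the generated data.
#' @export
setClass("SyntheticTruth",
         representation(moduleOf = "integer", loadings = "numeric",
                        envDriver = "data.frame", zoneFold = "numeric",
                        algalOtus = "character", regionEffect = "numeric",
                        seed = "integer"))

setMethod("show", "SyntheticTruth", function(object) {
  k <- table(object@moduleOf)
  cat(sprintf("SyntheticTruth: %d OTUs, %d planted modules, seed %d\n",
              length(object@moduleOf), sum(names(k) != "0"), object@seed))
  cat("  module sizes:",
      paste(sprintf("%s=%d", names(k), k), collapse = ", "), "\n")
  if (nrow(object@envDriver))
    cat("  env drivers:",
        paste(sprintf("%s<-m%d", object@envDriver$feature,
                      object@envDriver$module), collapse = ", "), "\n")
  invisible(NULL)
})

#' @describeIn SyntheticTruth-class planted OTU -> module map.
#' @param x,object a `SyntheticTruth`.
#' @export
plantedModules <- function(x) x@moduleOf

# Environmental features emulated by the generator, with field units and a
# plausible location/scale used to place standardized values on the
# instrument's scale (affine; rank-based statistics are unaffected).
ENV_FEATURES <- data.frame(
  feature = c("ORP", "DO", "conductivity", "TDS", "salinity", "NO3",
              "NH4", "K", "pH", "elevation"),
  unit = c("mV", "%", "uS/cm", "ppm", "PSU", "mV", "mV", "mV", "", "m"),
  center = c(5, 50, 7, 4, 0.02, 100, -217, -200, 7.2, 2500),
  scale = c(12, 8, 5, 3, 0.05, 20, 8, 10, 0.5, 600),
  stringsAsFactors = FALSE)

#' Generate a synthetic bloom community with planted structure
#'
#' Draws sparse, overdispersed OTU counts for a two-region, multi-bloom,
#' three-zone design with: correlated OTU blocks (modules) driven by latent
#' per-sample factors, environmental features coupled to a subset of those
#' factors, a multiplicative density gradient for designated "algal" OTUs
#' across the A < P < M zones, a regional offset for noise fungal OTUs, and
#' unstructured noise OTUs.
#'
#' The count model is log-linear: for OTU `j` in sample `i`,
#' `log mu_ij = mu_j + w_j * z_{m(j),i} + zone/region offsets`, with
#' `z_m ~ N(0,1)` per module per sample, counts drawn negative-binomially
#' with variance `mu + dispersion * mu^2`, then thinned to the requested
#' sparsity by independent zeroing. Environmental feature `k` driven by
#' module `m` is `alpha * z_m + N(0,1)`, placed on the instrument scale by
#' an affine map. Two zone-gradient biological features (`algae` cells/mL
#' and `pollen` grains/mL) follow the observed A < P < M concentration
#' pattern. Everything is deterministic under `seed`.
#'
#' @param n_samples number of samples; must equal
#'   `sum(blooms) * length(zones)` when `zone_design` is given.
#' @param n_otus total OTU count (modules + noise).
#' @param n_modules number of planted modules.
#' @param module_size OTUs per module; `n_modules * module_size <= n_otus`.
#' @param w loading scale of module members (noise OTUs have loading 0).
#' @param alpha coupling of driven environmental features to their module
#'   factor.
#' @param dispersion negative-binomial overdispersion `phi`
#'   (variance `mu + phi mu^2`); 0 gives Poisson counts.
#' @param sparsity probability of independently zeroing a count (excess
#'   zeros beyond the count model).
#' @param zone_design list with `regions` (character), `blooms` (integer
#'   per region), `zones` (character); `NULL` for an unstructured design.
#' @param n_algal number of algal (A-prefixed) gradient-carrying OTUs.
#' @param zone_fold named multiplicative gradient (`A`, `P`, `M`) for the
#'   algal OTUs.
#' @param region_effect log-scale magnitude of the regional offset applied
#'   to noise fungal OTUs (random sign per OTU).
#' @param n_driven number of environmental features coupled to module
#'   factors (at most `min(n_modules, 10)`).
#' @param seed integer seed (mandatory; no silent clock seeding).
#' @return list with elements `otu` ([OtuTable-class]),
#'   `env` ([EnvTable-class]) and `truth` ([SyntheticTruth-class]).
#' @examples
#' sim <- generateCommunity(n_otus = 40, n_modules = 2, module_size = 8,
#'                          seed = 1)
#' table(plantedModules(sim$truth))
#' @export
generateCommunity <- function(n_samples = 30, n_otus = 120, n_modules = 4,
                              module_size = 10, w = 1.2, alpha = 1.0,
                              dispersion = 0.1, sparsity = 0.05,
                              zone_design = list(
                                regions = c("Cascades", "Rockies"),
                                blooms = c(6L, 4L),
                                zones = c("M", "P", "A")),
                              n_algal = 3,
                              zone_fold = c(A = 1, P = 2, M = 4),
                              region_effect = 0.5,
                              n_driven = min(n_modules, 4),
                              seed) {
  if (missing(seed)) stop("'seed' is required")
  if (n_modules * module_size > n_otus)
    stop(sprintf("infeasible design: %d modules x %d OTUs > %d total OTUs",
                 n_modules, module_size, n_otus))
  if (!is.null(zone_design)) {
    n_design <- sum(zone_design$blooms) * length(zone_design$zones)
    if (n_samples != n_design)
      stop(sprintf("n_samples (%d) must equal blooms x zones (%d)",
                   n_samples, n_design))
  }
  set.seed(as.integer(seed))

  ## --- design ---------------------------------------------------------
  if (!is.null(zone_design)) {
    bloom_region <- rep(zone_design$regions,
                        times = zone_design$blooms)
    bloom_id <- sprintf("bloom%02d", seq_along(bloom_region))
    meta <- data.frame(
      region = rep(bloom_region, each = length(zone_design$zones)),
      zone = rep(zone_design$zones, times = length(bloom_id)),
      bloom_id = rep(bloom_id, each = length(zone_design$zones)),
      stringsAsFactors = FALSE)
  } else {
    meta <- data.frame(region = NA_character_, zone = NA_character_,
                       bloom_id = NA_character_,
                       stringsAsFactors = FALSE)[rep(1, n_samples), ]
  }
  rownames(meta) <- sprintf("s%02d", seq_len(n_samples))
  sids <- rownames(meta)

  ## --- OTU identities -------------------------------------------------
  n_noise <- n_otus - n_modules * module_size
  n_algal <- min(n_algal, n_noise)
  module_of <- c(rep(seq_len(n_modules), each = module_size),
                 rep(0L, n_noise))
  prefix <- character(n_otus)
  bf <- c("B", "F")
  prefix[module_of > 0] <- bf[(seq_len(n_modules * module_size) %% 2L) + 1L]
  noise_idx <- which(module_of == 0L)
  if (n_algal > 0) prefix[noise_idx[seq_len(n_algal)]] <- "A"
  rest <- noise_idx[setdiff(seq_len(n_noise), seq_len(n_algal))]
  prefix[rest] <- bf[(seq_along(rest) %% 2L) + 1L]
  num <- stats::ave(seq_len(n_otus), prefix, FUN = seq_along)
  otu_ids <- sprintf("%sOTU%04d", prefix, num)
  algal_otus <- otu_ids[prefix == "A"]
  names(module_of) <- otu_ids

  ## --- latent factors and log-means -----------------------------------
  z <- matrix(stats::rnorm(n_samples * n_modules), n_samples, n_modules)
  mu_j <- stats::rnorm(n_otus, mean = log(30), sd = 0.7)
  loadings <- ifelse(module_of > 0, w, 0)
  names(loadings) <- otu_ids
  eta <- matrix(rep(mu_j, each = n_samples), n_samples, n_otus)
  for (j in which(module_of > 0))
    eta[, j] <- eta[, j] + loadings[j] * z[, module_of[j]]
  # zone gradient on algal OTUs
  if (!is.null(zone_design) && length(algal_otus)) {
    zoff <- log(zone_fold)[meta$zone]
    for (j in which(prefix == "A")) eta[, j] <- eta[, j] + zoff
  }
  # region offset on noise fungal OTUs
  reg_eff <- stats::setNames(numeric(n_otus), otu_ids)
  if (!is.null(zone_design) && region_effect > 0) {
    f_noise <- which(module_of == 0L & prefix == "F")
    signs <- sample(c(-1, 1), length(f_noise), replace = TRUE)
    reg_eff[f_noise] <- region_effect * signs
    second <- meta$region == zone_design$regions[length(zone_design$regions)]
    for (k in seq_along(f_noise))
      eta[second, f_noise[k]] <- eta[second, f_noise[k]] + reg_eff[f_noise[k]]
  }

  ## --- counts ---------------------------------------------------------
  mu <- exp(eta)
  counts <- if (dispersion > 0) {
    matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / dispersion),
           n_samples, n_otus)
  } else {
    matrix(stats::rpois(length(mu), lambda = mu), n_samples, n_otus)
  }
  if (sparsity > 0) {
    keep <- matrix(stats::rbinom(length(counts), 1L, 1 - sparsity),
                   n_samples, n_otus)
    counts <- counts * keep
  }
  dimnames(counts) <- list(sids, otu_ids)
  # guard: rarefaction and Hellinger need a positive total per sample
  empty <- rowSums(counts) == 0
  if (any(empty)) counts[empty, 1] <- 1L

  ## --- environment ----------------------------------------------------
  n_driven <- min(n_driven, n_modules, nrow(ENV_FEATURES))
  env_std <- matrix(stats::rnorm(n_samples * nrow(ENV_FEATURES)),
                    n_samples, nrow(ENV_FEATURES))
  driver <- data.frame(feature = character(0), module = integer(0),
                       alpha = numeric(0), stringsAsFactors = FALSE)
  if (n_driven > 0) {
    driver <- data.frame(feature = ENV_FEATURES$feature[seq_len(n_driven)],
                         module = seq_len(n_driven), alpha = alpha,
                         stringsAsFactors = FALSE)
    for (k in seq_len(n_driven))
      env_std[, k] <- alpha * z[, k] + env_std[, k]
  }
  env <- sweep(sweep(env_std, 2, ENV_FEATURES$scale, "*"),
               2, ENV_FEATURES$center, "+")
  colnames(env) <- ENV_FEATURES$feature
  env <- as.data.frame(env)
  if (!is.null(zone_design)) {
    algae_mean <- c(A = 2.1e3, P = 1.4e4, M = 1.68e5)
    pollen_mean <- c(A = 320, P = 420, M = 1440)
    env$algae <- stats::rlnorm(n_samples, log(algae_mean[meta$zone]), 0.5)
    env$pollen <- stats::rlnorm(n_samples, log(pollen_mean[meta$zone]), 0.5)
  } else {
    env$algae <- stats::rlnorm(n_samples, log(1e4), 1)
    env$pollen <- stats::rlnorm(n_samples, log(500), 1)
  }
  rownames(env) <- sids
  units <- c(stats::setNames(ENV_FEATURES$unit, ENV_FEATURES$feature),
             algae = "cells/mL", pollen = "grains/mL")

  otu <- OtuTable(counts, sample_meta = meta)
  truth <- new("SyntheticTruth", moduleOf = as.integer(module_of),
               loadings = loadings, envDriver = driver,
               zoneFold = zone_fold, algalOtus = algal_otus,
               regionEffect = reg_eff, seed = as.integer(seed))
  truth@moduleOf <- stats::setNames(as.integer(module_of), otu_ids)
  list(otu = otu, env = EnvTable(env, units), truth = truth)
}

#' Overlay a zonal density gradient onto an existing table
#'
#' Rescales the counts of focal OTUs in peripheral (P) and medial (M)
#' samples by binomial thinning/amplification so that the expected count is
#' `fold_P` (respectively `fold_M`) times the original; adjacent (A) samples
#' and all other OTUs are untouched, so gradients can be layered onto any
#' table. For a fold `f`, the new count given original `n` is
#' `n * floor(f) + Binomial(n, f - floor(f))`, whose expectation is `n * f`
#' exactly; `f <= 1` reduces to plain binomial thinning.
#'
#' @param base an [OtuTable-class] with zones assigned.
#' @param focal_otus character, OTUs carrying the gradient.
#' @param fold_P,fold_M expected multiplicative change in P and M relative
#'   to the untouched counts; `fold_M >= fold_P >= 1` (use folds below 1 by
#'   swapping the baseline zone upstream).
#' @param seed integer seed.
#' @return a new [OtuTable-class] with rescaled counts.
#' @export
generateZoneGradient <- function(base, focal_otus, fold_P, fold_M, seed) {
  stopifnot(is(base, "OtuTable"))
  if (!(fold_M >= fold_P && fold_P >= 1))
    stop("require fold_M >= fold_P >= 1")
  missing_otus <- setdiff(focal_otus, rownames(base))
  if (length(missing_otus))
    stop("focal OTU absent from table: ",
         paste(missing_otus, collapse = ", "))
  if (fold_P == 1 && fold_M == 1) return(base)
  set.seed(as.integer(seed))
  m <- otuCounts(base)
  zone <- sampleData(base)$zone
  scaleCount <- function(n, f) {
    if (f == 1) return(n)
    base_part <- n * floor(f)
    frac <- f - floor(f)
    extra <- if (frac > 0) stats::rbinom(length(n), n, frac) else 0L
    as.integer(base_part + extra)
  }
  for (otu in focal_otus) {
    for (zn in c("P", "M")) {
      idx <- which(zone == zn)
      if (!length(idx)) next
      f <- if (zn == "P") fold_P else fold_M
      m[idx, otu] <- scaleCount(m[idx, otu], f)
    }
  }
  OtuTable(m, sample_meta = sampleData(base),
           taxonomy = taxonomyTable(base))
}
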