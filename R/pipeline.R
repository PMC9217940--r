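#' Remove low-count OTUs
#'
#' Drops OTUs whose total count across samples is strictly fewer than
#' `min_otu_total` (the conventional rare-sequence prefilter: an OTU with
#' exactly `min_otu_total` reads is retained). Dropped ids are recorded in
#' `metadata(table)$dropped_otus`.
#'
#' @param table an [OtuTable-class].
#' @param min_otu_total minimum total count to keep an OTU (default 10).
#' @return the filtered [OtuTable-class].
#' @export
applyPrefilters <- function(table, min_otu_total = 10) {
  aa <- absoluteAbundance(table)
  drop <- names(aa)[aa < min_otu_total]
  if (length(drop) == length(aa))
    stop("prefilter would drop every OTU")
  keep <- setdiff(names(aa), drop)
  out <- OtuTable(otuCounts(table)[, keep, drop = FALSE],
                  sample_meta = sampleData(table),
                  taxonomy = taxonomyTable(table)[keep, , drop = FALSE])
  metadata(out)$dropped_otus <- drop
  out
}

#' Default run configuration
#'
#' Builds the nested configuration list consumed by [runPipeline()]. The
#' `defaults` profile encodes the analysis constants carried by the
#' workflow -- 1000 rarefaction iterations, the < 10-sequence OTU
#' prefilter, network thresholds AA > 100, |tau| >= 0.40, p <= 0.10 --
#' while everything else (depths, soft power, module sizes, permutation
#' and bootstrap counts) is an explicit knob. A master `seed` is mandatory
#' whenever any stochastic stage is enabled. Configurations can also be
#' read from a YAML file with [readRunConfig()].
#'
#' @param seed integer master seed.
#' @param outdir output directory for the stage artifacts.
#' @param ... overrides of any default, as nested lists (e.g.
#'   `diversity = list(iterations = 100)`).
#' @return a config list of class `"wocnaConfig"`.
#' @export
runConfig <- function(seed = NULL, outdir = tempfile("wocna_run_"), ...) {
  cfg <- list(
    seed = seed,
    outdir = outdir,
    prefilter = list(min_otu_total = 10),
    diversity = list(depth = NULL, iterations = 1000),
    zonestats = list(pairs = c("M-P", "M-A", "P-A"), rank = "genus",
                     n_taxa = 10),
    permanova = list(covariates = NULL, permutations = 9999),
    wocna = list(power = "auto", mode = "unsigned", min_module_size = 5,
                 cut = "dynamic", min_gap = 0.2),
    stability = list(B = 100),
    networks = list(aa_min = 100, tau_min = 0.40, p_max = 0.10,
                    focal = NULL))
  dots <- list(...)
  for (nm in names(dots)) {
    if (is.list(dots[[nm]]) && is.list(cfg[[nm]])) {
      cfg[[nm]][names(dots[[nm]])] <- dots[[nm]]
    } else {
      cfg[[nm]] <- dots[[nm]]
    }
  }
  class(cfg) <- "wocnaConfig"
  cfg
}

#' Read a run configuration from YAML
#'
#' The file holds the same nested structure as [runConfig()]; unspecified
#' fields fall back to the defaults.
#'
#' @param path YAML file path.
#' @return a config list of class `"wocnaConfig"`.
#' @export
readRunConfig <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(runConfig, y)
}

.validateConfig <- function(cfg) {
  stochastic <- TRUE  # diversity, permanova and stability all draw
  if (stochastic && (is.null(cfg$seed) || is.na(cfg$seed)))
    stop("config error: a seed is required when stochastic stages run")
  nw <- cfg$networks
  if (nw$tau_min < 0 || nw$tau_min > 1) stop("tau_min must lie in [0, 1]")
  if (nw$p_max <= 0 || nw$p_max > 1) stop("p_max must lie in (0, 1]")
  if (cfg$wocna$min_module_size < 2) stop("min_module_size must be >= 2")
  if (cfg$diversity$iterations < 1) stop("iterations must be >= 1")
  invisible(TRUE)
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order -- prefilter, rarefaction diversity, zonal
#' statistics, PerMANOVA, WOCNA per region, bootstrap stability, and
#' co-association networks -- writing each stage's artifacts into
#' `config$outdir` and returning a JSON-serializable manifest that records
#' package/R versions, the seed, all parameter values, input checksums and
#' the output file list with checksums. Re-running with an identical
#' configuration reproduces byte-identical outputs (the manifest differs
#' only in its timestamp). A stage failure is recorded in the manifest
#' (status `"failed"`) and aborts later stages while preserving earlier
#' outputs.
#'
#' @param table an [OtuTable-class].
#' @param env an [EnvTable-class] aligned with the table's samples.
#' @param config a config list from [runConfig()] / [readRunConfig()].
#' @return the manifest, invisibly written to `manifest.json` in the
#'   output directory.
#' @export
runPipeline <- function(table, env, config = runConfig(seed = 1)) {
  .validateConfig(config)
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed)
  manifest <- list(
    r_version = R.version.string,
    package_version = as.character(utils::packageVersion("wocna")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    parameters = unclass(config),
    input = list(n_samples = ncol(table), n_otus = nrow(table),
                 counts_checksum = .checksumMatrix(otuCounts(table))),
    stages = list())
  outputs <- character(0)
  writeCsv <- function(df, name) {
    p <- file.path(config$outdir, name)
    utils::write.csv(df, p, row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
    outputs <<- c(outputs, p)
    p
  }
  writeTsv <- function(df, name) {
    p <- file.path(config$outdir, name)
    utils::write.table(df, p, sep = "\t", row.names = FALSE, quote = FALSE,
                       fileEncoding = "UTF-8", eol = "\n")
    outputs <<- c(outputs, p)
    p
  }
  stage <- function(name, fun) {
    res <- tryCatch(list(value = fun(), status = "ok"),
                    error = function(e)
                      list(value = NULL, status = "failed",
                           error = conditionMessage(e)))
    manifest$stages[[name]] <<- c(list(status = res$status),
                                  if (res$status == "failed")
                                    list(error = res$error))
    if (res$status == "failed")
      stop(sprintf("stage '%s' failed: %s", name, res$error),
           call. = FALSE)
    res$value
  }

  ## 1. prefilter -------------------------------------------------------
  tab <- stage("prefilter", function() {
    ft <- applyPrefilters(table, config$prefilter$min_otu_total)
    writeTsv(data.frame(otu = metadata(ft)$dropped_otus),
             "prefilter_dropped.tsv")
    writeOtuTable(ft, file.path(config$outdir, "counts_filtered.tsv"))
    outputs <<- c(outputs, file.path(config$outdir, "counts_filtered.tsv"))
    ft
  })

  ## 2. diversity -------------------------------------------------------
  depth <- config$diversity$depth
  if (is.null(depth)) depth <- min(rowSums(otuCounts(tab)))
  bc <- stage("diversity", function() {
    alpha <- meanRarefiedAlpha(tab, depth = depth,
                               iterations = config$diversity$iterations,
                               seed = seed)
    writeCsv(alpha, "alpha_diversity.csv")
    bc <- meanBrayCurtis(tab, depth = depth,
                         iterations = config$diversity$iterations,
                         seed = seed + 1L)
    writeTsv(cbind(sample = rownames(bc), as.data.frame(bc)),
             "bray_curtis_mean.tsv")
    bc
  })

  ## 3. zonal statistics -------------------------------------------------
  stage("zonestats", function() {
    zc <- config$zonestats
    ra_tot <- colSums(otuCounts(tab)) / sum(otuCounts(tab))
    taxa <- taxonomyTable(tab)[[zc$rank]]
    top_all <- names(sort(tapply(ra_tot, taxa, sum), decreasing = TRUE))
    top <- setdiff(top_all, "unclassified")
    if (!length(top)) top <- top_all
    top <- top[seq_len(min(zc$n_taxa, length(top)))]
    res_t <- zonePairScreen(tab, targets = top, pairs = zc$pairs,
                            data = "taxa", rank = zc$rank)
    res_e <- zonePairScreen(tab, targets = colnames(envData(env)),
                            pairs = zc$pairs, data = "env", env = env)
    writeCsv(rbind(cbind(kind = "taxon", res_t), cbind(kind = "env", res_e)),
             "zone_tests.csv")
  })

  ## 4. PerMANOVA --------------------------------------------------------
  stage("permanova", function() {
    covs <- config$permanova$covariates
    cdat <- envData(env)[rownames(otuCounts(tab)), , drop = FALSE]
    cdat$region <- sampleData(tab)$region
    if (is.null(covs)) covs <- colnames(cdat)
    res <- permanovaScreen(bc, cdat[, covs, drop = FALSE],
                           permutations = config$permanova$permutations,
                           seed = seed + 2L)
    writeCsv(res, "permanova.csv")
  })

  ## 5. WOCNA per region -------------------------------------------------
  regions <- unique(stats::na.omit(sampleData(tab)$region))
  if (!length(regions)) regions <- NA_character_
  wres <- stage("wocna", function() {
    out <- list()
    for (rg in regions) {
      keep <- if (is.na(rg)) rep(TRUE, ncol(tab)) else
        sampleData(tab)$region == rg
      msub <- otuCounts(tab)[keep, , drop = FALSE]
      msub <- msub[, colSums(msub) > 0, drop = FALSE]
      sub <- OtuTable(msub,
                      sample_meta = sampleData(tab)[keep, , drop = FALSE],
                      taxonomy = taxonomyTable(tab)[colnames(msub), ,
                                                    drop = FALSE])
      h <- hellingerTransform(sub)
      wc <- config$wocna
      beta <- if (identical(wc$power, "auto"))
        pickSoftPower(h, mode = wc$mode)$beta else wc$power
      adj <- suppressWarnings(softAdjacency(h, beta = beta, mode = wc$mode))
      tom <- tomSimilarity(adj)
      ms <- detectModules(tom, min_module_size = wc$min_module_size,
                          cut = wc$cut, min_gap = wc$min_gap)
      ms <- eigenOtus(h[, colnames(tom), drop = FALSE], ms)
      tag <- if (is.na(rg)) "all" else rg
      writeTsv(data.frame(otu = names(moduleLabels(ms)),
                          module = unname(moduleLabels(ms))),
               sprintf("modules_%s.tsv", tag))
      E <- eigenOtuScores(ms)
      writeTsv(cbind(module = rownames(E), as.data.frame(E)),
               sprintf("eigen_otus_%s.tsv", tag))
      xy <- mdsEmbed(tom, k = 2)
      writeTsv(cbind(otu = rownames(xy), as.data.frame(xy)),
               sprintf("mds_%s.tsv", tag))
      mc <- moduleCorrelations(ms, env = EnvTable(
        envData(env)[rownames(h), , drop = FALSE], envUnits(env)))
      writeCsv(cbind(module = rownames(mc$env@tau),
                     as.data.frame(mc$env@tau)),
               sprintf("module_env_tau_%s.csv", tag))
      writeCsv(cbind(module = rownames(mc$env@p),
                     as.data.frame(mc$env@p)),
               sprintf("module_env_p_%s.csv", tag))
      out[[tag]] <- list(table = sub, h = h, beta = beta, modules = ms)
    }
    out
  })

  ## 6. stability --------------------------------------------------------
  stage("stability", function() {
    for (tag in names(wres)) {
      w <- wres[[tag]]
      rep_ <- bootstrapStability(
        w$h[, names(moduleLabels(w$modules)), drop = FALSE],
        beta = w$beta, mode = config$wocna$mode,
        min_module_size = config$wocna$min_module_size,
        cut = config$wocna$cut, min_gap = config$wocna$min_gap,
        B = config$stability$B, seed = seed + 3L,
        reference = w$modules)
      writeCsv(stabilityTable(rep_), sprintf("stability_%s.csv", tag))
    }
  })

  ## 7. networks ---------------------------------------------------------
  stage("networks", function() {
    nc <- config$networks
    for (tag in names(wres)) {
      w <- wres[[tag]]
      net <- buildNetwork(w$table,
                          region = if (tag == "all") NULL else tag,
                          aa_min = nc$aa_min, tau_min = nc$tau_min,
                          p_max = nc$p_max, modules = w$modules)
      p <- file.path(config$outdir, sprintf("network_%s.tsv", tag))
      writeNetwork(net, p, format = "edge_tsv")
      outputs <<- c(outputs, p)
      focal <- nc$focal
      if (is.null(focal)) {
        nd <- networkNodes(net)
        focal <- nd$otu[order(-nd$aa)][seq_len(min(3, nrow(nd)))]
      }
      focal <- intersect(focal, networkNodes(net)$otu)
      if (length(focal))
        writeCsv(connectivitySummary(net, focal),
                 sprintf("connectivity_%s.csv", tag))
    }
  })

  manifest$outputs <- lapply(stats::setNames(outputs, basename(outputs)),
                             function(p) unname(tools::md5sum(p)))
  jsonlite::write_json(manifest,
                       file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null", force = TRUE)
  invisible(manifest)
}

.checksumMatrix <- function(m) {
  f <- tempfile()
  on.exit(unlink(f))
  utils::write.table(m, f)
  unname(tools::md5sum(f))
}
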