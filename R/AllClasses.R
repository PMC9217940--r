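#' @import methods
#' @import SummarizedExperiment
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

#' Taxonomic ranks used throughout the package
#'
#' Lineages are stored as seven ranked fields, kingdom through species.
#' Unresolved levels carry the value `"unclassified"`.
#' @keywords internal
TAX_RANKS <- c("kingdom", "phylum", "class", "order", "family",
               "genus", "species")

#' OtuTable: an OTU count table with sample metadata and taxonomy
#'
#' An `OtuTable` extends [SummarizedExperiment::SummarizedExperiment] and
#' holds a single integer assay `"counts"` with OTUs as rows and samples as
#' columns. `colData` carries the per-sample design (`region`, `zone` in
#' M/P/A, `bloom_id`); `rowData` carries the ranked lineage (kingdom through
#' species) and the OTU absolute abundance `aa` (its total count over all
#' samples). OTU identifiers follow the lineage-prefix convention: a leading
#' `A`, `B` or `F` marks algal, bacterial or fungal OTUs (e.g. `"FOTU0001"`).
#'
#' Validity requires: non-negative integral counts, unique OTU and sample
#' identifiers, `aa` equal to the count row sums, zones restricted to
#' M, P, A (NA permitted for tables without a zonal design), and a complete
#' taxonomy for every OTU.
#'
#' @seealso [OtuTable()], [readOtuTable()], [otuCounts()]
#' @export
setClass("OtuTable", contains = "SummarizedExperiment")

setValidity("OtuTable", function(object) {
  msgs <- character(0)
  if (!"counts" %in% assayNames(object))
    return("assay 'counts' is required")
  m <- assay(object, "counts")
  if (anyNA(m)) msgs <- c(msgs, "counts contain NA")
  if (any(m < 0, na.rm = TRUE)) msgs <- c(msgs, "counts contain negative values")
  if (any(abs(m - round(m)) > 1e-8, na.rm = TRUE))
    msgs <- c(msgs, "counts are not integral")
  if (anyDuplicated(rownames(object)))
    msgs <- c(msgs, "duplicate OTU ids")
  if (anyDuplicated(colnames(object)))
    msgs <- c(msgs, "duplicate sample ids")
  cd <- colData(object)
  need <- c("region", "zone", "bloom_id")
  if (!all(need %in% colnames(cd))) {
    msgs <- c(msgs, sprintf("colData must contain %s",
                            paste(need, collapse = ", ")))
  } else {
    z <- as.character(cd$zone)
    bad <- !(is.na(z) | z %in% c("M", "P", "A"))
    if (any(bad))
      msgs <- c(msgs, sprintf("invalid zone value(s): %s",
                              paste(unique(z[bad]), collapse = ", ")))
  }
  rd <- rowData(object)
  if (!all(c(TAX_RANKS, "aa") %in% colnames(rd))) {
    msgs <- c(msgs, "rowData must contain the seven taxonomic ranks and 'aa'")
  } else {
    aa <- rd$aa
    if (!isTRUE(all.equal(as.numeric(aa), unname(rowSums(m)))))
      msgs <- c(msgs, "'aa' does not equal count row sums")
    tax <- as.data.frame(rd[, TAX_RANKS, drop = FALSE])
    if (anyNA(tax)) msgs <- c(msgs, "taxonomy has NA entries (use 'unclassified')")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct an OtuTable
#'
#' @param counts numeric matrix of non-negative integer counts with
#'   **samples as rows** and OTUs as columns (the layout of the on-disk
#'   tables); stored internally in the SummarizedExperiment orientation.
#' @param sample_meta data.frame with one row per sample and columns
#'   `region`, `zone` (M/P/A or NA) and `bloom_id`; row names are sample ids.
#'   When omitted, all three fields are NA.
#' @param taxonomy data.frame with one row per OTU and the seven rank
#'   columns kingdom..species (row names are OTU ids), or NULL, in which
#'   case a minimal lineage is derived from the OTU id prefix (A/B/F ->
#'   Algae/Bacteria/Fungi kingdom-level assignment, other ranks
#'   "unclassified").
#' @return an [OtuTable-class] object.
#' @examples
#' cnt <- matrix(c(5L, 1L, 0L, 1L, 2L, 1L), nrow = 2,
#'               dimnames = list(c("s1", "s2"), c("BOTU1", "BOTU2", "FOTU1")))
#' ot <- OtuTable(cnt)
#' absoluteAbundance(ot)
#' @export
OtuTable <- function(counts, sample_meta = NULL, taxonomy = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("'counts' must have sample row names and OTU column names")
  storage.mode(counts) <- "double"
  bad <- which(counts < 0 | abs(counts - round(counts)) > 1e-8, arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("negative or non-integer count at sample '%s', OTU '%s'",
                 rownames(counts)[bad[1, 1]], colnames(counts)[bad[1, 2]]))
  m <- t(counts)  # OTUs x samples
  storage.mode(m) <- "integer"
  sids <- colnames(m)
  if (is.null(sample_meta)) {
    sample_meta <- data.frame(region = rep(NA_character_, length(sids)),
                              zone = rep(NA_character_, length(sids)),
                              bloom_id = rep(NA_character_, length(sids)),
                              row.names = sids)
  }
  sample_meta <- as.data.frame(sample_meta)
  if (!all(sids %in% rownames(sample_meta)))
    stop("sample_meta is missing rows for: ",
         paste(setdiff(sids, rownames(sample_meta)), collapse = ", "))
  sample_meta <- sample_meta[sids, , drop = FALSE]
  for (f in c("region", "zone", "bloom_id"))
    if (!f %in% colnames(sample_meta)) sample_meta[[f]] <- NA_character_
  if (is.null(taxonomy)) {
    taxonomy <- taxonomyFromPrefix(rownames(m))
  } else {
    taxonomy <- as.data.frame(taxonomy)
    if (!all(rownames(m) %in% rownames(taxonomy)))
      stop("taxonomy does not cover every OTU id")
    taxonomy <- taxonomy[rownames(m), , drop = FALSE]
    for (r in TAX_RANKS) {
      if (!r %in% colnames(taxonomy)) taxonomy[[r]] <- "unclassified"
      taxonomy[[r]][is.na(taxonomy[[r]]) | taxonomy[[r]] == ""] <- "unclassified"
    }
  }
  rd <- DataFrame(taxonomy[, TAX_RANKS, drop = FALSE],
                  aa = as.numeric(rowSums(m)), row.names = rownames(m))
  se <- SummarizedExperiment(assays = list(counts = m), rowData = rd,
                             colData = DataFrame(sample_meta))
  new("OtuTable", se)
}

#' Derive a minimal taxonomy from OTU id prefixes
#'
#' The leading character of an OTU id encodes its lineage group
#' (A = algae, B = bacteria, F = fungi); all other ranks are
#' `"unclassified"`.
#' @param otu_ids character vector of OTU ids.
#' @return data.frame of the seven ranks, row names = `otu_ids`.
#' @export
taxonomyFromPrefix <- function(otu_ids) {
  kingdom <- c(A = "Algae", B = "Bacteria", F = "Fungi")[substr(otu_ids, 1, 1)]
  kingdom[is.na(kingdom)] <- "unclassified"
  tax <- data.frame(kingdom = unname(kingdom), row.names = otu_ids)
  for (r in TAX_RANKS[-1]) tax[[r]] <- "unclassified"
  tax
}

#' @describeIn OtuTable-class count matrix in analysis orientation
#'   (samples as rows, OTUs as columns).
#' @param x,object an `OtuTable`.
#' @export
otuCounts <- function(x) t(assay(x, "counts"))

#' @describeIn OtuTable-class sample metadata as a plain data.frame.
#' @export
sampleData <- function(x) as.data.frame(colData(x))

#' @describeIn OtuTable-class ranked lineage table as a plain data.frame.
#' @export
taxonomyTable <- function(x) as.data.frame(rowData(x)[, TAX_RANKS, drop = FALSE])

#' @describeIn OtuTable-class per-OTU absolute abundance (total count).
#' @export
absoluteAbundance <- function(x) {
  stats::setNames(as.numeric(rowData(x)$aa), rownames(x))
}

#' @describeIn OtuTable-class per-sample relative abundances
#'   (rows sum to 1); a derived view, never stored.
#' @export
relativeAbundance <- function(x) {
  m <- otuCounts(x)
  sweep(m, 1, rowSums(m), "/")
}

setMethod("show", "OtuTable", function(object) {
  cat(sprintf("OtuTable: %d OTUs x %d samples\n", nrow(object), ncol(object)))
  k <- table(substr(rownames(object), 1, 1))
  cat("  lineage prefixes:",
      paste(sprintf("%s=%d", names(k), k), collapse = ", "), "\n")
  z <- colData(object)$zone
  if (!all(is.na(z)))
    cat("  zones:", paste(sprintf("%s=%d", names(table(z)), table(z)),
                          collapse = ", "), "\n")
  r <- colData(object)$region
  if (!all(is.na(r)))
    cat("  regions:", paste(unique(stats::na.omit(r)), collapse = ", "), "\n")
  invisible(NULL)
})

#' EnvTable: per-sample environmental features
#'
#' Numeric environmental measurements, one row per sample, with a unit
#' string recorded for every feature. Missing values stay `NA` and are
#' excluded pairwise by the correlation machinery -- they are never
#' silently imputed or zeroed.
#'
#' @slot data data.frame of numeric feature columns, row names = sample ids.
#' @slot units named character vector, one unit string per feature.
#' @seealso [EnvTable()], [readEnvTable()]
#' @export
setClass("EnvTable", representation(data = "data.frame", units = "character"))

setValidity("EnvTable", function(object) {
  d <- object@data
  msgs <- character(0)
  if (nrow(d) && anyDuplicated(rownames(d)))
    msgs <- c(msgs, "duplicate sample ids")
  if (!all(vapply(d, is.numeric, logical(1))))
    msgs <- c(msgs, "all feature columns must be numeric")
  if (length(object@units) && !all(colnames(d) %in% names(object@units)))
    msgs <- c(msgs, "units missing for some features")
  if (length(msgs)) msgs else TRUE
})

#' Construct an EnvTable
#'
#' @param data data.frame of numeric features, row names = sample ids.
#' @param units named character vector of unit strings; features without an
#'   entry get `""`.
#' @return an [EnvTable-class] object.
#' @export
EnvTable <- function(data, units = character(0)) {
  data <- as.data.frame(data)
  u <- stats::setNames(rep("", ncol(data)), colnames(data))
  u[names(units)[names(units) %in% names(u)]] <-
    units[names(units) %in% names(u)]
  new("EnvTable", data = data, units = u)
}

#' @describeIn EnvTable-class the feature data.frame.
#' @param x,object an `EnvTable`.
#' @export
envData <- function(x) x@data

#' @describeIn EnvTable-class the named unit vector.
#' @export
envUnits <- function(x) x@units

setMethod("show", "EnvTable", function(object) {
  cat(sprintf("EnvTable: %d samples x %d features\n",
              nrow(object@data), ncol(object@data)))
  if (ncol(object@data))
    cat("  features:", paste(sprintf("%s [%s]", colnames(object@data),
                                     object@units), collapse = ", "), "\n")
  invisible(NULL)
})

#' ModuleSet: detected co-occurrence modules and their eigen-OTUs
#'
#' @slot moduleOf named character vector mapping every OTU to a module
#'   label; the reserved label `"grey"` marks unassigned OTUs.
#' @slot eigenOtus matrix (modules x samples) of first-principal-component
#'   scores, unit variance, sign-oriented so that the mean correlation with
#'   member profiles is non-negative.
#' @slot varExplained named numeric, fraction of member variance captured
#'   by each eigen-OTU.
#' @slot colors named character map from module label to a colour alias
#'   (presentation only; size-ordered labels are the stable identifiers).
#' @slot flags character vector of module labels whose eigen-OTU
#'   orientation was ambiguous (mean member correlation near zero) or that
#'   are singletons.
#' @seealso [detectModules()], [eigenOtus()]
#' @export
setClass("ModuleSet",
         representation(moduleOf = "character", eigenOtus = "matrix",
                        varExplained = "numeric", colors = "character",
                        flags = "character"))

setValidity("ModuleSet", function(object) {
  msgs <- character(0)
  if (is.null(names(object@moduleOf)))
    msgs <- c(msgs, "moduleOf must be named by OTU id")
  labs <- setdiff(unique(object@moduleOf), "grey")
  if (nrow(object@eigenOtus) &&
      !all(rownames(object@eigenOtus) %in% labs))
    msgs <- c(msgs, "eigenOtus rows must be module labels")
  ve <- object@varExplained
  if (length(ve) && any(ve < -1e-8 | ve > 1 + 1e-8, na.rm = TRUE))
    msgs <- c(msgs, "varExplained must lie in [0, 1]")
  if (length(msgs)) msgs else TRUE
})

#' @describeIn ModuleSet-class named OTU -> module label vector.
#' @param x,object a `ModuleSet`.
#' @export
moduleLabels <- function(x) x@moduleOf

#' @describeIn ModuleSet-class module sizes (number of member OTUs),
#'   decreasing; includes `"grey"` when present.
#' @export
moduleSizes <- function(x) {
  s <- table(x@moduleOf)
  grey <- s[names(s) == "grey"]
  s <- sort(s[names(s) != "grey"], decreasing = TRUE)
  c(s, grey)
}

#' @describeIn ModuleSet-class membership share: module size as a fraction
#'   of all OTUs (the dominant module's share is a headline community
#'   statistic).
#' @export
moduleShare <- function(x) {
  s <- moduleSizes(x)
  s / length(x@moduleOf)
}

#' @describeIn ModuleSet-class eigen-OTU score matrix (modules x samples).
#' @export
eigenOtuScores <- function(x) x@eigenOtus

setMethod("show", "ModuleSet", function(object) {
  s <- moduleSizes(object)
  cat(sprintf("ModuleSet: %d modules over %d OTUs (%d unassigned)\n",
              sum(names(s) != "grey"), length(object@moduleOf),
              sum(object@moduleOf == "grey")))
  if (length(s))
    cat("  sizes:", paste(sprintf("%s=%d", names(s), s), collapse = ", "), "\n")
  if (nrow(object@eigenOtus))
    cat(sprintf("  eigen-OTUs over %d samples; var explained %s\n",
                ncol(object@eigenOtus),
                paste(sprintf("%s=%.2f", names(object@varExplained),
                              object@varExplained), collapse = ", ")))
  invisible(NULL)
})

#' CorrelationHeatmap: Kendall-tau correlations with p-values
#'
#' Rows are modules (eigen-OTUs); columns are environmental features or
#' focal OTU profiles. The two matrices are aligned cell-for-cell.
#' Cells with fewer than 3 complete observation pairs are `NA`.
#'
#' @slot tau numeric matrix of Kendall tau-b coefficients.
#' @slot p numeric matrix of two-sided p-values.
#' @seealso [moduleCorrelations()]
#' @export
setClass("CorrelationHeatmap", representation(tau = "matrix", p = "matrix"))

setValidity("CorrelationHeatmap", function(object) {
  if (!identical(dim(object@tau), dim(object@p)))
    return("tau and p must have identical dimensions")
  if (any(abs(object@tau) > 1 + 1e-12, na.rm = TRUE))
    return("|tau| must not exceed 1")
  TRUE
})

setMethod("show", "CorrelationHeatmap", function(object) {
  cat(sprintf("CorrelationHeatmap: %d modules x %d variables\n",
              nrow(object@tau), ncol(object@tau)))
  invisible(NULL)
})

#' CoassociationNetwork: thresholded Kendall-tau OTU network
#'
#' Undirected network over abundant OTUs; each retained edge satisfies
#' both the |tau| floor and the p-value cap used at construction. Isolated
#' candidate nodes are kept so that "limited connectivity" is representable.
#'
#' @slot nodes data.frame with columns `otu`, `lineage`, `aa`, `module`.
#' @slot edges data.frame with columns `from`, `to`, `tau`, `p`;
#'   canonical order `from < to` by node position.
#' @slot region character region tag ("" when unconstrained).
#' @slot thresholds named numeric: `aa_min`, `tau_min`, `p_max`.
#' @seealso [buildNetwork()], [egoSubnetwork()], [writeNetwork()]
#' @export
setClass("CoassociationNetwork",
         representation(nodes = "data.frame", edges = "data.frame",
                        region = "character", thresholds = "numeric"))

setValidity("CoassociationNetwork", function(object) {
  msgs <- character(0)
  nd <- object@nodes; ed <- object@edges
  if (!all(c("otu", "lineage", "aa", "module") %in% colnames(nd)))
    msgs <- c(msgs, "nodes need columns otu, lineage, aa, module")
  if (!all(c("from", "to", "tau", "p") %in% colnames(ed)))
    msgs <- c(msgs, "edges need columns from, to, tau, p")
  if (nrow(ed)) {
    if (any(ed$from == ed$to)) msgs <- c(msgs, "self-edges are not allowed")
    if (!all(c(ed$from, ed$to) %in% nd$otu))
      msgs <- c(msgs, "edge endpoints must be nodes")
    th <- object@thresholds
    if (all(c("tau_min", "p_max") %in% names(th))) {
      if (any(abs(ed$tau) < th["tau_min"] - 1e-12))
        msgs <- c(msgs, "edge below the |tau| threshold")
      if (any(ed$p > th["p_max"] + 1e-12))
        msgs <- c(msgs, "edge above the p-value cap")
    }
    pos <- match(ed$from, nd$otu) < match(ed$to, nd$otu)
    if (!all(pos)) msgs <- c(msgs, "edges must be in canonical from<to order")
  }
  if (length(msgs)) msgs else TRUE
})

#' @describeIn CoassociationNetwork-class node table.
#' @param x,object a `CoassociationNetwork`.
#' @export
networkNodes <- function(x) x@nodes

#' @describeIn CoassociationNetwork-class edge table.
#' @export
networkEdges <- function(x) x@edges

setMethod("show", "CoassociationNetwork", function(object) {
  cat(sprintf("CoassociationNetwork [%s]: %d nodes, %d edges\n",
              if (nzchar(object@region)) object@region else "all regions",
              nrow(object@nodes), nrow(object@edges)))
  th <- object@thresholds
  cat(sprintf("  thresholds: AA > %g, |tau| >= %g, p <= %g\n",
              th["aa_min"], th["tau_min"], th["p_max"]))
  invisible(NULL)
})

#' StabilityReport: bootstrap clusterwise Jaccard stability of modules
#'
#' @slot stability data.frame with columns `module`, `size`,
#'   `mean_jaccard`, `dissolved_fraction` (share of bootstrap replicates
#'   with best-match Jaccard below the dissolution threshold).
#' @slot B integer, number of bootstrap replicates.
#' @slot seed integer master seed.
#' @slot dissolutionThreshold numeric, Jaccard value below which a module
#'   counts as dissolved in a replicate (default 0.5).
#' @seealso [bootstrapStability()]
#' @export
setClass("StabilityReport",
         representation(stability = "data.frame", B = "integer",
                        seed = "integer", dissolutionThreshold = "numeric"))

setMethod("show", "StabilityReport", function(object) {
  cat(sprintf("StabilityReport: %d modules, B = %d bootstrap replicates\n",
              nrow(object@stability), object@B))
  print(object@stability, row.names = FALSE)
  invisible(NULL)
})

#' @describeIn StabilityReport-class the per-module stability table.
#' @param x,object a `StabilityReport`.
#' @export
stabilityTable <- function(x) x@stability
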