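#' Read an OTU count table
#'
#' Two on-disk dialects are supported. `"wide_tsv"` is a generic wide table:
#' first column sample id, remaining columns one OTU each. `"mothur_shared"`
#' is the mothur `.shared` layout: columns `label`, `Group` (sample id),
#' `numOtus`, then one column per OTU; `numOtus` must match the number of
#' OTU columns.
#'
#' @param path path to the TSV file.
#' @param dialect `"wide_tsv"` or `"mothur_shared"`.
#' @param sample_meta optional data.frame (or CSV path) of per-sample
#'   `region`, `zone`, `bloom_id`, row names / first column = sample id.
#' @param taxonomy optional taxonomy data.frame (or path to a taxonomy TSV
#'   in the `OTU<TAB>Size<TAB>Taxonomy` layout with a semicolon-delimited
#'   lineage, see [readTaxonomyTable()]).
#' @return an [OtuTable-class]; sample and OTU order as on disk, absolute
#'   abundances recomputed from the counts.
#' @export
readOtuTable <- function(path, dialect = c("wide_tsv", "mothur_shared"),
                         sample_meta = NULL, taxonomy = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (dialect == "mothur_shared") {
    need <- c("label", "Group", "numOtus")
    if (!all(need %in% colnames(df)))
      stop("mothur_shared file must have columns label, Group, numOtus")
    otu_cols <- setdiff(colnames(df), need)
    n_declared <- unique(as.integer(df$numOtus))
    if (length(n_declared) != 1L || n_declared != length(otu_cols))
      stop(sprintf("numOtus (%s) does not match the %d OTU columns present",
                   paste(unique(df$numOtus), collapse = "/"),
                   length(otu_cols)))
    sids <- df$Group
    cnt <- df[, otu_cols, drop = FALSE]
  } else {
    sids <- df[[1]]
    cnt <- df[, -1, drop = FALSE]
  }
  if (anyDuplicated(sids))
    stop("duplicate sample id: ",
         paste(unique(sids[duplicated(sids)]), collapse = ", "))
  m <- matrix(NA_real_, nrow = length(sids), ncol = ncol(cnt),
              dimnames = list(sids, colnames(cnt)))
  for (j in seq_len(ncol(cnt))) {
    v <- suppressWarnings(as.numeric(cnt[[j]]))
    bad <- which(is.na(v) | v < 0 | abs(v - round(v)) > 1e-8)
    if (length(bad))
      stop(sprintf(
        "negative or non-integer count at sample '%s', OTU column '%s'",
        sids[bad[1]], colnames(cnt)[j]))
    m[, j] <- v
  }
  if (is.character(sample_meta)) sample_meta <- readSampleMeta(sample_meta)
  if (is.character(taxonomy)) taxonomy <- readTaxonomyTable(taxonomy)
  OtuTable(m, sample_meta = sample_meta, taxonomy = taxonomy)
}

#' Write an OtuTable to disk
#'
#' Counts go to `path` in the requested dialect; sample metadata and the
#' taxonomy table are written alongside when paths are given, so that
#' `readOtuTable(...)` on the written files reproduces the object exactly.
#' All outputs are UTF-8 with LF line endings.
#'
#' @inheritParams readOtuTable
#' @param x an [OtuTable-class].
#' @param meta_path,taxonomy_path optional output paths for the sample
#'   metadata CSV and taxonomy TSV.
#' @return invisibly, the count file path.
#' @export
writeOtuTable <- function(x, path, dialect = c("wide_tsv", "mothur_shared"),
                          meta_path = NULL, taxonomy_path = NULL) {
  dialect <- match.arg(dialect)
  m <- otuCounts(x)
  if (dialect == "mothur_shared") {
    df <- data.frame(label = "0.03", Group = rownames(m),
                     numOtus = ncol(m), check.names = FALSE)
    df <- cbind(df, as.data.frame(m, check.names = FALSE))
  } else {
    df <- data.frame(sample = rownames(m), check.names = FALSE)
    df <- cbind(df, as.data.frame(m, check.names = FALSE))
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8", eol = "\n")
  if (!is.null(meta_path)) {
    sm <- sampleData(x)
    utils::write.csv(cbind(sample = rownames(sm), sm), meta_path,
                     row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  }
  if (!is.null(taxonomy_path)) {
    tax <- taxonomyTable(x)
    lineage <- apply(tax, 1, paste, collapse = ";")
    utils::write.table(
      data.frame(OTU = rownames(tax), Size = absoluteAbundance(x),
                 Taxonomy = paste0(lineage, ";")),
      taxonomy_path, sep = "\t", quote = FALSE, row.names = FALSE,
      fileEncoding = "UTF-8", eol = "\n")
  }
  invisible(path)
}

#' Read a sample metadata CSV
#'
#' First column = sample id; remaining columns kept as-is (at least
#' `region`, `zone`, `bloom_id` are expected downstream).
#' @param path CSV path.
#' @return data.frame with sample ids as row names.
#' @export
readSampleMeta <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  rownames(df) <- df[[1]]
  df[, -1, drop = FALSE]
}

#' Read a consensus taxonomy table
#'
#' mothur-style TSV with columns `OTU`, `Size`, `Taxonomy`; the lineage is
#' semicolon-delimited from kingdom downwards, with optional trailing
#' semicolon and optional bootstrap annotations in parentheses (stripped).
#' Missing trailing ranks become `"unclassified"`.
#'
#' @param path TSV path.
#' @return data.frame of the seven ranks, row names = OTU ids.
#' @export
readTaxonomyTable <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("OTU", "Taxonomy") %in% colnames(df)))
    stop("taxonomy file must have columns OTU and Taxonomy")
  lin <- gsub("\\([0-9.]+\\)", "", df$Taxonomy)
  lin <- sub(";+$", "", lin)
  parts <- strsplit(lin, ";", fixed = TRUE)
  tax <- t(vapply(parts, function(p) {
    p <- trimws(p)
    p <- p[nzchar(p)]
    out <- rep("unclassified", length(TAX_RANKS))
    out[seq_len(min(length(p), length(TAX_RANKS)))] <-
      p[seq_len(min(length(p), length(TAX_RANKS)))]
    out
  }, character(length(TAX_RANKS))))
  colnames(tax) <- TAX_RANKS
  out <- as.data.frame(tax, stringsAsFactors = FALSE)
  rownames(out) <- df$OTU
  out
}

#' Read an environmental feature table
#'
#' CSV with a header; the first column is the sample id, every other column
#' is parsed as a numeric feature with a locale-independent decimal point.
#' Empty cells and `NA` become missing values (never zero). A header-only
#' file yields a 0-sample table.
#'
#' @param path CSV path.
#' @param units named character vector of unit strings per feature
#'   (a config-declared map; features without an entry get `""`).
#' @return an [EnvTable-class].
#' @export
readEnvTable <- function(path, units = character(0)) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                        colClasses = "character")
  if (ncol(df) < 1) stop("env table needs a sample id column")
  sids <- df[[1]]
  feats <- df[, -1, drop = FALSE]
  num <- as.data.frame(lapply(seq_along(feats), function(j) {
    v <- trimws(feats[[j]])
    v[v == "" | v == "NA"] <- NA
    out <- suppressWarnings(as.numeric(v))
    bad <- which(!is.na(v) & is.na(out))
    if (length(bad))
      stop(sprintf("non-numeric value '%s' at sample '%s', feature '%s'",
                   v[bad[1]], sids[bad[1]], colnames(feats)[j]))
    out
  }), check.names = FALSE)
  colnames(num) <- colnames(feats)
  rownames(num) <- sids
  EnvTable(num, units = units)
}

#' Write an EnvTable to CSV
#'
#' @param x an [EnvTable-class].
#' @param path output CSV path.
#' @return invisibly, `path`.
#' @export
writeEnvTable <- function(x, path) {
  d <- envData(x)
  out <- cbind(sample = rownames(d),
               as.data.frame(lapply(d, function(v) {
                 ifelse(is.na(v), "", sprintf("%.15g", v))
               }), check.names = FALSE))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Write a co-association network
#'
#' `"edge_tsv"` writes the edge list (`from`, `to`, `tau`, `p`) at full
#' double precision, one data row per edge. `"graphml"` writes a GraphML
#' document via igraph with node attributes `lineage`, `aa`, `module` and
#' edge attributes `tau`, `p`.
#'
#' @param net a [CoassociationNetwork-class].
#' @param path output path.
#' @param format `"graphml"` or `"edge_tsv"`.
#' @return invisibly, `path`.
#' @export
writeNetwork <- function(net, path, format = c("graphml", "edge_tsv")) {
  if (length(format) == 1 && !format %in% c("graphml", "edge_tsv"))
    stop("unknown network format: ", format)
  format <- match.arg(format)
  stopifnot(is(net, "CoassociationNetwork"))
  validObject(net)
  if (format == "edge_tsv") {
    ed <- networkEdges(net)
    lines <- c("from\tto\ttau\tp",
               if (nrow(ed)) sprintf("%s\t%s\t%.17g\t%.17g",
                                     ed$from, ed$to, ed$tau, ed$p))
    writeLines(lines, path, useBytes = TRUE)
  } else {
    g <- asIgraph(net)
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Convert a CoassociationNetwork to an igraph graph
#' @param net a [CoassociationNetwork-class].
#' @return an undirected igraph graph with node/edge attributes.
#' @export
asIgraph <- function(net) {
  nd <- networkNodes(net)
  ed <- networkEdges(net)
  vert <- data.frame(name = nd$otu, lineage = nd$lineage, aa = nd$aa,
                     module = nd$module, stringsAsFactors = FALSE)
  igraph::graph_from_data_frame(
    ed[, c("from", "to", "tau", "p"), drop = FALSE][seq_len(nrow(ed)), ,
                                                    drop = FALSE],
    directed = FALSE, vertices = vert)
}

#' Read a network written by [writeNetwork()]
#'
#' @param path input path.
#' @param format `"graphml"` or `"edge_tsv"`. The edge-TSV carries no node
#'   table, so isolated nodes and node attributes are not recoverable from
#'   that format.
#' @param thresholds named numeric `aa_min`, `tau_min`, `p_max` recorded on
#'   the returned object (the file formats do not store them).
#' @return a [CoassociationNetwork-class].
#' @export
readNetwork <- function(path, format = c("graphml", "edge_tsv"),
                        thresholds = c(aa_min = 0, tau_min = 0, p_max = 1)) {
  format <- match.arg(format)
  if (format == "edge_tsv") {
    ed <- utils::read.table(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
    otus <- unique(c(ed$from, ed$to))
    nd <- data.frame(otu = otus,
                     lineage = rep("unclassified", length(otus)),
                     aa = rep(NA_real_, length(otus)),
                     module = rep("grey", length(otus)),
                     stringsAsFactors = FALSE)
  } else {
    g <- igraph::read_graph(path, format = "graphml")
    nd <- data.frame(otu = igraph::V(g)$name,
                     lineage = igraph::V(g)$lineage,
                     aa = igraph::V(g)$aa,
                     module = igraph::V(g)$module,
                     stringsAsFactors = FALSE)
    el <- igraph::as_data_frame(g, what = "edges")
    ed <- data.frame(from = el$from, to = el$to, tau = el$tau, p = el$p,
                     stringsAsFactors = FALSE)
  }
  newCoassociationNetwork(nd, ed, region = "", thresholds = thresholds)
}

# Internal constructor enforcing the canonical edge order.
newCoassociationNetwork <- function(nodes, edges, region, thresholds) {
  if (nrow(edges)) {
    i <- match(edges$from, nodes$otu)
    j <- match(edges$to, nodes$otu)
    flip <- i > j
    tmp <- edges$from[flip]
    edges$from[flip] <- edges$to[flip]
    edges$to[flip] <- tmp
    o <- order(match(edges$from, nodes$otu), match(edges$to, nodes$otu))
    edges <- edges[o, , drop = FALSE]
    rownames(edges) <- NULL
  }
  new("CoassociationNetwork", nodes = nodes, edges = edges,
      region = region, thresholds = thresholds)
}
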