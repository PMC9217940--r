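#' Edge retention predicate for co-association networks
#'
#' An edge is retained when `|tau| >= tau_min` **and** `p <= p_max`; both
#' comparisons are boundary-inclusive (a pair with tau exactly 0.40 and p
#' exactly 0.10 is kept at the default thresholds), with a small absolute
#' tolerance against floating-point representation of the thresholds.
#'
#' @param tau,p numeric vectors of edge statistics.
#' @param tau_min minimum |tau| (default 0.40).
#' @param p_max maximum p-value (default 0.10).
#' @return logical vector.
#' @export
filterEdges <- function(tau, p, tau_min = 0.40, p_max = 0.10) {
  !is.na(tau) & !is.na(p) &
    abs(tau) >= tau_min - 1e-12 & p <= p_max + 1e-12
}

#' Build a thresholded Kendall-tau co-association network
#'
#' Restricts the table to one region's samples, takes as candidate nodes
#' the OTUs whose absolute abundance within that region exceeds `aa_min`,
#' computes Kendall tau-b (with p-value, see [kendallTau()]) between the
#' per-sample relative-abundance profiles of every candidate pair, and
#' retains the edges passing [filterEdges()]. Isolated candidates are kept
#' as nodes so that low connectivity of a focal taxon is representable. An
#' empty candidate set yields an empty network, not an error.
#'
#' @param table an [OtuTable-class].
#' @param region region label to subset on (NULL = all samples); at least
#'   4 samples must remain.
#' @param aa_min absolute-abundance floor: candidates have AA strictly
#'   greater than this (default 100).
#' @param tau_min,p_max edge thresholds (defaults 0.40 and 0.10).
#' @param modules optional [ModuleSet-class] used to annotate nodes.
#' @param profile `"relative"` (default) or `"counts"`: the abundance
#'   profile on which tau is computed.
#' @return a [CoassociationNetwork-class].
#' @export
buildNetwork <- function(table, region = NULL, aa_min = 100,
                         tau_min = 0.40, p_max = 0.10, modules = NULL,
                         profile = c("relative", "counts")) {
  profile <- match.arg(profile)
  sm <- sampleData(table)
  keep <- if (is.null(region)) rep(TRUE, nrow(sm)) else
    !is.na(sm$region) & sm$region == region
  if (sum(keep) < 4) stop("need at least 4 samples in the region")
  m <- otuCounts(table)[keep, , drop = FALSE]
  aa_region <- colSums(m)
  cand <- colnames(m)[aa_region > aa_min]
  thresholds <- c(aa_min = aa_min, tau_min = tau_min, p_max = p_max)
  tax <- taxonomyTable(table)
  lineage <- apply(tax, 1, function(r) {
    r <- r[r != "unclassified"]
    if (length(r)) r[length(r)] else "unclassified"
  })
  mod_of <- if (is.null(modules)) NULL else moduleLabels(modules)
  nodes <- data.frame(
    otu = cand, lineage = unname(lineage[cand]),
    aa = unname(aa_region[cand]),
    module = if (is.null(mod_of)) rep("grey", length(cand)) else
      ifelse(is.na(mod_of[cand]), "grey", mod_of[cand]),
    stringsAsFactors = FALSE)
  if (!length(cand)) {
    message("no OTUs exceed the abundance floor; returning an empty network")
    return(newCoassociationNetwork(
      nodes, data.frame(from = character(0), to = character(0),
                        tau = numeric(0), p = numeric(0)),
      region = if (is.null(region)) "" else region,
      thresholds = thresholds))
  }
  prof <- if (profile == "relative") sweep(m, 1, rowSums(m), "/") else m
  prof <- prof[, cand, drop = FALSE]
  from <- to <- character(0)
  tauv <- pv <- numeric(0)
  if (length(cand) > 1) {
    for (i in seq_len(length(cand) - 1)) {
      for (j in seq(i + 1, length(cand))) {
        kt <- kendallTau(prof[, i], prof[, j])
        if (kt$flagged) next
        if (filterEdges(kt$tau, kt$p, tau_min, p_max)) {
          from <- c(from, cand[i]); to <- c(to, cand[j])
          tauv <- c(tauv, kt$tau); pv <- c(pv, kt$p)
        }
      }
    }
  }
  newCoassociationNetwork(
    nodes, data.frame(from = from, to = to, tau = tauv, p = pv,
                      stringsAsFactors = FALSE),
    region = if (is.null(region)) "" else region, thresholds = thresholds)
}

#' First-order (ego) subnetwork around a focal OTU
#'
#' Extracts the focal node, its direct neighbours, and the focal-neighbour
#' edges; with `include_neighbor_edges = TRUE` (the default) the edges
#' among the neighbours are included too.
#'
#' @param net a [CoassociationNetwork-class].
#' @param focal an OTU id present in the network's nodes.
#' @param include_neighbor_edges logical (default TRUE).
#' @return a [CoassociationNetwork-class] restricted to the neighbourhood.
#' @export
egoSubnetwork <- function(net, focal, include_neighbor_edges = TRUE) {
  nd <- networkNodes(net); ed <- networkEdges(net)
  if (!focal %in% nd$otu) stop("focal OTU not in network: ", focal)
  nb <- unique(c(ed$to[ed$from == focal], ed$from[ed$to == focal]))
  keep_nodes <- c(focal, nb)
  if (include_neighbor_edges) {
    keep <- ed$from %in% keep_nodes & ed$to %in% keep_nodes
  } else {
    keep <- ed$from == focal | ed$to == focal
  }
  newCoassociationNetwork(
    nd[nd$otu %in% keep_nodes, , drop = FALSE],
    ed[keep, , drop = FALSE],
    region = net@region, thresholds = net@thresholds)
}

#' Connectivity summary for focal OTUs
#'
#' Degree, positive/negative edge counts and mean |tau| for each focal
#' OTU, the quantities used to contrast sparsely connected taxa (degree
#' near zero) with hub taxa.
#'
#' @param net a [CoassociationNetwork-class].
#' @param focal character vector of OTU ids present in the network.
#' @return data.frame: `otu`, `degree`, `n_positive`, `n_negative`,
#'   `mean_abs_tau` (NA for isolated nodes).
#' @export
connectivitySummary <- function(net, focal) {
  nd <- networkNodes(net); ed <- networkEdges(net)
  missing_f <- setdiff(focal, nd$otu)
  if (length(missing_f))
    stop("focal OTU(s) not in network: ", paste(missing_f, collapse = ", "))
  rows <- lapply(focal, function(f) {
    inc <- ed$from == f | ed$to == f
    tt <- ed$tau[inc]
    data.frame(otu = f, degree = sum(inc),
               n_positive = sum(tt > 0), n_negative = sum(tt < 0),
               mean_abs_tau = if (sum(inc)) mean(abs(tt)) else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
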