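# Small fixtures built in code.

# a 2-sample x 3-OTU table with hand-checkable column sums
tinyTable <- function() {
  cnt <- matrix(c(5L, 1L, 0L, 1L, 2L, 1L), nrow = 2,
                dimnames = list(c("s1", "s2"),
                                c("BOTU0001", "BOTU0002", "FOTU0001")))
  OtuTable(cnt)
}

# a zoned 10-bloom table (2 regions) with constant baseline counts, handy
# for planting deterministic gradients
zonedTable <- function(base = 100L, n_otus = 4) {
  zones <- rep(c("M", "P", "A"), times = 10)
  blooms <- rep(sprintf("bloom%02d", 1:10), each = 3)
  region <- rep(c("Cascades", "Rockies"), times = c(18, 12))
  sids <- sprintf("s%02d", 1:30)
  otus <- sprintf("BOTU%04d", seq_len(n_otus))
  cnt <- matrix(base, nrow = 30, ncol = n_otus,
                dimnames = list(sids, otus))
  meta <- data.frame(region = region, zone = zones, bloom_id = blooms,
                     row.names = sids)
  tax <- data.frame(family = paste0("fam", seq_len(n_otus)),
                    species = otus, row.names = otus)
  OtuTable(cnt, sample_meta = meta, taxonomy = tax)
}

# build a CoassociationNetwork directly from node/edge vectors
handNetwork <- function(nodes, from, to, tau, p,
                        thresholds = c(aa_min = 0, tau_min = 0, p_max = 1)) {
  nd <- data.frame(otu = nodes, lineage = "unclassified", aa = 1000,
                   module = "grey", stringsAsFactors = FALSE)
  ed <- data.frame(from = from, to = to, tau = tau, p = p,
                   stringsAsFactors = FALSE)
  wocna:::newCoassociationNetwork(nd, ed, region = "", thresholds = thresholds)
}
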