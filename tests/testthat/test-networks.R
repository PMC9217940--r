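test_that("edge thresholds are boundary-inclusive and monotone", {
  expect_true(filterEdges(0.40, 0.10))          # both exactly at the boundary
  expect_true(filterEdges(-0.40, 0.10))         # magnitude criterion
  expect_false(filterEdges(0.39, 0.001))        # tau below the floor
  expect_false(filterEdges(0.9, 0.11))          # p above the cap
  expect_false(filterEdges(NA, 0.01))

  # raising tau_min or lowering p_max never adds edges
  set.seed(2)
  tau <- runif(200, -1, 1); p <- runif(200)
  base_keep <- filterEdges(tau, p, 0.3, 0.2)
  expect_true(all(filterEdges(tau, p, 0.5, 0.2) <= base_keep))
  expect_true(all(filterEdges(tau, p, 0.3, 0.05) <= base_keep))
})

test_that("network construction filters by regional abundance and tau", {
  set.seed(71)
  n <- 20
  base <- matrix(rpois(n * 5, 50), n, 5,
                 dimnames = list(sprintf("s%02d", 1:n),
                                 sprintf("BOTU%04d", 1:5)))
  base[, 2] <- base[, 1]                  # duplicate profile pair
  base[, 5] <- rpois(n, 2)                # rare OTU below the AA floor
  meta <- data.frame(region = rep("Cascades", n),
                     zone = rep(c("M", "P", "A"), length.out = n),
                     bloom_id = rep(sprintf("b%02d", 1:10), each = 2),
                     row.names = rownames(base))
  ot <- OtuTable(base, sample_meta = meta)
  net <- buildNetwork(ot, region = "Cascades", aa_min = 100,
                      tau_min = 0.9, p_max = 0.1)
  nd <- networkNodes(net); ed <- networkEdges(net)
  expect_false("BOTU0005" %in% nd$otu)    # AA floor applied within region
  expect_true("BOTU0003" %in% nd$otu)     # isolated candidates retained
  # at tau_min 0.9 only the duplicated pair survives
  expect_equal(nrow(ed), 1L)
  expect_setequal(c(ed$from, ed$to), c("BOTU0001", "BOTU0002"))
  expect_equal(ed$tau, 1)
  # every stored edge satisfies both thresholds
  expect_true(all(filterEdges(ed$tau, ed$p, 0.9, 0.1)))

  # invariance to sample order and OTU order
  perm_s <- sample(rownames(base)); perm_o <- sample(colnames(base))
  ot2 <- OtuTable(base[perm_s, perm_o], sample_meta = meta[perm_s, ],
                  taxonomy = taxonomyTable(ot)[perm_o, ])
  net2 <- buildNetwork(ot2, region = "Cascades", aa_min = 100,
                       tau_min = 0.9, p_max = 0.1)
  e2 <- networkEdges(net2)
  expect_setequal(paste(e2$from, e2$to), paste(ed$from, ed$to))
  expect_equal(sort(e2$tau), sort(ed$tau))

  expect_error(buildNetwork(ot, region = "Rockies"), "at least 4 samples")
  # no candidates above the floor: an empty network, not an error
  expect_message(
    net0 <- buildNetwork(ot, region = "Cascades", aa_min = 1e9),
    "empty network")
  expect_equal(nrow(networkNodes(net0)), 0L)
  expect_equal(nrow(networkEdges(net0)), 0L)
})

test_that("an independent focal OTU stays unconnected", {
  # an "algal" OTU drawn independently of every other profile (no planted
  # modules, no shared gradients) should be isolated at the default
  # thresholds in nearly every replicate
  hits <- vapply(1:20, function(s) {
    sim <- generateCommunity(n_otus = 60, n_modules = 2, module_size = 10,
                             w = 0, zone_fold = c(A = 1, P = 1, M = 1),
                             region_effect = 0, seed = s)
    net <- buildNetwork(sim$otu, region = NULL, aa_min = 100,
                        tau_min = 0.4, p_max = 0.1)
    algal <- intersect(sim$truth@algalOtus, networkNodes(net)$otu)
    if (!length(algal)) return(NA)
    min(connectivitySummary(net, algal)$degree) == 0
  }, logical(1))
  expect_gte(sum(hits, na.rm = TRUE), 18)
})

test_that("ego subnetworks carry the right nodes and edges", {
  # star around f with one neighbour-neighbour edge
  net <- handNetwork(c("f", "n1", "n2", "n3", "far"),
                     from = c("f", "f", "f", "n1", "n3"),
                     to = c("n1", "n2", "n3", "n2", "far"),
                     tau = c(.9, .8, -.7, .6, .5),
                     p = rep(.01, 5))
  ego_on <- egoSubnetwork(net, "f", include_neighbor_edges = TRUE)
  expect_setequal(networkNodes(ego_on)$otu, c("f", "n1", "n2", "n3"))
  expect_equal(nrow(networkEdges(ego_on)), 4L)
  ego_off <- egoSubnetwork(net, "f", include_neighbor_edges = FALSE)
  expect_equal(nrow(networkEdges(ego_off)), 3L)
  expect_setequal(networkNodes(ego_off)$otu, c("f", "n1", "n2", "n3"))

  # isolated focal: single node, no edges
  iso <- handNetwork(c("lone", "a", "b"), from = "a", to = "b",
                     tau = .9, p = .01)
  ei <- egoSubnetwork(iso, "lone")
  expect_equal(networkNodes(ei)$otu, "lone")
  expect_equal(nrow(networkEdges(ei)), 0L)

  expect_error(egoSubnetwork(net, "nope"), "not in network")
})

test_that("connectivity summaries match a brute-force count", {
  set.seed(9)
  otus <- paste0("o", 1:10)
  pairs <- t(combn(10, 2))
  keep <- runif(nrow(pairs)) < 0.4
  ed_from <- otus[pairs[keep, 1]]; ed_to <- otus[pairs[keep, 2]]
  taus <- runif(sum(keep), -1, 1)
  net <- handNetwork(otus, ed_from, ed_to, taus, rep(.01, sum(keep)))
  cs <- connectivitySummary(net, otus)
  for (i in seq_along(otus)) {
    inc <- ed_from == otus[i] | ed_to == otus[i]
    expect_equal(cs$degree[i], sum(inc))
    expect_equal(cs$n_positive[i], sum(taus[inc] > 0))
    expect_equal(cs$n_negative[i], sum(taus[inc] < 0))
    if (any(inc)) expect_equal(cs$mean_abs_tau[i], mean(abs(taus[inc])))
  }
  # duplicate-profile pairs always register degree >= 1 with a unit tau
  expect_error(connectivitySummary(net, "missing"), "not in network")
})
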