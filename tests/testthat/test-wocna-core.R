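test_that("Hellinger transform: shares, degenerate rows, invariances", {
  expect_equal(as.vector(hellingerTransform(matrix(c(4, 4, 4, 4), 1))),
               rep(0.5, 4))
  expect_equal(as.vector(hellingerTransform(matrix(c(9, 0, 0), 1))),
               c(1, 0, 0))
  expect_equal(as.vector(hellingerTransform(matrix(c(1, 4, 4), 1))),
               sqrt(c(1, 4, 4) / 9))

  m <- matrix(c(3, 1, 2, 5), 2, dimnames = list(c("s1", "s2"), NULL))
  h <- hellingerTransform(m)
  expect_equal(unname(rowSums(h^2)), c(1, 1))           # unit squared norm
  expect_equal(hellingerTransform(10 * m), h)           # scale invariance

  m0 <- matrix(c(0, 0, 1, 2), 2, byrow = TRUE,
               dimnames = list(c("sA", "sB"), NULL))
  expect_error(hellingerTransform(m0), "sA")
})

test_that("Kendall tau-b matches hand values and the all-pairs oracle", {
  expect_equal(kendallTau(1:5, (1:5)^3)$tau, 1)
  expect_equal(kendallTau(1:5, rev(1:5))$tau, -1)
  expect_equal(kendallTau(1:4, c(1, 3, 2, 4))$tau, 4 / 6)

  set.seed(8)
  for (i in 1:10) {
    n <- sample(c(10, 50, 200), 1)
    x <- rnorm(n)
    y <- if (i %% 2) rnorm(n) else sample(1:4, n, replace = TRUE)  # ties
    if (i %% 3 == 0) x <- round(x)                                 # more ties
    kt <- kendallTau(x, y)
    expect_equal(kt$tau, tauOracle(x, y), tolerance = 1e-12,
                 label = paste("tau case", i))
    # cross-check against the reference implementation in base R
    expect_equal(kt$tau, cor(x, y, method = "kendall"), tolerance = 1e-12)
  }

  # exact p by enumeration on small untied vectors equals the permutation
  # distribution of the statistic
  kt <- kendallTau(c(1, 2, 3, 4, 5), c(2, 1, 4, 3, 5))
  ct <- cor.test(c(1, 2, 3, 4, 5), c(2, 1, 4, 3, 5), method = "kendall")
  expect_equal(kt$p, ct$p.value, tolerance = 1e-12)

  # missing pairs removed; constant vectors flagged
  expect_equal(kendallTau(c(1, 2, NA, 4), c(1, NA, 3, 4))$n, 2L)
  expect_true(kendallTau(rep(1, 5), 1:5)$flagged)
})

test_that("soft adjacency follows the stated power laws", {
  # perfectly collinear profiles saturate at 1 for any power
  h <- cbind(a = c(1, 2, 3, 4), b = c(2, 4, 6, 8), c = c(4, 3, 2, 1))
  a2 <- softAdjacency(h, beta = 2)
  expect_equal(a2["a", "b"], 1)
  expect_equal(a2["a", "c"], 1)        # unsigned: |cor| = 1
  s2 <- softAdjacency(h, beta = 2, mode = "signed")
  expect_equal(s2["a", "c"], 0)        # signed: ((1 - 1)/2)^2

  # numeric power law against the raw correlation
  set.seed(14)
  hm <- matrix(rnorm(60), 10, 6, dimnames = list(NULL, paste0("o", 1:6)))
  r <- cor(hm)
  expect_equal(softAdjacency(hm, 2), unname(abs(r)^2),
               ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(softAdjacency(hm, 3, "signed"), unname(((1 + r) / 2)^3),
               ignore_attr = TRUE, tolerance = 1e-12)
  # the correlation backbone is switchable to Kendall tau-b
  rk <- cor(hm, method = "kendall")
  expect_equal(softAdjacency(hm, 2, cor_method = "kendall"),
               unname(abs(rk)^2), ignore_attr = TRUE, tolerance = 1e-12)
  expect_error(softAdjacency(hm, 0.5), "beta")

  # zero-variance columns are excluded with a record
  hm2 <- cbind(hm, flat = rep(1, 10))
  expect_warning(a <- softAdjacency(hm2, 2), "zero-variance")
  expect_equal(attr(a, "excluded"), "flat")
  expect_false("flat" %in% colnames(a))
})

test_that("TOM matches hand computation and the triple-loop oracle", {
  # saturated complete graph
  a1 <- matrix(1, 4, 4)
  expect_true(all(tomSimilarity(a1) == 1))

  # 3-node path: TOM12 = (0 + 0.5)/(min(1, 0.5) + 1 - 0.5) = 0.5
  a <- matrix(c(1, .5, .5, .5, 1, 0, .5, 0, 1), 3, 3)
  expect_equal(tomSimilarity(a)[1, 2], 0.5)

  set.seed(15)
  for (i in 1:5) {
    n <- sample(5:20, 1)
    r <- cor(matrix(rnorm(n * 12), 12, n))
    av <- abs(r)^3
    diag(av) <- 1
    expect_equal(tomSimilarity(av), tomOracle(av), tolerance = 1e-12)
  }

  # bounds on random adjacencies
  tm <- tomSimilarity(abs(cor(matrix(rnorm(200), 10, 20)))^4)
  expect_true(all(tm >= 0 & tm <= 1))
  expect_equal(unname(diag(tm)), rep(1, 20))
})

test_that("soft power selection reports fits and flags", {
  sim <- generateCommunity(n_otus = 60, n_modules = 2, module_size = 10,
                           w = 1.8, seed = 2)
  h <- hellingerTransform(sim$otu)
  sp <- suppressWarnings(pickSoftPower(h))
  expect_true(sp$beta %in% sp$fit_table$power)
  # mean connectivity is non-increasing in the power
  expect_true(all(diff(sp$fit_table$mean_k) <= 1e-12))
  # a single candidate power comes back flagged
  one <- pickSoftPower(h, powers = 6)
  expect_equal(one$beta, 6)
  expect_equal(one$flag, "unverified")
})

test_that("module detection recovers planted blocks and ignores noise", {
  # two strongly planted blocks: perfect recovery
  sim <- generateCommunity(n_otus = 40, n_modules = 2, module_size = 10,
                           w = 2, seed = 6)
  h <- hellingerTransform(sim$otu)
  ms <- detectModules(tomSimilarity(softAdjacency(h)))
  truth <- plantedModules(sim$truth)
  expect_equal(mclust::adjustedRandIndex(moduleLabels(ms)[names(truth)],
                                         truth), 1)
  expect_equal(sum(names(moduleSizes(ms)) != "grey"), 2L)

  # structureless tables stay (almost) entirely unassigned
  greys <- vapply(1:10, function(s) {
    simn <- generateCommunity(n_otus = 60, n_modules = 2, module_size = 8,
                              w = 0, seed = s)
    hn <- hellingerTransform(simn$otu)
    msn <- detectModules(tomSimilarity(suppressWarnings(softAdjacency(hn))))
    mean(moduleLabels(msn) == "grey")
  }, numeric(1))
  expect_gte(median(greys), 0.9)

  # duplicated profiles always land in the same module
  m <- otuCounts(sim$otu)
  dup <- cbind(m, m)
  colnames(dup) <- c(colnames(m), paste0(colnames(m), "dup"))
  msd <- detectModules(tomSimilarity(softAdjacency(hellingerTransform(dup))))
  lab <- moduleLabels(msd)
  expect_true(all(lab[colnames(m)] == lab[paste0(colnames(m), "dup")]))

  expect_error(detectModules(matrix(1, 4, 4), min_module_size = 1), ">= 2")
  expect_error(detectModules(matrix(1, 4, 4), min_module_size = 5),
               "2 \\* min_module_size")
})

test_that("static height cut separates block structure deterministically", {
  # block-diagonal adjacency: two tight blocks, weak background
  blocks <- rep(c(1, 2), each = 8)
  a <- outer(blocks, blocks, function(i, j) ifelse(i == j, 0.9, 0.05))
  diag(a) <- 1
  dimnames(a) <- list(paste0("o", 1:16), paste0("o", 1:16))
  tom <- tomSimilarity(a)
  m1 <- detectModules(tom, min_module_size = 5, cut = 0.5)
  m2 <- detectModules(tom, min_module_size = 5, cut = 0.5)
  expect_identical(moduleLabels(m1), moduleLabels(m2))
  expect_equal(mclust::adjustedRandIndex(moduleLabels(m1), blocks), 1)
  # an overly low static cut leaves sub-minimum clusters unassigned
  m3 <- detectModules(tom, min_module_size = 5, cut = 1e-6)
  expect_true(all(moduleLabels(m3) == "grey"))
})

test_that("eigen-OTUs are unit variance, oriented, and flag odd modules", {
  sim <- generateCommunity(n_otus = 40, n_modules = 2, module_size = 10,
                           w = 2, seed = 6)
  h <- hellingerTransform(sim$otu)
  ms <- eigenOtus(h, detectModules(tomSimilarity(softAdjacency(h))))
  E <- eigenOtuScores(ms)
  expect_equal(unname(apply(E, 1, sd)), rep(1, nrow(E)))
  lab <- moduleLabels(ms)
  for (md in rownames(E)) {
    mem <- names(lab)[lab == md]
    expect_gte(mean(cor(E[md, ], h[, mem])), 0)
  }
  expect_true(all(ms@varExplained >= 0 & ms@varExplained <= 1))

  # identical member profiles: the component explains everything
  hi <- matrix(rep(rnorm(10), 4), 10, 4,
               dimnames = list(paste0("s", 1:10), paste0("o", 1:4)))
  msi <- new("ModuleSet",
             moduleOf = setNames(rep("M1", 4), colnames(hi)),
             eigenOtus = matrix(numeric(0), 0, 0),
             varExplained = setNames(numeric(0), character(0)),
             colors = c(M1 = "turquoise"), flags = character(0))
  out <- eigenOtus(hi, msi)
  expect_equal(unname(out@varExplained["M1"]), 1)

  # two anti-correlated halves: orientation is ambiguous and flagged
  v <- rnorm(12)
  ha <- cbind(a1 = v, a2 = v + rnorm(12, sd = .05),
              b1 = -v, b2 = -v + rnorm(12, sd = .05))
  rownames(ha) <- paste0("s", 1:12)
  msa <- new("ModuleSet",
             moduleOf = setNames(rep("M1", 4), colnames(ha)),
             eigenOtus = matrix(numeric(0), 0, 0),
             varExplained = setNames(numeric(0), character(0)),
             colors = c(M1 = "turquoise"), flags = character(0))
  outa <- eigenOtus(ha, msa)
  expect_gt(unname(outa@varExplained["M1"]), 0.9)
  expect_true("M1" %in% outa@flags)
})

test_that("module-trait correlations find planted environmental drivers", {
  # a feature equal to an eigen-OTU correlates perfectly
  sim <- generateCommunity(n_otus = 40, n_modules = 2, module_size = 10,
                           w = 2, seed = 13)
  h <- hellingerTransform(sim$otu)
  ms <- eigenOtus(h, detectModules(tomSimilarity(softAdjacency(h))))
  E <- eigenOtuScores(ms)
  fake <- EnvTable(data.frame(self = E[1, ], row.names = colnames(E)))
  mc <- moduleCorrelations(ms, env = fake)
  expect_equal(mc$env@tau[1, "self"], 1)

  # planted driver: the driven module's |tau| is the column maximum
  hits <- vapply(1:20, function(s) {
    si <- generateCommunity(n_otus = 60, n_modules = 2, module_size = 10,
                            w = 1.8, alpha = 2, seed = s)
    hh <- hellingerTransform(si$otu)
    mm <- detectModules(tomSimilarity(suppressWarnings(softAdjacency(hh))))
    if (!sum(names(moduleSizes(mm)) != "grey")) return(NA)
    mm <- eigenOtus(hh, mm)
    mc <- moduleCorrelations(mm, env = si$env)
    drv <- si$truth@envDriver$feature[1]
    lab <- moduleLabels(mm)
    planted1 <- names(plantedModules(si$truth))[plantedModules(si$truth) == 1]
    # which detected module carries planted module 1?
    md <- names(which.max(table(lab[planted1])))
    if (is.null(md) || md == "grey") return(NA)
    which.max(abs(mc$env@tau[, drv])) == which(rownames(mc$env@tau) == md)
  }, logical(1))
  expect_gte(sum(hits, na.rm = TRUE), 18)
})

test_that("classical MDS embedding is centered with sane geometry", {
  # three mutually equidistant OTUs embed as an equilateral triangle
  tom3 <- diag(3)
  dimnames(tom3) <- list(paste0("o", 1:3), paste0("o", 1:3))
  xy <- mdsEmbed(tom3, k = 2)
  dd <- dist(xy)
  expect_equal(max(dd) - min(dd), 0, tolerance = 1e-10)
  expect_equal(unname(colMeans(xy)), c(0, 0), tolerance = 1e-12)

  # OTUs with identical overlap profiles land on identical coordinates
  toma <- matrix(c(1, 1, .3, 1, 1, .3, .3, .3, 1), 3, 3,
                 dimnames = list(paste0("o", 1:3), paste0("o", 1:3)))
  xa <- mdsEmbed(toma, k = 2)
  expect_lt(max(abs(xa[1, ] - xa[2, ])), 1e-6)

  # k beyond the rank pads zero axes with a warning
  expect_warning(xz <- mdsEmbed(tom3, k = 5), "zero-filled")
  expect_equal(ncol(xz), 5L)
  expect_true(all(xz[, 4:5] == 0))
})

test_that("the WOCNA path is deterministic once data are fixed", {
  sim <- generateCommunity(n_otus = 40, n_modules = 2, module_size = 8,
                           seed = 99)
  h <- hellingerTransform(sim$otu)
  run <- function() {
    a <- softAdjacency(h)
    ms <- eigenOtus(h, detectModules(tomSimilarity(a)))
    list(moduleLabels(ms), eigenOtuScores(ms))
  }
  set.seed(1); r1 <- run()
  set.seed(999); r2 <- run()
  expect_identical(r1, r2)
})
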