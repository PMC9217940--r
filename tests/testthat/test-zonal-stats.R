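test_that("rank-sum test: exact p, sign convention, identical groups", {
  r <- rankSumTest(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$p_value, 0.1)  # 2 / choose(6, 3)
  expect_equal(r$median_difference, -3)

  # identical multisets: MD 0 and p near 1 (ties force the normal path)
  r <- rankSumTest(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r$median_difference, 0)
  expect_gte(r$p_value, 0.9)

  # group order carries the sign: larger first group gives positive S/MD
  r <- rankSumTest(c(10, 12, 14, 16), c(1, 2, 3, 4))
  expect_gt(r$median_difference, 0)
  expect_gt(r$statistic_S, 0)

  expect_error(rankSumTest(numeric(0), 1:3), "non-empty")
})

test_that("signed-rank test matches its exact small-sample analytics", {
  # 9 positive untied differences: the half-sum-of-signed-ranks statistic
  # attains its maximum and the exact two-sided tail is 2 / 2^9
  r <- signedRankTest(c(1.1, 2.2, 3.3, 4.4, 5.5, 6.6, 7.7, 8.8, 9.9))
  expect_equal(r$statistic_S, 22.5)
  expect_equal(r$p_value, 0.00390625)
  expect_equal(round(r$p_value, 4), 0.0039)

  # equal-magnitude opposite pair is perfectly symmetric
  r <- signedRankTest(c(3, -3))
  expect_equal(r$statistic_S, 0)

  # [1, -2, 3]: ranks 1, 2, 3; S = (4 - 2)/2 = 1; exact p = 0.75
  r <- signedRankTest(c(1, -2, 3))
  expect_equal(r$statistic_S, 1)
  expect_equal(r$p_value, 0.75)

  # zeros are dropped before ranking
  r <- signedRankTest(c(0, 0, 1, 2, 3))
  expect_equal(r$n_used, 3L)
  expect_error(signedRankTest(c(0, 0)), "zero")
})

test_that("exact p-values agree with brute-force enumeration", {
  set.seed(21)
  for (i in 1:12) {
    n <- sample(4:11, 1)
    d <- round(rnorm(n), 3)
    d <- d[d != 0]
    if (length(d) < 2 || anyDuplicated(abs(d))) next
    expect_equal(signedRankTest(d)$p_value, enumSignedRankP(d),
                 tolerance = 1e-12, label = paste("signed-rank case", i))
  }
  for (i in 1:12) {
    n1 <- sample(3:6, 1); n2 <- sample(3:6, 1)
    x <- round(rnorm(n1), 3); y <- round(rnorm(n2), 3)
    if (anyDuplicated(c(x, y))) next
    expect_equal(rankSumTest(x, y)$p_value, enumRankSumP(x, y),
                 tolerance = 1e-12, label = paste("rank-sum case", i))
  }
})

test_that("signed-rank statistic conventions agree for untied data", {
  set.seed(33)
  for (i in 1:20) {
    d <- rnorm(sample(5:15, 1))
    n <- length(d)
    r <- rank(abs(d))
    w_pos <- sum(r[d > 0]); w_neg <- sum(r[d < 0])
    s <- signedRankTest(d)$statistic_S
    expect_equal(s, (w_pos - w_neg) / 2)
    expect_equal(s, w_pos - n * (n + 1) / 4)
  }
})

test_that("taxonomic rollup thresholds and remainder behave as specified", {
  # three taxa with RA 0.7 / 0.25 / 0.05 and threshold 0.1
  cnt <- matrix(c(70L, 25L, 5L), 1, 3,
                dimnames = list("s1", c("B1", "B2", "B3")))
  tax <- data.frame(family = c("famA", "famB", "famC"),
                    row.names = c("B1", "B2", "B3"))
  ot <- OtuTable(cnt, taxonomy = tax)
  ru <- taxonRollup(ot, rank = "family", threshold = 0.1,
                    scope = "per_total")
  expect_equal(ru$famA, 0.7)
  expect_equal(ru$famB, 0.25)
  expect_equal(ru$remainder, 0.05)
  expect_equal(sum(unlist(ru)), 1, tolerance = 1e-12)

  # threshold 0: everything retained, no remainder column
  ru0 <- taxonRollup(ot, rank = "family", threshold = 0, scope = "per_total")
  expect_false("remainder" %in% colnames(ru0))
  expect_equal(sum(unlist(ru0)), 1, tolerance = 1e-12)

  # all OTUs in one family collapse to a single unit column
  tax1 <- data.frame(family = rep("famX", 3),
                     row.names = c("B1", "B2", "B3"))
  ru1 <- taxonRollup(OtuTable(cnt, taxonomy = tax1), rank = "family",
                     threshold = 0.1, scope = "per_total")
  expect_equal(unlist(ru1), c(famX = 1))

  expect_error(taxonRollup(ot, rank = "clade"), "unknown rank")

  # per-group rows each sum to 1
  sim <- generateCommunity(n_otus = 30, n_modules = 2, module_size = 5,
                           seed = 3)
  rg <- taxonRollup(sim$otu, rank = "kingdom", threshold = 0,
                    scope = "per_group")
  expect_equal(unname(rowSums(rg)), rep(1, nrow(rg)), tolerance = 1e-12)
})

test_that("zone-pair screening pairs within blooms and reports n_used", {
  base <- zonedTable(base = 100L)
  g <- generateZoneGradient(base, "BOTU0001", fold_P = 2, fold_M = 12,
                            seed = 3)
  scr <- zonePairScreen(g, targets = "BOTU0001",
                        pairs = c("M-P", "M-A", "P-A"), rank = "species")
  expect_equal(nrow(scr), 3L)
  expect_equal(scr$n_used, rep(10L, 3))
  ma <- scr[scr$zone1 == "M" & scr$zone2 == "A", ]
  expect_gt(ma$MD, 0)
  expect_lt(ma$p, 0.05)

  # constant feature across zones: no signal, p = 1 by convention
  env <- EnvTable(data.frame(flat = rep(3.3, 30),
                             row.names = sprintf("s%02d", 1:30)))
  scr_e <- zonePairScreen(base, targets = "flat", data = "env", env = env)
  expect_true(all(scr_e$p >= 0.9))

  # a bloom missing one zone is excluded and n_used says so
  m <- otuCounts(g)
  keep <- sprintf("s%02d", 2:30)  # drops bloom01's M sample
  sub <- OtuTable(m[keep, ], sample_meta = sampleData(g)[keep, ],
                  taxonomy = taxonomyTable(g))
  scr2 <- zonePairScreen(sub, targets = "BOTU0001", pairs = "M-A",
                         rank = "species")
  expect_equal(scr2$n_used, 9L)

  # Benjamini-Hochberg column on request
  scr3 <- zonePairScreen(g, targets = c("BOTU0001", "BOTU0002"),
                         pairs = "M-A", rank = "species", p_adjust = "BH")
  expect_true("p_adj" %in% colnames(scr3))
  expect_true(all(scr3$p_adj >= scr3$p - 1e-12))
})

test_that("type-I error of both tests is nominal under the null", {
  # designs whose exact tests have size close to 0.05
  set.seed(101)
  rej_sr <- mean(vapply(1:400, function(i)
    signedRankTest(rnorm(10))$p_value <= 0.05, logical(1)))
  rej_rs <- mean(vapply(1:400, function(i)
    rankSumTest(rnorm(8), rnorm(8))$p_value <= 0.05, logical(1)))
  expect_gt(rej_sr, 0.02); expect_lt(rej_sr, 0.08)
  expect_gt(rej_rs, 0.02); expect_lt(rej_rs, 0.08)
})
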