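test_that("fisherOr matches hand values and the enumeration oracle", {
  r <- fisherOr(20, 80, 100, 900)
  expect_equal(r$odds_ratio, 2.25)
  expect_equal(r$p, fisherOracle(20, 80, 100, 900))

  r2 <- fisherOr(5, 5, 5, 5)
  expect_equal(r2$odds_ratio, 1)
  expect_equal(r2$p, 1)

  # Haldane-Anscombe correction on zero cells
  r3 <- fisherOr(3, 0, 0, 3)
  expect_equal(r3$odds_ratio, 49)
  expect_equal(r3$p, fisherOracle(3, 0, 0, 3))

  expect_warning(r4 <- fisherOr(0, 0, 3, 4), "margin")
  expect_true(is.na(r4$p))
  expect_error(fisherOr(-1, 2, 3, 4), "non-negative")
})

test_that("fisher p equals the enumeration oracle on a table grid", {
  # exhaustive over all tables with grand total <= 20
  for (n in 1:20) {
    for (a in 0:n) for (b in 0:(n - a)) for (cc in 0:(n - a - b)) {
      d <- n - a - b - cc
      if (a + b == 0 || cc + d == 0) next
      expect_equal(fisherOr(a, b, cc, d)$p, fisherOracle(a, b, cc, d),
                   tolerance = 1e-12)
    }
  }
  # random tables with margins up to 30
  set.seed(30)
  for (i in 1:500) {
    a <- sample(0:30, 1); b <- sample(0:(30 - a), 1)
    cc <- sample(0:30, 1); d <- sample(0:(30 - cc), 1)
    if (a + b == 0 || cc + d == 0) next
    expect_equal(fisherOr(a, b, cc, d)$p, fisherOracle(a, b, cc, d),
                 tolerance = 1e-12)
  }
})

test_that("BH adjustment matches the hand-applied step-up rule", {
  expect_equal(bhAdjust(0.03), 0.03)
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  # hand-computed: p * n / rank with running minimum from the top
  p <- c(0.001, 0.008, 0.039, 0.041, 0.042, 0.06, 0.074, 0.205, 0.212, 0.216)
  manual <- rev(cummin(rev(p * length(p) / seq_along(p))))
  expect_equal(bhAdjust(p), pmin(manual, 1))

  set.seed(31)
  pr <- runif(50)
  q <- bhAdjust(pr)
  expect_true(all(q >= pr))          # q >= p elementwise
  expect_true(all(q <= 1))
  # re-adjusting never lowers a q-value and preserves the ranking
  q2 <- bhAdjust(q)
  expect_true(all(q2 >= q))
  expect_true(all(diff(q2[order(q)]) >= -1e-12))  # weak order preserved
  expect_true(all(bhAdjust(p) >= p))
})

test_that("planted amino-acid signal is recovered at the A site", {
  lens <- setNames(rep(40L, 12), sprintf("g%02d", 1:12))
  cds <- randomCds(lens, seed = 20)
  # place CCA (Pro) downstream of every pause position
  pauses <- data.frame(orf_id = rep(names(lens), each = 2),
                       codon_index = rep(c(10L, 25L), 12))
  for (i in seq_len(nrow(pauses)))
    cds <- setCodons(cds, pauses$orf_id[i], pauses$codon_index[i] + 1L, "CCA")
  calls <- makeCallSet(lens, pauses)
  res <- siteFeatureEnrichment(calls, cds, site = "A")
  pro <- res[res$feature == "P", ]
  expect_gt(pro$odds_ratio, 1)
  expect_lt(pro$q, 0.05)
  expect_equal(res$feature[which.max(res$odds_ratio)], "P")
  # a + b equals the number of pause-site observations for every feature
  expect_true(all(res$a + res$b == sum(res$a)))
})

test_that("uniform random calls show no enrichment", {
  lens <- setNames(rep(60L, 15), sprintf("r%02d", 1:15))
  cds <- randomCds(lens, seed = 21)
  set.seed(22)
  pauses <- data.frame(orf_id = sample(names(lens), 40, replace = TRUE),
                       codon_index = sample(5:50, 40, replace = TRUE))
  calls <- makeCallSet(lens, unique(pauses))
  res <- siteFeatureEnrichment(calls, cds, site = "A")
  expect_gt(min(res$q), 0.05)
})

test_that("optimality triplets classify and enrich by construction", {
  lens <- setNames(rep(50L, 10), sprintf("t%02d", 1:10))
  cds <- randomCds(lens, seed = 23)
  scale <- setNames(rep("O", 61), senseCodons())
  nCodons <- c("CCG", "AGG", "GGA")
  scale[nCodons] <- "N"
  # pauses whose A-site codon is non-optimal, E/P optimal
  pauses <- data.frame(orf_id = names(lens), codon_index = 20L)
  for (id in names(lens)) {
    cds <- setCodons(cds, id, c(19L, 20L), "GCT")  # optimal E, P
    cds <- setCodons(cds, id, 21L, "CCG")          # non-optimal A
  }
  calls <- makeCallSet(lens, pauses)
  res <- optimalityTripletEnrichment(calls, cds, scale)
  oon <- res[res$feature == "OON", ]
  expect_gt(oon$odds_ratio, 1)
  ooo <- res[res$feature == "OOO", ]
  expect_lt(ooo$odds_ratio, 1)
  # triplet counts over pause sites sum to the retained pause sites
  expect_equal(sum(res$a), nrow(pauses))
})

test_that("bicodon pairs are tested against anchor-matched background", {
  lens <- setNames(rep(60L, 10), sprintf("b%02d", 1:10))
  cds <- randomCds(lens, seed = 24)
  # every ORF: pause at CCG-AGG-CCG at 14/15/16; non-pause AGG-CCT at 40/41
  for (id in names(lens)) {
    cds <- setCodons(cds, id, 14L, "CCG")
    cds <- setCodons(cds, id, 15L, "AGG"); cds <- setCodons(cds, id, 16L, "CCG")
    cds <- setCodons(cds, id, 40L, "AGG"); cds <- setCodons(cds, id, 41L, "CCT")
  }
  calls <- makeCallSet(lens, data.frame(orf_id = names(lens),
                                        codon_index = 15L))
  res <- bicodonPairEnrichment(calls, cds, anchorCodon = "AGG")
  ccg <- res[res$feature == "CCG", ]
  expect_gt(ccg$odds_ratio, 1)
  # inverse-order pairs (partner upstream of the anchor) via the site swap
  res2 <- bicodonPairEnrichment(calls, cds, anchorCodon = "AGG",
                                partnerCodons = "CCG", partnerOffset = -1L)
  expect_equal(res2$feature, "CCG")
  expect_gt(res2$odds_ratio, 1)
})

test_that("Theil-Sen slope/intercept and MAD outliers are exact on toys", {
  x <- setNames(seq(0.01, 0.61, by = 0.01), paste0("c", 1:61))
  ts <- theilSenOutliers(x, x)
  expect_equal(ts$slope, 1)
  expect_equal(ts$intercept, 0)
  expect_length(ts$outliers, 0)

  ts2 <- theilSenOutliers(x, 2 * x + 1)
  expect_equal(ts2$slope, 2)
  expect_equal(ts2$intercept, 1)

  y <- x
  y["c30"] <- y["c30"] + 0.5
  ts3 <- theilSenOutliers(x, y)
  expect_equal(ts3$outliers, "c30")

  expect_error(theilSenOutliers(setNames(rep(1, 5), letters[1:5]),
                                setNames(1:5 / 10, letters[1:5])),
               "slope undefined")
})
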