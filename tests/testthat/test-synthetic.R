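test_that("the generator is seeded, reproducible and honors its knobs", {
  cfg <- simConfig(nOrfs = 30, seed = 5)
  t1 <- generateTranslatome(cfg)
  t2 <- generateTranslatome(cfg)
  expect_identical(t1$profiles, t2$profiles)
  expect_identical(as.character(t1$sequences), as.character(t2$sequences))
  expect_false(identical(
    t1$profiles, generateTranslatome(simConfig(nOrfs = 30, seed = 6))$profiles))

  # sequences are framed ATG ... TAA and consistent with profile lengths
  L <- lengths(t1$profiles)
  expect_true(all(Biostrings::width(t1$sequences) == 3 * (L + 1)))
  expect_true(all(startsWith(as.character(t1$sequences), "ATG")))
  expect_true(all(endsWith(as.character(t1$sequences), "TAA")))
})

test_that("null model: flat dwell and no ramps give index-independent means", {
  cfg <- simConfig(nOrfs = 60, ramp5Height = 1, ramp3Height = 1,
                   exprMeanLog = log(20), exprSdLog = 0, lengthSdLog = 0,
                   seed = 8)
  tl <- generateTranslatome(cfg)
  m <- colMeans(do.call(rbind, unname(tl$profiles)))
  expect_equal(mean(m), 20, tolerance = 0.05)
  firstHalf <- mean(m[seq_len(length(m) / 2)])
  secondHalf <- mean(m[-seq_len(length(m) / 2)])
  expect_equal(firstHalf / secondHalf, 1, tolerance = 0.05)
})

test_that("dwell multipliers scale coverage at the decoded codon", {
  cfg <- simConfig(nOrfs = 80, dwell = c(CCG = 5), dwellSite = "A",
                   ramp5Height = 1, ramp3Height = 1,
                   exprMeanLog = log(10), exprSdLog = 0, seed = 9)
  tl <- generateTranslatome(cfg)
  chars <- setNames(as.character(tl$sequences), names(tl$sequences))
  rat <- vapply(names(tl$profiles), function(id) {
    L <- length(tl$profiles[[id]])
    cv <- substring(chars[[id]], seq(1, 3 * L - 2, 3), seq(3, 3 * L, 3))
    aSite <- c(cv[-1], "TAA")
    c(mean(tl$profiles[[id]][aSite == "CCG"]),
      mean(tl$profiles[[id]][aSite != "CCG"]))
  }, numeric(2))
  expect_equal(mean(rat[1, ], na.rm = TRUE) / mean(rat[2, ]), 5,
               tolerance = 0.1)

  # ramps elevate terminal coverage
  cfgR <- simConfig(nOrfs = 60, ramp5Height = 2, ramp5Length = 50,
                    exprSdLog = 0, lengthSdLog = 0, seed = 10)
  tlR <- generateTranslatome(cfgR)
  m <- colMeans(do.call(rbind, unname(tlR$profiles)))
  expect_gt(mean(m[1:5]) / mean(m[100:200]), 1.5)
})

test_that("pause injection flattens outliers then spikes labeled positions", {
  # step 1 alone: [1,1,1,9] has 9 > 2*sd -> flattened to the ORF mean
  prof <- list(a = c(1, 1, 1, 9), b = c(2, 3, 2, 3, 2, 3))
  inj <- injectPauses(prof, nPerOrf = 0, seed = 1)
  # normalized profile is [1/3, 1/3, 1/3, 3]; the 3 exceeds 2*sd = 2.67 and
  # is replaced by the ORF mean (1), i.e. count 9 -> count 3
  expect_equal(inj$profiles$a, c(1 / 3, 1 / 3, 1 / 3, 1))

  # step 1 strictly reduces the per-ORF max when outliers exist
  expect_lt(max(inj$profiles$a), max(c(1, 1, 1, 9) / 3))

  # injection: the labeled position exceeds 2 SD afterwards and is the max
  set.seed(2)
  prof2 <- setNames(lapply(1:20, function(i) rnbinom(60, mu = 10, size = 10) + 1),
                    paste0("g", 1:20))
  inj2 <- injectPauses(prof2, nPerOrf = 1, seed = 3)
  expect_equal(nrow(inj2$labels), 20)
  for (id in names(prof2)[1:8]) {
    v <- inj2$profiles[[id]]
    j <- inj2$labels$codon_index[inj2$labels$orf_id == id] + 1L
    expect_equal(which.max(v), j)
    expect_gt(v[j], 2 * inj2$sd[id])
  }

  # seeded twice: identical labels and profiles
  inj3 <- injectPauses(prof2, nPerOrf = 1, seed = 3)
  expect_identical(inj2, inj3)
})

test_that("replicate resampling keeps ground truth but redraws noise", {
  cfg <- simConfig(nOrfs = 25, dwell = c(AGG = 4), seed = 11)
  tl <- generateTranslatome(cfg)
  rep2 <- resampleCounts(tl, seed = 12)
  expect_identical(as.character(tl$sequences), as.character(rep2$sequences))
  expect_false(identical(tl$profiles, rep2$profiles))
  expect_equal(lengths(tl$profiles), lengths(rep2$profiles))
  # same expected coverage: totals correlate strongly across ORFs
  expect_gt(cor(vapply(tl$profiles, sum, numeric(1)),
                vapply(rep2$profiles, sum, numeric(1))), 0.95)
})

test_that("ROC benchmark follows the rank formulation", {
  lab <- c(rep(TRUE, 5), rep(FALSE, 5))
  expect_equal(benchmarkRoc(as.numeric(lab), lab)$auc, 1)
  expect_equal(benchmarkRoc(as.numeric(lab), lab,
                            flagged = lab)$tpr, 1)
  expect_equal(benchmarkRoc(as.numeric(lab), lab, flagged = lab)$fpr, 0)

  set.seed(14)
  sc <- runif(20000)
  lab2 <- runif(20000) < 0.2
  expect_equal(benchmarkRoc(sc, lab2)$auc, 0.5, tolerance = 0.02)

  # AUC invariant under monotone transforms of the scores
  sc2 <- rnorm(500); lab3 <- runif(500) < 0.3
  expect_equal(benchmarkRoc(exp(3 * sc2), lab3)$auc,
               benchmarkRoc(sc2, lab3)$auc)

  expect_error(benchmarkRoc(sc2, rep(TRUE, 500)), "both classes")
})
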