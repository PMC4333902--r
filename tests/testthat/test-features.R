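# the six alignment features, the SVM wrapper and the eSDC analysis

test_that("stem entropy and mutual information hit their analytic values", {
  # pair column perfectly covarying over the four WC/wobble-free types
  al <- StructuredAlignment(
    c(a = "GAAAC", b = "CAAAG", c = "AAAAU", d = "UAAAA"),
    consensus = "(...)")
  expect_equal(meanStemMutualInformation(al), 2)
  expect_equal(meanStemEntropy(al), 2)  # 4 equiprobable bases per column
  # identical rows: zero entropy and zero MI
  alId <- StructuredAlignment(c(a = "GAAAC", b = "GAAAC"),
                              consensus = "(...)")
  expect_equal(meanStemEntropy(alId), 0)
  expect_equal(meanStemMutualInformation(alId), 0)
  # two-base uniform column has 1 bit of entropy
  al2 <- StructuredAlignment(
    c(a = "GAAAC", b = "GAAAC", c = "CAAAG", d = "CAAAG"),
    consensus = "(...)")
  expect_equal(meanStemEntropy(al2), 1)
  expect_error(meanStemEntropy(
    StructuredAlignment(c(a = "GAAAC", b = "GAAAC"),
                        consensus = ".....")), "no base pairs")
})

test_that("MI and entropy agree with brute-force frequency tables", {
  withr::with_seed(19, {
    for (rep in 1:5) {
      rows <- vapply(1:6, function(k) random_rna(12), character(1))
      al <- StructuredAlignment(stats::setNames(rows, paste0("s", 1:6)),
                                consensus = "((........))")
      # brute force on the two pair columns
      bf <- mean(vapply(list(c(1, 12), c(2, 11)), function(pr) {
        x <- substr(rows, pr[1], pr[1])
        y <- substr(rows, pr[2], pr[2])
        joint <- table(x, y) / length(x)
        hx <- -sum((fx <- rowSums(joint)) * log2(fx))
        hy <- -sum((fy <- colSums(joint)) * log2(fy))
        hxy <- -sum(joint[joint > 0] * log2(joint[joint > 0]))
        hx + hy - hxy
      }, numeric(1)))
      expect_equal(meanStemMutualInformation(al), bf, tolerance = 1e-12)
      expect_gte(meanStemMutualInformation(al), 0)
      expect_lte(meanStemEntropy(al), 2)
    }
  })
})

test_that("pairwise identity counts matching columns with gap rules", {
  alId <- StructuredAlignment(c(a = "GAAAC", b = "GAAAC"),
                              consensus = "(...)")
  expect_equal(meanPairwiseIdentity(alId), 1.0)
  al <- StructuredAlignment(c(a = "AAAA", b = "AAAU"),
                            consensus = "....")
  expect_equal(meanPairwiseIdentity(al), 0.75)
  # gap in both rows is excluded; gap vs base is a mismatch
  alGap <- StructuredAlignment(c(a = "AA-A", b = "A--A"),
                               consensus = "....")
  expect_equal(meanPairwiseIdentity(alGap), 2 / 3)
  expect_error(meanPairwiseIdentity(
    StructuredAlignment(c(a = "AAAA"), consensus = "....")), "2 rows")
})

test_that("SCI is 1 for identical rows; MFE z-score flags designed stability", {
  alId <- StructuredAlignment(c(a = HAIRPIN_SEQ, b = HAIRPIN_SEQ),
                              consensus = HAIRPIN_DB)
  expect_equal(structureConservationIndex(alId, toy), 1.0)
  # a designed stable alignment has an MFE well below its shuffles
  fix <- syntheticStructuredAlignment(defaultBenchmarkStructure(),
                                      nSeq = 4, seed = 10)
  z <- mfeZScore(fix, toy, nShuffles = 30, seed = 1)
  expect_lt(z, -1)
  # homopolymer rows are shuffle-invariant: z contribution 0
  alHomo <- StructuredAlignment(c(a = "AAAAAAAA", b = "AAAAAAAA"),
                                consensus = "........")
  expect_equal(mfeZScore(alHomo, toy, nShuffles = 5, seed = 1), 0)
})

test_that("feature vectors assemble deterministically", {
  fix <- syntheticStructuredAlignment("(((((....)))))", nSeq = 4,
                                      seed = 3)
  fv <- featureVector(fix, toy, withNeutrality = TRUE, n = 100, seed = 2,
                      nShuffles = 20)
  expect_setequal(names(fv), c("zscore_mfe", "sci", "mean_stem_entropy",
                               "mean_stem_mi", "mean_pairwise_identity",
                               "n_sequences", "neutrality"))
  expect_true(all(is.finite(unlist(fv))))
  expect_equal(fv$n_sequences, 4L)
  fv2 <- featureVector(fix, toy, withNeutrality = TRUE, n = 100, seed = 2,
                       nShuffles = 20)
  expect_identical(fv, fv2)
  fvNo <- featureVector(fix, toy, withNeutrality = FALSE, nShuffles = 20)
  expect_false("neutrality" %in% names(fvNo))
})

test_that("SVM cross-validation separates, nulls and respects monotone maps", {
  withr::with_seed(42, {
    n <- 30
    feats <- data.frame(x = c(rnorm(n, 0), rnorm(n, 6)),
                        y = c(rnorm(n, 0), rnorm(n, 6)))
    labels <- rep(c("other", "structured"), each = n)
    cv <- svmCrossValidate(feats, labels, seed = 1)
    expect_equal(cv$auc, 1.0)
    # label shuffling destroys the signal
    aucs <- vapply(1:20, function(r) {
      svmCrossValidate(feats, sample(labels), seed = r)$auc
    }, numeric(1))
    expect_lt(abs(mean(aucs) - 0.5), 0.1)
    # single feature classifier; AUC about invariant under monotone maps
    cv1 <- svmCrossValidate(feats, labels, featureSubset = "x", seed = 2)
    featsT <- data.frame(x = exp(feats$x / 4), y = feats$y)
    cv1T <- svmCrossValidate(featsT, labels, featureSubset = "x", seed = 2)
    expect_lt(abs(cv1$auc - cv1T$auc), 0.05)
  })
  expect_error(svmCrossValidate(data.frame(x = rnorm(8)),
                                rep(c("a", "b"), 4)), "folds")
})

test_that("eSDC conversion and top-half disruption labelling", {
  expect_equal(esdc(1, 100), 0)
  expect_equal(esdc(0.9, 100), 1.0)
  expect_true(all(esdc(runif(10, -1, 1), 50) >= 0))
  lab <- labelDisrupting(c(3, 1, 4, 2))
  expect_equal(lab, c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(sum(labelDisrupting(c(5, 5, 5, 5))), 2L)  # stable ties
  expect_equal(sum(labelDisrupting(1:5)), 2L)            # strict half
})

test_that("logistic disruption regression recovers a planted signal", {
  withr::with_seed(77, {
    sen <- runif(200)
    disrupting <- rbinom(200, 1, plogis(4 - 8 * sen))  # low SEN disrupts
    fit <- disruptionRegression(sen, disrupting)
    expect_lt(stats::coef(fit$model)[["neutrality"]], 0)
    expect_gt(fit$auc, 0.6)
  })
})
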