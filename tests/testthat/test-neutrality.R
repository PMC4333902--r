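# the three neutrality metrics and the alignment workflow

test_that("1-mutant neighbourhood has exactly 3L unique members", {
  m <- mutantNeighbors("AC")
  expect_setequal(m, c("CC", "GC", "UC", "AA", "AG", "AU"))
  expect_equal(length(m), 6L)
  expect_setequal(mutantNeighbors("G"), c("A", "C", "U"))
  withr::with_seed(31, {
    for (L in c(1, 3, 17, 40)) {
      s <- random_rna(L)
      muts <- mutantNeighbors(s)
      expect_equal(length(muts), 3L * L)
      expect_equal(anyDuplicated(muts), 0L)
      hd <- vapply(muts, function(m) {
        sum(strsplit(m, "")[[1]] != strsplit(s, "")[[1]])
      }, numeric(1))
      expect_true(all(hd == 1))
      expect_equal(as.integer(table(attr(muts, "position"))),
                   rep(3L, L))
    }
  })
})

test_that("sampled BPROB counts pair fractions", {
  samp <- new("EnsembleSample", sequence = "GGAC",
              structures = c("()..", "(..)"), n = 2L,
              seed = 1L, stream = 0L)
  P <- sampledBasePairProbs(samp)
  expect_equal(P[1, 2], 0.5)
  expect_equal(P[1, 4], 0.5)
  expect_equal(sum(P), 2)  # symmetric entries
  expect_true(all(rowSums(P) <= 1))
  # all identical samples -> 0/1 matrix
  sampId <- new("EnsembleSample", sequence = "GGGAAACCC",
                structures = rep(HAIRPIN_DB, 3), n = 3L,
                seed = 1L, stream = 0L)
  expect_true(all(sampledBasePairProbs(sampId) %in% c(0, 1)))
})

test_that("centroid keeps pairs sampled strictly more than half the time", {
  samp <- new("EnsembleSample", sequence = "GGAC",
              structures = c("(())", "(())", "().."), n = 3L,
              seed = 1L, stream = 0L)
  expect_equal(dotBracket(centroidStructure(samp)), "(())")
  # exactly 0.5 is excluded
  tie <- new("EnsembleSample", sequence = "GGAC",
             structures = c("()..", "(..)"), n = 2L,
             seed = 1L, stream = 0L)
  expect_equal(numPairs(centroidStructure(tie)), 0L)
  single <- new("EnsembleSample", sequence = "GGGAAACCC",
                structures = HAIRPIN_DB, n = 1L, seed = 1L, stream = 0L)
  expect_equal(dotBracket(centroidStructure(single)), HAIRPIN_DB)
})

test_that("SEN distance counts retained reference pairs only", {
  ref <- SecondaryStructure(rbind(c(1, 10), c(2, 9), c(3, 8)), 10)
  # sampled structure keeps 2 of 3 reference pairs; its extra pair
  # (4,7) is not penalised
  got <- senDistance(ref, "((.(..).))")
  expect_equal(got, 2 / 3)
  expect_equal(senDistance(ref, rep("(((....)))", 5)), 1.0)
  expect_equal(senDistance(ref, ".........."), 0.0)
  expect_error(senDistance(SecondaryStructure(NULL, 10), "...."),
               "undefined")
})

test_that("adding non-conflicting pairs leaves SEN unchanged but lowers the bp-distance term", {
  ref <- parseDotBracket("(((...)))....")
  base <- c("(((...)))....", "((.....))....", ".((...)).....")
  # same structures with an extra non-conflicting pair at (10, 13)
  augmented <- c("(((...)))(..)", "((.....))(..)", ".((...)).(..)")
  expect_equal(senDistance(ref, augmented), senDistance(ref, base))
  for (k in seq_along(base)) {
    expect_lt(bpDistanceTerm(ref, parseDotBracket(augmented[k])),
              bpDistanceTerm(ref, parseDotBracket(base[k])))
  }
  # identical structures give exactly 1 on all metrics
  expect_equal(senDistance(ref, dotBracket(ref)), 1.0)
  expect_equal(bpDistanceTerm(ref, ref), 1.0)
  expect_equal(senRNA:::.pccTerm(pairedVector(ref), pairedVector(ref),
                                 "adjusted"), 1.0)
})

test_that("SEN agrees with the closed-form exact-ensemble expectation", {
  # E[SEN] over a mutant's exact ensemble is sum over reference pairs
  # of their exact pair probability, divided by |T|; averaging over
  # mutants gives the expected SEN, against which the sampled value is
  # checked within 3 sigma of its binomial error
  s <- HAIRPIN_SEQ
  ref <- parseDotBracket(HAIRPIN_DB)
  refIdx <- structurePairs(ref)
  muts <- mutantNeighbors(s)
  exact <- vapply(muts, function(m) {
    P <- oracle_bpp(m)
    sum(P[refIdx]) / nrow(refIdx)
  }, numeric(1))
  n <- 1000L
  res <- senNeutrality(s, ref, toy, n = n, seed = 77)
  # conservative bound on the Monte Carlo sd of the mutant average
  sdBound <- sqrt(sum(0.25 / n) * length(muts)) / length(muts)
  expect_lt(abs(res$value - mean(exact)), 3 * max(sdBound, 1e-3))
  expect_true(res$value >= 0 && res$value <= 1)
})

test_that("SEN fast path equals the generic engine-agnostic path", {
  s <- "GGCGAAAGCC"
  ref <- mfeStructure(toy, s)
  fast <- senNeutrality(s, ref, toy, n = 60, seed = 9, fastPath = TRUE)
  slow <- senNeutrality(s, ref, toy, n = 60, seed = 9, fastPath = FALSE)
  expect_equal(attr(fast, "per_mutant"), attr(slow, "per_mutant"))
  expect_equal(fast$value, slow$value)
})

test_that("bp-distance neutrality matches a per-mutant recomputation", {
  s <- "GGCAAAAGCC"
  ref <- mfeStructure(toy, s)
  res <- bpDistanceNeutrality(s, ref, toy)
  muts <- mutantNeighbors(s)
  # recompute each term through the R-level structure API, checking
  # each mutant MFE against the enumerated optimum on the way
  recomputed <- vapply(muts, function(m) {
    mfe <- mfeStructure(toy, m)
    expect_equal(attr(mfe, "energy"), oracle_mfe_energy(m))
    1 - bpDistance(ref, mfe) / nchar(s)
  }, numeric(1), USE.NAMES = FALSE)
  expect_equal(attr(res, "per_mutant"), recomputed)
  expect_true(res$value >= 0 && res$value <= 1)
  # worked example: d((()) vs ()..) = 3 -> 1 - 3/4
  a <- parseDotBracket("(())")
  b <- parseDotBracket("()..")
  expect_equal(1 - bpDistance(a, b) / 4, 0.25)
})

test_that("PCC neutrality conventions and degenerate vectors", {
  # identical centroid -> 1 under the adjusted form, 0 under printed
  v <- c(1L, 0L, 0L, 1L)
  expect_equal(senRNA:::.pccTerm(v, v, "adjusted"), 1.0)
  expect_equal(senRNA:::.pccTerm(v, v, "printed"), 0.0)
  # complementary balanced vectors -> r = -1
  expect_equal(senRNA:::.pccTerm(v, 1L - v, "adjusted"), 0.0)
  # constant reference vector: 1 if equal else 0.5
  z <- c(0L, 0L, 0L, 0L)
  expect_equal(senRNA:::.pccTerm(z, z, "adjusted"), 1.0)
  expect_equal(senRNA:::.pccTerm(z, v, "adjusted"), 0.5)
  s <- "GGCGAAAGCC"
  ref <- mfeStructure(toy, s)
  adj <- pccNeutrality(s, ref, toy, n = 100, seed = 4, form = "adjusted")
  pri <- pccNeutrality(s, ref, toy, n = 100, seed = 4, form = "printed")
  expect_true(adj$value > pri$value)  # structured sequence scores high
  fast <- pccNeutrality(s, ref, toy, n = 100, seed = 4, fastPath = FALSE)
  expect_equal(adj$value, fast$value)
})

test_that("positional profile averages back to the global SEN", {
  s <- "GGCGAAAGCC"
  ref <- mfeStructure(toy, s)
  prof <- positionalNeutrality(s, ref, toy, n = 120, seed = 6)
  expect_length(prof, nchar(s))
  expect_equal(mean(prof), attr(prof, "global"))
  expect_equal(mean(prof), senNeutrality(s, ref, toy, 120, 6)$value)
})

test_that("loop positions are more neutral than stem positions", {
  # strong two-stem fixture: mutations inside stems disrupt reference
  # pairs, loop/tail mutations mostly do not
  db <- "((((((....))))))........"
  s <- plateauSequence(db)
  ref <- parseDotBracket(db)
  prof <- positionalNeutrality(s, ref, toy, n = 300, seed = 8)
  stem <- c(structurePairs(ref))
  loop <- setdiff(seq_len(nchar(s)), stem)
  expect_gt(mean(prof[loop]), mean(prof[stem]))
})

test_that("alignment workflow computes per-row metrics and records skips", {
  al <- readStockholm(fixture_stockholm())
  res <- alignmentNeutrality(al, "SEN", toy, n = 100, seed = 2)
  expect_equal(nrow(res), 2L)
  expect_false(any(res$skipped))
  expect_true(all(res$value >= 0 & res$value <= 1))
  # a row with an ambiguity code is skipped by name
  al2 <- StructuredAlignment(c(good = "GGGAAACCC", bad = "GGGANACCC"),
                             consensus = HAIRPIN_DB)
  res2 <- suppressWarnings(alignmentNeutrality(al2, "SEN", toy, 50, 1))
  expect_true(res2$skipped[res2$sequence_id == "bad"])
  expect_match(res2$skip_reason[2], "ambiguity")
  expect_false(res2$skipped[1])
  # row incompatible with every consensus pair -> |T| = 0 skip
  al3 <- StructuredAlignment(c(a = "GGGAAACCC", b = "AAAAAAAAA"),
                             consensus = HAIRPIN_DB)
  res3 <- suppressWarnings(alignmentNeutrality(al3, "SEN", toy, 50, 1))
  expect_match(res3$skip_reason[2], "no canonical")
  # an alignment with no rows is rejected outright
  expect_error(StructuredAlignment(character(0),
                                   consensus = NA_character_,
                                   structureSource = "predicted"),
               "at least one row")
})

test_that("metric results are deterministic under a fixed seed", {
  al <- readStockholm(fixture_stockholm())
  a <- alignmentNeutrality(al, "SEN", toy, n = 80, seed = 5)
  b <- alignmentNeutrality(al, "SEN", toy, n = 80, seed = 5)
  expect_identical(a, b)
  c <- alignmentNeutrality(al, "SEN", toy, n = 80, seed = 6)
  expect_false(identical(a$value, c$value))
})
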