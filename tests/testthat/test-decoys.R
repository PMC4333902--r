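# decoy construction and synthetic fixtures

dinucs <- function(s) {
  chars <- strsplit(s, "")[[1]]
  if (length(chars) < 2) return(character(0))
  sort(paste0(chars[-length(chars)], chars[-1]))
}

test_that("dinucleotide shuffle preserves the exact dinucleotide multiset", {
  withr::with_seed(51, {
    for (rep in 1:20) {
      s <- random_rna(sample(10:80, 1))
      sh <- dinucleotideShuffle(s, seed = rep)
      expect_equal(dinucs(sh), dinucs(s))
      expect_equal(substr(sh, 1, 1), substr(s, 1, 1))
      # mononucleotide composition preserved as a corollary
      expect_equal(nucleotideComposition(sh), nucleotideComposition(s))
    }
  })
  expect_equal(dinucleotideShuffle("AAAA", seed = 1), "AAAA")
  # shuffles are seed-driven and usually differ between seeds
  s <- random_rna(60)
  expect_identical(dinucleotideShuffle(s, 7), dinucleotideShuffle(s, 7))
  expect_false(identical(dinucleotideShuffle(s, 7),
                         dinucleotideShuffle(s, 8)))
})

test_that("alignment shuffling preserves per-row gaps and re-predicts the consensus", {
  al <- StructuredAlignment(
    c(a = "GGGAA-ACCC", b = "GGG-AAACCC", c = "GGGAAAC-CC"),
    consensus = "(((..-.)))")
  dec <- dinucleotideShuffleAlignment(al, toy, seed = 3)
  expect_equal(structureSource(dec), "predicted")
  seqs <- alignedSequences(dec)
  orig <- alignedSequences(al)
  for (k in seq_along(seqs)) {
    expect_equal(gregexpr("-", seqs[k])[[1]], gregexpr("-", orig[k])[[1]])
    expect_equal(dinucs(gsub("-", "", seqs[k])),
                 dinucs(gsub("-", "", orig[k])))
  }
  # column mode permutes columns jointly
  dcol <- dinucleotideShuffleAlignment(al, toy, seed = 3, mode = "column")
  expect_equal(sort(strsplit(alignedSequences(dcol)[1], "")[[1]]),
               sort(strsplit(orig[1], "")[[1]]))
})

test_that("synthetic alignments keep rows structure-compatible with covariation", {
  db <- defaultBenchmarkStructure()
  st <- parseDotBracket(db)
  canon <- c("AU", "UA", "GC", "CG", "GU", "UG")
  al <- syntheticStructuredAlignment(db, nSeq = 5, substitutionRate = 0.3,
                                     covariation = TRUE, seed = 5)
  expect_equal(consensus(al), db)
  expect_equal(structureSource(al), "given")
  p <- structurePairs(st)
  for (s in alignedSequences(al)) {
    chars <- strsplit(s, "")[[1]]
    expect_true(all(paste0(chars[p[, 1]], chars[p[, 2]]) %in% canon))
  }
  # zero substitution rate: all rows identical
  al0 <- syntheticStructuredAlignment(db, nSeq = 4, substitutionRate = 0,
                                      seed = 5)
  expect_equal(length(unique(alignedSequences(al0))), 1L)
  # covariation produces positive stem mutual information (20 replicates)
  mis <- vapply(1:20, function(r) {
    meanStemMutualInformation(
      syntheticStructuredAlignment(db, nSeq = 6, substitutionRate = 0.3,
                                   covariation = TRUE, seed = r))
  }, numeric(1))
  expect_true(all(mis >= 0))
  expect_gt(mean(mis), 0.2)
})

test_that("structured fixtures outscore their shuffled decoys on SEN", {
  al <- syntheticStructuredAlignment(defaultBenchmarkStructure(),
                                     nSeq = 5, seed = 21)
  dec <- dinucleotideShuffleAlignment(al, toy, seed = 22)
  pos <- alignmentNeutrality(al, "SEN", toy, n = 300, seed = 1)
  neg <- suppressWarnings(alignmentNeutrality(dec, "SEN", toy, n = 300,
                                              seed = 1))
  expect_gt(stats::median(pos$value, na.rm = TRUE),
            stats::median(neg$value, na.rm = TRUE))
})

test_that("subalignments draw 3-6 rows and stay consistent", {
  al <- syntheticStructuredAlignment(defaultBenchmarkStructure(),
                                     nSeq = 10, seed = 31)
  withr::with_seed(1, {
    sizes <- vapply(1:15, function(r) {
      length(subalignmentSample(al, seed = r))
    }, integer(1))
  })
  expect_true(all(sizes %in% 3:6))
  al3 <- syntheticStructuredAlignment(HAIRPIN_DB, nSeq = 3, seed = 1)
  expect_equal(length(subalignmentSample(al3, seed = 2)), 3L)
  expect_error(subalignmentSample(
    StructuredAlignment(c(a = "GGGAAACCC", b = "GGGAAACCC"),
                        consensus = HAIRPIN_DB), seed = 1), "3 rows")
  expect_identical(alignedSequences(subalignmentSample(al, seed = 4)),
                   alignedSequences(subalignmentSample(al, seed = 4)))
})

test_that("delta SEN reports differences and structural diagnostics", {
  full <- data.frame(sequence_id = "s", value = 0.6)
  sub <- data.frame(sequence_id = "s", value = 0.5)
  d <- deltaSen(full, sub)
  expect_equal(d$delta_sen, 0.1)
  expect_equal(deltaSen(full, full)$delta_sen, 0)
  fullSt <- parseDotBracket("(((...)))")
  subSt <- parseDotBracket("((.....))")
  d2 <- deltaSen(full, sub, fullSt, subSt)
  expect_equal(d2$bp_distance, 1L)
  expect_equal(d2$pair_ratio, 3 / 2)
  expect_error(deltaSen(full, data.frame(sequence_id = "t", value = 0.5)),
               "different sequences")
})
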