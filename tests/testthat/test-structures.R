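test_that("dot-bracket parsing matches brackets and errors on imbalance", {
  s <- parseDotBracket("(())")
  expect_equal(structurePairs(s), matrix(c(1L, 2L, 4L, 3L), ncol = 2,
                                         dimnames = list(NULL, c("i", "j"))))
  expect_equal(numPairs(parseDotBracket("....")), 0L)
  expect_error(parseDotBracket("(()"), "unbalanced")
  expect_error(parseDotBracket("())"), "position 3")
  # WUSS bracket classes and non-nested symbols
  w <- parseDotBracket("<<...>>")
  expect_equal(unname(structurePairs(w)[, 2]), c(7L, 6L))
  expect_equal(numPairs(parseDotBracket("AA..aa,,::--")), 0L)
})

test_that("parse/serialise round-trips on random structures", {
  withr::with_seed(11, {
    for (rep in 1:25) {
      st <- random_structure(sample(10:60, 1))
      expect_equal(structurePairs(parseDotBracket(dotBracket(st))),
                   structurePairs(st))
    }
  })
})

test_that("projections satisfy their invariants", {
  s <- parseDotBracket("(())")
  expect_equal(pairedVector(s), c(1L, 1L, 1L, 1L))
  M <- adjacencyMatrix(s)
  expect_equal(M[1, 4], 1L)
  expect_equal(M[2, 3], 1L)
  expect_true(isSymmetric(M))
  expect_equal(pairedVector(parseDotBracket("(..)")), c(1L, 0L, 0L, 1L))
  expect_equal(sum(adjacencyMatrix(parseDotBracket("...."))), 0L)
  withr::with_seed(7, {
    for (rep in 1:10) {
      st <- random_structure(sample(8:40, 1))
      expect_equal(sum(pairedVector(st)), 2L * numPairs(st))
      expect_true(all(rowSums(adjacencyMatrix(st)) <= 1L))
    }
  })
})

test_that("degapping removes gap columns and dissolves orphan/short pairs", {
  r <- degapPair("GC-GC", "((-))")
  expect_equal(r$seq, "GCGC")
  # the surviving pairs are renumbered but the (1,4)/(2,3) nesting with
  # span < 4 is dissolved by the loop-length rule
  expect_equal(dotBracket(r$structure), "....")
  # wide hairpin survives
  r2 <- degapPair("GGGA-AACCC", "(((.-..)))")
  expect_equal(r2$seq, "GGGAAACCC")
  expect_equal(dotBracket(r2$structure), "(((...)))")
  # partner deleted -> unpaired
  r3 <- degapPair("GGGAAACC-", "(((...)))")
  expect_equal(r3$seq, "GGGAAACC")
  expect_equal(dotBracket(r3$structure), ".((...))")
  expect_error(degapPair("GC", "(.)"), "length")
  # identity case
  r4 <- degapPair("ACGU", "....")
  expect_equal(r4$seq, "ACGU")
  expect_equal(numPairs(r4$structure), 0L)
  # degapping never increases the pair count
  withr::with_seed(5, {
    for (rep in 1:10) {
      L <- 30
      st <- random_structure(L)
      seq <- random_rna(L)
      chars <- strsplit(seq, "")[[1]]
      gapAt <- sample(L, 6)
      chars[gapAt] <- "-"
      dg <- degapPair(paste(chars, collapse = ""), dotBracket(st))
      expect_lte(numPairs(dg$structure), numPairs(st))
      if (numPairs(dg$structure) > 0)
        expect_true(all(structurePairs(dg$structure) <= nchar(dg$seq)))
    }
  })
})

test_that("canonical filter keeps Watson-Crick and wobble pairs only", {
  keep <- canonicalFilter("GAAAC", parseDotBracket("(...)"))
  expect_equal(numPairs(keep), 1L)
  drop <- canonicalFilter("AAAAC", parseDotBracket("(...)"))
  expect_equal(numPairs(drop), 0L)
  wobble <- canonicalFilter("GAAAU", parseDotBracket("(...)"))
  expect_equal(numPairs(wobble), 1L)
  # idempotent
  st <- parseDotBracket("((...))")
  f1 <- canonicalFilter("GGAAACC", st)
  expect_equal(structurePairs(canonicalFilter("GGAAACC", f1)),
               structurePairs(f1))
})

test_that("sequence normalisation maps DNA/lower-case and flags ambiguity", {
  expect_equal(normalizeSequence("acgt")$seq, "ACGU")
  expect_true(normalizeSequence("ACGU")$ok)
  amb <- normalizeSequence("ACGN")
  expect_false(amb$ok)
  expect_match(amb$reason, "N")
  expect_false(normalizeSequence("AC-GU")$ok)
})

test_that("Stockholm round-trips rows, ids and consensus", {
  path <- fixture_stockholm()
  al <- readStockholm(path)
  expect_equal(length(al), 2L)
  expect_equal(names(alignedSequences(al)), c("seqA", "seqB"))
  expect_equal(consensus(al), "<<<...>>>")
  out <- tempfile(fileext = ".sto")
  writeStockholm(al, out)
  back <- readStockholm(out)
  expect_equal(alignedSequences(back), alignedSequences(al))
  expect_equal(consensus(back), consensus(al))
  # missing SS_cons
  noSS <- tempfile(fileext = ".sto")
  writeLines(c("# STOCKHOLM 1.0", "a GGGAAACCC", "b GGGAAACCC", "//"), noSS)
  expect_error(readStockholm(noSS), "SS_cons")
  al2 <- readStockholm(noSS, structureSource = "predicted")
  expect_true(is.na(consensus(al2)))
  # ragged rows
  ragged <- tempfile(fileext = ".sto")
  writeLines(c("# STOCKHOLM 1.0", "a GGGAAACCC", "b GGGAAA",
               "#=GC SS_cons .........", "//"), ragged)
  expect_error(readStockholm(ragged), "ragged|length")
})

test_that("FASTA input normalises and filters plain sequences", {
  fa <- tempfile(fileext = ".fa")
  writeLines(c(">one", "gggaaaccc", ">two", "ACGTACGT", ">bad", "ACGNN"),
             fa)
  seqs <- suppressWarnings(readFastaSequences(fa))
  expect_equal(seqs, c(one = "GGGAAACCC", two = "ACGUACGU"))
  expect_warning(readFastaSequences(fa), "dropping 1")
})

test_that("base-pair distance counts the symmetric difference", {
  a <- parseDotBracket("((....))")
  b <- parseDotBracket("(......)")
  expect_equal(bpDistance(a, b), 1L)
  expect_equal(bpDistance(a, a), 0L)
  c <- parseDotBracket(".(....).")
  expect_equal(bpDistance(a, c), 1L)
  expect_equal(bpDistance(b, c), 2L)
})
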