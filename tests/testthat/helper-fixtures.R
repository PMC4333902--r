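# shared small fixtures

toy <- toyEngine()

# hairpin with a strong GC stem; MFE (((...))) under the toy model
HAIRPIN_SEQ <- "GGGAAACCC"
HAIRPIN_DB <- "(((...)))"

fixture_stockholm <- function(path = tempfile(fileext = ".sto")) {
  writeLines(c(
    "# STOCKHOLM 1.0",
    "seqA GGGAAACCC",
    "seqB GGCAAAGCC",
    "#=GC SS_cons <<<...>>>",
    "//"), path)
  path
}

# random nested structure on L positions (for round-trip properties)
random_structure <- function(L, pairProb = 0.4) {
  pairs <- list()
  rec <- function(i, j) {
    if (j - i < 4) return()
    if (stats::runif(1) < pairProb) {
      ks <- seq(i + 4, j)
      k <- ks[sample.int(length(ks), 1)]
      pairs[[length(pairs) + 1L]] <<- c(i, k)
      rec(i + 1, k - 1)
      rec(k + 1, j)
    } else {
      rec(i + 1, j)
    }
  }
  rec(1L, L)
  SecondaryStructure(do.call(rbind, pairs), L)
}
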