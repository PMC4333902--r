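#' Toy folding engine
#'
#' Self-contained thermodynamic backend with additive per-pair
#' energies (GC/CG -3, AU/UA -2, GU/UG -1 model units), a minimum
#' hairpin loop of 3 unpaired bases, no stacking or loop terms, and
#' Boltzmann weights `exp(-E)` (kT = 1).  The model is deliberately
#' small enough that all quantities can be checked against exhaustive
#' enumeration, while still producing diffuse ensembles for
#' unstructured sequences and stable stems for designed ones.
#'
#' @return a [ToyFoldingEngine-class].
#' @examples
#' eng <- toyEngine()
#' mfeStructure(eng, "GGGAAACCC")
#' @export
toyEngine <- function() {
  new("ToyFoldingEngine", name = "toy", temperature = NA_real_)
}

#' @rdname engineCapabilities
#' @export
setMethod("engineCapabilities", "ToyFoldingEngine", function(engine) {
  c("mfe", "sample", "exact_bpp", "consensus", "inverse")
})

.checkSeq <- function(seq) {
  ns <- normalizeSequence(seq)
  if (!ns$ok) stop("invalid sequence: ", ns$reason)
  ns$seq
}

#' @rdname mfeStructure
#' @export
setMethod("mfeStructure", "ToyFoldingEngine", function(engine, seq) {
  seq <- .checkSeq(seq)
  res <- .toy_mfe(seq)
  out <- parseDotBracket(res$structure)
  attr(out, "energy") <- res$energy
  out
})

#' @rdname sampleStructures
#' @export
setMethod("sampleStructures", "ToyFoldingEngine",
  function(engine, seq, n = 1000L, seed = 1L, stream = 0L) {
    seq <- .checkSeq(seq)
    dbs <- .toy_sample(seq, as.integer(n), as.integer(seed),
                       as.integer(stream))
    new("EnsembleSample", sequence = seq, structures = as.character(dbs),
        n = as.integer(n), seed = as.integer(seed),
        stream = as.integer(stream))
  })

#' @rdname basePairProbs
#' @export
setMethod("basePairProbs", "ToyFoldingEngine", function(engine, seq) {
  seq <- .checkSeq(seq)
  .toy_bpp(seq)
})

#' @rdname structureEnergy
#' @export
setMethod("structureEnergy", "ToyFoldingEngine",
  function(engine, seq, structure) {
    seq <- .checkSeq(seq)
    if (nchar(seq) != structure@length)
      stop("sequence/structure length mismatch")
    p <- structure@pairs
    .toy_energy(seq, p[, 1L], p[, 2L])
  })

#' @rdname predictConsensus
#' @export
setMethod("predictConsensus", "ToyFoldingEngine",
  function(engine, alignment) {
    if (length(alignment) < 2L)
      stop("consensus folding needs at least 2 rows")
    rows <- gsub("[._~]", "-", alignment@seqs)
    res <- .toy_alifold(rows, 0.5)
    out <- alignment
    out@consensus <- res$structure
    out@structureSource <- "predicted"
    attr(out, "consensusEnergy") <- res$energy
    out
  })

# ---- generic inverse folding: adaptive walk on any engine ----------

.PAIR_TYPES <- c("GC", "CG", "AU", "UA", "GU", "UG")

# Random sequence compatible with a target structure.  Pair types are
# drawn with weights given by the product of their base frequencies in
# `comp`; unpaired positions are then drawn from the residual
# composition (target counts minus what the stems consumed), so the
# whole sequence tracks `comp` closely - important for the
# JSD-filtered background generation.  `comp` defaults to uniform.
.randomCompatible <- function(structure, comp = NULL) {
  L <- structure@length
  if (is.null(comp)) comp <- c(A = .25, C = .25, G = .25, U = .25)
  comp <- comp / sum(comp)
  bases <- c("A", "C", "G", "U")
  chars <- character(L)
  p <- structure@pairs
  if (nrow(p) > 0L) {
    w <- vapply(.PAIR_TYPES, function(pt) {
      comp[[substr(pt, 1L, 1L)]] * comp[[substr(pt, 2L, 2L)]]
    }, numeric(1))
    if (all(w == 0)) w <- rep(1, length(w))
    pts <- sample(.PAIR_TYPES, nrow(p), replace = TRUE, prob = w)
    chars[p[, 1L]] <- substr(pts, 1L, 1L)
    chars[p[, 2L]] <- substr(pts, 2L, 2L)
  }
  unpaired <- setdiff(seq_len(L), c(p))
  if (length(unpaired) > 0L) {
    used <- table(factor(chars[chars != ""], levels = bases))
    residual <- pmax(comp * L - as.numeric(used), 0)
    if (sum(residual) == 0) residual <- comp
    chars[unpaired] <- sample(bases, length(unpaired), replace = TRUE,
                              prob = residual)
  }
  paste(chars, collapse = "")
}

#' Compensatory partner base
#'
#' Minimal symmetric completion of the compensatory-mutation rule used
#' in neutral walks: a position mutated to `G` gets partner `C` or `U`
#' with probability 1/2 each, `U` gets `A` or `G`, `A` gets `U`, `C`
#' gets `G`.
#'
#' @param base the new base at the mutated position.
#' @return the partner base restoring a canonical pair.
#' @export
compensatoryPartner <- function(base) {
  switch(base,
         A = "U",
         C = "G",
         G = sample(c("C", "U"), 1L),
         U = sample(c("A", "G"), 1L),
         stop("unknown base ", base))
}

#' @rdname inverseFold
#' @export
setMethod("inverseFold", "ToyFoldingEngine",
  function(engine, structure, seed = 1L, restarts = 50L,
           stepsPerRestart = NULL, startComposition = NULL) {
    stopifnot(is(structure, "SecondaryStructure"))
    L <- structure@length
    if (is.null(stepsPerRestart)) stepsPerRestart <- 10L * L
    comp <- if (is.null(startComposition))
      c(A = .25, C = .25, G = .25, U = .25) else startComposition
    p <- structure@pairs
    res <- .toy_inverse_fold(L, p[, 1L], p[, 2L], as.integer(seed),
                             as.integer(restarts),
                             as.integer(stepsPerRestart),
                             as.numeric(comp[c("A", "C", "G", "U")]))
    list(sequence = res$sequence, distance = as.integer(res$distance),
         mfe = mfeStructure(engine, res$sequence))
  })

#' @rdname inverseFold
#' @export
setMethod("inverseFold", "FoldingEngine",
  function(engine, structure, seed = 1L, restarts = 50L,
           stepsPerRestart = NULL, startComposition = NULL) {
    stopifnot(is(structure, "SecondaryStructure"))
    L <- structure@length
    if (is.null(stepsPerRestart)) stepsPerRestart <- 10L * L
    target <- structure
    # distance of a candidate's MFE structure to the target; the toy
    # engine has a dedicated path avoiding the structure round trip
    distFun <- if (is(engine, "ToyFoldingEngine")) {
      p <- target@pairs
      function(s) .toy_mfe_bpdist(s, p[, 1L], p[, 2L])
    } else {
      function(s) bpDistance(mfeStructure(engine, s), target)
    }
    withSeed(seed, {
      best <- NULL
      bestD <- Inf
      for (r in seq_len(restarts)) {
        cur <- .randomCompatible(target, startComposition)
        curD <- distFun(cur)
        step <- 0L
        while (curD > 0L && step < stepsPerRestart) {
          step <- step + 1L
          cand <- .mutateCompatible(cur, target, startComposition)
          candD <- distFun(cand)
          if (candD <= curD) {
            cur <- cand
            curD <- candD
          }
        }
        if (curD < bestD) {
          best <- cur
          bestD <- curD
        }
        if (bestD == 0L) break
      }
      list(sequence = best, distance = bestD,
           mfe = mfeStructure(engine, best))
    })
  })

# One-point mutation that keeps paired sites of `structure` canonical.
# With `comp` given (inverse-folding under a composition constraint),
# replacement bases and compensatory partners are drawn from it so the
# search stays near the target composition; otherwise the base is
# uniform and the partner follows compensatoryPartner().
.mutateCompatible <- function(seq, structure, comp = NULL) {
  chars <- strsplit(seq, "")[[1L]]
  pos <- sample.int(length(chars), 1L)
  alts <- setdiff(c("A", "C", "G", "U"), chars[pos])
  newBase <- .sampleBase(alts, comp)
  chars[pos] <- newBase
  partner <- .partnerOf(structure, pos)
  if (!is.na(partner)) {
    opts <- switch(newBase, A = "U", C = "G", G = c("C", "U"),
                   U = c("A", "G"))
    chars[partner] <- if (is.null(comp) && length(opts) > 1L)
      compensatoryPartner(newBase) else .sampleBase(opts, comp)
  }
  paste(chars, collapse = "")
}

.sampleBase <- function(opts, comp) {
  if (length(opts) == 1L) return(opts)
  w <- if (is.null(comp)) rep(1, length(opts)) else comp[opts]
  if (all(w == 0)) w <- rep(1, length(opts))
  opts[sample.int(length(opts), 1L, prob = w)]
}

.partnerOf <- function(structure, pos) {
  p <- structure@pairs
  hit <- which(p[, 1L] == pos | p[, 2L] == pos)
  if (length(hit) == 0L) return(NA_integer_)
  ifelse(p[hit, 1L] == pos, p[hit, 2L], p[hit, 1L])
}

#' Evaluate code with a temporary RNG seed
#'
#' Runs `expr` under `set.seed(seed)` and restores the caller's RNG
#' state afterwards, so seeded package internals never disturb user
#' code.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return value of `expr`.
#' @export
withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

setMethod("show", "FoldingEngine", function(object) {
  cat(sprintf("<%s folding engine: %s>\n", object@name,
              paste(engineCapabilities(object), collapse = "/")))
})
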