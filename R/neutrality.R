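#' 1-mutant neighbourhood of a sequence
#'
#' All `3L` sequences at Hamming distance exactly 1 from the input,
#' enumerated position-major with alternative bases in the fixed order
#' `A < C < G < U`.  Mutant rank `r` (1-based) therefore corresponds to
#' position `ceiling(r / 3)`.
#'
#' @param seq gap-free `ACGU` sequence.
#' @return character vector of `3L` mutants with a `position`
#'   attribute giving the mutated position of each.
#' @export
mutantNeighbors <- function(seq) {
  seq <- .checkSeq(seq)
  chars <- strsplit(seq, "")[[1L]]
  L <- length(chars)
  bases <- c("A", "C", "G", "U")
  out <- character(3L * L)
  pos <- integer(3L * L)
  r <- 0L
  for (i in seq_len(L)) {
    for (b in setdiff(bases, chars[i])) {
      r <- r + 1L
      m <- chars
      m[i] <- b
      out[r] <- paste(m, collapse = "")
      pos[r] <- i
    }
  }
  attr(out, "position") <- pos
  out
}

#' Sampled base-pair probability matrix
#'
#' Entry `(i, j)` is the fraction of sampled structures in which `i`
#' pairs with `j` (the mean of the sampled adjacency matrices).
#'
#' @param sample an [EnsembleSample-class].
#' @return symmetric `L x L` matrix with entries in `[0, 1]`.
#' @export
sampledBasePairProbs <- function(sample) {
  stopifnot(is(sample, "EnsembleSample"))
  L <- nchar(sample@sequence)
  P <- matrix(0, L, L)
  for (db in sample@structures) {
    p <- parseDotBracket(db)@pairs
    if (nrow(p) > 0L) {
      P[p] <- P[p] + 1
      P[p[, c(2L, 1L), drop = FALSE]] <- P[p[, c(2L, 1L), drop = FALSE]] + 1
    }
  }
  P / sample@n
}

#' Centroid structure of an ensemble sample
#'
#' The structure containing exactly those pairs that occur in strictly
#' more than half of the sampled structures.  Such pairs can never
#' conflict, so the result is always a valid structure.
#'
#' @param sample an [EnsembleSample-class].
#' @return a [SecondaryStructure-class].
#' @export
centroidStructure <- function(sample) {
  P <- sampledBasePairProbs(sample)
  P[lower.tri(P, diag = TRUE)] <- 0
  idx <- which(P > 0.5, arr.ind = TRUE)
  SecondaryStructure(idx, nchar(sample@sequence))
}

#' SEN distance between a reference structure and an ensemble sample
#'
#' Mean, over the sampled structures, of the fraction of reference
#' base pairs retained, `|T intersect T'| / |T|`.  Pairs formed in the
#' sampled structure but absent from the reference are not penalised.
#'
#' @param structure reference [SecondaryStructure-class] with at least
#'   one pair.
#' @param sample an [EnsembleSample-class] (or plain character vector
#'   of dot-bracket strings).
#' @return value in `[0, 1]`.
#' @export
senDistance <- function(structure, sample) {
  stopifnot(is(structure, "SecondaryStructure"))
  if (numPairs(structure) == 0L)
    stop("SEN distance is undefined for a reference with no base pairs")
  dbs <- if (is(sample, "EnsembleSample")) sample@structures else sample
  refKeys <- paste(structure@pairs[, 1L], structure@pairs[, 2L])
  vals <- vapply(dbs, function(db) {
    p <- parseDotBracket(db)@pairs
    if (nrow(p) == 0L) return(0)
    sum(paste(p[, 1L], p[, 2L]) %in% refKeys) / length(refKeys)
  }, numeric(1), USE.NAMES = FALSE)
  mean(vals)
}

#' Per-structure normalized base-pair similarity term
#'
#' The contribution of one mutant to base-pair-distance neutrality:
#' `1 - d(T, T_mut) / L` where `d` is the symmetric-difference
#' base-pair distance.  Normalisation is by the full length `L`.
#'
#' @param structure reference [SecondaryStructure-class].
#' @param other comparison [SecondaryStructure-class].
#' @return value in `[0, 1]`.
#' @export
bpDistanceTerm <- function(structure, other) {
  1 - bpDistance(structure, other) / structure@length
}

.mutantStream <- function(rank) rank - 1L  # substream index of mutant `rank`

# generic (engine-agnostic) per-mutant SEN profile
.senProfileGeneric <- function(seq, structure, engine, n, seed) {
  muts <- mutantNeighbors(seq)
  vapply(seq_along(muts), function(r) {
    samp <- sampleStructures(engine, muts[r], n = n, seed = seed,
                             stream = .mutantStream(r))
    senDistance(structure, samp)
  }, numeric(1))
}

.senProfile <- function(seq, structure, engine, n, seed,
                        fastPath = TRUE) {
  if (fastPath && is(engine, "ToyFoldingEngine")) {
    p <- structure@pairs
    as.numeric(.toy_sen_profile(seq, p[, 1L], p[, 2L],
                                as.integer(n), as.integer(seed)))
  } else {
    .senProfileGeneric(seq, structure, engine, n, seed)
  }
}

.neutralityResult <- function(id, metric, value, perMutant, position,
                              n, seed) {
  res <- data.frame(sequence_id = id, metric = metric, value = value,
                    n_samples = n, seed = seed,
                    stringsAsFactors = FALSE)
  attr(res, "per_mutant") <- perMutant
  attr(res, "position") <- position
  res
}

#' Structural ensemble neutrality (SEN) of a sequence
#'
#' Mean over all `3L` 1-mutant neighbours of the SEN distance between
#' the reference structure and `n` structures sampled from each
#' mutant's Boltzmann ensemble.  Every mutant draws from its own RNG
#' substream (indexed by mutant rank), so the value is reproducible
#' and independent of evaluation order.
#'
#' @param seq gap-free `ACGU` sequence.
#' @param structure reference [SecondaryStructure-class] (from the
#'   alignment, canonical-filtered) with at least one pair.
#' @param engine a [FoldingEngine-class].
#' @param n ensemble sample size per mutant (default 1000; 100 is
#'   documented as too small for stable values).
#' @param seed integer seed.
#' @param fastPath use the optimised toy-engine path when available
#'   (identical results to the generic path).
#' @return one-row data.frame (`sequence_id`, `metric`, `value`,
#'   `n_samples`, `seed`) with the per-mutant profile in
#'   `attr(, "per_mutant")`.
#' @export
senNeutrality <- function(seq, structure, engine = toyEngine(),
                          n = 1000L, seed = 1L, fastPath = TRUE) {
  seq <- .checkSeq(seq)
  stopifnot(nchar(seq) == structure@length)
  if (numPairs(structure) == 0L)
    stop("SEN is undefined for a reference structure with no base pairs")
  prof <- .senProfile(seq, structure, engine, n, seed, fastPath)
  .neutralityResult("seq", "SEN", mean(prof), prof,
                    attr(mutantNeighbors(seq), "position"), n, seed)
}

#' Base-pair-distance neutrality of a sequence
#'
#' Mean over the 1-mutant neighbours of `1 - d(T, MFE(mutant)) / L`,
#' where `d` is the symmetric-difference base-pair distance between
#' the reference and the mutant's MFE structure.  Deterministic (no
#' sampling involved).
#'
#' @inheritParams senNeutrality
#' @return one-row data.frame as for [senNeutrality()].
#' @export
bpDistanceNeutrality <- function(seq, structure, engine = toyEngine(),
                                 fastPath = TRUE) {
  seq <- .checkSeq(seq)
  stopifnot(nchar(seq) == structure@length)
  L <- nchar(seq)
  if (fastPath && is(engine, "ToyFoldingEngine")) {
    p <- structure@pairs
    d <- as.numeric(.toy_bpdist_profile(seq, p[, 1L], p[, 2L]))
  } else {
    muts <- mutantNeighbors(seq)
    d <- vapply(muts, function(m)
      bpDistance(structure, mfeStructure(engine, m)), numeric(1),
      USE.NAMES = FALSE)
  }
  prof <- 1 - d / L
  .neutralityResult("seq", "bp_distance", mean(prof), prof,
                    attr(mutantNeighbors(seq), "position"), 0L, NA_integer_)
}

#' Pearson-correlation neutrality of a sequence
#'
#' For each 1-mutant neighbour, the centroid of `n` sampled structures
#' is reduced to its 0/1 paired vector and correlated with the paired
#' vector of the reference.  The per-mutant term maps the correlation
#' `r` into `[0, 1]`; with the default `form = "adjusted"` the term is
#' `(1 + r) / 2` so that an identical centroid scores 1.  The literal
#' printed form `(1 - r) / 2` (which scores identity as 0) is exposed
#' via `form = "printed"` for comparison.  When either vector is
#' constant the correlation is undefined; the term is then 1 if the
#' vectors are equal and 0.5 (the no-information midpoint) otherwise.
#'
#' @inheritParams senNeutrality
#' @param form `"adjusted"` (default) or `"printed"`; see Details.
#' @return one-row data.frame as for [senNeutrality()].
#' @export
pccNeutrality <- function(seq, structure, engine = toyEngine(),
                          n = 1000L, seed = 1L,
                          form = c("adjusted", "printed"),
                          fastPath = TRUE) {
  form <- match.arg(form)
  seq <- .checkSeq(seq)
  stopifnot(nchar(seq) == structure@length)
  vref <- pairedVector(structure)
  if (fastPath && is(engine, "ToyFoldingEngine")) {
    cent <- .toy_centroid_profile(seq, as.integer(n), as.integer(seed))
  } else {
    muts <- mutantNeighbors(seq)
    cent <- t(vapply(seq_along(muts), function(r) {
      samp <- sampleStructures(engine, muts[r], n = n, seed = seed,
                               stream = .mutantStream(r))
      pairedVector(centroidStructure(samp))
    }, integer(nchar(seq))))
  }
  prof <- apply(cent, 1L, function(v) .pccTerm(vref, v, form))
  .neutralityResult("seq", "PCC", mean(prof), prof,
                    attr(mutantNeighbors(seq), "position"), n, seed)
}

.pccTerm <- function(vref, v, form) {
  if (stats::sd(vref) == 0 || stats::sd(v) == 0) {
    equal <- all(vref == v)
    if (form == "adjusted") return(if (equal) 1 else 0.5)
    return(if (equal) 0 else 0.5)
  }
  r <- stats::cor(vref, v)
  if (form == "adjusted") (1 + r) / 2 else (1 - r) / 2
}

#' Positional neutrality profile
#'
#' `SEN(i)`: the mean SEN distance over the three point mutants at
#' each position `i`.  Averaging the profile over positions recovers
#' the global SEN exactly (same samples, same substreams).
#'
#' @inheritParams senNeutrality
#' @return numeric vector of length `L` with the global SEN in
#'   `attr(, "global")`.
#' @export
positionalNeutrality <- function(seq, structure, engine = toyEngine(),
                                 n = 1000L, seed = 1L, fastPath = TRUE) {
  res <- senNeutrality(seq, structure, engine, n, seed, fastPath)
  prof <- attr(res, "per_mutant")
  pos <- attr(res, "position")
  out <- as.numeric(tapply(prof, pos, mean))
  attr(out, "global") <- res$value
  out
}

#' Neutrality of every sequence in a structured alignment
#'
#' The alignment workflow: for each row, (1) the sequence and the
#' consensus structure are simultaneously degapped and non-canonical
#' pairs are removed; (2) the 1-mutant neighbourhood is built; (3) the
#' requested metric is computed against the degapped reference.  Rows
#' containing ambiguity codes, or whose filtered reference has no base
#' pairs, are skipped with a recorded reason.
#'
#' @param alignment a [StructuredAlignment-class]; if its consensus is
#'   missing (`structureSource = "predicted"` with no structure yet)
#'   it is predicted with the engine first.
#' @param metric one of `"SEN"`, `"bp_distance"`, `"PCC"`.
#' @param engine a [FoldingEngine-class].
#' @param n,seed sampling parameters (per-row seeds are derived from
#'   `seed` and the row index).
#' @param pccForm PCC convention, see [pccNeutrality()].
#' @return data.frame with one row per alignment row: `sequence_id`,
#'   `metric`, `value`, `n_pairs`, `length`, `n_samples`, `seed`,
#'   `skipped`, `skip_reason`.
#' @export
alignmentNeutrality <- function(alignment,
                                metric = c("SEN", "bp_distance", "PCC"),
                                engine = toyEngine(), n = 1000L,
                                seed = 1L, pccForm = "adjusted") {
  metric <- match.arg(metric)
  stopifnot(is(alignment, "StructuredAlignment"))
  if (length(alignment) == 0L) stop("empty alignment")
  if (is.na(alignment@consensus))
    alignment <- predictConsensus(engine, alignment)
  consStruct <- parseDotBracket(alignment@consensus)
  rows <- lapply(seq_along(alignment@seqs), function(k) {
    id <- alignment@ids[k]
    rowSeed <- .rowSeed(seed, k)
    dg <- degapPair(alignment@seqs[k], consStruct)
    ns <- normalizeSequence(dg$seq)
    if (!ns$ok)
      return(.skipRow(id, metric, n, rowSeed, ns$reason))
    ref <- canonicalFilter(ns$seq, dg$structure)
    if (numPairs(ref) == 0L)
      return(.skipRow(id, metric, n, rowSeed,
                      "no canonical base pairs in reference"))
    res <- switch(metric,
      SEN = senNeutrality(ns$seq, ref, engine, n, rowSeed),
      bp_distance = bpDistanceNeutrality(ns$seq, ref, engine),
      PCC = pccNeutrality(ns$seq, ref, engine, n, rowSeed,
                          form = pccForm))
    data.frame(sequence_id = id, metric = metric, value = res$value,
               n_pairs = numPairs(ref), length = nchar(ns$seq),
               n_samples = res$n_samples, seed = res$seed,
               skipped = FALSE, skip_reason = NA_character_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

.rowSeed <- function(seed, row) {
  as.integer((as.numeric(seed) + 7919 * (row - 1)) %% 2147483647)
}

.skipRow <- function(id, metric, n, seed, reason) {
  warning("skipping sequence '", id, "': ", reason, call. = FALSE)
  data.frame(sequence_id = id, metric = metric, value = NA_real_,
             n_pairs = NA_integer_, length = NA_integer_,
             n_samples = n, seed = seed, skipped = TRUE,
             skip_reason = reason, stringsAsFactors = FALSE)
}
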