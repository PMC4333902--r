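#' Exact dinucleotide-preserving shuffle
#'
#' Altschul-Erickson Euler-path shuffle: the returned sequence starts
#' and ends with the same bases as the input and has exactly the same
#' multiset of dinucleotides (hence also the same mononucleotide
#' composition).  Deterministic under a fixed seed.
#'
#' @param seq gap-free sequence.
#' @param seed integer seed.
#' @return shuffled sequence.
#' @export
dinucleotideShuffle <- function(seq, seed = 1L) {
  seq <- .checkSeq(seq)
  chars <- strsplit(seq, "")[[1L]]
  n <- length(chars)
  if (n <= 2L || length(unique(chars)) == 1L) return(seq)
  withSeed(seed, .euler_shuffle(chars))
}

.euler_shuffle <- function(chars) {
  n <- length(chars)
  last <- chars[n]
  verts <- unique(chars)
  # outgoing edge targets per vertex
  edges <- split(chars[-1L], chars[-n])
  for (tries in seq_len(1000L)) {
    # pick a candidate terminal edge for every vertex except `last`
    lastEdge <- list()
    ok <- TRUE
    for (v in verts) {
      if (v == last) next
      outs <- edges[[v]]
      if (is.null(outs) || length(outs) == 0L) next
      lastEdge[[v]] <- outs[sample.int(length(outs), 1L)]
    }
    # arborescence check: following terminal edges must reach `last`
    for (v in names(lastEdge)) {
      cur <- v
      seen <- character(0)
      while (cur != last && !is.null(lastEdge[[cur]])) {
        if (cur %in% seen) break
        seen <- c(seen, cur)
        cur <- lastEdge[[cur]]
      }
      if (cur != last) {
        ok <- FALSE
        break
      }
    }
    if (ok) break
  }
  if (!ok) return(paste(chars, collapse = ""))  # degenerate graph
  # permute the non-terminal edges, append the terminal edge last
  ordered <- list()
  for (v in names(edges)) {
    outs <- edges[[v]]
    if (!is.null(lastEdge[[v]])) {
      drop <- match(lastEdge[[v]], outs)
      rest <- outs[-drop]
      if (length(rest) > 1L) rest <- rest[sample.int(length(rest))]
      ordered[[v]] <- c(rest, lastEdge[[v]])
    } else {
      if (length(outs) > 1L) outs <- outs[sample.int(length(outs))]
      ordered[[v]] <- outs
    }
  }
  # walk the Euler path
  ptr <- stats::setNames(rep(1L, length(ordered)), names(ordered))
  out <- character(n)
  out[1L] <- chars[1L]
  cur <- chars[1L]
  for (k in 2:n) {
    nxt <- ordered[[cur]][ptr[[cur]]]
    ptr[[cur]] <- ptr[[cur]] + 1L
    out[k] <- nxt
    cur <- nxt
  }
  paste(out, collapse = "")
}

#' Dinucleotide-shuffled decoy alignment
#'
#' The primary negative control: each row's degapped sequence is
#' replaced by an exact dinucleotide shuffle of itself and the bases
#' are written back into the row's original non-gap columns, so the
#' gap pattern is untouched.  The decoy's consensus structure is then
#' re-predicted with the engine (decoy alignments never inherit the
#' positive consensus).  `mode = "column"` instead permutes alignment
#' columns jointly across rows - an alternative decoy construction
#' that preserves per-column covariation but destroys dinucleotide
#' composition.
#'
#' @param alignment positive [StructuredAlignment-class].
#' @param engine engine used to re-predict the decoy consensus.
#' @param seed integer seed.
#' @param mode `"dinucleotide"` (default) or `"column"`.
#' @return decoy [StructuredAlignment-class]
#'   (`structureSource = "predicted"`).
#' @export
dinucleotideShuffleAlignment <- function(alignment, engine = toyEngine(),
                                         seed = 1L,
                                         mode = c("dinucleotide", "column")) {
  mode <- match.arg(mode)
  stopifnot(is(alignment, "StructuredAlignment"))
  seqs <- alignment@seqs
  if (mode == "dinucleotide") {
    seqs <- vapply(seq_along(seqs), function(k) {
      chars <- strsplit(seqs[k], "")[[1L]]
      keep <- !grepl(.GAP_RX, chars)
      degapped <- paste(chars[keep], collapse = "")
      ns <- normalizeSequence(degapped)
      if (!ns$ok) return(seqs[k])
      sh <- dinucleotideShuffle(ns$seq, seed = .rowSeed(seed, k))
      chars[keep] <- strsplit(sh, "")[[1L]]
      paste(chars, collapse = "")
    }, character(1))
  } else {
    w <- nchar(seqs[1L])
    perm <- withSeed(seed, sample.int(w))
    seqs <- vapply(seqs, function(s) {
      paste(strsplit(s, "")[[1L]][perm], collapse = "")
    }, character(1), USE.NAMES = FALSE)
  }
  decoy <- StructuredAlignment(stats::setNames(seqs, alignment@ids),
                               consensus = NA_character_,
                               structureSource = "predicted")
  predictConsensus(engine, decoy)
}

#' Synthetic structured alignment fixture
#'
#' Generates an alignment with the statistical structure the
#' neutrality method assumes: an ancestor sequence compatible with a
#' target structure (paired sites canonical, pair types drawn with
#' GC-biased weights), from which each row is derived by per-unit
#' substitution at `substitutionRate`.  With `covariation = TRUE` a
#' substitution hitting a paired site triggers the compensatory rule,
#' so every row remains structure compatible and paired columns
#' covary; with `covariation = FALSE` paired sites mutate freely.
#' The consensus is the target structure (`structureSource =
#' "given"`), playing the role of a curated seed alignment.
#'
#' @param structure target structure (dot-bracket string or
#'   [SecondaryStructure-class]).
#' @param nSeq number of rows (default 5).
#' @param substitutionRate per-unit (pair or unpaired site)
#'   substitution probability (default 0.15).
#' @param covariation compensate mutations at paired sites?
#' @param seed integer seed.
#' @param pairWeights sampling weights for ancestor pair types
#'   `GC, CG, AU, UA, GU, UG`.
#' @return a [StructuredAlignment-class] (gap free).
#' @export
syntheticStructuredAlignment <- function(structure, nSeq = 5L,
                                         substitutionRate = 0.15,
                                         covariation = TRUE, seed = 1L,
                                         pairWeights = c(0.3, 0.3, 0.15,
                                                         0.15, 0.05, 0.05)) {
  if (is.character(structure)) structure <- parseDotBracket(structure)
  stopifnot(substitutionRate >= 0, substitutionRate <= 1, nSeq >= 2L)
  L <- structure@length
  p <- structure@pairs
  withSeed(seed, {
    anc <- character(L)
    unpaired <- setdiff(seq_len(L), c(p))
    anc[unpaired] <- sample(c("A", "C", "G", "U"), length(unpaired),
                            replace = TRUE)
    if (nrow(p) > 0L) {
      pts <- sample(.PAIR_TYPES, nrow(p), replace = TRUE,
                    prob = pairWeights)
      anc[p[, 1L]] <- substr(pts, 1L, 1L)
      anc[p[, 2L]] <- substr(pts, 2L, 2L)
    }
    rows <- vapply(seq_len(nSeq), function(k) {
      chars <- anc
      # mutate unpaired sites
      for (i in unpaired) {
        if (stats::runif(1) < substitutionRate)
          chars[i] <- sample(setdiff(c("A", "C", "G", "U"), chars[i]), 1L)
      }
      # mutate pairs as units
      for (m in seq_len(nrow(p))) {
        if (stats::runif(1) < substitutionRate) {
          side <- sample(1:2, 1L)
          i <- p[m, side]
          j <- p[m, 3L - side]
          newBase <- sample(setdiff(c("A", "C", "G", "U"), chars[i]), 1L)
          chars[i] <- newBase
          if (covariation) chars[j] <- compensatoryPartner(newBase)
        }
      }
      paste(chars, collapse = "")
    }, character(1))
    StructuredAlignment(stats::setNames(rows, paste0("seq", seq_len(nSeq))),
                        consensus = dotBracket(structure),
                        structureSource = "given")
  })
}

#' Random subalignment
#'
#' Draws a uniform random subset of 3-6 rows (capped at the row
#' count), removes columns that become all-gap, dissolving consensus
#' pairs that involve a removed column, and - when the alignment's
#' structure is `"predicted"` and an engine is supplied - re-predicts
#' the consensus from the subset.
#'
#' @param alignment a [StructuredAlignment-class] with at least 3 rows.
#' @param seed integer seed.
#' @param engine optional engine for consensus re-prediction.
#' @return a [StructuredAlignment-class].
#' @export
subalignmentSample <- function(alignment, seed = 1L, engine = NULL) {
  stopifnot(is(alignment, "StructuredAlignment"))
  n <- length(alignment)
  if (n < 3L) stop("subalignment sampling needs at least 3 rows")
  withSeed(seed, {
    sizes <- 3:min(6L, n)
    k <- sizes[sample.int(length(sizes), 1L)]
    rows <- sort(sample.int(n, k))
  })
  sub <- alignmentRows(alignment, rows)
  # drop all-gap columns
  mat <- do.call(rbind, strsplit(sub@seqs, ""))
  allGap <- apply(matrix(grepl(.GAP_RX, mat), nrow = k), 2L, all)
  if (any(allGap)) {
    keep <- which(!allGap)
    seqs <- apply(mat[, keep, drop = FALSE], 1L, paste, collapse = "")
    cons <- sub@consensus
    if (!is.na(cons)) {
      cs <- parseDotBracket(cons)
      newIdx <- cumsum(!allGap)
      p <- cs@pairs
      if (nrow(p) > 0L) {
        ok <- !allGap[p[, 1L]] & !allGap[p[, 2L]]
        p <- cbind(newIdx[p[ok, 1L]], newIdx[p[ok, 2L]])
      }
      cons <- dotBracket(SecondaryStructure(p, length(keep)))
    }
    sub <- StructuredAlignment(stats::setNames(seqs, sub@ids),
                               consensus = cons,
                               structureSource = sub@structureSource)
  }
  if (identical(sub@structureSource, "predicted") && !is.null(engine))
    sub <- predictConsensus(engine, sub)
  sub
}

#' Alignment-quality effect on SEN
#'
#' `delta = SEN(full) - SEN(sub)` for the same underlying sequence,
#' with companion diagnostics when the two degapped, canonical-filtered
#' reference structures are supplied: their base-pair distance and the
#' pair-count ratio full/sub.
#'
#' @param fullResult,subResult one-row neutrality results (from
#'   [senNeutrality()] or rows of [alignmentNeutrality()]) for the
#'   same sequence id.
#' @param fullStructure,subStructure optional reference
#'   [SecondaryStructure-class] objects for the diagnostics.
#' @return one-row data.frame: `sequence_id`, `delta_sen`, and (when
#'   structures are given) `bp_distance`, `pair_ratio`.
#' @export
deltaSen <- function(fullResult, subResult, fullStructure = NULL,
                     subStructure = NULL) {
  if (!identical(fullResult$sequence_id, subResult$sequence_id))
    stop("results refer to different sequences")
  out <- data.frame(sequence_id = fullResult$sequence_id,
                    delta_sen = fullResult$value - subResult$value,
                    stringsAsFactors = FALSE)
  if (!is.null(fullStructure) && !is.null(subStructure)) {
    out$bp_distance <- bpDistance(fullStructure, subStructure)
    out$pair_ratio <- numPairs(fullStructure) /
      max(1L, numPairs(subStructure))
  }
  out
}

#' Designed neutral-plateau sequence
#'
#' A maximally neutral sequence for a structure under the toy model:
#' every pair is G-C with the orientation alternating along the pair
#' list (GC, CG, GC, ...), which locks the helix register - a
#' homopolymeric G/C stem would allow equally stable register-shifted
#' helices and dilute the ensemble - and every unpaired position is A,
#' which cannot pair in the absence of U.  Its 1-mutant neighbours
#' retain the target pairs in most of their ensembles, making it a
#' designed high-neutrality control for robustness experiments.
#'
#' @param structure target (dot-bracket string or
#'   [SecondaryStructure-class]).
#' @return sequence string.
#' @export
plateauSequence <- function(structure) {
  if (is.character(structure)) structure <- parseDotBracket(structure)
  chars <- rep("A", structure@length)
  p <- structure@pairs
  if (nrow(p) > 0L) {
    odd <- seq_len(nrow(p)) %% 2L == 1L
    chars[p[odd, 1L]] <- "G"
    chars[p[odd, 2L]] <- "C"
    chars[p[!odd, 1L]] <- "C"
    chars[p[!odd, 2L]] <- "G"
  }
  paste(chars, collapse = "")
}

#' Default benchmark structure
#'
#' The 60-nt two-hairpin target used by the synthetic separation
#' benchmark: two 9-bp stems with 4-nt loops, a 3-nt spacer and a
#' 13-nt single-stranded tail.
#'
#' @return dot-bracket string of length 60.
#' @export
defaultBenchmarkStructure <- function() {
  paste0("(((((((((....)))))))))", "...",
         "(((((((((....)))))))))", ".............")
}

#' Generate the synthetic separation benchmark
#'
#' `nAlign` structured fixture alignments (default: 60-nt two-hairpin
#' target, 5 rows, covariation on) and their dinucleotide-shuffled
#' decoys.
#'
#' @param nAlign number of structured/decoy pairs (default 30).
#' @param structure target structure for the fixtures.
#' @param nSeq,substitutionRate,covariation fixture parameters, see
#'   [syntheticStructuredAlignment()].
#' @param engine engine for decoy consensus prediction.
#' @param seed integer seed.
#' @return list with `structured` and `shuffled`, each a list of
#'   [StructuredAlignment-class] objects.
#' @export
generateBenchmark <- function(nAlign = 30L,
                              structure = defaultBenchmarkStructure(),
                              nSeq = 5L, substitutionRate = 0.15,
                              covariation = TRUE, engine = toyEngine(),
                              seed = 1L) {
  structured <- lapply(seq_len(nAlign), function(k) {
    syntheticStructuredAlignment(structure, nSeq = nSeq,
                                 substitutionRate = substitutionRate,
                                 covariation = covariation,
                                 seed = .rowSeed(seed, k))
  })
  shuffled <- lapply(seq_len(nAlign), function(k) {
    dinucleotideShuffleAlignment(structured[[k]], engine,
                                 seed = .rowSeed(seed, 10000L + k))
  })
  list(structured = structured, shuffled = shuffled)
}
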