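#' @importFrom methods show
NULL

# characters treated as gaps in aligned sequences / structures
.GAP_CHARS <- c("-", ".", "_", "~")
.GAP_RX <- "[-._~]"

#' Construct a SecondaryStructure from a pair list
#'
#' @param pairs two-column matrix (or empty) of 1-based `(i, j)` pairs.
#' @param length sequence length `L`.
#' @return a [SecondaryStructure-class].
#' @export
SecondaryStructure <- function(pairs, length) {
  if (is.null(pairs) || NROW(pairs) == 0L) {
    pairs <- matrix(integer(0), ncol = 2L)
  } else {
    pairs <- matrix(as.integer(pairs), ncol = 2L)
    flip <- pairs[, 1L] > pairs[, 2L]
    if (any(flip)) pairs[flip, ] <- pairs[flip, c(2L, 1L)]
    pairs <- pairs[order(pairs[, 1L]), , drop = FALSE]
  }
  colnames(pairs) <- c("i", "j")
  new("SecondaryStructure", pairs = pairs, length = as.integer(length))
}

#' Parse a dot-bracket (or WUSS) string into a SecondaryStructure
#'
#' Accepts plain dot-bracket as well as the WUSS dialect used in
#' Stockholm `SS_cons` lines: the four bracket classes `()`, `<>`,
#' `[]`, `{}` are matched independently; every other character
#' (including gap characters, commas and pseudoknot letters) is
#' treated as unpaired, since all metrics here are defined on nested
#' structures.
#'
#' @param db structure string.
#' @return a [SecondaryStructure-class] of the same length.
#' @export
parseDotBracket <- function(db) {
  stopifnot(is.character(db), length(db) == 1L)
  chars <- strsplit(db, "", fixed = TRUE)[[1L]]
  openers <- c("(" = 1L, "<" = 2L, "[" = 3L, "{" = 4L)
  closers <- c(")" = 1L, ">" = 2L, "]" = 3L, "}" = 4L)
  stacks <- vector("list", 4L)
  pairs <- list()
  for (pos in seq_along(chars)) {
    ch <- chars[pos]
    if (ch %in% names(openers)) {
      cls <- openers[[ch]]
      stacks[[cls]] <- c(stacks[[cls]], pos)
    } else if (ch %in% names(closers)) {
      cls <- closers[[ch]]
      if (length(stacks[[cls]]) == 0L)
        stop("unbalanced structure string: unmatched '", ch,
             "' at position ", pos)
      i <- stacks[[cls]][length(stacks[[cls]])]
      stacks[[cls]] <- stacks[[cls]][-length(stacks[[cls]])]
      pairs[[length(pairs) + 1L]] <- c(i, pos)
    }
  }
  for (cls in 1:4) {
    if (length(stacks[[cls]]) > 0L)
      stop("unbalanced structure string: unmatched '",
           names(openers)[cls], "' at position ",
           stacks[[cls]][length(stacks[[cls]])])
  }
  SecondaryStructure(do.call(rbind, pairs), length(chars))
}

#' @rdname dotBracket
#' @export
setMethod("dotBracket", "SecondaryStructure", function(x) {
  out <- rep(".", x@length)
  p <- x@pairs
  if (nrow(p) > 0L) {
    out[p[, 1L]] <- "("
    out[p[, 2L]] <- ")"
  }
  paste(out, collapse = "")
})

#' @rdname numPairs
#' @export
setMethod("numPairs", "SecondaryStructure", function(x) nrow(x@pairs))

#' @rdname adjacencyMatrix
#' @export
setMethod("adjacencyMatrix", "SecondaryStructure", function(x) {
  M <- matrix(0L, x@length, x@length)
  p <- x@pairs
  if (nrow(p) > 0L) {
    M[p] <- 1L
    M[p[, c(2L, 1L), drop = FALSE]] <- 1L
  }
  M
})

#' @rdname adjacencyMatrix
#' @export
setMethod("pairedVector", "SecondaryStructure", function(x) {
  v <- integer(x@length)
  v[c(x@pairs)] <- 1L
  v
})

#' Pair table accessor
#' @param x a [SecondaryStructure-class].
#' @return two-column integer matrix of 1-based pairs.
#' @export
structurePairs <- function(x) x@pairs

setMethod("show", "SecondaryStructure", function(object) {
  cat(sprintf("SecondaryStructure: L = %d, %d base pair(s)\n",
              object@length, nrow(object@pairs)))
  if (object@length <= 120L) cat(" ", dotBracket(object), "\n")
})

#' Normalise an RNA sequence
#'
#' Upper-cases, converts `T` to `U`, and reports whether the result is
#' a valid gap-free `ACGU` sequence.  Sequences containing ambiguity
#' codes are flagged rather than guessed: neutrality over the 3L
#' defined point mutants is ill-posed for ambiguous bases.
#'
#' @param seq character sequence (possibly lower-case / DNA alphabet).
#' @return list with `seq` (normalised), `ok` (logical) and `reason`.
#' @export
normalizeSequence <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  s <- chartr("tT", "uU", seq)
  s <- toupper(s)
  if (nchar(s) == 0L)
    return(list(seq = s, ok = FALSE, reason = "empty sequence"))
  if (grepl(.GAP_RX, s))
    return(list(seq = s, ok = FALSE, reason = "contains gap characters"))
  bad <- regmatches(s, regexpr("[^ACGU]", s))
  if (length(bad) > 0L)
    return(list(seq = s, ok = FALSE,
                reason = paste0("ambiguity code '", bad, "'")))
  list(seq = s, ok = TRUE, reason = NA_character_)
}

#' Degap a sequence/structure pair drawn from an alignment
#'
#' Simultaneously removes the columns where the aligned sequence has a
#' gap from both the sequence and the aligned structure.  A pair whose
#' partner column is deleted becomes unpaired, and a pair whose
#' degapped span falls below the minimum hairpin loop (fewer than 3
#' enclosed bases) is dissolved, since such a pair is physically
#' impossible in the gap-free sequence.
#'
#' @param alignedSeq aligned sequence with gaps.
#' @param alignedStructure aligned structure string (dot-bracket/WUSS)
#'   or a [SecondaryStructure-class] in column coordinates.
#' @return list with `seq` (gap-free, normalised but possibly holding
#'   ambiguity codes) and `structure` ([SecondaryStructure-class] in
#'   gap-free coordinates).
#' @export
degapPair <- function(alignedSeq, alignedStructure) {
  stopifnot(is.character(alignedSeq), length(alignedSeq) == 1L)
  if (is.character(alignedStructure)) {
    if (nchar(alignedSeq) != nchar(alignedStructure))
      stop("aligned sequence and structure have different lengths")
    alignedStructure <- parseDotBracket(alignedStructure)
  }
  if (alignedStructure@length != nchar(alignedSeq))
    stop("aligned sequence and structure have different lengths")
  chars <- strsplit(chartr("tT", "uU", toupper(alignedSeq)), "")[[1L]]
  keep <- !grepl(.GAP_RX, chars)
  newIndex <- cumsum(keep)       # column -> degapped position
  p <- alignedStructure@pairs
  if (nrow(p) > 0L) {
    ok <- keep[p[, 1L]] & keep[p[, 2L]]
    p <- p[ok, , drop = FALSE]
    p <- cbind(newIndex[p[, 1L]], newIndex[p[, 2L]])
    if (nrow(p) > 0L) p <- p[p[, 2L] - p[, 1L] >= 4L, , drop = FALSE]
  }
  list(seq = paste(chars[keep], collapse = ""),
       structure = SecondaryStructure(p, sum(keep)))
}

#' Remove non-canonical pairs from a structure
#'
#' Pairs that are not Watson-Crick or G-U wobble are considered
#' single-stranded.  Idempotent.
#'
#' @param seq gap-free sequence the structure annotates.
#' @param structure a [SecondaryStructure-class].
#' @return filtered [SecondaryStructure-class].
#' @export
canonicalFilter <- function(seq, structure) {
  stopifnot(is(structure, "SecondaryStructure"))
  if (nchar(seq) != structure@length)
    stop("sequence length does not match structure length")
  p <- structure@pairs
  if (nrow(p) == 0L) return(structure)
  chars <- strsplit(seq, "")[[1L]]
  canon <- c("AU", "UA", "GC", "CG", "GU", "UG")
  keep <- paste0(chars[p[, 1L]], chars[p[, 2L]]) %in% canon
  SecondaryStructure(p[keep, , drop = FALSE], structure@length)
}

#' Base-pair distance between two structures
#'
#' Size of the symmetric difference of the two pair sets.
#'
#' @param a,b [SecondaryStructure-class] objects of equal length.
#' @return integer distance.
#' @export
bpDistance <- function(a, b) {
  stopifnot(is(a, "SecondaryStructure"), is(b, "SecondaryStructure"))
  key <- function(x) {
    p <- x@pairs
    if (nrow(p) == 0L) return(character(0))
    paste(p[, 1L], p[, 2L])
  }
  ka <- key(a)
  kb <- key(b)
  length(setdiff(ka, kb)) + length(setdiff(kb, ka))
}

#' Construct a StructuredAlignment
#'
#' @param seqs aligned sequences (with gaps); names are used as ids
#'   when `ids` is missing.
#' @param consensus aligned consensus structure string (or `NA` when
#'   the structure is to be predicted later).
#' @param ids sequence identifiers.
#' @param structureSource `"given"` or `"predicted"`.
#' @return a [StructuredAlignment-class].
#' @export
StructuredAlignment <- function(seqs, consensus = NA_character_,
                                ids = names(seqs),
                                structureSource = c("given", "predicted")) {
  structureSource <- match.arg(structureSource)
  if (length(seqs) == 0L) stop("alignment must have at least one row")
  if (is.null(ids)) ids <- paste0("seq", seq_along(seqs))
  seqs <- toupper(chartr("tT", "uU", unname(seqs)))
  new("StructuredAlignment", ids = ids, seqs = seqs,
      consensus = consensus, structureSource = structureSource)
}

#' @describeIn StructuredAlignment number of rows.
#' @param x a StructuredAlignment.
#' @export
setMethod("length", "StructuredAlignment", function(x) length(x@seqs))

#' Accessors for StructuredAlignment
#'
#' `alignedSequences` returns the named character vector of aligned
#' rows; `consensus` the aligned consensus structure string;
#' `alignmentWidth` the number of columns.
#'
#' @param x a [StructuredAlignment-class].
#' @name alignment-accessors
#' @export
alignedSequences <- function(x) stats::setNames(x@seqs, x@ids)

#' @rdname alignment-accessors
#' @export
consensus <- function(x) x@consensus

#' @rdname alignment-accessors
#' @export
alignmentWidth <- function(x) nchar(x@seqs[1L])

#' @rdname alignment-accessors
#' @export
structureSource <- function(x) x@structureSource

setMethod("show", "StructuredAlignment", function(object) {
  cat(sprintf("StructuredAlignment: %d row(s) x %d column(s), structure %s\n",
              length(object@seqs), nchar(object@seqs[1L]),
              object@structureSource))
  if (!is.na(object@consensus) && nchar(object@consensus) <= 100L)
    cat("  SS_cons:", object@consensus, "\n")
})

#' Subset alignment rows
#' @param x a [StructuredAlignment-class].
#' @param i row indices.
#' @export
alignmentRows <- function(x, i) {
  new("StructuredAlignment", ids = x@ids[i], seqs = x@seqs[i],
      consensus = x@consensus, structureSource = x@structureSource)
}
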