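#' @importFrom methods new is validObject setClass setValidity slot
NULL

#' SecondaryStructure: a nested set of RNA base pairs
#'
#' Represents a pseudoknot-free secondary structure on a sequence of
#' length `L` as a set of `(i, j)` index pairs with `i < j`, 1-based.
#' Each position participates in at most one pair.  The minimum hairpin
#' loop of 3 unpaired bases is enforced on structures produced by the
#' folding engines; structures taken from alignment annotation are
#' accepted as given (degapping dissolves any pair it shortens below
#' the loop limit).
#'
#' @slot pairs integer matrix with two columns (`i`, `j`), one row per
#'   base pair, `i < j`.
#' @slot length total sequence length `L`.
#' @export
setClass("SecondaryStructure",
  representation(pairs = "matrix", length = "integer"))

setValidity("SecondaryStructure", function(object) {
  p <- object@pairs
  L <- object@length
  if (length(L) != 1L || is.na(L) || L < 0L)
    return("length must be a single non-negative integer")
  if (!is.numeric(p) || ncol(p) != 2L)
    return("pairs must be a two-column integer matrix")
  if (nrow(p) == 0L) return(TRUE)
  if (any(p < 1L) || any(p > L)) return("pair indices out of bounds")
  if (any(p[, 1L] >= p[, 2L])) return("pairs must satisfy i < j")
  if (anyDuplicated(c(p[, 1L], p[, 2L])))
    return("a position may participate in at most one pair")
  TRUE
})

#' StructuredAlignment: aligned RNA sequences with a consensus structure
#'
#' A multiple sequence alignment together with an aligned consensus
#' secondary-structure string (plain dot-bracket over alignment
#' columns).  The consensus is either taken as given (e.g. an Rfam seed
#' `SS_cons` line) or predicted by a folding engine.
#'
#' @slot ids sequence identifiers, one per row.
#' @slot seqs aligned sequences (upper-case, `U` alphabet, `-` gaps).
#' @slot consensus aligned consensus structure string (dot-bracket).
#' @slot structureSource `"given"` or `"predicted"`.
#' @export
setClass("StructuredAlignment",
  representation(ids = "character", seqs = "character",
                 consensus = "character", structureSource = "character"))

setValidity("StructuredAlignment", function(object) {
  if (length(object@ids) != length(object@seqs))
    return("ids and seqs must have equal length")
  if (length(object@seqs) < 1L) return("alignment must have at least one row")
  w <- unique(nchar(object@seqs))
  if (length(w) != 1L) return("ragged alignment rows")
  if (length(object@consensus) != 1L)
    return("consensus must be a single string")
  if (!is.na(object@consensus) && nchar(object@consensus) != w)
    return("consensus length must equal the aligned width")
  if (!object@structureSource %in% c("given", "predicted"))
    return("structureSource must be 'given' or 'predicted'")
  TRUE
})

#' FoldingEngine: pluggable thermodynamic backend
#'
#' Virtual parent of the folding backends.  An engine provides (a
#' subset of) minimum-free-energy folding, seedable Boltzmann sampling,
#' exact base-pair probabilities, consensus folding of an alignment,
#' and inverse folding.  Identical `(engine, seed, input)` triples give
#' identical sampling output.
#'
#' @slot name engine identifier used in provenance records.
#' @slot temperature folding temperature in degrees Celsius (only
#'   meaningful for physical backends; 37 by default).
#' @export
setClass("FoldingEngine",
  representation("VIRTUAL", name = "character", temperature = "numeric"))

#' Toy folding engine class
#'
#' Self-contained exactly-enumerable model: per-pair energies GC/CG
#' -3, AU/UA -2, GU/UG -1 (model units), hairpin loop >= 3, kT = 1.
#' Construct with [toyEngine()].
#' @export
setClass("ToyFoldingEngine", contains = "FoldingEngine")

#' ViennaRNA folding engine class
#'
#' Adapter over the ViennaRNA command-line suite (RNAfold, RNAsubopt,
#' RNAalifold, RNAeval, RNAinverse).  Construct with [viennaEngine()].
#'
#' @slot binaries named character vector of resolved tool paths.
#' @slot version reported ViennaRNA version string.
#' @export
setClass("ViennaFoldingEngine", contains = "FoldingEngine",
  representation(binaries = "character", version = "character"))

#' EnsembleSample: structures drawn from a Boltzmann ensemble
#'
#' `n` secondary structures drawn with replacement from the ensemble of
#' `sequence`, stored as dot-bracket strings.
#'
#' @slot sequence the source sequence.
#' @slot structures character vector of `n` dot-bracket strings.
#' @slot n number of draws.
#' @slot seed,stream RNG coordinates used for the draw (for provenance).
#' @export
setClass("EnsembleSample",
  representation(sequence = "character", structures = "character",
                 n = "integer", seed = "integer", stream = "integer"))

setValidity("EnsembleSample", function(object) {
  if (length(object@structures) != object@n)
    return("number of structures must equal n")
  if (any(nchar(object@structures) != nchar(object@sequence)))
    return("every structure must match the sequence length")
  TRUE
})
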