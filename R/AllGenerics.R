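#' @importFrom methods setGeneric setMethod
NULL

#' Minimum free energy structure of a sequence
#'
#' @param engine a [FoldingEngine-class] object.
#' @param seq gap-free RNA sequence (character, `ACGU`).
#' @return a [SecondaryStructure-class] with an `energy` attribute.
#' @export
setGeneric("mfeStructure", function(engine, seq) standardGeneric("mfeStructure"))

#' Draw structures from the Boltzmann ensemble
#'
#' Samples `n` secondary structures with replacement according to
#' their equilibrium probability.  Sampling is seed-reproducible; the
#' `stream` argument selects an independent substream for the same
#' seed (used to give every 1-mutant neighbour its own stream so that
#' results do not depend on evaluation order).
#'
#' @inheritParams mfeStructure
#' @param n number of structures to draw (default 1000).
#' @param seed integer seed.
#' @param stream integer substream index (default 0).
#' @return an [EnsembleSample-class].
#' @export
setGeneric("sampleStructures",
  function(engine, seq, n = 1000L, seed = 1L, stream = 0L)
    standardGeneric("sampleStructures"))

#' Exact base-pair probability matrix
#'
#' @inheritParams mfeStructure
#' @return symmetric `L x L` matrix of equilibrium pair probabilities.
#' @export
setGeneric("basePairProbs", function(engine, seq) standardGeneric("basePairProbs"))

#' Predict an aligned consensus structure
#'
#' Folds an alignment into a consensus structure over alignment
#' columns (RNAalifold for the Vienna engine; an alifold-style column
#' DP for the toy engine).  Used for alignments whose structure is
#' `"predicted"` and for all decoy alignments.
#'
#' @inheritParams mfeStructure
#' @param alignment a [StructuredAlignment-class] with at least 2 rows.
#' @return the input alignment with `consensus` replaced by the
#'   prediction, `structureSource = "predicted"`, and a
#'   `consensusEnergy` attribute.
#' @export
setGeneric("predictConsensus",
  function(engine, alignment) standardGeneric("predictConsensus"))

#' Inverse folding: find a sequence for a target structure
#'
#' Searches sequence space for a sequence whose MFE structure
#' approximates the target (an adaptive walk minimising base-pair
#' distance to the target; the match is not forced to be exact).
#'
#' @inheritParams mfeStructure
#' @param structure target [SecondaryStructure-class].
#' @param seed integer seed.
#' @param restarts,stepsPerRestart attempt budget (default 50 restarts
#'   of `10 * L` steps).
#' @param startComposition optional base-frequency vector (named
#'   `A`,`C`,`G`,`U`) used to draw unpaired bases and pick pair types
#'   in the random start sequences; defaults to uniform.
#' @return list with `sequence`, `distance` (base-pair distance of its
#'   MFE structure to the target) and `mfe` (the achieved structure).
#' @export
setGeneric("inverseFold",
  function(engine, structure, seed = 1L, restarts = 50L,
           stepsPerRestart = NULL, startComposition = NULL)
    standardGeneric("inverseFold"))

#' Evaluate the energy of a structure on a sequence
#'
#' Non-canonical pairs contribute nothing (they are treated as
#' unpaired, mirroring the alignment workflow).
#'
#' @inheritParams mfeStructure
#' @param structure a [SecondaryStructure-class].
#' @return energy (model units for the toy engine, kcal/mol for Vienna).
#' @export
setGeneric("structureEnergy",
  function(engine, seq, structure) standardGeneric("structureEnergy"))

#' Capabilities of a folding engine
#'
#' @inheritParams mfeStructure
#' @return character vector drawn from
#'   `c("mfe", "sample", "exact_bpp", "consensus", "inverse")`.
#' @export
setGeneric("engineCapabilities",
  function(engine) standardGeneric("engineCapabilities"))

#' Dot-bracket serialisation of a structure
#'
#' @param x a [SecondaryStructure-class].
#' @return dot-bracket string of length `L`.
#' @export
setGeneric("dotBracket", function(x) standardGeneric("dotBracket"))

#' Structure projections: adjacency matrix and paired vector
#'
#' `adjacencyMatrix` returns the symmetric `L x L` 0/1 matrix with
#' `M[i, j] = 1` iff `i` and `j` pair; `pairedVector` returns the
#' length-`L` 0/1 vector marking paired positions, so
#' `sum(pairedVector(x)) == 2 * numPairs(x)`.
#'
#' @param x a [SecondaryStructure-class].
#' @return `adjacencyMatrix`: integer matrix; `pairedVector`: integer
#'   vector.
#' @export
setGeneric("adjacencyMatrix", function(x) standardGeneric("adjacencyMatrix"))

#' @rdname adjacencyMatrix
#' @export
setGeneric("pairedVector", function(x) standardGeneric("pairedVector"))

#' Number of base pairs in a structure
#' @param x a [SecondaryStructure-class].
#' @export
setGeneric("numPairs", function(x) standardGeneric("numPairs"))
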