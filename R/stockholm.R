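#' Read a Stockholm alignment with consensus structure
#'
#' Minimal Stockholm 1.0 reader sufficient for Rfam-style seed
#' alignments: per-row sequences (possibly wrapped over several
#' blocks) and the `#=GC SS_cons` consensus line.  WUSS annotation is
#' kept verbatim in the `consensus` slot; [parseDotBracket()] maps it
#' to nested pairs (non-nested WUSS symbols are treated as unpaired).
#'
#' @param path file path.
#' @param structureSource `"given"` requires an `SS_cons` line;
#'   `"predicted"` tolerates its absence (the consensus is filled in
#'   later by [predictConsensus()]).
#' @return a [StructuredAlignment-class].
#' @export
readStockholm <- function(path, structureSource = c("given", "predicted")) {
  structureSource <- match.arg(structureSource)
  lines <- readLines(path, warn = FALSE)
  seqs <- character(0)
  ss <- character(0)
  for (ln in lines) {
    if (grepl("^\\s*$", ln) || ln == "//") next
    if (startsWith(ln, "#")) {
      if (grepl("^#=GC\\s+SS_cons\\s", ln)) {
        ss <- c(ss, sub("^#=GC\\s+SS_cons\\s+", "", ln))
      }
      next
    }
    m <- regmatches(ln, regexec("^(\\S+)\\s+(\\S+)\\s*$", ln))[[1L]]
    if (length(m) != 3L)
      stop("malformed Stockholm sequence line: ", ln)
    id <- m[2L]
    if (id %in% names(seqs)) {
      seqs[[id]] <- paste0(seqs[[id]], m[3L])
    } else {
      seqs[[id]] <- m[3L]
    }
  }
  if (length(seqs) == 0L) stop("no sequences found in ", path)
  if (length(unique(nchar(seqs))) != 1L)
    stop("ragged rows in Stockholm file ", path)
  cons <- if (length(ss) > 0L) paste(ss, collapse = "") else NA_character_
  if (is.na(cons) && structureSource == "given")
    stop("no #=GC SS_cons line in ", path,
         " but structureSource = 'given'")
  if (!is.na(cons) && nchar(cons) != nchar(seqs[[1L]]))
    stop("SS_cons length does not match alignment width in ", path)
  StructuredAlignment(seqs, consensus = cons,
                      structureSource = structureSource)
}

#' Read plain RNA sequences from a FASTA file
#'
#' Thin wrapper over [Biostrings][Biostrings::readRNAStringSet] for
#' single-sequence inputs (e.g. sequences to test for robustness
#' against a user-supplied structure).  DNA alphabets are converted;
#' sequences failing [normalizeSequence()] are dropped with a warning.
#'
#' @param path FASTA file path.
#' @return named character vector of normalised `ACGU` sequences.
#' @export
readFastaSequences <- function(path) {
  if (!requireNamespace("Biostrings", quietly = TRUE))
    stop("readFastaSequences() needs the Biostrings package")
  set <- Biostrings::readBStringSet(path)
  seqs <- stats::setNames(as.character(set), names(set))
  norm <- lapply(seqs, normalizeSequence)
  ok <- vapply(norm, `[[`, logical(1), "ok")
  if (any(!ok))
    warning("dropping ", sum(!ok), " sequence(s): ",
            paste(unique(vapply(norm[!ok], `[[`, character(1), "reason")),
                  collapse = "; "))
  vapply(norm[ok], `[[`, character(1), "seq")
}

#' Write a Stockholm alignment
#'
#' Single-block Stockholm 1.0 with an `SS_cons` line when the
#' alignment has a consensus.  `comments` are written as `#=GF CC`
#' records (used to record decoy provenance).
#'
#' @param alignment a [StructuredAlignment-class].
#' @param path output file path.
#' @param comments optional character vector of free-text comments.
#' @return `path`, invisibly.
#' @export
writeStockholm <- function(alignment, path, comments = NULL) {
  stopifnot(is(alignment, "StructuredAlignment"))
  ids <- alignment@ids
  width <- max(nchar(c(ids, "#=GC SS_cons")))
  out <- c("# STOCKHOLM 1.0")
  if (!is.null(comments))
    out <- c(out, paste("#=GF CC", comments))
  out <- c(out, sprintf("%-*s %s", width, ids, alignment@seqs))
  if (!is.na(alignment@consensus))
    out <- c(out, sprintf("%-*s %s", width, "#=GC SS_cons",
                          alignment@consensus))
  out <- c(out, "//")
  writeLines(out, path)
  invisible(path)
}
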