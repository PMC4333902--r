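# Independent exhaustive-enumeration oracle for the toy energy model.
# Written against the model definition only (per-pair energies GC/CG
# -3, AU/UA -2, GU/UG -1, hairpin loop >= 3, kT = 1); deliberately
# shares no code with the engine.

oracle_pair_energy <- function(a, b) {
  key <- paste0(a, b)
  if (key %in% c("GC", "CG")) return(-3)
  if (key %in% c("AU", "UA")) return(-2)
  if (key %in% c("GU", "UG")) return(-1)
  NA_real_
}

# all nested structures (lists of pair matrices) on seq, recursively:
# position i is unpaired, or paired with an admissible k
oracle_enumerate <- function(seq) {
  chars <- strsplit(seq, "")[[1L]]
  memo <- new.env()
  rec <- function(i, j) {
    if (i >= j) return(list(matrix(integer(0), ncol = 2)))
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    out <- lapply(rec(i + 1, j), identity)
    ks <- if (j >= i + 4) seq(i + 4, j) else integer(0)
    for (k in ks) {
      if (is.na(oracle_pair_energy(chars[i], chars[k]))) next
      inner <- rec(i + 1, k - 1)
      outer <- rec(k + 1, j)
      for (a in inner) for (b in outer)
        out[[length(out) + 1L]] <- rbind(c(i, k), a, b)
    }
    memo[[key]] <- out
    out
  }
  rec(1L, length(chars))
}

oracle_energy <- function(seq, pairs) {
  if (nrow(pairs) == 0L) return(0)
  chars <- strsplit(seq, "")[[1L]]
  sum(vapply(seq_len(nrow(pairs)), function(m) {
    oracle_pair_energy(chars[pairs[m, 1L]], chars[pairs[m, 2L]])
  }, numeric(1)))
}

oracle_db <- function(pairs, L) {
  v <- rep(".", L)
  if (nrow(pairs) > 0L) {
    v[pairs[, 1L]] <- "("
    v[pairs[, 2L]] <- ")"
  }
  paste(v, collapse = "")
}

# full ensemble table: structure strings, energies, Boltzmann probs
oracle_ensemble <- function(seq) {
  structs <- oracle_enumerate(seq)
  L <- nchar(seq)
  e <- vapply(structs, function(p) oracle_energy(seq, p), numeric(1))
  w <- exp(-e)
  data.frame(db = vapply(structs, oracle_db, character(1), L = L),
             energy = e, prob = w / sum(w), stringsAsFactors = FALSE)
}

oracle_mfe_energy <- function(seq) min(oracle_ensemble(seq)$energy)

# exact pair probability matrix by enumeration
oracle_bpp <- function(seq) {
  L <- nchar(seq)
  structs <- oracle_enumerate(seq)
  e <- vapply(structs, function(p) oracle_energy(seq, p), numeric(1))
  w <- exp(-e)
  w <- w / sum(w)
  P <- matrix(0, L, L)
  for (s in seq_along(structs)) {
    p <- structs[[s]]
    if (nrow(p) > 0L) {
      P[p] <- P[p] + w[s]
      P[p[, c(2, 1), drop = FALSE]] <- P[p[, c(2, 1), drop = FALSE]] + w[s]
    }
  }
  P
}

random_rna <- function(L) {
  paste(sample(c("A", "C", "G", "U"), L, replace = TRUE), collapse = "")
}

# majority-rule consensus oracle: fold each degapped row with the
# engine, map pairs to columns, keep pairs present in > half the rows
oracle_majority_consensus <- function(alignment, engine) {
  seqs <- alignedSequences(alignment)
  w <- alignmentWidth(alignment)
  counts <- matrix(0, w, w)
  for (s in seqs) {
    chars <- strsplit(s, "")[[1L]]
    keep <- !grepl("[-._~]", chars)
    cols <- which(keep)
    mfe <- mfeStructure(engine, paste(chars[keep], collapse = ""))
    p <- structurePairs(mfe)
    if (nrow(p) > 0L) {
      cp <- cbind(cols[p[, 1L]], cols[p[, 2L]])
      counts[cp] <- counts[cp] + 1
    }
  }
  idx <- which(counts > length(seqs) / 2, arr.ind = TRUE)
  SecondaryStructure(idx, w)
}
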