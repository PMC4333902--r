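#' Mononucleotide composition of a sequence
#'
#' @param seq gap-free `ACGU` sequence.
#' @return named probability vector over `A`, `C`, `G`, `U`.
#' @export
nucleotideComposition <- function(seq) {
  chars <- strsplit(.checkSeq(seq), "")[[1L]]
  tab <- table(factor(chars, levels = c("A", "C", "G", "U")))
  stats::setNames(as.numeric(tab) / length(chars), c("A", "C", "G", "U"))
}

#' Jensen-Shannon divergence between base compositions
#'
#' Symmetric, log base 2, bounded in `[0, 1]`; 0 iff the compositions
#' are equal.  Used to composition-match background sequences to the
#' wild type (threshold 0.01).
#'
#' @param p,q probability distributions over `A`, `C`, `G`, `U`.
#' @return divergence in bits.
#' @export
jsDivergence <- function(p, q) {
  if (abs(sum(p) - 1) > 1e-8 || abs(sum(q) - 1) > 1e-8)
    stop("inputs must be normalised probability distributions")
  if (any(p < 0) || any(q < 0)) stop("negative probabilities")
  m <- (p + q) / 2
  kl <- function(a, b) {
    nz <- a > 0
    sum(a[nz] * log2(a[nz] / b[nz]))
  }
  (kl(p, m) + kl(q, m)) / 2
}

#' Neutral random walk in sequence space
#'
#' Attempts exactly `4L` mutation steps starting from `start`.  Each
#' proposal mutates one random position to a random alternative base;
#' if the position is paired in the reference structure `structure`,
#' the partner receives a compensatory mutation restoring a canonical
#' pair (see [compensatoryPartner()]).  A proposal is accepted only if
#' the structure does not change - by default the candidate's MFE
#' structure must equal the MFE structure of the current sequence
#' (`reference = "mfe"`); `reference = "target"` compares against
#' `structure` instead.  An optional composition guard rejects
#' proposals whose Jensen-Shannon divergence from `compositionRef`
#' would reach `jsdMax`.
#'
#' @param start starting sequence.
#' @param structure [SecondaryStructure-class] giving the pairing used
#'   for compensatory mutations (and the acceptance target when
#'   `reference = "target"`).
#' @param engine a [FoldingEngine-class].
#' @param seed integer seed.
#' @param reference `"mfe"` (default) or `"target"`.
#' @param compositionRef optional composition vector to guard against
#'   (typically the wild type's); `NULL` disables the guard.
#' @param jsdMax guard threshold (default 0.01).
#' @return the final sequence (possibly equal to `start`), with the
#'   number of accepted steps in `attr(, "accepted")`.
#' @export
neutralWalk <- function(start, structure, engine = toyEngine(),
                        seed = 1L, reference = c("mfe", "target"),
                        compositionRef = NULL, jsdMax = 0.01) {
  reference <- match.arg(reference)
  start <- .checkSeq(start)
  L <- nchar(start)
  stopifnot(structure@length == L)
  refStruct <- if (reference == "target") structure else
    mfeStructure(engine, start)
  # acceptance keeps the MFE structure fixed at refStruct for the
  # "target" reading, and at the current sequence's MFE for the "mfe"
  # reading - where an accepted step by definition leaves the MFE
  # unchanged, so refStruct stays valid throughout either way
  refPairs <- refStruct@pairs
  structOk <- if (is(engine, "ToyFoldingEngine")) {
    function(s) .toy_mfe_bpdist(s, refPairs[, 1L], refPairs[, 2L]) == 0L
  } else {
    function(s) bpDistance(mfeStructure(engine, s), refStruct) == 0L
  }
  withSeed(seed, {
    cur <- start
    accepted <- 0L
    attempted <- 0L
    for (step in seq_len(4L * L)) {
      attempted <- attempted + 1L
      cand <- .mutateCompatible(cur, structure)
      if (!is.null(compositionRef) &&
          jsDivergence(nucleotideComposition(cand), compositionRef) >= jsdMax)
        next
      if (structOk(cand)) {
        cur <- cand
        accepted <- accepted + 1L
      }
    }
    attr(cur, "accepted") <- accepted
    attr(cur, "attempted") <- attempted
    cur
  })
}

#' Background set of composition-matched structure-mates
#'
#' Builds the null ensemble against which robustness is judged: 10
#' inverse-folded sequences for the target structure, each seeding 10
#' neutral random walks, giving up to 100 background members.  Every
#' seed must pass the Jensen-Shannon composition filter (`jsd < 0.01`
#' against the wild type); seeds failing the filter are regenerated up
#' to `attemptBudget` times, and the walks carry the same composition
#' guard, so every final member passes the filter.  If no valid
#' inverse-folded seed can be made the sequence is omitted (an
#' explicit omission marker is returned).
#'
#' @param seq wild-type sequence.
#' @param structure target [SecondaryStructure-class].
#' @param engine a [FoldingEngine-class].
#' @param seed integer seed.
#' @param nSeeds,walksPerSeed background design (10 x 10 by default).
#' @param jsdMax composition threshold (0.01).
#' @param attemptBudget inverse-fold regeneration budget per seed.
#' @param walkReference acceptance reference for the neutral walks,
#'   see [neutralWalk()].
#' @return list with `members` (character vector), `seeds` (the
#'   inverse-fold seeds), `omitted` (logical) and `reason`.
#' @export
backgroundSet <- function(seq, structure, engine = toyEngine(),
                          seed = 1L, nSeeds = 10L, walksPerSeed = 10L,
                          jsdMax = 0.01, attemptBudget = 100L,
                          walkReference = c("mfe", "target")) {
  walkReference <- match.arg(walkReference)
  seq <- .checkSeq(seq)
  comp <- nucleotideComposition(seq)
  seeds <- character(0)
  attempt <- 0L
  while (length(seeds) < nSeeds && attempt < attemptBudget) {
    attempt <- attempt + 1L
    inv <- inverseFold(engine, structure,
                       seed = .rowSeed(seed, attempt),
                       startComposition = comp)
    if (is.null(inv$sequence)) next
    cand <- .compositionRepair(engine, inv$sequence, structure, comp,
                               jsdMax, seed = .rowSeed(seed, 90000L + attempt))
    if (jsDivergence(nucleotideComposition(cand), comp) < jsdMax)
      seeds <- c(seeds, cand)
  }
  if (length(seeds) == 0L)
    return(list(members = character(0), seeds = character(0),
                omitted = TRUE,
                reason = "no inverse-folded sequence passed the composition filter"))
  members <- character(0)
  for (si in seq_along(seeds)) {
    for (w in seq_len(walksPerSeed)) {
      walkSeed <- .rowSeed(seed, 1000L + si * 100L + w)
      member <- neutralWalk(seeds[si], structure, engine,
                            seed = walkSeed, reference = walkReference,
                            compositionRef = comp, jsdMax = jsdMax)
      members <- c(members, as.character(member))
    }
  }
  list(members = members, seeds = seeds, omitted = FALSE,
       reason = NA_character_)
}

# Structure-preserving composition repair: steers an inverse-folded
# sequence toward the wild-type composition with single mutations
# (compensatory at paired sites) that never worsen the base-pair
# distance of the MFE structure to the target and strictly reduce the
# Jensen-Shannon divergence, until the divergence passes `jsdMax` or
# the move budget is spent.
.compositionRepair <- function(engine, seq, structure, comp, jsdMax,
                               seed, budget = NULL) {
  L <- nchar(seq)
  if (is.null(budget)) budget <- 10L * L
  p <- structure@pairs
  distFun <- if (is(engine, "ToyFoldingEngine")) {
    function(s) .toy_mfe_bpdist(s, p[, 1L], p[, 2L])
  } else {
    function(s) bpDistance(mfeStructure(engine, s), structure)
  }
  baseDist <- distFun(seq)
  cur <- seq
  curJ <- jsDivergence(nucleotideComposition(cur), comp)
  bases <- c("A", "C", "G", "U")
  withSeed(seed, {
    for (k in seq_len(budget)) {
      if (curJ < jsdMax) break
      chars <- strsplit(cur, "")[[1L]]
      excess <- table(factor(chars, levels = bases)) - comp * L
      over <- bases[which.max(excess)]
      cand <- chars
      posOpts <- which(chars == over)
      if (length(posOpts) == 0L) break
      pos <- posOpts[sample.int(length(posOpts), 1L)]
      deficit <- pmax(comp * L - table(factor(chars, levels = bases)), 0)
      alts <- setdiff(bases, over)
      cand[pos] <- .sampleBase(alts, stats::setNames(as.numeric(deficit),
                                                     bases)[alts])
      partner <- .partnerOf(structure, pos)
      if (!is.na(partner)) cand[partner] <- compensatoryPartner(cand[pos])
      candSeq <- paste(cand, collapse = "")
      candJ <- jsDivergence(nucleotideComposition(candSeq), comp)
      if (candJ < curJ && distFun(candSeq) <= baseDist) {
        cur <- candSeq
        curJ <- candJ
      }
    }
    cur
  })
}

.sequenceNeutrality <- function(seq, structure, metric, engine, n, seed) {
  switch(metric,
    SEN = senNeutrality(seq, structure, engine, n, seed)$value,
    bp_distance = bpDistanceNeutrality(seq, structure, engine)$value,
    PCC = pccNeutrality(seq, structure, engine, n, seed)$value)
}

#' Mutational-robustness verdict for a sequence
#'
#' A sequence is mutationally robust when its neutrality is strictly
#' greater than the mean neutrality of its background set (inverse
#' folded, composition matched, walk refined).
#'
#' @param seq wild-type sequence.
#' @param structure reference [SecondaryStructure-class] (used both
#'   for the wild-type neutrality and as the inverse-folding target).
#' @param metric `"SEN"`, `"bp_distance"` or `"PCC"`.
#' @param engine a [FoldingEngine-class].
#' @param n ensemble sample size for sampling metrics.
#' @param seed integer seed.
#' @param background optional precomputed [backgroundSet()] result.
#' @param walkReference acceptance reference for the background walks,
#'   see [neutralWalk()].
#' @return one-row data.frame: `sequence_id`, `metric`,
#'   `wt_neutrality`, `background_mean`, `n_background`, `robust`
#'   (logical; `NA` when the background was omitted), `omitted`,
#'   `seed`.
#' @export
isRobust <- function(seq, structure, metric = c("SEN", "bp_distance", "PCC"),
                     engine = toyEngine(), n = 1000L, seed = 1L,
                     background = NULL,
                     walkReference = c("mfe", "target")) {
  metric <- match.arg(metric)
  seq <- .checkSeq(seq)
  if (is.null(background))
    background <- backgroundSet(seq, structure, engine, seed = seed,
                                walkReference = match.arg(walkReference))
  if (background$omitted)
    return(data.frame(sequence_id = "seq", metric = metric,
                      wt_neutrality = NA_real_, background_mean = NA_real_,
                      n_background = 0L, robust = NA, omitted = TRUE,
                      seed = seed, stringsAsFactors = FALSE))
  wt <- .sequenceNeutrality(seq, structure, metric, engine, n, seed)
  bg <- vapply(seq_along(background$members), function(k) {
    .sequenceNeutrality(background$members[k], structure, metric, engine,
                        n, .rowSeed(seed, 5000L + k))
  }, numeric(1))
  data.frame(sequence_id = "seq", metric = metric, wt_neutrality = wt,
             background_mean = mean(bg), n_background = length(bg),
             robust = wt > mean(bg), omitted = FALSE, seed = seed,
             stringsAsFactors = FALSE)
}

#' Fraction of robust sequences
#'
#' Robust count over non-omitted verdicts.
#'
#' @param verdicts data.frame of [isRobust()] rows.
#' @return fraction in `[0, 1]`.
#' @export
fractionRobust <- function(verdicts) {
  keep <- !verdicts$omitted
  if (!any(keep)) stop("all verdicts omitted")
  mean(verdicts$robust[keep])
}
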