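#' Mean Z-score of the minimum free energy
#'
#' For each row of the alignment, the degapped sequence is folded and
#' its MFE energy compared with `nShuffles` exact dinucleotide
#' shuffles of itself: `z = (E - mean(E_shuffle)) / sd(E_shuffle)`
#' (sample standard deviation).  Rows whose shuffle energies are
#' constant (`sd = 0`, e.g. homopolymers) contribute 0.  The feature
#' is the mean over rows.
#'
#' @param alignment a [StructuredAlignment-class].
#' @param engine a [FoldingEngine-class].
#' @param nShuffles dinucleotide shuffles per row (default 100).
#' @param seed integer seed.
#' @return mean Z-score (standard deviations; negative = more stable
#'   than composition expects).
#' @export
mfeZScore <- function(alignment, engine = toyEngine(), nShuffles = 100L,
                      seed = 1L) {
  stopifnot(is(alignment, "StructuredAlignment"), nShuffles >= 2L)
  zs <- vapply(seq_along(alignment@seqs), function(k) {
    dg <- gsub(.GAP_RX, "", alignment@seqs[k])
    ns <- normalizeSequence(dg)
    if (!ns$ok) return(NA_real_)
    e <- attr(mfeStructure(engine, ns$seq), "energy")
    esh <- vapply(seq_len(nShuffles), function(m) {
      sh <- dinucleotideShuffle(ns$seq, seed = .rowSeed(seed, k * 1000L + m))
      attr(mfeStructure(engine, sh), "energy")
    }, numeric(1))
    s <- stats::sd(esh)
    if (s == 0) 0 else (e - mean(esh)) / s
  }, numeric(1))
  mean(zs, na.rm = TRUE)
}

#' Structure conservation index
#'
#' Ratio of the consensus folding energy of the alignment to the mean
#' MFE energy of its individual (degapped) rows.  Near 1 when every
#' sequence can fold into the consensus as favourably as into its own
#' MFE structure.  When the mean row energy is 0 (nothing folds) the
#' index is undefined and reported as 0 with a warning.
#'
#' @inheritParams mfeZScore
#' @return the index (dimensionless ratio).
#' @export
structureConservationIndex <- function(alignment, engine = toyEngine()) {
  stopifnot(is(alignment, "StructuredAlignment"))
  pred <- predictConsensus(engine, alignment)
  eCons <- attr(pred, "consensusEnergy")
  eRows <- vapply(alignment@seqs, function(s) {
    ns <- normalizeSequence(gsub(.GAP_RX, "", s))
    if (!ns$ok) return(NA_real_)
    attr(mfeStructure(engine, ns$seq), "energy")
  }, numeric(1), USE.NAMES = FALSE)
  m <- mean(eRows, na.rm = TRUE)
  if (m == 0) {
    warning("mean row MFE is 0; structure conservation index undefined, ",
            "reporting 0")
    return(0)
  }
  eCons / m
}

.pairedColumns <- function(alignment) {
  if (is.na(alignment@consensus))
    stop("alignment has no consensus structure")
  parseDotBracket(alignment@consensus)@pairs
}

.columnBases <- function(alignment, col) {
  b <- substr(alignment@seqs, col, col)
  b[!grepl(.GAP_RX, b)]
}

#' Mean entropy of stems
#'
#' Mean, over consensus-paired alignment columns, of the Shannon
#' entropy (log2) of the column's base frequencies.  Rows gapped at a
#' column are excluded from that column.  Bounded by 2 bits.
#'
#' @param alignment a [StructuredAlignment-class] whose consensus has
#'   at least one pair.
#' @return entropy in bits.
#' @export
meanStemEntropy <- function(alignment) {
  p <- .pairedColumns(alignment)
  if (nrow(p) == 0L) stop("consensus structure has no base pairs")
  cols <- sort(unique(c(p)))
  ents <- vapply(cols, function(col) {
    b <- .columnBases(alignment, col)
    if (length(b) == 0L) return(0)
    f <- table(b) / length(b)
    -sum(f * log2(f))
  }, numeric(1))
  mean(ents)
}

#' Mean mutual information of stems
#'
#' Mean, over consensus column pairs `(i, j)`, of the mutual
#' information between the base distributions of columns `i` and `j`
#' (log2, rows gapped at either column excluded, `0 log 0 = 0`).
#' Perfectly covarying columns of `k` equiprobable pair types give
#' `log2(k)` bits.
#'
#' @inheritParams meanStemEntropy
#' @return mutual information in bits.
#' @export
meanStemMutualInformation <- function(alignment) {
  p <- .pairedColumns(alignment)
  if (nrow(p) == 0L) stop("consensus structure has no base pairs")
  mis <- vapply(seq_len(nrow(p)), function(m) {
    bi <- substr(alignment@seqs, p[m, 1L], p[m, 1L])
    bj <- substr(alignment@seqs, p[m, 2L], p[m, 2L])
    keep <- !grepl(.GAP_RX, bi) & !grepl(.GAP_RX, bj)
    bi <- bi[keep]
    bj <- bj[keep]
    if (length(bi) == 0L) return(0)
    joint <- table(bi, bj) / length(bi)
    fi <- rowSums(joint)
    fj <- colSums(joint)
    mi <- 0
    for (a in seq_along(fi)) for (b in seq_along(fj)) {
      if (joint[a, b] > 0)
        mi <- mi + joint[a, b] * log2(joint[a, b] / (fi[a] * fj[b]))
    }
    mi
  }, numeric(1))
  mean(mis)
}

#' Mean pairwise identity of an alignment
#'
#' Mean, over all row pairs, of the fraction of identical columns.
#' Columns gapped in both rows are excluded; a gap against a base
#' counts as a mismatch.
#'
#' @param alignment a [StructuredAlignment-class] with at least 2 rows.
#' @return identity fraction in `[0, 1]`.
#' @export
meanPairwiseIdentity <- function(alignment) {
  n <- length(alignment)
  if (n < 2L) stop("pairwise identity needs at least 2 rows")
  mat <- do.call(rbind, strsplit(alignment@seqs, ""))
  gap <- matrix(grepl(.GAP_RX, mat), nrow = n)
  ids <- c()
  for (a in seq_len(n - 1L)) for (b in seq(a + 1L, n)) {
    keep <- !(gap[a, ] & gap[b, ])
    if (!any(keep)) {
      ids <- c(ids, 0)
    } else {
      ids <- c(ids, mean(mat[a, keep] == mat[b, keep] &
                         !gap[a, keep] & !gap[b, keep]))
    }
  }
  mean(ids)
}

#' Assemble the alignment feature vector
#'
#' The standard six alignment features used for de novo structured-RNA
#' classification (MFE Z-score, structure conservation index, mean
#' stem entropy, mean stem mutual information, mean pairwise identity,
#' number of sequences), optionally extended with the mean alignment
#' neutrality as a seventh feature.
#'
#' @param alignment a [StructuredAlignment-class].
#' @param engine a [FoldingEngine-class].
#' @param withNeutrality add the neutrality feature?
#' @param metric neutrality metric for the seventh feature.
#' @param n,seed sampling parameters.
#' @param nShuffles dinucleotide shuffles for the Z-score.
#' @return one-row data.frame of features (plus `neutrality` when
#'   requested).
#' @export
featureVector <- function(alignment, engine = toyEngine(),
                          withNeutrality = TRUE, metric = "SEN",
                          n = 1000L, seed = 1L, nShuffles = 100L) {
  stopifnot(is(alignment, "StructuredAlignment"))
  al <- alignment
  if (is.na(al@consensus)) al <- predictConsensus(engine, al)
  out <- data.frame(
    zscore_mfe = mfeZScore(al, engine, nShuffles, seed),
    sci = structureConservationIndex(al, engine),
    mean_stem_entropy = meanStemEntropy(al),
    mean_stem_mi = meanStemMutualInformation(al),
    mean_pairwise_identity = meanPairwiseIdentity(al),
    n_sequences = length(al))
  if (withNeutrality) {
    nr <- alignmentNeutrality(al, metric, engine, n, seed)
    out$neutrality <- mean(nr$value, na.rm = TRUE)
  }
  out
}

#' SVM classification with stratified cross-validation
#'
#' Radial-basis SVM with default hyperparameters; features are
#' standardised on the training folds only and the learned location
#' and scale are applied to the held-out fold (leakage-free).
#' Decision values are pooled over folds for a single ROC/AUC.
#'
#' @param features data.frame of numeric features (rows = examples).
#' @param labels factor (or coercible) with two levels; the second
#'   level is treated as the positive class.
#' @param featureSubset optional character vector naming the columns
#'   to use (e.g. `"neutrality"` for the single-feature classifier).
#' @param folds number of CV folds (default 10).
#' @param seed integer seed for the fold assignment.
#' @return list with `auc`, `roc` (data.frame of `fpr`, `tpr`),
#'   `decision` (pooled decision values) and `labels`.
#' @export
svmCrossValidate <- function(features, labels, featureSubset = NULL,
                             folds = 10L, seed = 1L) {
  labels <- factor(labels)
  stopifnot(nlevels(labels) == 2L)
  if (!is.null(featureSubset)) features <- features[, featureSubset,
                                                    drop = FALSE]
  features <- as.data.frame(features)
  if (min(table(labels)) < folds)
    stop("each class needs at least as many examples as folds")
  nEx <- nrow(features)
  foldOf <- integer(nEx)
  withSeed(seed, {
    for (lv in levels(labels)) {
      idx <- which(labels == lv)
      foldOf[idx] <- sample(rep_len(seq_len(folds), length(idx)))
    }
  })
  decision <- numeric(nEx)
  for (f in seq_len(folds)) {
    trainIdx <- which(foldOf != f)
    testIdx <- which(foldOf == f)
    mu <- vapply(features[trainIdx, , drop = FALSE], mean, numeric(1))
    sg <- vapply(features[trainIdx, , drop = FALSE], stats::sd, numeric(1))
    sg[sg == 0 | is.na(sg)] <- 1
    scaleTo <- function(df) {
      out <- sweep(as.matrix(df), 2L, mu, "-")
      sweep(out, 2L, sg, "/")
    }
    fit <- e1071::svm(scaleTo(features[trainIdx, , drop = FALSE]),
                      labels[trainIdx], kernel = "radial", scale = FALSE)
    pred <- stats::predict(fit, scaleTo(features[testIdx, , drop = FALSE]),
                           decision.values = TRUE)
    dv <- as.numeric(attr(pred, "decision.values"))
    # e1071's decision-value sign depends on the training-data class
    # order; orient each fold so the positive class scores high on the
    # training data before pooling
    predTr <- stats::predict(fit, scaleTo(features[trainIdx, , drop = FALSE]),
                             decision.values = TRUE)
    dvTr <- as.numeric(attr(predTr, "decision.values"))
    pos <- labels[trainIdx] == levels(labels)[2L]
    if (mean(dvTr[pos]) < mean(dvTr[!pos])) dv <- -dv
    decision[testIdx] <- dv
  }
  rocObj <- pROC::roc(response = labels, predictor = decision,
                      levels = levels(labels), direction = "<",
                      quiet = TRUE)
  list(auc = as.numeric(pROC::auc(rocObj)),
       roc = data.frame(fpr = rev(1 - rocObj$specificities),
                        tpr = rev(rocObj$sensitivities)),
       decision = decision, labels = labels)
}

#' Expected structure disruption coefficient
#'
#' Converts a structure-correlation value into a per-mutation
#' disruption score: `eSDC = (1 - pcc) * sqrt(L)`.
#'
#' @param pcc Pearson correlation in `[-1, 1]`.
#' @param L sequence length.
#' @return non-negative disruption score.
#' @export
esdc <- function(pcc, L) {
  stopifnot(all(pcc >= -1 & pcc <= 1), all(L >= 1))
  (1 - pcc) * sqrt(L)
}

#' Label the top half of disruption scores
#'
#' The top 50 percent of eSDC values (strict upper half after a stable
#' descending sort; `floor(n / 2)` labels) are considered structure
#' disrupting.
#'
#' @param scores numeric eSDC values.
#' @return logical vector parallel to `scores`.
#' @export
labelDisrupting <- function(scores) {
  n <- length(scores)
  k <- n %/% 2L
  ord <- order(scores, decreasing = TRUE)  # stable for ties
  out <- logical(n)
  if (k > 0L) out[ord[seq_len(k)]] <- TRUE
  out
}

#' Logistic regression of structure disruption on neutrality
#'
#' Single-predictor binomial GLM predicting the disruption label (1 =
#' disrupting) from a neutrality score, evaluated by ROC/AUC on the
#' fitted probabilities.
#'
#' @param neutrality numeric predictor (e.g. positional SEN).
#' @param disrupting logical or 0/1 response.
#' @return list with `model` (the [stats::glm] fit), `auc` and `roc`.
#' @export
disruptionRegression <- function(neutrality, disrupting) {
  y <- as.integer(disrupting)
  fit <- stats::glm(y ~ neutrality, family = stats::binomial())
  prob <- stats::fitted(fit)
  rocObj <- pROC::roc(response = y, predictor = prob, quiet = TRUE,
                      levels = c(0, 1), direction = "<")
  list(model = fit, auc = as.numeric(pROC::auc(rocObj)),
       roc = data.frame(fpr = rev(1 - rocObj$specificities),
                        tpr = rev(rocObj$sensitivities)))
}
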