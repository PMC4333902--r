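#' @importFrom utils write.table packageVersion
NULL

.engineFromSpec <- function(engine) {
  if (is(engine, "FoldingEngine")) return(engine)
  switch(match.arg(engine, c("toy", "vienna")),
         toy = toyEngine(),
         vienna = viennaEngine())
}

.engineLabel <- function(engine) {
  if (is(engine, "ViennaFoldingEngine"))
    paste0("vienna (", engine@version, ")")
  else engine@name
}

.writeTsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}

.writeProvenance <- function(outDir, config, engine) {
  rec <- c(list(package = "senRNA",
                version = as.character(packageVersion("senRNA")),
                engine = .engineLabel(engine)),
           config)
  jsonlite::write_json(rec, file.path(outDir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

#' Neutrality workflow: Stockholm in, TSV out
#'
#' Runs [alignmentNeutrality()] for the requested metrics on a
#' structure-annotated alignment and writes `neutrality.tsv` (one row
#' per sequence and metric), optionally `positional.tsv` (1-based
#' positions), and a `provenance.json` sidecar.  Reruns with the same
#' configuration produce byte-identical files.
#'
#' @param input path to a Stockholm file, or a
#'   [StructuredAlignment-class].
#' @param outDir output directory (created if needed).
#' @param metrics subset of `c("SEN", "bp_distance", "PCC")`.
#' @param engine `"toy"`, `"vienna"`, or a [FoldingEngine-class].
#' @param n,seed sampling parameters.
#' @param positional also write per-position SEN profiles?
#' @param structureSource how to treat the consensus, see
#'   [readStockholm()].
#' @param pccForm PCC sign convention, see [pccNeutrality()].
#' @return invisibly, the neutrality data.frame.
#' @export
runNeutralityPipeline <- function(input, outDir, metrics = "SEN",
                                  engine = "toy", n = 1000L, seed = 1L,
                                  positional = FALSE,
                                  structureSource = "given",
                                  pccForm = "adjusted") {
  engine <- .engineFromSpec(engine)
  al <- if (is(input, "StructuredAlignment")) input else
    readStockholm(input, structureSource)
  if (is.na(al@consensus)) al <- predictConsensus(engine, al)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  res <- do.call(rbind, lapply(metrics, function(m) {
    alignmentNeutrality(al, m, engine, n, seed, pccForm = pccForm)
  }))
  .writeTsv(res, file.path(outDir, "neutrality.tsv"))
  if (positional) {
    cons <- parseDotBracket(al@consensus)
    prof <- do.call(rbind, lapply(seq_along(al@seqs), function(k) {
      dg <- degapPair(al@seqs[k], cons)
      ns <- normalizeSequence(dg$seq)
      if (!ns$ok) return(NULL)
      ref <- canonicalFilter(ns$seq, dg$structure)
      if (numPairs(ref) == 0L) return(NULL)
      v <- positionalNeutrality(ns$seq, ref, engine, n,
                                .rowSeed(seed, k))
      data.frame(sequence_id = al@ids[k], position = seq_along(v),
                 sen = v, stringsAsFactors = FALSE)
    }))
    .writeTsv(prof, file.path(outDir, "positional.tsv"))
  }
  .writeProvenance(outDir,
                   list(workflow = "neutrality", metrics = metrics,
                        n_samples = n, seed = seed,
                        positional = positional, pcc_form = pccForm),
                   engine)
  invisible(res)
}

#' Robustness screen: verdicts and robust fraction
#'
#' For every non-skipped sequence of the alignment, builds the
#' inverse-fold/neutral-walk background and records the
#' [isRobust()] verdict; writes `verdicts.tsv`, `summary.tsv` (the
#' robust fraction per metric) and `provenance.json`.
#'
#' @inheritParams runNeutralityPipeline
#' @param metric a single neutrality metric.
#' @param walkReference acceptance reference for background walks,
#'   see [neutralWalk()].
#' @return invisibly, the verdict data.frame.
#' @export
runRobustnessPipeline <- function(input, outDir, metric = "SEN",
                                  engine = "toy", n = 1000L, seed = 1L,
                                  structureSource = "given",
                                  walkReference = "mfe") {
  engine <- .engineFromSpec(engine)
  al <- if (is(input, "StructuredAlignment")) input else
    readStockholm(input, structureSource)
  if (is.na(al@consensus)) al <- predictConsensus(engine, al)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  cons <- parseDotBracket(al@consensus)
  verdicts <- do.call(rbind, lapply(seq_along(al@seqs), function(k) {
    dg <- degapPair(al@seqs[k], cons)
    ns <- normalizeSequence(dg$seq)
    reason <- if (!ns$ok) ns$reason else {
      ref <- canonicalFilter(ns$seq, dg$structure)
      if (numPairs(ref) == 0L) "no canonical base pairs in reference"
      else NA_character_
    }
    if (!is.na(reason))
      return(data.frame(sequence_id = al@ids[k], metric = metric,
                        wt_neutrality = NA_real_,
                        background_mean = NA_real_, n_background = 0L,
                        robust = NA, omitted = TRUE, seed = seed,
                        reason = reason, stringsAsFactors = FALSE))
    v <- isRobust(ns$seq, ref, metric, engine, n, .rowSeed(seed, k),
                  walkReference = walkReference)
    v$sequence_id <- al@ids[k]
    v$reason <- NA_character_
    v
  }))
  .writeTsv(verdicts, file.path(outDir, "verdicts.tsv"))
  fr <- if (all(verdicts$omitted)) NA_real_ else fractionRobust(verdicts)
  .writeTsv(data.frame(metric = metric, fraction_robust = fr,
                       n_sequences = sum(!verdicts$omitted)),
            file.path(outDir, "summary.tsv"))
  .writeProvenance(outDir,
                   list(workflow = "robustness", metric = metric,
                        n_samples = n, seed = seed,
                        walk_reference = walkReference), engine)
  if (all(verdicts$omitted)) stop("all sequences omitted")
  invisible(verdicts)
}

#' Classification benchmark: features, ROC, separation statistics
#'
#' Builds (or accepts) a positive and a negative set of alignments,
#' assembles per-alignment feature vectors, cross-validates the SVM on
#' the full 7-feature set and on neutrality alone, and reports the
#' Wilcoxon rank-sum separation of neutrality between the classes and
#' the Spearman correlation matrix across metrics (after family-mean
#' standardisation: the neutrality values of each alignment are
#' averaged before correlating, because different metrics skip
#' different sequences).  Writes `features.tsv`, `roc_*.tsv`,
#' `stats.tsv` and `provenance.json`.
#'
#' @param positives,negatives lists of [StructuredAlignment-class]
#'   objects; when `NULL`, a synthetic benchmark of `nAlign` fixture
#'   alignments and their dinucleotide-shuffled decoys is generated.
#' @param outDir output directory.
#' @param nAlign number of generated pairs when the sets are `NULL`.
#' @param engine,n,seed as in [runNeutralityPipeline()].
#' @param nShuffles dinucleotide shuffles for the Z-score feature.
#' @param spearman also compute the cross-metric Spearman matrix
#'   (needs all three metrics on every alignment; slower).
#' @return invisibly, a list with `features`, `aucs`, `wilcoxon_p`
#'   and (optionally) `spearman`.
#' @export
runBenchmarkPipeline <- function(positives = NULL, negatives = NULL,
                                 outDir, nAlign = 30L, engine = "toy",
                                 n = 1000L, seed = 1L, nShuffles = 100L,
                                 spearman = FALSE) {
  engine <- .engineFromSpec(engine)
  if (is.null(positives) || is.null(negatives)) {
    bench <- generateBenchmark(nAlign, engine = engine, seed = seed)
    positives <- bench$structured
    negatives <- bench$shuffled
  }
  if (length(positives) < 10L || length(negatives) < 10L)
    stop("need at least 10 alignments per class for 10-fold CV")
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  alignments <- c(positives, negatives)
  labels <- factor(rep(c("structured", "other"),
                       c(length(positives), length(negatives))),
                   levels = c("other", "structured"))
  feats <- do.call(rbind, lapply(seq_along(alignments), function(k) {
    featureVector(alignments[[k]], engine, withNeutrality = TRUE,
                  metric = "SEN", n = n, seed = .rowSeed(seed, 777L + k),
                  nShuffles = nShuffles)
  }))
  featOut <- cbind(data.frame(alignment = seq_along(alignments),
                              label = as.character(labels)), feats)
  .writeTsv(featOut, file.path(outDir, "features.tsv"))
  cvAll <- svmCrossValidate(feats, labels, seed = seed)
  cvSen <- svmCrossValidate(feats, labels, featureSubset = "neutrality",
                            seed = seed)
  cvSix <- svmCrossValidate(feats, labels,
                            featureSubset = setdiff(names(feats),
                                                    "neutrality"),
                            seed = seed)
  .writeTsv(cvAll$roc, file.path(outDir, "roc_7feature.tsv"))
  .writeTsv(cvSen$roc, file.path(outDir, "roc_sen_only.tsv"))
  .writeTsv(cvSix$roc, file.path(outDir, "roc_6feature.tsv"))
  wil <- stats::wilcox.test(feats$neutrality[labels == "structured"],
                            feats$neutrality[labels == "other"],
                            alternative = "greater", exact = FALSE)
  stats <- data.frame(
    statistic = c("auc_7feature", "auc_6feature", "auc_sen_only",
                  "wilcoxon_p_sen", "median_sen_structured",
                  "median_sen_other"),
    value = c(cvAll$auc, cvSix$auc, cvSen$auc, wil$p.value,
              stats::median(feats$neutrality[labels == "structured"]),
              stats::median(feats$neutrality[labels == "other"])))
  out <- list(features = featOut,
              aucs = c(seven = cvAll$auc, six = cvSix$auc,
                       sen_only = cvSen$auc),
              wilcoxon_p = wil$p.value)
  if (spearman) {
    sp <- .metricSpearman(alignments, engine, n, seed)
    out$spearman <- sp
    .writeTsv(as.data.frame(as.table(sp)),
              file.path(outDir, "spearman.tsv"))
  }
  .writeTsv(stats, file.path(outDir, "stats.tsv"))
  .writeProvenance(outDir,
                   list(workflow = "benchmark",
                        n_positives = length(positives),
                        n_negatives = length(negatives),
                        n_samples = n, seed = seed,
                        n_shuffles = nShuffles), engine)
  invisible(out)
}

# family-mean standardised Spearman correlations across metrics
.metricSpearman <- function(alignments, engine, n, seed) {
  metrics <- c("SEN", "bp_distance", "PCC")
  fam <- vapply(metrics, function(m) {
    vapply(seq_along(alignments), function(k) {
      r <- alignmentNeutrality(alignments[[k]], m, engine, n,
                               .rowSeed(seed, 333L + k))
      mean(r$value, na.rm = TRUE)
    }, numeric(1))
  }, numeric(length(alignments)))
  stats::cor(fam, method = "spearman", use = "pairwise.complete.obs")
}

#' Recipe for a full-scale reproduction on Rfam seed alignments
#'
#' The published-scale experiment - Rfam seed alignments of bacterial
#' regulatory RNAs as positives, dinucleotide-shuffled decoys as
#' negatives, the ViennaRNA engine at its defaults - cannot run from
#' the package's own fixtures because it needs externally downloaded
#' data; this function drives it against a local directory of
#' Stockholm seed alignments.  With `run = FALSE` (default) it
#' validates the inputs and returns the plan (files found, engine,
#' workflow stages) without computing anything; with `run = TRUE` it
#' executes the benchmark and robustness workflows, which can take
#' hours on a full 35-family set.  Expected qualitative outcome: the
#' SEN distribution of the positives sits well above the shuffled
#' decoys, and the SEN robust fraction is far above the bp-distance
#' one.
#'
#' @param stockholmDir directory containing `.sto`/`.stk` seed
#'   alignments with `SS_cons` lines.
#' @param outDir output directory for the full run.
#' @param engine a [FoldingEngine-class]; the Vienna engine is the
#'   physically meaningful choice here.
#' @param n,seed sampling parameters.
#' @param run execute (TRUE) or just validate and plan (FALSE).
#' @return the plan list (invisibly the results list when `run = TRUE`).
#' @export
reproduceRfamStudy <- function(stockholmDir, outDir = NULL,
                               engine = NULL, n = 1000L, seed = 1L,
                               run = FALSE) {
  if (!dir.exists(stockholmDir))
    stop("Stockholm directory not found: ", stockholmDir)
  files <- list.files(stockholmDir, pattern = "\\.(sto|stk|stockholm)$",
                      full.names = TRUE)
  if (length(files) == 0L)
    stop("no Stockholm files (*.sto, *.stk) in ", stockholmDir)
  plan <- list(
    files = files,
    engine = if (is.null(engine)) "vienna (resolved at run time)"
             else .engineLabel(engine),
    n_samples = n, seed = seed,
    stages = c(
      "read each seed alignment (given SS_cons)",
      "generate dinucleotide-shuffled decoys; predict their consensus",
      "benchmark workflow: features + SVM CV + Wilcoxon separation",
      "robustness workflow: SEN robust fraction per family"))
  if (!run) return(plan)
  if (is.null(engine)) engine <- viennaEngine()
  if (is.null(outDir)) stop("outDir is required when run = TRUE")
  positives <- lapply(files, readStockholm)
  negatives <- lapply(seq_along(positives), function(k) {
    dinucleotideShuffleAlignment(positives[[k]], engine,
                                 seed = .rowSeed(seed, 424200L + k))
  })
  bench <- runBenchmarkPipeline(positives, negatives,
                                outDir = file.path(outDir, "benchmark"),
                                engine = engine, n = n, seed = seed)
  verdicts <- lapply(seq_along(positives), function(k) {
    runRobustnessPipeline(positives[[k]],
                          file.path(outDir, sprintf("robustness_%02d", k)),
                          metric = "SEN", engine = engine, n = n,
                          seed = .rowSeed(seed, 900000L + k))
  })
  invisible(list(plan = plan, benchmark = bench, verdicts = verdicts))
}
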