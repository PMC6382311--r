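# Evaluation against a reference cancer-gene list: precision/recall of the
# consensus gene set, and PR / ROC curves over a score-ranked gene list.

#' Precision and recall of a predicted gene set
#'
#' Precision is the fraction of predicted genes found in the reference list;
#' recall is the fraction of reference genes *mutated in the cohort* that
#' are predicted (reference genes the cohort never mutates cannot be
#' recovered and are excluded from the denominator).
#'
#' @param predicted character vector of predicted genes (e.g.
#'   [consensusGenes()] output).
#' @param reference character vector of reference cancer genes.
#' @param cohortMutated genes mutated in the cohort; should contain
#'   \code{predicted} (warned otherwise).
#' @return a list: \code{precision}, \code{recall}, \code{nPredicted},
#'   \code{nHits}, \code{nReferenceMutated}. An empty prediction gives
#'   precision 0 with a warning; an empty mutated-reference denominator
#'   gives recall \code{NA} with a warning.
#' @examples
#' precisionRecall(c("a", "b", "c"), reference = c("a", "b", "x"),
#'                 cohortMutated = c("a", "b", "c", "x"))
#' @export
precisionRecall <- function(predicted, reference, cohortMutated) {
  predicted <- unique(as.character(predicted))
  reference <- unique(as.character(reference))
  cohortMutated <- unique(as.character(cohortMutated))
  stray <- setdiff(predicted, cohortMutated)
  if (length(stray))
    warning("predicted gene(s) not among cohort-mutated genes: ",
            paste(utils::head(stray, 5L), collapse = ", "))
  hits <- intersect(predicted, reference)
  if (length(predicted)) {
    precision <- length(hits) / length(predicted)
  } else {
    warning("empty prediction; precision reported as 0")
    precision <- 0
  }
  refMut <- intersect(reference, cohortMutated)
  if (length(refMut)) {
    recall <- length(intersect(hits, refMut)) / length(refMut)
  } else {
    warning("no reference gene is mutated in the cohort; recall undefined")
    recall <- NA_real_
  }
  list(precision = precision, recall = recall,
       nPredicted = length(predicted), nHits = length(hits),
       nReferenceMutated = length(refMut))
}

#' Score-derived gene ranking from a module catalog
#'
#' Ranks every cohort-mutated gene by the maximum composite score of any
#' catalog module containing it (0 for genes in no module). This is the
#' ranking used for PR/ROC curves over all mutated genes.
#'
#' @param catalog a scored [ModuleCatalog-class] (or list of catalogs, whose
#'   per-gene maxima are combined).
#' @param m the [MutationMatrix-class].
#' @return data.frame with columns \code{gene}, \code{score}, sorted by
#'   descending score then gene symbol.
#' @export
geneRanking <- function(catalog, m) {
  stopifnot(is(m, "MutationMatrix"))
  if (is(catalog, "ModuleCatalog")) catalog <- list(catalog)
  mutated <- m@geneIds[lengths(m@mutatedSamples) > 0L]
  score <- stats::setNames(rep(0, length(mutated)), mutated)
  for (cat in catalog) {
    stopifnot(is(cat, "ModuleCatalog"))
    for (mod in cat@modules) {
      comp <- if (is.null(mod@score)) 0 else mod@score@composite
      g <- intersect(mod@genes, mutated)
      score[g] <- pmax(score[g], comp)
    }
  }
  out <- data.frame(gene = mutated, score = unname(score))
  out <- out[order(-out$score, out$gene, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' PR and ROC curves over a ranked gene list
#'
#' Sweeps a score ranking of the cohort-mutated genes against a reference
#' gene list and reports precision-recall and ROC curves with their areas.
#' Genes of \code{cohortMutated} absent from the ranking are appended with
#' score 0 in lexicographic order (a deterministic, random-free tail). The
#' area under the PR curve is the average-precision step integral (mean of
#' the precision at each positive's rank), which avoids the optimistic bias
#' of trapezoidal PR interpolation; the ROC area is the usual trapezoid.
#'
#' @param ranking data.frame with columns \code{gene} and \code{score}
#'   (higher = stronger driver evidence), e.g. from [geneRanking()].
#' @param reference character vector of reference cancer genes.
#' @param cohortMutated genes mutated in the cohort (the evaluation
#'   universe).
#' @return a list: \code{prPoints} (recall, precision), \code{rocPoints}
#'   (fpr, tpr), \code{aupr}, \code{auc}, \code{nPositives}, \code{nGenes}.
#' @export
rankedCurves <- function(ranking, reference, cohortMutated) {
  stopifnot(is.data.frame(ranking), all(c("gene", "score") %in% names(ranking)))
  cohortMutated <- unique(as.character(cohortMutated))
  ranking <- ranking[ranking$gene %in% cohortMutated, , drop = FALSE]
  missing <- sort(setdiff(cohortMutated, ranking$gene))
  if (length(missing))
    ranking <- rbind(ranking, data.frame(gene = missing, score = 0))
  ranking <- ranking[order(-ranking$score, ranking$gene, method = "radix"), ,
                     drop = FALSE]
  positives <- intersect(cohortMutated, unique(as.character(reference)))
  nPos <- length(positives)
  if (nPos == 0L)
    stop("no reference gene is mutated in the cohort; curves undefined",
         call. = FALSE)
  isPos <- ranking$gene %in% positives
  n <- nrow(ranking)
  nNeg <- n - nPos
  tp <- cumsum(isPos)
  fp <- cumsum(!isPos)
  precision <- tp / seq_len(n)
  recall <- tp / nPos
  aupr <- sum(precision[isPos]) / nPos
  tpr <- tp / nPos
  fpr <- if (nNeg > 0L) fp / nNeg else rep(0, n)
  rocX <- c(0, fpr)
  rocY <- c(0, tpr)
  auc <- sum(diff(rocX) * (utils::head(rocY, -1) + utils::tail(rocY, -1)) / 2)
  list(prPoints = data.frame(recall = recall, precision = precision),
       rocPoints = data.frame(fpr = fpr, tpr = tpr),
       aupr = aupr, auc = auc, nPositives = nPos, nGenes = n)
}

#' Read a reference gene list
#'
#' Plain text, one gene symbol per line; blank lines and lines starting
#' with \code{#} are skipped.
#'
#' @param path file path.
#' @return character vector of unique gene symbols.
#' @export
readGeneList <- function(path) {
  lines <- trimws(.readTabLines(path))
  unique(lines[nzchar(lines) & !startsWith(lines, "#")])
}

#' Write an evaluation report as JSON
#'
#' @param report list combining [precisionRecall()] and [rankedCurves()]
#'   output (any subset of their fields).
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeEvaluationReport <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}
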