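#' Exclusive degree of genes in a module
#'
#' The exclusive degree of a module gene g_i is Ex(g_i) = n'_i / n_i, the
#' fraction of its mutated samples in which no other module gene is mutated.
#'
#' @param profiles a profile data.frame from [exclusivityProfiles()] (or any
#'   data.frame with columns \code{exclusiveCount} and \code{mutatedCount}).
#' @return numeric vector of per-gene exclusive degrees, named by gene.
#' @export
exclusiveDegree <- function(profiles) {
  stopifnot(all(c("exclusiveCount", "mutatedCount") %in% names(profiles)))
  if (any(profiles$mutatedCount == 0L))
    stop("exclusive degree undefined for gene(s) with zero mutated samples: ",
         paste(profiles$gene[profiles$mutatedCount == 0L], collapse = ", "),
         call. = FALSE)
  stats::setNames(profiles$exclusiveCount / profiles$mutatedCount,
                  profiles$gene)
}

#' Exclusive score of a gene module
#'
#' Ex(M), the arithmetic mean of the per-gene exclusive degrees of the
#' module. Equals 1 exactly when the genes' mutated-sample sets are pairwise
#' disjoint.
#'
#' @param m a [MutationMatrix-class].
#' @param module character vector of module genes.
#' @return Ex(M) in [0, 1].
#' @export
exclusiveScore <- function(m, module) {
  mean(exclusiveDegree(exclusivityProfiles(m, module)))
}

#' Exclusive entropy of a gene module
#'
#' H(M) = -sum_i p_i log2 p_i, the Shannon entropy (bits) of the
#' exclusive-mutation ratios p_i = n'_i / n', where n'_i is the number of
#' samples in which gene i is the only mutated module gene and n' = sum n'_i.
#' H(M) measures how evenly the exclusively mutated samples are balanced
#' across the module genes: it is maximal (log2 s) when all n'_i are equal.
#' Conventions: 0 log 0 = 0; H(M) = 0 when n' = 0 (no exclusive mass carries
#' no balance information) and for singleton modules.
#'
#' @param m a [MutationMatrix-class].
#' @param module character vector of module genes.
#' @return entropy in bits, in [0, log2(length(module))].
#' @export
exclusiveEntropy <- function(m, module) {
  prof <- exclusivityProfiles(m, module)
  nEx <- sum(prof$exclusiveCount)
  if (nEx == 0L) return(0)
  p <- prof$exclusiveCount / nEx
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Minimum and union coverage of a gene module
#'
#' \code{minCoverage} is the smallest per-gene coverage min_i |P_i| (the
#' coverage term entering the composite score); \code{unionCoverage} is the
#' number of samples with at least one module gene mutated (the
#' module-coverage notion used for sample covering and tie-breaks). Both are
#' always reported side by side.
#'
#' @param m a [MutationMatrix-class].
#' @param module character vector of module genes.
#' @return an integer sample count.
#' @export
minCoverage <- function(m, module) {
  .assertGenesPresent(m, module)
  stopifnot(length(module) >= 1)
  min(lengths(m@mutatedSamples[module]))
}

#' @rdname minCoverage
#' @export
unionCoverage <- function(m, module) {
  .assertGenesPresent(m, module)
  stopifnot(length(module) >= 1)
  length(unique(unlist(m@mutatedSamples[module], use.names = FALSE)))
}

#' Dendrix weight of a gene module
#'
#' W(M) = 2 |union_i P_i| - sum_i |P_i|, i.e. union coverage minus coverage
#' overlap. Reported for comparison with coverage/exclusivity-only scoring;
#' never used for selection. A strictly exclusive module covering c samples
#' has W(M) = c.
#'
#' @param m a [MutationMatrix-class].
#' @param module character vector of module genes.
#' @return an integer weight (samples).
#' @export
dendrixWeight <- function(m, module) {
  .assertGenesPresent(m, module)
  stopifnot(length(module) >= 1)
  sizes <- lengths(m@mutatedSamples[module])
  as.integer(2L * unionCoverage(m, module) - sum(sizes))
}

#' Composite module score
#'
#' Evaluates a module M with the composite score
#' \deqn{\mathrm{score}(M) = \mathrm{cov}(M)\,\mathrm{Ex}(M)\,H(M)}
#' where cov(M) is the minimum per-gene coverage, Ex(M) the exclusive score
#' and H(M) the exclusive entropy. The score jointly rewards coverage,
#' mutual exclusivity and balance of the exclusive coverage; singleton
#' modules always score 0 (H = 0).
#'
#' @param m a [MutationMatrix-class].
#' @param module character vector of module genes.
#' @return a [ModuleScore-class].
#' @examples
#' # 4 strictly exclusive genes, 2 samples each: cov 2, Ex 1, H 2 => 4
#' m <- MutationMatrix(gene = rep(paste0("g", 1:4), each = 2),
#'                     sample = paste0("s", 1:8))
#' compositeScore(unicovexScore(m, paste0("g", 1:4)))
#' @export
unicovexScore <- function(m, module) {
  prof <- exclusivityProfiles(m, module)
  ex <- mean(exclusiveDegree(prof))
  nEx <- sum(prof$exclusiveCount)
  if (nEx > 0L) {
    p <- prof$exclusiveCount / nEx
    pp <- p[p > 0]
    entropy <- -sum(pp * log2(pp))
  } else {
    p <- rep(0, nrow(prof))
    entropy <- 0
  }
  covMin <- min(prof$mutatedCount)
  uni <- unionCoverage(m, module)
  new("ModuleScore",
      genes = prof$gene,
      exScore = ex,
      entropy = entropy,
      minCoverage = as.integer(covMin),
      unionCoverage = as.integer(uni),
      exclusiveTotal = as.integer(nEx),
      ratios = stats::setNames(as.numeric(p), prof$gene),
      composite = covMin * ex * entropy,
      dendrixW = as.integer(2L * uni - sum(prof$mutatedCount)))
}

#' @rdname ModuleScore-class
#' @export
setMethod("compositeScore", "ModuleScore", function(x) x@composite)

#' @rdname GeneModule-class
#' @export
setMethod("compositeScore", "GeneModule", function(x) {
  if (is.null(x@score)) NA_real_ else x@score@composite
})

setMethod("show", "ModuleScore", function(object) {
  cat("ModuleScore {", paste(object@genes, collapse = ", "), "}\n",
      "  Ex = ", signif(object@exScore, 4),
      ", H = ", signif(object@entropy, 4), " bits",
      ", cov(min) = ", object@minCoverage,
      ", cov(union) = ", object@unionCoverage, "\n",
      "  composite = ", signif(object@composite, 6),
      ", Dendrix W = ", object@dendrixW, "\n", sep = "")
})
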