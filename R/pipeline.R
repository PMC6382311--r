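# End-to-end orchestration: run configuration and the full pipeline
# (reduce -> local networks -> grow -> score -> select -> set cover ->
# consensus -> evaluation), with provenance written next to the results.

#' Pipeline run configuration
#'
#' Collects the tunable parameters of the pipeline with their standard
#' defaults: local networks of up to 100 genes, modules of size at most 5,
#' exclusive-score cutoff 0.95, gene recurrence filter 2 samples, influence
#' networks reduced to average degree 15, and consensus support of at least
#' 2 networks.
#'
#' @param localSize maximal genes per local network.
#' @param maxSize maximal module size.
#' @param exCutoff exclusive-score growth cutoff.
#' @param minRecurrence minimum mutated-sample count per considered gene.
#' @param targetAvgDegree average degree of the reduced influence network.
#' @param minSupport minimum number of networks supporting a consensus
#'   module.
#' @param agreement consensus agreement rule, \code{"exact"} or
#'   \code{"jaccard"}.
#' @param jaccardThreshold Jaccard threshold for \code{"jaccard"} agreement.
#' @param beta restart probability for [diffuseInfluence()].
#' @param symmetrize symmetrization rule for [diffuseInfluence()].
#' @return a validated named list of class \code{unicovexConfig}.
#' @export
unicovexConfig <- function(localSize = 100, maxSize = 5, exCutoff = 0.95,
                           minRecurrence = 2, targetAvgDegree = 15,
                           minSupport = 2,
                           agreement = c("exact", "jaccard"),
                           jaccardThreshold = 0.5, beta = 0.45,
                           symmetrize = c("min", "max", "mean")) {
  agreement <- match.arg(agreement)
  symmetrize <- match.arg(symmetrize)
  stopifnot(localSize >= 1, maxSize >= 2, exCutoff >= 0, exCutoff <= 1,
            minRecurrence >= 1, targetAvgDegree > 0, minSupport >= 1,
            jaccardThreshold > 0, jaccardThreshold <= 1,
            beta > 0, beta < 1)
  structure(list(localSize = as.integer(localSize),
                 maxSize = as.integer(maxSize), exCutoff = exCutoff,
                 minRecurrence = as.integer(minRecurrence),
                 targetAvgDegree = targetAvgDegree,
                 minSupport = as.integer(minSupport), agreement = agreement,
                 jaccardThreshold = jaccardThreshold, beta = beta,
                 symmetrize = symmetrize),
            class = "unicovexConfig")
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys absent from the file keep their [unicovexConfig()] defaults;
#' unknown keys are an error.
#'
#' @param path YAML file path.
#' @return a \code{unicovexConfig} list.
#' @export
readConfig <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(unicovexConfig))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  do.call(unicovexConfig, vals)
}

#' Run the full driver-module pipeline
#'
#' For each influence network: reduce to the target average degree, build
#' the candidate-module catalog, select high-scoring modules per size until
#' the cohort is covered, and solve the greedy set cover per module-size
#' group. Then call consensus modules across networks and, if a reference
#' gene list is given, evaluate precision/recall and PR/ROC curves. All
#' interface files plus a provenance manifest are written to \code{outDir}.
#' The pipeline is fully deterministic: identical inputs and configuration
#' reproduce byte-identical catalogs, covers and consensus files.
#'
#' @param mutations path to a mutation file (tsv_pairs or MAF) or a
#'   [MutationMatrix-class].
#' @param networks named character vector of edge-list paths, or named list
#'   of [InfluenceNetwork-class] objects.
#' @param reference optional path to a reference gene list (or character
#'   vector of genes) for evaluation.
#' @param outDir output directory (created if needed).
#' @param config a [unicovexConfig()] list.
#' @return invisibly, a list with the per-network catalogs and covers, the
#'   consensus set, and the evaluation report (if computed).
#' @export
runPipeline <- function(mutations, networks, reference = NULL, outDir,
                        config = unicovexConfig()) {
  t0 <- Sys.time()
  stopifnot(length(networks) >= 1)
  if (config$minSupport > length(networks))
    stop("minSupport (", config$minSupport,
         ") exceeds the number of networks (", length(networks), ")",
         call. = FALSE)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)

  m <- if (is(mutations, "MutationMatrix")) mutations else
    readMutations(mutations)
  if (is.null(names(networks)) || any(!nzchar(names(networks))))
    stop("networks must be named", call. = FALSE)
  nets <- lapply(names(networks), function(nm) {
    x <- networks[[nm]]
    net <- if (is(x, "InfluenceNetwork")) x else readInfluenceNetwork(x, nm)
    net@name <- nm
    net
  })
  names(nets) <- names(networks)

  catalogs <- list()
  covers <- list()
  for (nm in names(nets)) {
    .stage(nm, "reduce + discover", {
      red <- reduceToAverageDegree(nets[[nm]], config$targetAvgDegree)
      cat0 <- buildCatalog(m, red, config)
      sel <- selectCoveringModules(cat0, m)
      catalogs[[nm]] <- sel
      writeCatalog(sel$catalog, file.path(outDir, paste0("catalog_", nm, ".tsv")))
    })
    .stage(nm, "set cover", {
      pickTabs <- list()
      assignTabs <- list()
      solutions <- list()
      for (s in names(catalogs[[nm]]$selected)) {
        mods <- catalogs[[nm]]$selected[[s]]
        if (!length(mods)) next
        sol <- greedySetCover(mods, m, sizeGroup = as.integer(s))
        solutions[[s]] <- sol
        p <- sol@picks
        if (nrow(p))
          pickTabs[[s]] <- data.frame(size_group = as.integer(s),
                                      pick_rank = p$pickRank, genes = p$genes,
                                      marginal_gain = p$marginalGain,
                                      cumulative_coverage = p$cumulativeCoverage)
        a <- sol@sampleAssignment
        if (length(a))
          assignTabs[[s]] <- data.frame(sample = names(a),
                                        size_group = as.integer(s),
                                        modules = vapply(a, paste, "",
                                                         collapse = "|"))
      }
      covers[[nm]] <- solutions
      .writeTab(do.call(rbind, pickTabs),
                file.path(outDir, paste0("cover_", nm, ".tsv")),
                c("size_group", "pick_rank", "genes", "marginal_gain",
                  "cumulative_coverage"))
      .writeTab(do.call(rbind, assignTabs),
                file.path(outDir, paste0("assignment_", nm, ".tsv")),
                c("sample", "size_group", "modules"))
    })
  }

  selectedLists <- lapply(catalogs, function(x) unlist(x$selected,
                                                       use.names = FALSE))
  consensus <- NULL
  if (length(nets) >= 2L) {
    .stage("all", "consensus", {
      consensus <- consensusModules(selectedLists,
                                     minSupport = config$minSupport,
                                     agreement = config$agreement,
                                     jaccardThreshold = config$jaccardThreshold)
    })
  } else {
    message("single network: its selected modules are the final predictions")
    mods <- selectedLists[[1L]]
    keys <- vapply(mods, function(mod) moduleKey(mod@genes), character(1))
    keep <- !duplicated(keys)
    tab <- if (any(keep)) data.frame(
      genes = keys[keep],
      size = vapply(mods[keep], function(mod) length(mod@genes), integer(1)),
      support = 1L, networks = names(nets),
      bestComposite = vapply(mods[keep], compositeScore, numeric(1))) else
        .emptyConsensus()@table
    if (nrow(tab)) {
      ord <- order(-tab$bestComposite, tab$genes, method = "radix")
      tab <- tab[ord, , drop = FALSE]
      rownames(tab) <- NULL
      consensus <- new("ConsensusSet", table = tab, modules = mods[keep][ord])
    } else consensus <- .emptyConsensus()
  }
  writeConsensus(consensus, file.path(outDir, "consensus.tsv"))

  evalReport <- NULL
  if (!is.null(reference)) {
    .stage("all", "evaluation", {
      ref <- if (length(reference) == 1L && file.exists(reference))
        readGeneList(reference) else as.character(reference)
      cohortMutated <- geneIds(m)[lengths(mutatedSamples(m)) > 0L]
      pr <- precisionRecall(consensusGenes(consensus), ref, cohortMutated)
      ranking <- geneRanking(lapply(catalogs, function(x) x$catalog), m)
      curves <- rankedCurves(ranking, ref, cohortMutated)
      evalReport <- c(pr, curves)
      writeEvaluationReport(evalReport, file.path(outDir, "evaluation.json"))
    })
  }

  yaml::write_yaml(unclass(config), file.path(outDir, "config.yaml"))
  manifest <- list(
    package = "unicovex",
    version = as.character(utils::packageVersion("unicovex")),
    rVersion = R.version.string,
    config = unclass(config),
    networks = names(nets),
    nGenes = length(geneIds(m)),
    nSamples = length(sampleIds(m)),
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    wallSeconds = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(mutations = m, catalogs = catalogs, covers = covers,
                 consensus = consensus, evaluation = evalReport,
                 outDir = outDir))
}

# Stage wrapper: stderr log with timing; errors rethrown with stage context.
.stage <- function(unit, what, expr) {
  t0 <- Sys.time()
  res <- tryCatch(expr, error = function(e)
    stop("stage '", what, "' failed for ", unit, ": ", conditionMessage(e),
         call. = FALSE))
  message(sprintf("[%s] %s: %.2fs", unit, what,
                  as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  invisible(res)
}

.writeTab <- function(tab, path, cols) {
  if (is.null(tab))
    tab <- stats::setNames(data.frame(matrix(nrow = 0, ncol = length(cols))),
                           cols)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
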