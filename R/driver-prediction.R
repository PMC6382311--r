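# Sample-specific driver-module prediction (greedy minimum set cover per
# module-size group) and consensus calling across networks.

#' Greedy minimum set cover of the cohort by gene modules
#'
#' Classic greedy set cover within one module-size group: in each iteration
#' the module covering the most not-yet-covered samples is chosen (a sample
#' is covered by a module when at least one module gene is mutated in it).
#' Ties are broken by the higher composite score, then by lexicographic
#' gene-set key. The iteration stops when no module adds coverage; samples
#' never covered are reported as uncovered. Every sample is finally assigned
#' all chosen modules that cover it -- its sample-specific driver modules.
#' Greedy covering is biased toward large modules, so sizes are always
#' handled as separate groups; mixing sizes is an error.
#'
#' @param modules list of scored [GeneModule-class]s, all of one size.
#' @param m the [MutationMatrix-class].
#' @param sizeGroup the expected module size; inferred from the modules when
#'   \code{NULL}.
#' @return a [CoverSolution-class].
#' @export
greedySetCover <- function(modules, m, sizeGroup = NULL) {
  stopifnot(is(m, "MutationMatrix"))
  sizes <- unique(vapply(modules, function(x) length(x@genes), integer(1)))
  if (length(sizes) > 1L)
    stop("modules of mixed sizes (", paste(sort(sizes), collapse = ", "),
         "); cover each size group separately", call. = FALSE)
  if (is.null(sizeGroup)) sizeGroup <- if (length(sizes)) sizes else 0L
  if (length(sizes) && sizes != sizeGroup)
    stop("modules have size ", sizes, ", not ", sizeGroup, call. = FALSE)

  covSets <- lapply(modules, function(mod)
    unique(unlist(m@mutatedSamples[mod@genes], use.names = FALSE)))
  keys <- vapply(modules, function(mod) moduleKey(mod@genes), character(1))
  comps <- vapply(modules, function(mod)
    if (is.null(mod@score)) 0 else mod@score@composite, numeric(1))

  covered <- character()
  pickIdx <- integer()
  picks <- data.frame(pickRank = integer(), genes = character(),
                      marginalGain = integer(), cumulativeCoverage = integer())
  remaining <- seq_along(modules)
  while (length(remaining)) {
    gain <- vapply(remaining, function(i)
      length(setdiff(covSets[[i]], covered)), integer(1))
    if (!length(gain) || max(gain) == 0L) break
    best <- remaining[gain == max(gain)]
    if (length(best) > 1L) {
      best <- best[comps[best] == max(comps[best])]
      if (length(best) > 1L) best <- best[order(keys[best])][1L]
    }
    best <- best[1L]
    covered <- union(covered, covSets[[best]])
    pickIdx <- c(pickIdx, best)
    picks <- rbind(picks, data.frame(
      pickRank = length(pickIdx), genes = keys[best],
      marginalGain = max(gain), cumulativeCoverage = length(covered)))
    remaining <- setdiff(remaining, best)
  }
  assignment <- lapply(stats::setNames(nm = sort(covered)), function(s)
    keys[pickIdx][vapply(pickIdx, function(i) s %in% covSets[[i]], logical(1))])
  new("CoverSolution",
      sizeGroup = as.integer(sizeGroup),
      modules = modules[pickIdx],
      picks = picks,
      sampleAssignment = assignment,
      uncovered = setdiff(m@sampleIds, covered))
}

#' Consensus modules across influence networks
#'
#' Calls final predictions as the modules supported by at least
#' \code{minSupport} networks. Under \code{"exact"} agreement a module's
#' gene set must appear identically in that many networks. Under
#' \code{"jaccard"} agreement, modules from different networks are merged
#' (single linkage) whenever their gene-set Jaccard index reaches
#' \code{jaccardThreshold}, and a merged group counts the distinct networks
#' it spans; the representative of a group is its highest-scoring member.
#'
#' @param catalogs named list (one element per network) of lists of scored
#'   [GeneModule-class]s -- typically the selected modules of each network.
#'   [ModuleCatalog-class] elements are accepted and reduced to their
#'   selected modules (or all modules when none is flagged).
#' @param minSupport minimum number of supporting networks (default 2).
#' @param agreement \code{"exact"} or \code{"jaccard"}.
#' @param jaccardThreshold Jaccard index threshold for merging (default 0.5).
#' @return a [ConsensusSet-class], sorted by best composite score.
#' @export
consensusModules <- function(catalogs, minSupport = 2,
                             agreement = c("exact", "jaccard"),
                             jaccardThreshold = 0.5) {
  agreement <- match.arg(agreement)
  if (length(catalogs) < 2L) stop("need at least 2 network catalogs")
  if (minSupport > length(catalogs))
    stop("minSupport (", minSupport, ") exceeds the number of networks (",
         length(catalogs), ")", call. = FALSE)
  if (is.null(names(catalogs)) || any(!nzchar(names(catalogs))))
    names(catalogs) <- paste0("network", seq_along(catalogs))
  entries <- list()
  for (netName in names(catalogs)) {
    mods <- catalogs[[netName]]
    if (is(mods, "ModuleCatalog")) {
      sel <- mods@table$selected
      idx <- if (any(sel)) which(sel) else seq_along(mods@modules)
      mods <- mods@modules[idx]
    }
    for (mod in mods)
      entries[[length(entries) + 1L]] <- list(module = mod, network = netName)
  }
  if (!length(entries)) return(.emptyConsensus())
  keys <- vapply(entries, function(e) moduleKey(e$module@genes), character(1))
  nets <- vapply(entries, `[[`, character(1), "network")
  comps <- vapply(entries, function(e)
    if (is.null(e$module@score)) 0 else e$module@score@composite, numeric(1))

  if (agreement == "exact") {
    group <- match(keys, unique(keys))
  } else {
    # single-linkage union-find over cross-network pairs with J >= threshold
    geneSets <- lapply(entries, function(e) sort(e$module@genes))
    parent <- seq_along(entries)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    n <- length(entries)
    for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
      if (nets[i] == nets[j] && keys[i] != keys[j]) next
      inter <- length(intersect(geneSets[[i]], geneSets[[j]]))
      uni <- length(union(geneSets[[i]], geneSets[[j]]))
      if (inter / uni >= jaccardThreshold) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
    }
    roots <- vapply(seq_len(n), find, integer(1))
    group <- match(roots, unique(roots))
  }

  rows <- list()
  mods <- list()
  for (g in unique(group)) {
    idx <- which(group == g)
    supNets <- sort(unique(nets[idx]))
    if (length(supNets) < minSupport) next
    rep <- idx[order(-comps[idx], keys[idx])][1L]
    mods[[length(mods) + 1L]] <- entries[[rep]]$module
    rows[[length(rows) + 1L]] <- data.frame(
      genes = keys[rep], size = length(entries[[rep]]$module@genes),
      support = length(supNets), networks = paste(supNets, collapse = ";"),
      bestComposite = comps[rep])
  }
  if (!length(rows)) return(.emptyConsensus())
  tab <- do.call(rbind, rows)
  ord <- order(-tab$bestComposite, tab$genes, method = "radix")
  tab <- tab[ord, , drop = FALSE]
  rownames(tab) <- NULL
  new("ConsensusSet", table = tab, modules = mods[ord])
}

.emptyConsensus <- function() {
  new("ConsensusSet", modules = list(),
      table = data.frame(genes = character(), size = integer(),
                         support = integer(), networks = character(),
                         bestComposite = numeric()))
}

#' Union of genes in a consensus set
#'
#' @param consensus a [ConsensusSet-class].
#' @return sorted character vector of the genes appearing in any consensus
#'   module (the predicted driver genes).
#' @export
consensusGenes <- function(consensus) {
  stopifnot(is(consensus, "ConsensusSet"))
  sort(unique(unlist(lapply(consensus@modules, function(m) m@genes))))
}

#' Write a cover solution as TSV files
#'
#' Writes the pick table (size_group, pick_rank, genes, marginal_gain,
#' cumulative_coverage) and, optionally, the per-sample assignment
#' (sample, size_group, modules).
#'
#' @param cover a [CoverSolution-class].
#' @param path pick-table output path.
#' @param assignmentPath optional assignment output path.
#' @return \code{path}, invisibly.
#' @export
writeCoverSolution <- function(cover, path, assignmentPath = NULL) {
  p <- cover@picks
  out <- data.frame(size_group = rep(cover@sizeGroup, nrow(p)),
                    pick_rank = p$pickRank, genes = p$genes,
                    marginal_gain = p$marginalGain,
                    cumulative_coverage = p$cumulativeCoverage)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(assignmentPath)) {
    a <- cover@sampleAssignment
    out2 <- data.frame(sample = names(a),
                       size_group = rep(cover@sizeGroup, length(a)),
                       modules = vapply(a, paste, "", collapse = "|"))
    utils::write.table(out2, assignmentPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Write a consensus report as TSV
#'
#' @param consensus a [ConsensusSet-class].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeConsensus <- function(consensus, path) {
  tab <- consensus@table
  out <- data.frame(genes = tab$genes, size = tab$size,
                    support = tab$support, networks = tab$networks,
                    best_composite = sprintf("%.10g", tab$bestComposite))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname CoverSolution-class
#' @export
setMethod("chosenModules", "CoverSolution", function(x) x@modules)

#' @rdname CoverSolution-class
#' @export
setMethod("sampleAssignment", "CoverSolution", function(x) x@sampleAssignment)

#' @rdname CoverSolution-class
#' @export
setMethod("uncoveredSamples", "CoverSolution", function(x) x@uncovered)

setMethod("show", "CoverSolution", function(object) {
  cat("CoverSolution (size ", object@sizeGroup, "): ",
      length(object@modules), " modules covering ",
      length(object@sampleAssignment), " samples; ",
      length(object@uncovered), " uncovered\n", sep = "")
})

setMethod("show", "ConsensusSet", function(object) {
  cat("ConsensusSet:", nrow(object@table), "consensus modules,",
      length(consensusGenes(object)), "genes\n")
})
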