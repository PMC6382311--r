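# Candidate module identification: greedy exclusive growth inside local
# networks, catalog assembly, and per-size covering selection.

# Exclusive score and union coverage for a list of per-gene sample-index
# sets (integer indices into the sample universe).
.exUnion <- function(idxSets) {
  counts <- tabulate(unlist(idxSets, use.names = FALSE))
  exCounts <- vapply(idxSets, function(s) sum(counts[s] == 1L), integer(1))
  list(ex = mean(exCounts / lengths(idxSets)), union = sum(counts > 0L))
}

#' Grow candidate modules greedily inside a local network
#'
#' Starting from the local network's center gene, repeatedly adds the pool
#' gene that maximizes the exclusive score Ex of the grown module. Ties on
#' Ex are broken by the larger union coverage of the grown module, then by
#' lexicographic gene symbol (determinism). Growth stops when the module
#' reaches \code{maxSize} or when the best attainable Ex of the grown module
#' falls strictly below \code{exCutoff} (a candidate reaching the cutoff
#' exactly is still added). The candidate pool is restricted to local-network
#' members mutated in at least \code{minRecurrence} samples.
#'
#' The full nested chain of intermediate modules (sizes 2 up to the final
#' size) is returned: sub-modules found along the way are candidate modules
#' in their own right.
#'
#' @param m a [MutationMatrix-class].
#' @param local a [LocalNetwork-class].
#' @param maxSize maximal module size (default 5).
#' @param exCutoff exclusive-score cutoff (default 0.95).
#' @param minRecurrence minimum mutated-sample count for pool genes
#'   (default 2; also applied to the center, which is skipped otherwise).
#' @param network provenance tag stored on the modules.
#' @return list of [GeneModule-class]s of sizes 2..final (possibly empty).
#' @export
growModule <- function(m, local, maxSize = 5, exCutoff = 0.95,
                       minRecurrence = 2, network = "network") {
  stopifnot(is(m, "MutationMatrix"), is(local, "LocalNetwork"), maxSize >= 1)
  center <- local@center
  if (!center %in% m@geneIds) {
    message("skipping center absent from the mutation matrix: ", center)
    return(list())
  }
  counts <- lengths(m@mutatedSamples)
  names(counts) <- m@geneIds
  if (counts[[center]] < minRecurrence) return(list())
  pool <- setdiff(local@members, center)
  pool <- pool[pool %in% m@geneIds]
  pool <- pool[counts[pool] >= minRecurrence]
  idx <- lapply(m@mutatedSamples, match, m@sampleIds)
  module <- center
  chain <- list()
  eps <- 1e-12
  while (length(module) < maxSize && length(pool)) {
    stats <- lapply(pool, function(g) .exUnion(idx[c(module, g)]))
    ex <- vapply(stats, `[[`, numeric(1), "ex")
    best <- max(ex)
    if (best < exCutoff - eps) break
    tied <- which(ex >= best - eps)
    if (length(tied) > 1L) {
      uni <- vapply(stats[tied], `[[`, numeric(1), "union")
      tied <- tied[uni >= max(uni) - eps]
    }
    pick <- sort(pool[tied])[1L]
    module <- c(module, pick)
    pool <- setdiff(pool, pick)
    chain[[length(chain) + 1L]] <- new("GeneModule", genes = module,
                                       center = center, network = network,
                                       score = NULL)
  }
  chain
}

#' Build the candidate-module catalog for one influence network
#'
#' Runs [extractLocalNetwork()] + [growModule()] from every eligible seed
#' gene (every gene present in both the reduced network and the
#' recurrence-filtered mutation matrix), scores every module and sub-module
#' with [unicovexScore()], deduplicates by gene set, and sorts entries
#' within each size by descending composite score (ties by gene-set key).
#'
#' @param m a [MutationMatrix-class] (unfiltered; the recurrence filter is
#'   applied internally so coverage denominators stay cohort-wide).
#' @param net a reduced [InfluenceNetwork-class].
#' @param config a [unicovexConfig()] list (localSize, maxSize, exCutoff,
#'   minRecurrence).
#' @return a [ModuleCatalog-class].
#' @export
buildCatalog <- function(m, net, config = unicovexConfig()) {
  stopifnot(is(m, "MutationMatrix"), is(net, "InfluenceNetwork"))
  mf <- filterMinRecurrence(m, config$minRecurrence)
  seeds <- sort(intersect(net@nodes, mf@geneIds))
  if (!length(seeds)) {
    warning("no eligible seed genes (network and filtered matrix are disjoint)")
    return(.emptyCatalog())
  }
  adj <- .adjacencyList(net)
  seen <- new.env(parent = emptyenv(), hash = TRUE)
  modules <- list()
  for (seed in seeds) {
    members <- .bfsLocal(adj, seed, as.integer(config$localSize))
    local <- new("LocalNetwork", center = seed, members = members,
                 sizeCap = as.integer(config$localSize))
    for (mod in growModule(m, local, maxSize = config$maxSize,
                           exCutoff = config$exCutoff,
                           minRecurrence = config$minRecurrence,
                           network = net@name)) {
      key <- moduleKey(mod@genes)
      if (!exists(key, envir = seen, inherits = FALSE)) {
        assign(key, TRUE, envir = seen)
        modules[[length(modules) + 1L]] <- mod
      }
    }
  }
  if (!length(modules)) return(.emptyCatalog())
  modules <- lapply(modules, function(mod) {
    mod@score <- unicovexScore(m, mod@genes)
    mod
  })
  tab <- do.call(rbind, lapply(modules, function(mod) {
    s <- mod@score
    data.frame(network = mod@network, size = length(mod@genes),
               genes = moduleKey(mod@genes), minCoverage = s@minCoverage,
               unionCoverage = s@unionCoverage, exScore = s@exScore,
               entropy = s@entropy, composite = s@composite,
               dendrixW = s@dendrixW, selected = FALSE)
  }))
  ord <- order(tab$size, -tab$composite, tab$genes, method = "radix")
  tab <- tab[ord, , drop = FALSE]
  rownames(tab) <- NULL
  new("ModuleCatalog", modules = modules[ord], table = tab)
}

.emptyCatalog <- function() {
  new("ModuleCatalog", modules = list(),
      table = data.frame(network = character(), size = integer(),
                         genes = character(), minCoverage = integer(),
                         unionCoverage = integer(), exScore = numeric(),
                         entropy = numeric(), composite = numeric(),
                         dendrixW = integer(), selected = logical()))
}

#' Select high-scoring modules per size until the cohort is covered
#'
#' Independently for each module size s in the catalog, walks the size-s
#' entries by descending composite score and accumulates them until every
#' coverable sample is covered, where a sample is coverable at size s if at
#' least one gene of some size-s catalog module is mutated in it. Samples no
#' size-s module can touch are reported as uncoverable for that size rather
#' than looped on.
#'
#' @param catalog a scored [ModuleCatalog-class].
#' @param m the [MutationMatrix-class] the catalog was built from.
#' @return a list with elements \code{catalog} (the catalog with its
#'   \code{selected} flags filled in), \code{selected} (per-size list of
#'   selected [GeneModule-class]s) and \code{uncoverable} (per-size character
#'   vectors of samples outside the reach of that size class).
#' @export
selectCoveringModules <- function(catalog, m) {
  stopifnot(is(catalog, "ModuleCatalog"), is(m, "MutationMatrix"))
  tab <- catalog@table
  selected <- list()
  uncoverable <- list()
  for (s in sort(unique(tab$size))) {
    rows <- which(tab$size == s)       # already sorted by composite desc
    sizeGenes <- unique(unlist(lapply(catalog@modules[rows],
                                      function(mod) mod@genes)))
    coverable <- unique(unlist(m@mutatedSamples[sizeGenes], use.names = FALSE))
    covered <- character()
    picked <- integer()
    for (r in rows) {
      if (length(setdiff(coverable, covered)) == 0L) break
      picked <- c(picked, r)
      covered <- union(covered,
                       unlist(m@mutatedSamples[catalog@modules[[r]]@genes],
                              use.names = FALSE))
    }
    tab$selected[picked] <- TRUE
    selected[[as.character(s)]] <- catalog@modules[picked]
    uncoverable[[as.character(s)]] <- setdiff(m@sampleIds, coverable)
  }
  catalog@table <- tab
  list(catalog = catalog, selected = selected, uncoverable = uncoverable)
}

#' Write a module catalog as TSV
#'
#' One row per module: network, size, genes, composite, ex, entropy,
#' min_cov, union_cov, dendrix_w, selected_flag.
#'
#' @param catalog a [ModuleCatalog-class].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeCatalog <- function(catalog, path) {
  tab <- catalog@table
  out <- data.frame(network = tab$network, size = tab$size, genes = tab$genes,
                    composite = sprintf("%.10g", tab$composite),
                    ex = sprintf("%.10g", tab$exScore),
                    entropy = sprintf("%.10g", tab$entropy),
                    min_cov = tab$minCoverage, union_cov = tab$unionCoverage,
                    dendrix_w = tab$dendrixW,
                    selected_flag = as.integer(tab$selected))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname GeneModule-class
#' @export
setMethod("moduleGenes", "GeneModule", function(x) x@genes)

#' @rdname GeneModule-class
#' @export
setMethod("moduleScore", "GeneModule", function(x) x@score)

setMethod("show", "GeneModule", function(object) {
  cat("GeneModule {", paste(object@genes, collapse = ", "), "} center=",
      object@center, " network=", object@network,
      if (!is.null(object@score))
        paste0(" composite=", signif(object@score@composite, 6)) else "",
      "\n", sep = "")
})

#' @rdname ModuleCatalog-class
#' @export
setMethod("catalogTable", "ModuleCatalog", function(x) x@table)

#' @rdname ModuleCatalog-class
#' @export
setMethod("catalogModules", "ModuleCatalog", function(x) x@modules)

#' @rdname ModuleCatalog-class
#' @export
setMethod("length", "ModuleCatalog", function(x) length(x@modules))

setMethod("show", "ModuleCatalog", function(object) {
  cat("ModuleCatalog:", length(object@modules), "distinct modules\n")
  if (nrow(object@table)) {
    bySize <- table(object@table$size)
    cat("  sizes:", paste(names(bySize), bySize, sep = ":", collapse = ", "),
        "\n")
  }
})
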