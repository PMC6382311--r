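#' @import methods
NULL

#' Binary somatic mutation matrix
#'
#' A binary gene-by-sample mutation incidence container. Rather than a dense
#' matrix, the data are kept as a gene -> sample-set map: for each gene the
#' set of samples in which it carries at least one somatic mutation.
#' Multiplicity (several variants of a gene in one sample) is collapsed to
#' presence/absence. The sample universe is fixed at construction and is not
#' shrunk by gene filtering, so cohort-wide coverage denominators are stable.
#'
#' @slot geneIds ordered unique gene symbols.
#' @slot sampleIds ordered unique sample identifiers (the cohort universe).
#' @slot mutatedSamples named list, one sorted character vector of sample ids
#'   per gene.
#'
#' @seealso [readMutations()], [filterMinRecurrence()], [exclusivityProfiles()]
#' @export
setClass("MutationMatrix",
  representation(
    geneIds = "character",
    sampleIds = "character",
    mutatedSamples = "list"
  )
)

setValidity("MutationMatrix", function(object) {
  msg <- character()
  if (anyDuplicated(object@geneIds)) msg <- c(msg, "duplicated gene ids")
  if (anyDuplicated(object@sampleIds)) msg <- c(msg, "duplicated sample ids")
  if (!identical(names(object@mutatedSamples), object@geneIds))
    msg <- c(msg, "mutatedSamples must be named by geneIds, in order")
  bad <- vapply(object@mutatedSamples, function(s) {
    anyDuplicated(s) > 0L || !all(s %in% object@sampleIds)
  }, logical(1))
  if (any(bad))
    msg <- c(msg, paste0("mutated sample sets not unique subsets of sampleIds for: ",
                         paste(object@geneIds[bad], collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Weighted gene influence network
#'
#' An undirected, weighted gene-gene graph whose edge weights quantify
#' topological influence (e.g. diffusion scores derived from a
#' protein-protein interaction network). Edges are stored canonically with
#' \code{geneA < geneB}, so there are no duplicate undirected edges and no
#' self-loops.
#'
#' @slot nodes gene symbols.
#' @slot edges data.frame with columns \code{geneA}, \code{geneB},
#'   \code{weight} (finite, non-negative).
#' @slot name provenance tag for the network (e.g. source PPI network).
#'
#' @seealso [readInfluenceNetwork()], [reduceToAverageDegree()],
#'   [extractLocalNetwork()], [diffuseInfluence()]
#' @export
setClass("InfluenceNetwork",
  representation(
    nodes = "character",
    edges = "data.frame",
    name = "character"
  )
)

setValidity("InfluenceNetwork", function(object) {
  msg <- character()
  e <- object@edges
  if (!all(c("geneA", "geneB", "weight") %in% names(e)))
    return("edges must have columns geneA, geneB, weight")
  if (anyDuplicated(object@nodes)) msg <- c(msg, "duplicated nodes")
  if (nrow(e)) {
    if (any(e$geneA == e$geneB)) msg <- c(msg, "self-loops not allowed")
    if (any(e$geneA > e$geneB)) msg <- c(msg, "edges must be stored with geneA < geneB")
    if (anyDuplicated(paste(e$geneA, e$geneB, sep = "\r")))
      msg <- c(msg, "duplicate undirected edges")
    if (any(!is.finite(e$weight)) || any(e$weight < 0))
      msg <- c(msg, "weights must be finite and >= 0")
    if (!all(c(e$geneA, e$geneB) %in% object@nodes))
      msg <- c(msg, "edge endpoints must be nodes")
  }
  if (length(msg)) msg else TRUE
})

#' Local neighborhood of an influence network
#'
#' The breadth-first neighborhood of a center gene in a reduced influence
#' network, truncated at a maximal number of genes. Members are listed in BFS
#' discovery order with the center first; within each BFS step neighbors are
#' visited by descending edge weight from the discovering node, with
#' lexicographic gene order as the final tie-break, so extraction is fully
#' deterministic.
#'
#' @slot center the seed gene.
#' @slot members genes in discovery order (center first).
#' @slot sizeCap the maximal number of genes requested.
#'
#' @export
setClass("LocalNetwork",
  representation(
    center = "character",
    members = "character",
    sizeCap = "integer"
  )
)

setValidity("LocalNetwork", function(object) {
  msg <- character()
  if (length(object@center) != 1L) msg <- c(msg, "center must be a single gene")
  if (!length(object@members) || object@members[1L] != object@center)
    msg <- c(msg, "members must start with the center")
  if (anyDuplicated(object@members)) msg <- c(msg, "duplicated members")
  if (length(object@members) > object@sizeCap)
    msg <- c(msg, "more members than the size cap")
  if (length(msg)) msg else TRUE
})

#' Evaluation scores of a gene module
#'
#' Holds all evaluation quantities for one gene module M of size s: the
#' exclusive score Ex(M) (mean over genes of the fraction of a gene's mutated
#' samples where no other module gene is mutated), the exclusive entropy H(M)
#' in bits (Shannon entropy of the distribution of exclusively mutated
#' samples across module genes), the minimum and union per-gene coverages,
#' and the composite score cov(M) * Ex(M) * H(M) used to rank modules, where
#' cov(M) is the minimum per-gene coverage. The Dendrix weight
#' W(M) = 2|union| - sum|P_i| is carried for comparison only.
#'
#' @slot genes the module genes.
#' @slot exScore Ex(M) in [0, 1].
#' @slot entropy H(M) in bits, in [0, log2 s].
#' @slot minCoverage minimum per-gene coverage, in samples.
#' @slot unionCoverage number of samples with >= 1 module gene mutated.
#' @slot exclusiveTotal n', the number of samples with exactly one module
#'   gene mutated.
#' @slot ratios p_i = n'_i / n' per gene (empty-sum convention: all 0 when
#'   n' = 0).
#' @slot composite cov(M) * Ex(M) * H(M).
#' @slot dendrixW Dendrix weight (samples).
#'
#' @seealso [unicovexScore()]
#' @export
setClass("ModuleScore",
  representation(
    genes = "character",
    exScore = "numeric",
    entropy = "numeric",
    minCoverage = "integer",
    unionCoverage = "integer",
    exclusiveTotal = "integer",
    ratios = "numeric",
    composite = "numeric",
    dendrixW = "integer"
  )
)

#' A candidate driver gene module
#'
#' An ordered gene set produced by the greedy growth procedure. The order is
#' the greedy insertion order, so \code{genes[1]} is the seed (center) gene
#' of the local network the module was grown in.
#'
#' @slot genes module genes in insertion order.
#' @slot center the seed gene.
#' @slot network provenance tag of the influence network.
#' @slot score a [ModuleScore-class] once evaluated, otherwise \code{NULL}.
#'
#' @seealso [growModule()], [buildCatalog()]
#' @export
setClass("GeneModule",
  representation(
    genes = "character",
    center = "character",
    network = "character",
    score = "ANY"
  )
)

setValidity("GeneModule", function(object) {
  msg <- character()
  if (anyDuplicated(object@genes)) msg <- c(msg, "duplicated genes")
  if (length(object@genes) && object@genes[1L] != object@center)
    msg <- c(msg, "genes[1] must be the center")
  if (length(msg)) msg else TRUE
})

#' Catalog of distinct scored candidate modules
#'
#' All distinct candidate modules of sizes 2..maxSize discovered across the
#' local networks of one influence network, deduplicated by gene set and
#' sorted within each size by descending composite score (ties by
#' lexicographic gene-set key, for determinism).
#'
#' @slot modules list of [GeneModule-class] objects, in table order.
#' @slot table data.frame with one row per module: network, size, genes
#'   (semicolon-joined sorted symbols), minCoverage, unionCoverage, exScore,
#'   entropy, composite, dendrixW, selected.
#'
#' @seealso [buildCatalog()], [selectCoveringModules()]
#' @export
setClass("ModuleCatalog",
  representation(
    modules = "list",
    table = "data.frame"
  )
)

setValidity("ModuleCatalog", function(object) {
  if (length(object@modules) != nrow(object@table))
    return("modules and table out of step")
  if (anyDuplicated(object@table$genes))
    return("catalog contains duplicate gene sets")
  TRUE
})

#' Greedy set-cover solution for one module-size group
#'
#' The result of greedily covering the cohort with candidate modules of a
#' single size: the pick order (by decreasing marginal sample coverage), the
#' per-sample assignment of covering modules (the sample-specific driver
#' modules), and the samples no module of this size can cover.
#'
#' @slot sizeGroup the module size s.
#' @slot modules chosen [GeneModule-class]s in pick order.
#' @slot picks data.frame: pickRank, genes, marginalGain, cumulativeCoverage.
#' @slot sampleAssignment named list mapping each covered sample to the
#'   gene-set keys of the chosen modules with >= 1 gene mutated in it.
#' @slot uncovered samples not covered by any module of this size.
#'
#' @seealso [greedySetCover()]
#' @export
setClass("CoverSolution",
  representation(
    sizeGroup = "integer",
    modules = "list",
    picks = "data.frame",
    sampleAssignment = "list",
    uncovered = "character"
  )
)

#' Consensus modules across influence networks
#'
#' Modules supported by at least \code{minSupport} networks, under either
#' exact gene-set identity or Jaccard-merged agreement. Each consensus entry
#' is represented by its highest-scoring member module.
#'
#' @slot table data.frame: genes, size, support, networks (semicolon-joined),
#'   bestComposite.
#' @slot modules list of representative [GeneModule-class]s, in table order.
#'
#' @seealso [consensusModules()]
#' @export
setClass("ConsensusSet",
  representation(
    table = "data.frame",
    modules = "list"
  )
)

#' A simulated cohort with planted driver modules
#'
#' A synthetic mutation matrix plus influence network with known ground
#' truth: a set of planted mutually exclusive modules, a long-tailed
#' passenger mutation background, and the generator parameters (including
#' the seed) needed to regenerate it exactly.
#'
#' @slot mutations a [MutationMatrix-class].
#' @slot network an [InfluenceNetwork-class] in which every planted module is
#'   wired as a connected subgraph.
#' @slot truthModules list of planted gene sets (character vectors).
#' @slot params the generator parameters, seed included.
#'
#' @seealso [generatePlantedCohort()], [recoveryHarness()]
#' @export
setClass("PlantedCohort",
  representation(
    mutations = "MutationMatrix",
    network = "InfluenceNetwork",
    truthModules = "list",
    params = "list"
  )
)
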