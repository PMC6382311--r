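# Planted-module cohort simulator: mutation cohorts and influence networks
# with known ground truth, for validating every pipeline stage offline.

#' Simulate a cohort with planted mutually exclusive driver modules
#'
#' Generates a binary mutation matrix plus an influence network with known
#' truth modules. Samples are partitioned into contiguous blocks, one per
#' planted module; within its block each covered sample mutates exactly one
#' module gene, drawn from a configurable balance distribution (uniform
#' weights give a balanced exclusive module, skewed weights an unbalanced
#' one). An exclusivity leak adds a second module gene to a covered sample
#' with probability \code{epsilon}. Passenger mutations follow a long-tailed
#' (power-law) per-gene frequency profile, emulating the rare-mutation tail
#' of real cohorts. The network wires every truth module as a clique with
#' heavy weights and adds random decoy edges with light weights.
#'
#' With \code{allocation = "deterministic"} the per-gene exclusive counts
#' are apportioned exactly (largest remainder) rather than sampled, so
#' entropy and exclusivity worked examples are exact rather than stochastic.
#'
#' @param nSamples cohort size (default 120).
#' @param nGenes total genes, planted plus passenger (default 60).
#' @param nModules number of planted modules (default 3).
#' @param moduleSize genes per planted module (default 4).
#' @param moduleCoverage fraction of a module's sample block that is covered
#'   by the module (default 1).
#' @param balance \code{"uniform"} or a numeric weight vector of length
#'   \code{moduleSize} giving each gene's share of the exclusive coverage.
#' @param allocation \code{"sampled"} or \code{"deterministic"} assignment
#'   of covered samples to module genes.
#' @param epsilon exclusivity leak rate in [0, 1] (default 0).
#' @param passengerRate per-sample mutation probability of the most frequent
#'   passenger gene (default 0.05).
#' @param powerLawExponent decay exponent of the passenger frequency profile
#'   (default 2; frequency of the r-th passenger is
#'   \code{passengerRate * r^-powerLawExponent}).
#' @param edgeProb probability of a decoy network edge (default 0.05).
#' @param separateComponents when \code{TRUE}, passenger genes are split
#'   round-robin across the modules and decoy edges are confined within
#'   each module's component, giving one graph component per module.
#' @param seed mandatory RNG seed; the same seed regenerates the identical
#'   cohort.
#' @return a [PlantedCohort-class].
#' @examples
#' cohort <- generatePlantedCohort(nSamples = 24, nGenes = 12, nModules = 1,
#'                                 moduleSize = 4, seed = 7)
#' truthModules(cohort)
#' @export
generatePlantedCohort <- function(nSamples = 120, nGenes = 60, nModules = 3,
                                  moduleSize = 4, moduleCoverage = 1,
                                  balance = "uniform",
                                  allocation = c("sampled", "deterministic"),
                                  epsilon = 0, passengerRate = 0.05,
                                  powerLawExponent = 2, edgeProb = 0.05,
                                  separateComponents = FALSE, seed) {
  allocation <- match.arg(allocation)
  if (missing(seed)) stop("a seed is mandatory for reproducibility")
  stopifnot(nSamples >= 1, nGenes >= 1, nModules >= 1, moduleSize >= 1,
            moduleCoverage >= 0, moduleCoverage <= 1,
            epsilon >= 0, epsilon <= 1,
            passengerRate >= 0, passengerRate <= 1, edgeProb >= 0,
            edgeProb <= 1)
  if (nModules * moduleSize > nGenes)
    stop("planted modules need ", nModules * moduleSize,
         " genes but nGenes = ", nGenes, call. = FALSE)
  if (identical(balance, "uniform")) balance <- rep(1, moduleSize)
  stopifnot(is.numeric(balance), length(balance) == moduleSize,
            all(balance > 0))
  weights <- balance / sum(balance)
  set.seed(seed)

  digits <- max(3L, nchar(nGenes))
  genes <- sprintf(paste0("g%0", digits, "d"), seq_len(nGenes))
  samples <- sprintf(paste0("S%0", max(3L, nchar(nSamples)), "d"),
                     seq_len(nSamples))
  truth <- split(genes[seq_len(nModules * moduleSize)],
                 rep(seq_len(nModules), each = moduleSize))
  truth <- lapply(truth, as.character)
  names(truth) <- paste0("module", seq_len(nModules))
  passengers <- genes[-seq_len(nModules * moduleSize)]

  blocks <- split(samples,
                  rep(seq_len(nModules),
                      each = ceiling(nSamples / nModules))[seq_len(nSamples)])
  pairGene <- character()
  pairSample <- character()
  for (k in seq_len(nModules)) {
    block <- blocks[[k]]
    covered <- block[seq_len(round(moduleCoverage * length(block)))]
    nCov <- length(covered)
    if (!nCov) next
    if (allocation == "deterministic") {
      quota <- floor(weights * nCov)
      rem <- nCov - sum(quota)
      if (rem > 0) {
        frac <- weights * nCov - quota
        quota[order(-frac, seq_along(frac))[seq_len(rem)]] <-
          quota[order(-frac, seq_along(frac))[seq_len(rem)]] + 1L
      }
      geneOf <- rep(seq_len(moduleSize), times = quota)
    } else {
      geneOf <- sample.int(moduleSize, nCov, replace = TRUE, prob = weights)
    }
    pairGene <- c(pairGene, truth[[k]][geneOf])
    pairSample <- c(pairSample, covered)
    if (epsilon > 0) {
      leak <- stats::runif(nCov) < epsilon
      if (any(leak)) {
        second <- vapply(geneOf[leak], function(i)
          sample(setdiff(seq_len(moduleSize), i), 1L), integer(1))
        pairGene <- c(pairGene, truth[[k]][second])
        pairSample <- c(pairSample, covered[leak])
      }
    }
  }
  if (length(passengers)) {
    rate <- passengerRate * seq_along(passengers)^(-powerLawExponent)
    for (r in seq_along(passengers)) {
      hit <- stats::runif(nSamples) < rate[r]
      if (any(hit)) {
        pairGene <- c(pairGene, rep(passengers[r], sum(hit)))
        pairSample <- c(pairSample, samples[hit])
      }
    }
  }
  mat <- MutationMatrix(gene = pairGene, sample = pairSample,
                        samples = samples)

  component <- rep(1L, nGenes)
  names(component) <- genes
  for (k in seq_len(nModules)) component[truth[[k]]] <- k
  if (separateComponents && length(passengers))
    component[passengers] <- rep(seq_len(nModules),
                                 length.out = length(passengers))
  edgeA <- character(); edgeB <- character(); edgeW <- numeric()
  for (k in seq_len(nModules)) {
    pairs <- utils::combn(truth[[k]], 2)
    edgeA <- c(edgeA, pairs[1, ])
    edgeB <- c(edgeB, pairs[2, ])
    edgeW <- c(edgeW, stats::runif(ncol(pairs), 0.7, 1))
  }
  inModule <- unlist(truth, use.names = FALSE)
  moduleOf <- rep(NA_integer_, nGenes)
  names(moduleOf) <- genes
  for (k in seq_len(nModules)) moduleOf[truth[[k]]] <- k
  allPairs <- utils::combn(genes, 2)
  sameModule <- !is.na(moduleOf[allPairs[1, ]]) &
    !is.na(moduleOf[allPairs[2, ]]) &
    moduleOf[allPairs[1, ]] == moduleOf[allPairs[2, ]]
  eligible <- !sameModule
  if (separateComponents)
    eligible <- eligible & component[allPairs[1, ]] == component[allPairs[2, ]]
  pick <- eligible & stats::runif(ncol(allPairs)) < edgeProb
  if (any(pick)) {
    edgeA <- c(edgeA, allPairs[1, pick])
    edgeB <- c(edgeB, allPairs[2, pick])
    edgeW <- c(edgeW, stats::runif(sum(pick), 0.05, 0.5))
  }
  net <- InfluenceNetwork(
    data.frame(geneA = edgeA, geneB = edgeB, weight = round(edgeW, 6)),
    name = "planted", nodes = genes)

  new("PlantedCohort", mutations = mat, network = net, truthModules = truth,
      params = list(nSamples = nSamples, nGenes = nGenes,
                    nModules = nModules, moduleSize = moduleSize,
                    moduleCoverage = moduleCoverage, balance = weights,
                    allocation = allocation, epsilon = epsilon,
                    passengerRate = passengerRate,
                    powerLawExponent = powerLawExponent,
                    edgeProb = edgeProb,
                    separateComponents = separateComponents, seed = seed))
}

#' Run the discovery pipeline on a planted cohort and score recovery
#'
#' Reduces the cohort's network, builds the candidate-module catalog, and
#' measures how well the planted truth modules are recovered: per-module
#' exact-recovery flags and best gene-set Jaccard against any catalog entry,
#' plus gene-level precision/recall of the catalog's top-k size-matched
#' modules (k = number of truth modules) against the union of planted genes.
#'
#' @param cohort a [PlantedCohort-class].
#' @param config a [unicovexConfig()] list.
#' @return a list: \code{perModule} data.frame (module, genes, exact,
#'   bestJaccard), \code{allExact}, \code{meanBestJaccard},
#'   \code{genePrecision}, \code{geneRecall}, and the \code{catalog}.
#' @export
recoveryHarness <- function(cohort, config = unicovexConfig()) {
  stopifnot(is(cohort, "PlantedCohort"), length(cohort@truthModules) >= 1)
  net <- reduceToAverageDegree(cohort@network, config$targetAvgDegree)
  catalog <- buildCatalog(cohort@mutations, net, config)
  tab <- catalog@table
  catKeys <- tab$genes
  catSets <- lapply(catalog@modules, function(mod) sort(mod@genes))
  perModule <- do.call(rbind, lapply(names(cohort@truthModules), function(nm) {
    t <- sort(cohort@truthModules[[nm]])
    jac <- if (length(catSets)) {
      max(vapply(catSets, function(s)
        length(intersect(s, t)) / length(union(s, t)), numeric(1)))
    } else 0
    data.frame(module = nm, genes = moduleKey(t),
               exact = moduleKey(t) %in% catKeys, bestJaccard = jac)
  }))
  k <- length(cohort@truthModules)
  truthSizes <- unique(lengths(cohort@truthModules))
  pool <- if (length(truthSizes) == 1L) which(tab$size == truthSizes) else
    seq_len(nrow(tab))
  topIdx <- pool[utils::head(order(-tab$composite[pool], tab$genes[pool],
                                   method = "radix"), k)]
  predGenes <- unique(unlist(lapply(catalog@modules[topIdx],
                                    function(mod) mod@genes)))
  truthGenes <- unique(unlist(cohort@truthModules, use.names = FALSE))
  list(perModule = perModule,
       allExact = all(perModule$exact),
       meanBestJaccard = mean(perModule$bestJaccard),
       genePrecision = if (length(predGenes))
         length(intersect(predGenes, truthGenes)) / length(predGenes) else 0,
       geneRecall = length(intersect(predGenes, truthGenes)) /
         length(truthGenes),
       catalog = catalog)
}

#' Write a planted cohort to disk
#'
#' Writes the mutation matrix (tsv_pairs), the network (edge-list TSV) and
#' a ground-truth JSON (truth modules plus generator parameters).
#'
#' @param cohort a [PlantedCohort-class].
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeMutations(cohort@mutations, file.path(dir, "mutations.tsv"))
  writeInfluenceNetwork(cohort@network, file.path(dir, "network.tsv"))
  jsonlite::write_json(list(truthModules = cohort@truthModules,
                            params = cohort@params),
                       file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname PlantedCohort-class
#' @export
setMethod("truthModules", "PlantedCohort", function(x) x@truthModules)

setMethod("show", "PlantedCohort", function(object) {
  cat("PlantedCohort:", length(object@truthModules), "planted modules;",
      length(object@mutations@geneIds), "genes x",
      length(object@mutations@sampleIds), "samples; seed",
      object@params$seed, "\n")
})
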