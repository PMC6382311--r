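# Fixtures and independent brute-force oracles used across the suite.

# Random binary mutation matrix with a fixed seed.
randomMatrix <- function(nGenes, nSamples, p = 0.25, seed) {
  set.seed(seed)
  genes <- sprintf("g%02d", seq_len(nGenes))
  samples <- sprintf("s%02d", seq_len(nSamples))
  hits <- which(matrix(runif(nGenes * nSamples) < p, nGenes, nSamples),
                arr.ind = TRUE)
  MutationMatrix(gene = genes[hits[, 1]], sample = samples[hits[, 2]],
                 samples = samples)
}

# Per-sample enumeration oracle for exclusivity: for every sample count the
# mutated module genes; EP_i is the set where gene i is the only one.
bruteProfiles <- function(m, module) {
  samples <- sampleIds(m)
  sets <- mutatedSamples(m)[module]
  hitCount <- vapply(samples, function(s)
    sum(vapply(sets, function(p) s %in% p, logical(1))), integer(1))
  lapply(module, function(g)
    samples[hitCount == 1L & samples %in% sets[[g]]])
}

bruteEx <- function(m, module) {
  ep <- bruteProfiles(m, module)
  n <- lengths(mutatedSamples(m)[module])
  mean(lengths(ep) / n)
}

bruteEntropy <- function(m, module) {
  counts <- lengths(bruteProfiles(m, module))
  tot <- sum(counts)
  if (tot == 0) return(0)
  p <- counts[counts > 0] / tot
  -sum(p * log2(p))
}

bruteDendrix <- function(m, module) {
  samples <- sampleIds(m)
  sets <- mutatedSamples(m)[module]
  hitCount <- vapply(samples, function(s)
    sum(vapply(sets, function(p) s %in% p, logical(1))), integer(1))
  covered <- sum(hitCount > 0)
  extra <- sum(pmax(hitCount - 1L, 0L))
  covered - extra
}

# Exhaustive minimum set cover: smallest number of sets whose union covers
# everything coverable. Returns the optimal size.
bruteSetCoverOpt <- function(covSets) {
  coverable <- sort(unique(unlist(covSets)))
  n <- length(covSets)
  for (k in seq_len(n)) {
    combos <- utils::combn(n, k, simplify = FALSE)
    for (cm in combos)
      if (setequal(sort(unique(unlist(covSets[cm]))), coverable))
        return(k)
  }
  0L
}

# Independent BFS with the package's tie-break contract (descending edge
# weight from the discovering node, then lexicographic), written against
# a plain edge data.frame rather than the package's adjacency structure.
referenceBFS <- function(edges, center, maxGenes) {
  nbrs <- function(u) {
    e <- edges[edges$geneA == u | edges$geneB == u, , drop = FALSE]
    v <- ifelse(e$geneA == u, e$geneB, e$geneA)
    v[order(-e$weight, v)]
  }
  out <- center
  queue <- center
  while (length(queue) && length(out) < maxGenes) {
    u <- queue[1]
    queue <- queue[-1]
    for (v in nbrs(u)) {
      if (!(v %in% out)) {
        out <- c(out, v)
        queue <- c(queue, v)
        if (length(out) == maxGenes) break
      }
    }
  }
  out
}

# A tiny module list for set-cover tests: each module is a fake GeneModule
# over the given genes, scored on the matrix.
makeModules <- function(m, geneSets, network = "test") {
  lapply(geneSets, function(g) {
    mod <- new("GeneModule", genes = g, center = g[1], network = network,
               score = unicovexScore(m, g))
    mod
  })
}

# Matrix where each listed gene is mutated in an explicit sample set.
matrixFromSets <- function(sets, samples = NULL) {
  gene <- rep(names(sets), lengths(sets))
  sample <- unlist(sets, use.names = FALSE)
  MutationMatrix(gene = gene, sample = sample,
                 samples = if (is.null(samples)) character() else samples)
}
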