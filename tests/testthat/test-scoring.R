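test_that("exclusive degree is the exclusive fraction of mutated samples", {
  m <- matrixFromSets(list(a = paste0("s", 1:4),
                           b = paste0("s", 1:5),
                           c = c("s1", "s2", "s9", "s10")))
  # a alone: fully exclusive
  expect_equal(unname(exclusiveDegree(exclusivityProfiles(m, "a"))), 1)
  # a vs b: a fully overlapped -> 0
  expect_equal(exclusiveDegree(exclusivityProfiles(m, c("a", "b")))[["a"]], 0)
  # a vs c: shares s1,s2 -> 2/4, cross-checked per sample
  deg <- exclusiveDegree(exclusivityProfiles(m, c("a", "c")))
  expect_equal(deg[["a"]], 0.5)
  expect_equal(deg[["a"]],
               lengths(bruteProfiles(m, c("a", "c")))[1] / 4,
               ignore_attr = TRUE)
  # undefined for a gene with no mutated samples
  m0 <- new("MutationMatrix", geneIds = "z", sampleIds = "s1",
            mutatedSamples = list(z = character()))
  expect_error(exclusiveDegree(exclusivityProfiles(m0, "z")), "zero")
})

test_that("exclusive score is the mean degree, 1 iff pairwise disjoint", {
  disjoint <- matrixFromSets(list(a = c("s1", "s2"), b = c("s3", "s4"),
                                  c = "s5"))
  expect_equal(exclusiveScore(disjoint, c("a", "b", "c")), 1)
  dup <- matrixFromSets(list(a = c("s1", "s2"), b = c("s1", "s2")))
  expect_equal(exclusiveScore(dup, c("a", "b")), 0)
  for (seed in 1:8) {
    r <- randomMatrix(6, 8, p = 0.3, seed = seed)
    module <- geneIds(r)[1:3]
    expect_equal(exclusiveScore(r, module), bruteEx(r, module))
    sets <- mutatedSamples(r)[module]
    pairwiseDisjoint <- all(combn(3, 2, function(ij)
      length(intersect(sets[[ij[1]]], sets[[ij[2]]])) == 0))
    expect_equal(exclusiveScore(r, module) == 1, pairwiseDisjoint)
  }
})

test_that("exclusive entropy reproduces the balanced and skewed examples", {
  balanced <- matrixFromSets(list(g1 = c("s1", "s2"), g2 = c("s3", "s4"),
                                  g3 = c("s5", "s6"), g4 = c("s7", "s8")))
  expect_equal(exclusiveEntropy(balanced, paste0("g", 1:4)), 2.0)
  skewed <- matrixFromSets(list(g1 = paste0("s", 1:4), g2 = c("s5", "s6"),
                                g3 = "s7", g4 = "s8"))
  expect_equal(exclusiveEntropy(skewed, paste0("g", 1:4)), 1.75)
  # singleton module carries no balance information
  expect_equal(exclusiveEntropy(balanced, "g1"), 0)
  # no exclusive sample at all
  dup <- matrixFromSets(list(a = c("s1", "s2"), b = c("s1", "s2")))
  expect_equal(exclusiveEntropy(dup, c("a", "b")), 0)
  # random modules vs per-sample enumeration oracle
  for (seed in 1:8) {
    r <- randomMatrix(7, 9, p = 0.35, seed = seed + 100)
    module <- geneIds(r)[2:5]
    expect_equal(exclusiveEntropy(r, module), bruteEntropy(r, module))
  }
})

test_that("entropy is maximal exactly at equal exclusive counts", {
  # all compositions of n' = 8 into 4 labelled non-negative parts
  H <- function(counts) {
    p <- counts[counts > 0] / sum(counts)
    -sum(p * log2(p))
  }
  best <- -Inf
  argmax <- NULL
  for (a in 0:8) for (b in 0:(8 - a)) for (c in 0:(8 - a - b)) {
    counts <- c(a, b, c, 8 - a - b - c)
    h <- H(counts)
    if (h > best + 1e-12) {
      best <- h
      argmax <- list(counts)
    } else if (abs(h - best) <= 1e-12) argmax <- c(argmax, list(counts))
  }
  expect_equal(best, 2)
  expect_equal(argmax, list(c(2, 2, 2, 2)))
})

test_that("coverage summaries take the minimum and the union", {
  m <- matrixFromSets(list(a = paste0("s", 1:7), b = paste0("s", 8:10),
                           c = paste0("s", 11:15)))
  expect_equal(minCoverage(m, c("a", "b", "c")), 3L)
  expect_equal(unionCoverage(m, c("a", "b", "c")), 15L)
  expect_equal(minCoverage(m, "a"), 7L)
  for (seed in 1:5) {
    r <- randomMatrix(6, 10, p = 0.3, seed = seed + 30)
    module <- geneIds(r)[1:4]
    expect_equal(minCoverage(r, module),
                 min(lengths(mutatedSamples(r)[module])))
  }
})

test_that("Dendrix weight is coverage minus coverage overlap", {
  # strictly exclusive module covering 6 samples
  m <- matrixFromSets(list(a = c("s1", "s2"), b = c("s3", "s4"),
                           c = c("s5", "s6")))
  expect_equal(dendrixWeight(m, c("a", "b", "c")), 6L)
  # full overlap cancels out
  dup <- matrixFromSets(list(a = paste0("s", 1:3), b = paste0("s", 1:3)))
  expect_equal(dendrixWeight(dup, c("a", "b")), 0L)
  for (seed in 1:8) {
    r <- randomMatrix(5, 9, p = 0.35, seed = seed + 60)
    module <- geneIds(r)[1:3]
    expect_equal(dendrixWeight(r, module), bruteDendrix(r, module))
  }
})

test_that("the composite score multiplies coverage, exclusivity, entropy", {
  m <- matrixFromSets(list(g1 = c("s1", "s2"), g2 = c("s3", "s4"),
                           g3 = c("s5", "s6"), g4 = c("s7", "s8")))
  sc <- unicovexScore(m, paste0("g", 1:4))
  expect_equal(sc@minCoverage, 2L)
  expect_equal(sc@exScore, 1)
  expect_equal(sc@entropy, 2)
  expect_equal(compositeScore(sc), 4)
  expect_equal(sum(sc@ratios), 1)
  # total overlap: Ex = 0 forces composite 0
  dup <- matrixFromSets(list(a = c("s1", "s2"), b = c("s1", "s2")))
  expect_equal(compositeScore(unicovexScore(dup, c("a", "b"))), 0)
  # singletons always score 0 (H = 0)
  expect_equal(compositeScore(unicovexScore(m, "g1")), 0)
})

test_that("scores are invariant under gene order and sample labels", {
  r <- randomMatrix(6, 9, p = 0.3, seed = 77)
  module <- geneIds(r)[1:4]
  s1 <- unicovexScore(r, module)
  s2 <- unicovexScore(r, rev(module))
  expect_equal(compositeScore(s1), compositeScore(s2))
  expect_equal(s1@entropy, s2@entropy)
  # relabel samples bijectively
  relabel <- setNames(sprintf("t%02d", seq_along(sampleIds(r))), sampleIds(r))
  r2 <- matrixFromSets(lapply(mutatedSamples(r), function(s)
    unname(relabel[s])), samples = unname(relabel))
  s3 <- unicovexScore(r2, module)
  expect_equal(compositeScore(s3), compositeScore(s1))
})

test_that("a sample hitting two module genes never raises Ex", {
  for (seed in 1:10) {
    r <- randomMatrix(5, 8, p = 0.3, seed = seed + 200)
    module <- geneIds(r)[1:3]
    before <- exclusiveScore(r, module)
    # add a fresh sample mutated in two module genes
    sets <- mutatedSamples(r)
    sets[[module[1]]] <- c(sets[[module[1]]], "sx")
    sets[[module[2]]] <- c(sets[[module[2]]], "sx")
    r2 <- matrixFromSets(sets, samples = c(sampleIds(r), "sx"))
    expect_lte(exclusiveScore(r2, module), before + 1e-12)
  }
})
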