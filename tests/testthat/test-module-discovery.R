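# Greedy exclusive growth and catalog assembly.

# A local network whose member list is simply the given pool.
poolLocal <- function(center, pool, cap = 100L) {
  new("LocalNetwork", center = center, members = c(center, pool),
      sizeCap = as.integer(cap))
}

test_that("greedy growth recovers a planted exclusive module", {
  # planted strictly exclusive triple around the center; decoys overlap it
  sets <- list(ctr = paste0("s", 1:4), p1 = paste0("s", 5:8),
               p2 = paste0("s", 9:12),
               d1 = c("s1", "s5", "s9"),        # overlaps everything
               d2 = c("s2", "s6", "s13"),
               d3 = c("s3", "s7"))
  m <- matrixFromSets(sets, samples = paste0("s", 1:14))
  chain <- growModule(m, poolLocal("ctr", c("p1", "p2", "d1", "d2", "d3")),
                      maxSize = 3, exCutoff = 0.95)
  final <- chain[[length(chain)]]
  expect_equal(sort(moduleGenes(final)), c("ctr", "p1", "p2"))
  # exhaustive confirmation: the planted triple is the best Ex among all
  # center-containing subsets of size 3
  pool <- c("p1", "p2", "d1", "d2", "d3")
  combos <- combn(pool, 2, simplify = FALSE)
  exAll <- vapply(combos, function(gs) exclusiveScore(m, c("ctr", gs)),
                  numeric(1))
  expect_equal(max(exAll), exclusiveScore(m, moduleGenes(final)))
})

test_that("growth stops immediately when no admissible extension exists", {
  m <- matrixFromSets(list(ctr = c("s1", "s2"), a = c("s1", "s2"),
                           b = c("s1", "s2")))
  expect_equal(growModule(m, poolLocal("ctr", c("a", "b")),
                          maxSize = 5, exCutoff = 0.95),
               list())
})

test_that("with no cutoff the best pair is chosen by (Ex, coverage, name)", {
  sets <- list(ctr = c("s1", "s2", "s3"),
               a = c("s4", "s5"),                  # Ex 1, union 5
               b = c("s4", "s5", "s6", "s7"),      # Ex 1, union 7 -> wins
               c = c("s1", "s4", "s5", "s6", "s7"))  # overlap, Ex < 1
  m <- matrixFromSets(sets)
  chain <- growModule(m, poolLocal("ctr", c("a", "b", "c")),
                      maxSize = 2, exCutoff = 0)
  expect_length(chain, 1L)
  expect_equal(moduleGenes(chain[[1]]), c("ctr", "b"))
  # enumeration oracle over all pairs
  pool <- c("a", "b", "c")
  ex <- vapply(pool, function(g) exclusiveScore(m, c("ctr", g)), numeric(1))
  best <- pool[ex == max(ex)]
  uni <- vapply(best, function(g) unionCoverage(m, c("ctr", g)), integer(1))
  expect_equal(moduleGenes(chain[[1]])[2], best[which.max(uni)])
})

test_that("each greedy step takes the max over single-gene extensions", {
  for (seed in 1:6) {
    r <- randomMatrix(10, 12, p = 0.25, seed = seed + 400)
    r2 <- filterMinRecurrence(r, 2)
    if (length(geneIds(r2)) < 4) next
    center <- geneIds(r2)[1]
    pool <- setdiff(geneIds(r2), center)
    chain <- growModule(r, poolLocal(center, pool), maxSize = 4,
                        exCutoff = 0, minRecurrence = 2)
    module <- center
    for (mod in chain) {
      added <- setdiff(moduleGenes(mod), module)
      candidates <- setdiff(pool, module)
      exAll <- vapply(candidates, function(g)
        exclusiveScore(r, c(module, g)), numeric(1))
      expect_equal(exclusiveScore(r, moduleGenes(mod)), max(exAll),
                   tolerance = 1e-12)
      module <- moduleGenes(mod)
    }
  }
})

test_that("grown chains are strictly nested and respect the cutoff", {
  for (seed in 1:6) {
    r <- randomMatrix(12, 15, p = 0.2, seed = seed + 500)
    r2 <- filterMinRecurrence(r, 2)
    if (length(geneIds(r2)) < 3) next
    center <- geneIds(r2)[1]
    chain <- growModule(r, poolLocal(center, setdiff(geneIds(r2), center)),
                        maxSize = 5, exCutoff = 0.95)
    prev <- center
    for (mod in chain) {
      expect_true(all(prev %in% moduleGenes(mod)))
      expect_equal(length(moduleGenes(mod)), length(prev) + 1L)
      expect_gte(exclusiveScore(r, moduleGenes(mod)), 0.95 - 1e-12)
      prev <- moduleGenes(mod)
    }
  }
})

test_that("catalog collects, scores, deduplicates and sorts modules", {
  cohort <- generatePlantedCohort(nSamples = 60, nGenes = 24, nModules = 3,
                                  moduleSize = 3, seed = 31,
                                  separateComponents = TRUE,
                                  passengerRate = 0.04)
  net <- reduceToAverageDegree(cohort@network, 15)
  catalog <- buildCatalog(cohort@mutations, net, unicovexConfig())
  tab <- catalogTable(catalog)
  expect_false(any(duplicated(tab$genes)))
  expect_true(all(tab$size >= 2 & tab$size <= 5))
  # sorted by composite within size
  for (s in unique(tab$size))
    expect_false(is.unsorted(-tab$composite[tab$size == s]))
  # the three planted triples are the top size-3 entries
  top3 <- tab$genes[tab$size == 3][1:3]
  expect_setequal(top3, vapply(truthModules(cohort), function(g)
    paste(sort(g), collapse = ";"), character(1)))
})

test_that("catalog edge cases: no eligible seeds, single mutated gene", {
  m <- matrixFromSets(list(a = c("s1", "s2")))
  net <- InfluenceNetwork(data.frame(geneA = "x", geneB = "y", weight = 1))
  expect_warning(cat0 <- buildCatalog(m, net), "seed")
  expect_equal(length(cat0), 0L)
  net2 <- InfluenceNetwork(data.frame(geneA = "a", geneB = "b", weight = 1))
  expect_equal(length(buildCatalog(m, net2)), 0L)
})

test_that("covering selection walks scores until coverable samples covered", {
  # two modules suffice; the third never enters
  sets <- list(a = paste0("s", 1:4), b = paste0("s", 5:8),
               c = paste0("s", 1:2), d = paste0("s", 3:4),
               e = paste0("s", 9:12))
  m <- matrixFromSets(sets, samples = c(paste0("s", 1:12), "s99"))
  mods <- makeModules(m, list(c("a", "b"), c("c", "d"), c("a", "e")))
  catalog <- new("ModuleCatalog", modules = mods,
                 table = data.frame(
                   network = "t", size = 2L,
                   genes = vapply(mods, function(x)
                     paste(sort(moduleGenes(x)), collapse = ";"), ""),
                   minCoverage = 0L, unionCoverage = 0L, exScore = 0,
                   entropy = 0,
                   composite = vapply(mods, compositeScore, numeric(1)),
                   dendrixW = 0L, selected = FALSE))
  ord <- order(-catalog@table$composite)
  catalog@table <- catalog@table[ord, ]
  catalog@modules <- catalog@modules[ord]
  sel <- selectCoveringModules(catalog, m)
  picked <- sel$selected[["2"]]
  coveredGenes <- unique(unlist(lapply(picked, moduleGenes)))
  covered <- unique(unlist(mutatedSamples(m)[coveredGenes]))
  expect_setequal(covered, paste0("s", 1:12))
  # s99 carries no mutation: uncoverable, not looped on
  expect_equal(sel$uncoverable[["2"]], "s99")
  # {a,b} and {a,e} jointly cover everything; {c,d} is redundant
  expect_length(picked, 2L)
})

test_that("identical inputs give byte-identical catalog files", {
  cohort <- generatePlantedCohort(nSamples = 40, nGenes = 18, nModules = 2,
                                  moduleSize = 3, seed = 8)
  net <- reduceToAverageDegree(cohort@network, 15)
  f1 <- withr::local_tempfile(fileext = ".tsv")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeCatalog(buildCatalog(cohort@mutations, net), f1)
  writeCatalog(buildCatalog(cohort@mutations, net), f2)
  expect_identical(readLines(f1), readLines(f2))
})
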