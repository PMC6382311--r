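test_that("edges are canonicalized and invalid networks rejected", {
  net <- InfluenceNetwork(data.frame(geneA = c("b", "a"), geneB = c("a", "c"),
                                     weight = c(2, 1)))
  e <- networkEdges(net)
  expect_true(all(e$geneA < e$geneB))
  expect_error(InfluenceNetwork(data.frame(geneA = c("a", "b"),
                                           geneB = c("b", "a"),
                                           weight = 1:2)),
               "duplicate")
  expect_warning(InfluenceNetwork(data.frame(geneA = "a", geneB = "a",
                                             weight = 1)), "self-loop")
})

test_that("edge-list TSV round-trips through read/write", {
  net <- InfluenceNetwork(data.frame(geneA = c("a", "a", "b"),
                                     geneB = c("b", "c", "c"),
                                     weight = c(0.5, 1.25, 2)))
  path <- withr::local_tempfile(fileext = ".tsv")
  writeInfluenceNetwork(net, path)
  net2 <- readInfluenceNetwork(path)
  expect_equal(networkEdges(net2), networkEdges(net))
  expect_equal(networkNodes(net2), networkNodes(net))
})

test_that("two-node diffusion matches the closed-form linear solve", {
  adj <- data.frame(geneA = "a", geneB = "b")
  Fmat <- influenceMatrix(adj, beta = 0.5)
  # by hand for the 2-node chain: F = b/(1-(1-b)^2) [[1, 1-b], [1-b, 1]]
  expect_equal(unname(Fmat), matrix(c(2, 1, 1, 2) / 3, 2), tolerance = 1e-12)
})

test_that("as the restart probability approaches 1 influence localizes", {
  adj <- data.frame(geneA = c("a", "b", "c"), geneB = c("b", "c", "d"))
  Fmat <- influenceMatrix(adj, beta = 0.999)
  expect_equal(unname(Fmat), diag(4), tolerance = 2e-3)
})

test_that("path-graph diffusion matches a dense linear-solve oracle", {
  adj <- data.frame(geneA = c("a", "b", "c"), geneB = c("b", "c", "d"))
  beta <- 0.4
  Fmat <- influenceMatrix(adj, beta = beta)
  # independent oracle: solve (I - (1-beta) W) x = beta e_j per column
  genes <- c("a", "b", "c", "d")
  A <- matrix(0, 4, 4, dimnames = list(genes, genes))
  A[cbind(c(1, 2, 2, 3, 3, 4), c(2, 1, 3, 2, 4, 3))] <- 1
  W <- sweep(A, 2, colSums(A), "/")
  for (j in 1:4) {
    x <- solve(diag(4) - (1 - beta) * W, beta * diag(4)[, j])
    expect_equal(unname(Fmat[, j]), unname(x), tolerance = 1e-10)
  }
  # conservation: diffused heat from each gene sums to 1
  expect_equal(unname(colSums(Fmat)), rep(1, 4), tolerance = 1e-9)
})

test_that("diffusion agrees with personalized PageRank", {
  skip_if_not_installed("igraph")
  g <- igraph::make_graph(~ a - b, b - c, c - d, a - d, b - d)
  beta <- 0.45
  Fmat <- influenceMatrix(igraph::as_data_frame(g)[, 1:2], beta = beta)
  for (v in igraph::V(g)$name) {
    pr <- igraph::page_rank(g, damping = 1 - beta,
                            personalized = as.numeric(igraph::V(g)$name == v))
    expect_equal(Fmat[igraph::V(g)$name, v], pr$vector[igraph::V(g)$name],
                 tolerance = 1e-6)
  }
})

test_that("diffused networks are symmetrized as configured", {
  adj <- data.frame(geneA = c("a", "b", "b"), geneB = c("b", "c", "d"))
  Fmat <- influenceMatrix(adj, beta = 0.45)
  for (rule in c("min", "max", "mean")) {
    net <- diffuseInfluence(adj, beta = 0.45, symmetrize = rule)
    e <- networkEdges(net)
    comb <- switch(rule, min = pmin, max = pmax,
                   mean = function(x, y) (x + y) / 2)
    for (i in seq_len(nrow(e)))
      expect_equal(e$weight[i],
                   comb(Fmat[e$geneA[i], e$geneB[i]],
                        Fmat[e$geneB[i], e$geneA[i]]))
  }
})

test_that("degree reduction keeps exactly the heaviest edges", {
  # 10 nodes, complete graph (45 edges), distinct weights, target 4
  genes <- letters[1:10]
  pairs <- t(combn(genes, 2))
  set.seed(42)
  w <- sample(seq(0.01, 0.45, by = 0.01))
  net <- InfluenceNetwork(data.frame(geneA = pairs[, 1], geneB = pairs[, 2],
                                     weight = w))
  red <- reduceToAverageDegree(net, 4)
  expect_equal(nrow(networkEdges(red)), 20L)   # ceiling(4*10/2)
  expect_setequal(networkEdges(red)$weight, sort(w, decreasing = TRUE)[1:20])
  expect_equal(averageDegree(red), 4)
  # no-op when already sparse enough
  expect_equal(networkEdges(reduceToAverageDegree(red, 10)),
               networkEdges(red))
  # all weights tied: the cutoff cannot remove anything
  tied <- InfluenceNetwork(data.frame(geneA = pairs[, 1], geneB = pairs[, 2],
                                      weight = 1))
  expect_equal(nrow(networkEdges(reduceToAverageDegree(tied, 4))), 45L)
})

test_that("degree reduction is idempotent and never adds edges", {
  genes <- letters[1:12]
  pairs <- t(combn(genes, 2))
  set.seed(3)
  net <- InfluenceNetwork(data.frame(geneA = pairs[, 1], geneB = pairs[, 2],
                                     weight = runif(nrow(pairs))))
  for (target in c(2, 5, 9)) {
    red <- reduceToAverageDegree(net, target)
    expect_lte(nrow(networkEdges(red)), nrow(networkEdges(net)))
    expect_equal(networkEdges(reduceToAverageDegree(red, target)),
                 networkEdges(red))
  }
})

test_that("local networks are BFS prefixes under the weight tie-break", {
  # star: everything within the cap
  star <- InfluenceNetwork(data.frame(geneA = "hub",
                                      geneB = paste0("leaf", 1:5),
                                      weight = 5:1))
  loc <- extractLocalNetwork(star, "hub", 100)
  expect_equal(length(loc@members), 6L)
  expect_equal(loc@members[1], "hub")
  # leaves discovered by descending weight
  expect_equal(loc@members[-1], paste0("leaf", 1:5))

  # long path: truncation at the cap
  n <- 200
  path <- InfluenceNetwork(data.frame(geneA = sprintf("n%03d", 1:(n - 1)),
                                      geneB = sprintf("n%03d", 2:n),
                                      weight = 1))
  loc2 <- extractLocalNetwork(path, "n001", 100)
  expect_equal(loc2@members, sprintf("n%03d", 1:100))

  # random graph: exact match with an independent BFS implementation
  set.seed(9)
  genes <- sprintf("v%02d", 1:15)
  pairs <- t(combn(genes, 2))
  keep <- runif(nrow(pairs)) < 0.3
  edges <- data.frame(geneA = pairs[keep, 1], geneB = pairs[keep, 2],
                      weight = round(runif(sum(keep)), 3))
  net <- InfluenceNetwork(edges)
  for (center in networkNodes(net)[c(1, 7, 12)]) {
    loc3 <- extractLocalNetwork(net, center, 10)
    expect_equal(loc3@members, referenceBFS(networkEdges(net), center, 10))
  }
  expect_error(extractLocalNetwork(net, "absent", 10), "absent")
})

test_that("local-network extraction is run-to-run deterministic", {
  set.seed(21)
  genes <- sprintf("v%02d", 1:20)
  pairs <- t(combn(genes, 2))
  keep <- runif(nrow(pairs)) < 0.25
  net <- InfluenceNetwork(data.frame(geneA = pairs[keep, 1],
                                     geneB = pairs[keep, 2],
                                     weight = sample(c(1, 2, 2, 3),
                                                     sum(keep), TRUE)))
  a <- extractLocalNetwork(net, genes[1], 12)
  b <- extractLocalNetwork(net, genes[1], 12)
  expect_identical(a@members, b@members)
})
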