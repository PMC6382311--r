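#' Construct an InfluenceNetwork from an edge table
#'
#' Edges are canonicalized (undirected, \code{geneA < geneB}); duplicate
#' undirected edges are an error, self-loops are dropped with a warning.
#'
#' @param edges data.frame with columns geneA, geneB, weight (weight defaults
#'   to 1 if absent).
#' @param name provenance tag.
#' @param nodes optional node set; defaults to the edge endpoints. Extra
#'   nodes are allowed (isolated genes).
#' @return an [InfluenceNetwork-class].
#' @export
InfluenceNetwork <- function(edges, name = "network", nodes = NULL) {
  stopifnot(is.data.frame(edges))
  if (!"weight" %in% names(edges)) edges$weight <- 1
  edges$geneA <- as.character(edges$geneA)
  edges$geneB <- as.character(edges$geneB)
  loop <- edges$geneA == edges$geneB
  if (any(loop)) {
    warning(sum(loop), " self-loop(s) dropped")
    edges <- edges[!loop, , drop = FALSE]
  }
  flip <- edges$geneA > edges$geneB
  tmp <- edges$geneA[flip]
  edges$geneA[flip] <- edges$geneB[flip]
  edges$geneB[flip] <- tmp
  key <- paste(edges$geneA, edges$geneB, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate undirected edge(s), e.g. ",
         sub("\r", "-", key[duplicated(key)][1L]), call. = FALSE)
  if (is.null(nodes)) nodes <- unique(c(edges$geneA, edges$geneB))
  edges <- edges[order(edges$geneA, edges$geneB),
                 c("geneA", "geneB", "weight"), drop = FALSE]
  rownames(edges) <- NULL
  new("InfluenceNetwork", nodes = sort(unique(as.character(nodes))),
      edges = edges, name = name)
}

#' Read a weighted influence network from an edge-list TSV
#'
#' Expects \code{gene_a<TAB>gene_b<TAB>weight} rows; a header row is
#' detected when the third field is not numeric. Two-column files are read
#' as unweighted (weight 1), e.g. a raw PPI edge list destined for
#' [diffuseInfluence()].
#'
#' @param path file path.
#' @param name provenance tag; defaults to the file name without extension.
#' @return an [InfluenceNetwork-class].
#' @seealso [writeInfluenceNetwork()]
#' @export
readInfluenceNetwork <- function(path, name = NULL) {
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  lines <- .readTabLines(path)
  if (!length(lines)) stop("empty network file: ", path, call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 2L)
  if (length(short))
    stop("line ", short[1L], " has fewer than 2 fields", call. = FALSE)
  hasW <- lengths(fields) >= 3L
  w <- rep(1, length(fields))
  w[hasW] <- suppressWarnings(as.numeric(vapply(fields[hasW], `[[`, "", 3L)))
  if (length(fields) && is.na(w[1L])) {       # header row
    fields <- fields[-1L]
    w <- w[-1L]
  }
  if (anyNA(w)) stop("non-numeric edge weight", call. = FALSE)
  InfluenceNetwork(
    data.frame(geneA = vapply(fields, `[[`, "", 1L),
               geneB = vapply(fields, `[[`, "", 2L),
               weight = w),
    name = name
  )
}

#' Write an influence network as an edge-list TSV
#'
#' @param net an [InfluenceNetwork-class].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeInfluenceNetwork <- function(net, path) {
  stopifnot(is(net, "InfluenceNetwork"))
  e <- net@edges
  writeLines(c("gene_a\tgene_b\tweight",
               paste(e$geneA, e$geneB, format(e$weight, scientific = FALSE,
                                              trim = TRUE), sep = "\t")),
             path)
  invisible(path)
}

#' Insulated heat diffusion influence matrix
#'
#' Computes the directed influence matrix of an insulated heat diffusion
#' (random walk with restart) on an unweighted graph:
#' \code{F = beta (I - (1 - beta) W)^-1} with \code{W} the column-normalized
#' adjacency matrix, so \code{F[i, j]} is the influence of gene j on gene i
#' and each column of \code{F} sums to 1 (diffused heat is conserved).
#'
#' @param adjacency data.frame of unweighted edges (columns geneA, geneB) or
#'   an [InfluenceNetwork-class] whose weights are ignored.
#' @param beta restart probability in (0, 1).
#' @return a dense numeric matrix with genes as dimnames.
#' @seealso [diffuseInfluence()]
#' @export
influenceMatrix <- function(adjacency, beta = 0.45) {
  stopifnot(beta > 0, beta < 1)
  if (is(adjacency, "InfluenceNetwork")) adjacency <- adjacency@edges
  a <- as.character(adjacency[[1L]])
  b <- as.character(adjacency[[2L]])
  keep <- a != b
  a <- a[keep]; b <- b[keep]
  genes <- sort(unique(c(a, b)))
  n <- length(genes)
  A <- matrix(0, n, n, dimnames = list(genes, genes))
  A[cbind(match(a, genes), match(b, genes))] <- 1
  A[cbind(match(b, genes), match(a, genes))] <- 1
  deg <- colSums(A)
  W <- sweep(A, 2L, deg, "/")
  beta * solve(diag(n) - (1 - beta) * W)
}

#' Derive a weighted influence network by heat diffusion on a PPI graph
#'
#' Runs [influenceMatrix()] on an unweighted protein-protein interaction
#' edge list and exports the symmetrized result as a weighted influence
#' network. The two directed influences of a gene pair are combined by
#' \code{min} (both genes must influence each other; the conservative
#' choice), \code{max} or \code{mean}. Isolated nodes (no edges) are dropped
#' with a warning, since no walk is defined from them.
#'
#' @param adjacency unweighted edge data.frame (geneA, geneB) or an
#'   [InfluenceNetwork-class] (weights ignored).
#' @param beta restart probability in (0, 1); default 0.45, the published
#'   choice for diffusion on PPI networks.
#' @param symmetrize one of \code{"min"}, \code{"max"}, \code{"mean"}.
#' @param name provenance tag of the resulting network.
#' @param nodes optional full node set; nodes without edges are dropped with
#'   a warning.
#' @return an [InfluenceNetwork-class] with an edge for every gene pair of
#'   positive symmetrized influence.
#' @export
diffuseInfluence <- function(adjacency, beta = 0.45,
                             symmetrize = c("min", "max", "mean"),
                             name = "diffused", nodes = NULL) {
  symmetrize <- match.arg(symmetrize)
  Fmat <- influenceMatrix(adjacency, beta = beta)
  genes <- rownames(Fmat)
  if (!is.null(nodes)) {
    iso <- setdiff(nodes, genes)
    if (length(iso))
      warning("dropping ", length(iso), " isolated node(s): ",
              paste(utils::head(iso, 5L), collapse = ", "))
  }
  comb <- switch(symmetrize,
                 min = pmin(Fmat, t(Fmat)),
                 max = pmax(Fmat, t(Fmat)),
                 mean = (Fmat + t(Fmat)) / 2)
  idx <- which(upper.tri(comb) & comb > 0, arr.ind = TRUE)
  InfluenceNetwork(
    data.frame(geneA = genes[idx[, 1L]], geneB = genes[idx[, 2L]],
               weight = comb[idx]),
    name = name, nodes = genes
  )
}

#' Reduce an influence network to a target average degree
#'
#' Applies a single global weight cutoff: the \code{ceiling(target * n / 2)}
#' highest-weight edges are retained, where n is the number of nodes. All
#' edges tied at the threshold weight are kept, so the achieved average
#' degree can slightly exceed the target; if the network is already at or
#' below the target it is returned unchanged. Node set and provenance are
#' preserved.
#'
#' @param net an [InfluenceNetwork-class].
#' @param targetAvgDegree desired average degree (default 15, close to the
#'   average degree of a real PPI network).
#' @return the reduced [InfluenceNetwork-class].
#' @export
reduceToAverageDegree <- function(net, targetAvgDegree = 15) {
  stopifnot(is(net, "InfluenceNetwork"), targetAvgDegree > 0)
  mKeep <- ceiling(targetAvgDegree * length(net@nodes) / 2)
  e <- net@edges
  if (nrow(e) <= mKeep) return(net)
  threshold <- sort(e$weight, decreasing = TRUE)[mKeep]
  e <- e[e$weight >= threshold, , drop = FALSE]
  rownames(e) <- NULL
  new("InfluenceNetwork", nodes = net@nodes, edges = e, name = net@name)
}

# Weighted adjacency list: per node, a data.frame of (neighbor, weight)
# pre-sorted by descending weight then lexicographic neighbor, i.e. the BFS
# visiting order.
.adjacencyList <- function(net) {
  e <- net@edges
  ends <- c(e$geneA, e$geneB)
  nbrs <- c(e$geneB, e$geneA)
  w <- c(e$weight, e$weight)
  ord <- order(ends, -w, nbrs, method = "radix")
  adj <- split(nbrs[ord], factor(ends[ord], levels = net@nodes))
  adj
}

.bfsLocal <- function(adj, center, maxGenes) {
  members <- character(maxGenes)
  members[1L] <- center
  nFound <- 1L
  seen <- new.env(parent = emptyenv(), hash = TRUE)
  assign(center, TRUE, envir = seen)
  queue <- center
  while (length(queue) && nFound < maxGenes) {
    u <- queue[1L]
    queue <- queue[-1L]
    for (v in adj[[u]]) {
      if (!exists(v, envir = seen, inherits = FALSE)) {
        assign(v, TRUE, envir = seen)
        nFound <- nFound + 1L
        members[nFound] <- v
        queue <- c(queue, v)
        if (nFound == maxGenes) break
      }
    }
  }
  members[seq_len(nFound)]
}

#' Extract the local network around a center gene
#'
#' Breadth-first search from \code{center} over the (reduced) influence
#' network, truncated at \code{maxGenes} members. Determinism contract:
#' within a BFS step, neighbors are visited by descending edge weight from
#' the discovering node, with lexicographic gene symbol as the final
#' tie-break.
#'
#' @param net an [InfluenceNetwork-class].
#' @param center the seed gene (must be a network node).
#' @param maxGenes maximal number of genes (default 100).
#' @return a [LocalNetwork-class].
#' @export
extractLocalNetwork <- function(net, center, maxGenes = 100) {
  stopifnot(is(net, "InfluenceNetwork"), maxGenes >= 1)
  if (!center %in% net@nodes)
    stop("center gene not in the network: ", center, call. = FALSE)
  members <- .bfsLocal(.adjacencyList(net), center, as.integer(maxGenes))
  new("LocalNetwork", center = center, members = members,
      sizeCap = as.integer(maxGenes))
}

#' @rdname InfluenceNetwork-class
#' @export
setMethod("networkNodes", "InfluenceNetwork", function(x) x@nodes)

#' @rdname InfluenceNetwork-class
#' @export
setMethod("networkEdges", "InfluenceNetwork", function(x) x@edges)

#' @rdname InfluenceNetwork-class
#' @export
setMethod("networkName", "InfluenceNetwork", function(x) x@name)

#' Average degree of an influence network
#'
#' @param net an [InfluenceNetwork-class].
#' @return \code{2 * edges / nodes}.
#' @export
averageDegree <- function(net) {
  stopifnot(is(net, "InfluenceNetwork"))
  2 * nrow(net@edges) / length(net@nodes)
}

setMethod("show", "InfluenceNetwork", function(object) {
  cat("InfluenceNetwork '", object@name, "': ", length(object@nodes),
      " nodes, ", nrow(object@edges), " edges (avg degree ",
      round(averageDegree(object), 2), ")\n", sep = "")
})

setMethod("show", "LocalNetwork", function(object) {
  cat("LocalNetwork around ", object@center, ": ", length(object@members),
      " genes (cap ", object@sizeCap, ")\n", sep = "")
})
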