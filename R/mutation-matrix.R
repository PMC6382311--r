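#' Construct a MutationMatrix from gene-sample pairs
#'
#' Builds a binary mutation matrix from a two-column table of (gene, sample)
#' pairs. Duplicate pairs collapse to a single mutation call. The sample
#' universe is the set of samples seen in the input (optionally extended via
#' \code{samples}); it is preserved by downstream gene filtering so coverage
#' denominators stay cohort-wide.
#'
#' @param gene character vector of gene symbols (recycled against sample).
#' @param sample character vector of sample identifiers.
#' @param samples optional additional sample ids to include in the universe
#'   (e.g. samples with no mutation among considered genes).
#'
#' @return a [MutationMatrix-class].
#' @examples
#' m <- MutationMatrix(gene = c("TP53", "TP53", "KRAS"),
#'                     sample = c("s1", "s1", "s2"))
#' geneIds(m)
#' mutatedSamples(m, "TP53")
#' @export
MutationMatrix <- function(gene, sample, samples = character()) {
  gene <- as.character(gene)
  sample <- as.character(sample)
  if (length(gene) != length(sample))
    stop("gene and sample must have equal length")
  sampleIds <- sort(unique(c(sample, samples)))
  geneIds <- sort(unique(gene))
  sets <- lapply(split(sample, factor(gene, levels = geneIds)),
                 function(s) sort(unique(s)))
  new("MutationMatrix", geneIds = geneIds, sampleIds = sampleIds,
      mutatedSamples = sets)
}

#' Read a somatic mutation table
#'
#' Reads gene-sample mutation calls from either a simple two-column TSV
#' (\code{gene<TAB>sample}, optional header whose first field is the literal
#' \code{gene}) or a MAF-dialect file, from which only the
#' \code{Hugo_Symbol} and \code{Tumor_Sample_Barcode} columns are used.
#' Comment lines starting with \code{#} are skipped in MAF mode.
#'
#' @param path path to the file.
#' @param format \code{"tsv_pairs"}, \code{"maf"}, or \code{"auto"}
#'   (MAF if the first non-comment line contains a \code{Hugo_Symbol} field).
#'
#' @return a [MutationMatrix-class] with deduplicated gene-sample pairs.
#' @seealso [writeMutations()]
#' @export
readMutations <- function(path, format = c("auto", "tsv_pairs", "maf")) {
  format <- match.arg(format)
  lines <- .readTabLines(path)
  if (!length(lines)) stop("empty mutation file: ", path, call. = FALSE)
  if (format == "auto") {
    first <- strsplit(lines[!startsWith(lines, "#")][1L], "\t", fixed = TRUE)[[1L]]
    format <- if ("Hugo_Symbol" %in% first) "maf" else "tsv_pairs"
  }
  if (format == "maf") {
    lines <- lines[!startsWith(lines, "#")]
    if (!length(lines)) stop("empty mutation file: ", path, call. = FALSE)
    header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
    for (col in c("Hugo_Symbol", "Tumor_Sample_Barcode"))
      if (!col %in% header)
        stop("MAF file is missing required column ", col, call. = FALSE)
    gi <- match("Hugo_Symbol", header)
    si <- match("Tumor_Sample_Barcode", header)
    fields <- strsplit(lines[-1L], "\t", fixed = TRUE)
    short <- which(lengths(fields) < max(gi, si))
    if (length(short))
      stop("MAF line ", short[1L] + 1L, " has too few fields", call. = FALSE)
    MutationMatrix(gene = vapply(fields, `[[`, "", gi),
                   sample = vapply(fields, `[[`, "", si))
  } else {
    fields <- strsplit(lines, "\t", fixed = TRUE)
    short <- which(lengths(fields) < 2L)
    if (length(short))
      stop("line ", short[1L], " has fewer than 2 fields", call. = FALSE)
    gene <- vapply(fields, `[[`, "", 1L)
    sample <- vapply(fields, `[[`, "", 2L)
    if (gene[1L] == "gene") {          # header row
      gene <- gene[-1L]
      sample <- sample[-1L]
    }
    if (!length(gene)) stop("no mutation records in ", path, call. = FALSE)
    MutationMatrix(gene = gene, sample = sample)
  }
}

#' Write a mutation matrix as gene-sample pairs
#'
#' Emits the two-column \code{tsv_pairs} format with a \code{gene<TAB>sample}
#' header, rows sorted by (gene, sample).
#'
#' @param m a [MutationMatrix-class].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeMutations <- function(m, path) {
  stopifnot(is(m, "MutationMatrix"))
  gene <- rep(m@geneIds, lengths(m@mutatedSamples))
  sample <- unlist(m@mutatedSamples, use.names = FALSE)
  ord <- order(gene, sample)
  writeLines(c("gene\tsample", paste(gene[ord], sample[ord], sep = "\t")), path)
  invisible(path)
}

#' Filter genes by minimum mutation recurrence
#'
#' Drops genes mutated in fewer than \code{k} samples. The sample universe is
#' unchanged: samples losing all their mutations remain in the cohort (they
#' become uncoverable and are reported as such downstream).
#'
#' @param m a [MutationMatrix-class].
#' @param k minimum number of mutated samples (default 2, the usual
#'   recurrence filter for module search).
#' @return a filtered [MutationMatrix-class].
#' @export
filterMinRecurrence <- function(m, k = 2) {
  stopifnot(is(m, "MutationMatrix"), k >= 1)
  keep <- lengths(m@mutatedSamples) >= k
  new("MutationMatrix", geneIds = m@geneIds[keep], sampleIds = m@sampleIds,
      mutatedSamples = m@mutatedSamples[keep])
}

#' Per-gene exclusivity profiles within a module
#'
#' For each gene g_i of a module, the exclusively mutated samples EP_i are
#' the samples where g_i is mutated and no other module gene is. Returns one
#' row per module gene, in module order, with the mutated-sample count n_i,
#' the exclusive count n'_i and the exclusive sample set itself.
#'
#' @param m a [MutationMatrix-class].
#' @param module character vector of module genes (nonempty, all present in
#'   \code{m}).
#' @return a data.frame with columns \code{gene}, \code{mutatedCount},
#'   \code{exclusiveCount} and list-column \code{exclusiveSamples}.
#' @examples
#' m <- MutationMatrix(gene = c("a", "a", "b"), sample = c("s1", "s2", "s2"))
#' exclusivityProfiles(m, c("a", "b"))
#' @export
exclusivityProfiles <- function(m, module) {
  stopifnot(is(m, "MutationMatrix"), length(module) >= 1)
  module <- as.character(module)
  if (anyDuplicated(module)) stop("module genes must be unique")
  .assertGenesPresent(m, module)
  counts <- .moduleHitCounts(m, module)
  exclusiveSamples <- lapply(m@mutatedSamples[module], function(p) {
    p[counts[p] == 1L]
  })
  data.frame(
    gene = module,
    mutatedCount = unname(lengths(m@mutatedSamples[module])),
    exclusiveCount = unname(lengths(exclusiveSamples)),
    exclusiveSamples = I(unname(exclusiveSamples)),
    row.names = NULL
  )
}

#' @rdname MutationMatrix-class
#' @export
setMethod("geneIds", "MutationMatrix", function(x) x@geneIds)

#' @rdname MutationMatrix-class
#' @export
setMethod("sampleIds", "MutationMatrix", function(x) x@sampleIds)

#' @rdname MutationMatrix-class
#' @export
setMethod("mutatedSamples", "MutationMatrix", function(x, genes = NULL) {
  if (is.null(genes)) return(x@mutatedSamples)
  .assertGenesPresent(x, genes)
  if (length(genes) == 1L) x@mutatedSamples[[genes]] else x@mutatedSamples[genes]
})

#' @rdname MutationMatrix-class
#' @export
setMethod("mutationCounts", "MutationMatrix", function(x, genes = NULL) {
  if (is.null(genes)) genes <- x@geneIds
  .assertGenesPresent(x, genes)
  stats::setNames(lengths(x@mutatedSamples[genes]), genes)
})

setMethod("show", "MutationMatrix", function(object) {
  cat("MutationMatrix:", length(object@geneIds), "genes x",
      length(object@sampleIds), "samples;",
      sum(lengths(object@mutatedSamples)), "mutation calls\n")
})

#' @rdname MutationMatrix-class
#' @export
setMethod("dim", "MutationMatrix", function(x)
  c(length(x@geneIds), length(x@sampleIds)))
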