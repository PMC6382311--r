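# Internal helpers shared across modules.

# Canonical identity key of a gene set (order-free).
moduleKey <- function(genes) paste(sort(genes), collapse = ";")

# Per-sample count of mutated module genes, as a named integer vector over
# the samples touched by at least one module gene.
.moduleHitCounts <- function(m, module) {
  hits <- unlist(m@mutatedSamples[module], use.names = FALSE)
  if (!length(hits)) return(integer(0))
  tab <- table(hits)
  stats::setNames(as.integer(tab), names(tab))
}

.assertGenesPresent <- function(m, module) {
  missing <- setdiff(module, m@geneIds)
  if (length(missing))
    stop("gene(s) not present in the mutation matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
}

.readTabLines <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines[nzchar(lines)]
}
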