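# unicovex

Discovery of cancer driver gene modules with high coverage, high mutual
exclusivity and **balanced exclusive coverage**, from a binary somatic
mutation matrix and one or more gene influence networks.

## The problem and the score

Driver mutations within one pathway tend to be mutually exclusive across
tumors, but the long tail of rarely mutated genes defeats frequency-based
detection, and coverage/exclusivity objectives can be dominated by a single
frequent gene. For a module *M* = {g₁, …, gₛ}, with *Pᵢ* the samples where
*gᵢ* is mutated and *EPᵢ* ⊆ *Pᵢ* the samples where it is the *only* mutated
module gene (nᵢ = |Pᵢ|, n′ᵢ = |EPᵢ|, n′ = Σ n′ᵢ), the package scores

* exclusive score Ex(M) = (1/s) Σᵢ n′ᵢ/nᵢ — mutual exclusivity;
* exclusive entropy H(M) = −Σᵢ pᵢ log₂ pᵢ, pᵢ = n′ᵢ/n′ — balance of the
  exclusive coverage, in bits, maximal (log₂ s) when all genes contribute
  equally;
* composite score(M) = cov(M) · Ex(M) · H(M), with cov(M) = minᵢ nᵢ.

Candidate modules (sizes 2–5) are grown greedily inside 100-gene
breadth-first neighborhoods of a degree-reduced influence network, selected
per size by descending composite until every coverable sample is covered,
turned into sample-specific driver modules by greedy minimum set cover per
size group, and reported as consensus modules supported by ≥ 2 networks.
The classic Dendrix weight W(M) = 2|∪Pᵢ| − Σ|Pᵢ| is reported alongside for
comparison. A planted-module cohort simulator provides ground truth for
validation without any external data.

## Worked example

A strictly exclusive, perfectly balanced four-gene module over eight
samples (two exclusive samples per gene):

```r
library(unicovex)
m <- MutationMatrix(gene = rep(paste0("g", 1:4), each = 2),
                    sample = paste0("s", 1:8))
unicovexScore(m, paste0("g", 1:4))
#> ModuleScore {g1, g2, g3, g4}
#>   Ex = 1, H = 2 bits, cov(min) = 2, cov(union) = 8
#>   composite = 4, Dendrix W = 8
```

Every gene is fully exclusive (Ex = 1), the exclusive coverage is perfectly
balanced over 4 genes (H = log₂ 4 = 2 bits), each gene covers 2 samples
(cov = 2), so the composite is 2 · 1 · 2 = 4. The unbalanced split
(4, 2, 1, 1) of the same eight samples scores H = 1.75 bits instead.

End to end, on a simulated cohort with three planted 4-gene modules on
separate network components (120 samples, 60 genes, long-tail passenger
background):

```r
cohort <- generatePlantedCohort(nSamples = 120, nGenes = 60, nModules = 3,
                                moduleSize = 4, passengerRate = 0.05,
                                separateComponents = TRUE, seed = 42)
rec <- recoveryHarness(cohort)
rec$perModule
#>    module               genes exact bestJaccard
#> 1 module1 g001;g002;g003;g004  TRUE           1
#> 2 module2 g005;g006;g007;g008  TRUE           1
#> 3 module3 g009;g010;g011;g012  TRUE           1
```

All three planted modules are recovered exactly, and the size-4 catalog is
headed by the planted gene sets:

```r
head(catalogTable(rec$catalog)[, c("genes", "minCoverage", "exScore",
                                   "entropy", "composite")], 3)
#>                  genes minCoverage exScore entropy composite
#> 16 g005;g006;g007;g008           9       1   1.996     17.97
#> 17 g001;g002;g003;g004           7       1   1.947     13.63
#> 18 g009;g010;g011;g012           6       1   1.904     11.42
```

The full pipeline (`runPipeline()`, or the `inst/scripts/unicovex.R` front
end with subcommands `simulate`, `reduce-net`, `discover`, `predict`,
`evaluate`, `run`) writes per-network module catalogs, per-size set-cover
and sample-assignment tables, a consensus report, an evaluation JSON
(precision, recall, PR/ROC curves against a reference cancer-gene list) and
a provenance manifest.

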