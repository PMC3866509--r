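# CompYeast

Comparative genomics and transcriptomics of compact yeast genomes.

Small budding-yeast genomes — seven-ish chromosomes, ~9 Mbp, ~5,000 genes,
few introns — invite a characteristic bundle of analyses: accounting for an
assembly's scaffold arithmetic, mapping the GC landscape and the AT-rich
mid-chromosome blocks that mark candidate centromeres, annotating telomeric
repeats and subtelomeric gene families, quantifying segmental duplication
and protein-family redundancy, tracing gene-order conservation and gene
loss between related species, and reading two-condition RNA-seq as simple
fold changes. CompYeast packages those procedures as tested, reusable R
functions for people studying methylotrophic and other non-conventional
yeasts, together with a synthetic-data module that generates genomes,
proteomes, count tables and coverage tracks with recorded ground truth, so
every stage can be validated against planted features.

## What is inside

| Stage | Key functions |
|---|---|
| Genome/annotation I/O, scaffold arithmetic, summaries | `readGenome`, `readAnnotation`, `scaffoldLength`, `genomeSummary`, `geneDensityPer10kbp` |
| Synthetic data with ground truth | `makeGenome`, `makeCounts`, `makeProteomePair`, `makeProteomeTriple`, `simulateCoverage` |
| Composition | `gcContent`, `slidingGC`, `findATRichRegions`, `codonUsage`, `positionalGC` |
| Telomeres and repeats | `findTelomericRepeats`, `subtelomericGenes`, `findRepeatClusters` |
| Duplication and redundancy | `fragmentGenome`, `selfSearch`, `duplicationReport`, `clusterProteins`, `redundancyRatio`, `estimateCopyNumber` |
| Orthology and synteny | `allVsAll`, `reciprocalBestHits`, `dotplotTable`, `syntenyBlocks`, `detectGeneLoss`, `locusSyntenyMap`, `proteomeDivergence`, `coreAndUnique` |
| Transcriptome | `normalizeCounts`, `deValues`, `expressionSummary`, `categoryRollup`, `chromosomeHeatmapTable`, `callRetainedIntrons` |
| Enrichment | `fisherExact`, `bhFdr`, `geneSetEnrichment` |
| End-to-end replay | `runPipeline`, `defaultPipelineConfig` |

The central quantities, in the field's usual notation:

* **Differential expression.** Per gene, normalized expression
  `E = n_gene / N_mapped` per condition and
  `log2(E_methanol / E_glucose)`, classified at the inclusive two-fold
  rule (`|log2 ratio| >= 1`); zero-in-both genes are *silent*, a one-sided
  zero receives a 0.5-read pseudocount.
* **Raw genome redundancy.** `n_genes / n_families` over single-linkage
  protein families (e.g. 5325 / 4217 = 1.26).
* **Copy number from coverage.** `round(mean depth over collapsed unit /
  median background depth)` — a tandem array collapsed into one assembly
  copy attracts copy-number-fold coverage.
* **Segmental duplication.** Non-overlapping 2/5-kbp fragments searched
  against their own genome (k-mer seeds + local alignment, admission at
  >= 1/3 of the fragment aligned and >= 70% identity), tallied by total
  hit count (2 or 3, self hit included) and identity bin (>70/80/90%).
* **Orthology and synteny.** Reciprocal best hits (unique symmetrical best,
  ties disqualify) chained into blocks with monotone gene order and index
  gaps <= 3; a gene missing between two in-block anchors with no ortholog
  anywhere is a gene-loss candidate.
* **Enrichment.** One-sided Fisher exact test per category with
  Benjamini-Hochberg FDR (threshold 0.25 for subtelomere screens).

## A worked example

```r
library(CompYeast)

## a scaled-down genome in the package's stated world: telomeric
## (GGTGGCGG)x10 ends, a mid-chromosome AT-rich block with five LTR-like
## repeats, a collapsed 25-copy rDNA unit, one planted duplication
sim <- makeGenome(genomeSpec(nChromosomes = 2, chromosomeLength = 150000,
                             seed = 7))

findTelomericRepeats(sim$genome)[, c("chrom", "end", "copies")]
#>   chrom    end copies
#> 1  chr1 5prime     10
#> 2  chr1 3prime     10
#> 3  chr2 5prime     10
#> 4  chr2 3prime     10

tr <- slidingGC(sim$genome[[1]], chromosomeId = "chr1")
findATRichRegions(tr)
#>   chrom start   end   meanGC distanceToNearestEnd
#> 1  chr1 67001 83200 0.338974                66800
sim$truth$centromeres[1, 1:3]   # the planted block: chr1 67501 82500

cov <- simulateCoverage(sim$genome, sim$truth, depth = 20,
                        readLength = 326, seed = 7)
rd <- sim$truth$rdna
estimateCopyNumber(cov[[rd$chrom]][rd$start:rd$end],
                   cov[[rd$chrom]][-(rd$start:rd$end)])
#> [1] 25

## two-condition counts with planted fold changes
cc <- makeCounts(countSpec(nGenes = 1000, fracUp = 0.4, fracDown = 0.2,
                           fracSilent = 0.05, seed = 2))
de <- deValues(cc$countTable)
table(truth = cc$truth$class, called = de$class)[c(3, 1, 4, 2), c(3, 1, 4, 2)]
#>            called
#> truth       unchanged down  up silent
#>   unchanged       329    9  12      0
#>   down             13  187   0      0
#>   up               19    0 381      0
#>   silent            0    0   0     50

redundancyRatio(5325, 4217)
#> [1] 1.26
```

The ends carry exactly the planted telomere copies, the one AT-rich
candidate per chromosome matches the planted block to within a window, the
collapsed rDNA unit is read back as 25 copies from the coverage ratio, and
the planted expression classes are recovered up to counting noise near the
two-fold boundary.

`runPipeline(config, outDir, seed)` replays every stage on simulated data
and writes TSV/JSON reports plus a manifest; the same config and seed give
byte-identical output.

## Acceptance script

`scripts/acceptance.R` recomputes, from scratch against the installed
package, the coverage-based copy number of a 7,737 bp unit collapsed from
25 tandem copies: ten seeded simulations (>= 500 kbp single-copy
background, 20x depth, 326 bp reads), `estimateCopyNumber` on each, and the
modal estimate, written as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Documentation

The methods vignette (`vignettes/compyeast-methods.Rmd`) documents the
models and assumptions, every tunable threshold with its default and
rationale, what the synthetic generators do and do not emulate, and known
limitations.
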