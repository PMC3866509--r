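#' Default configuration for the end-to-end demo pipeline
#'
#' A scaled-down stated world (three 150 kbp chromosomes instead of seven
#' 1.29 Mbp ones, and a reduced gene count) so that the full replay runs in
#' seconds; every module threshold is surfaced here with its default.
#'
#' @return nested configuration list understood by [runPipeline()]
#' @export
defaultPipelineConfig <- function() {
    list(
        genome = list(nChromosomes = 3, chromosomeLength = 150000,
                      baseGC = 0.478, telomereCopies = 10,
                      centromere = list(span = 12000, gcDrop = 15,
                                        ltrUnit = 290, ltrCopies = 5,
                                        includeInverted = TRUE),
                      duplications = list(list(length = 4000,
                                               identity = 0.85, copies = 2)),
                      rdna = list(unit = 7737, copies = 25),
                      dupAlign = 2000),
        coverage = list(depth = 20, readLength = 326),
        counts = list(fracUp = 0.43, fracDown = 0.18, fracSilent = 0.016,
                      log2fcMean = 2.5, log2fcSd = 1,
                      libraryTotals = c(glucose = 709815, methanol = 733393),
                      dispersion = 0.05),
        proteomes = list(nOrthologs = 80, divergence = 0.2,
                         nRearrangements = 2, losses = 40,
                         paralogFamilies = c(3, 2)),
        thresholds = list(gcWindow = 1000, gcStep = 200, gcDrop = 5,
                          minSpan = 5000, maxSpan = 30000,
                          minEndDistance = 50000, telomereMinCopies = 3,
                          telomereMaxOffset = 200, subtelomere = 50000,
                          fragmentSizes = c(2000, 5000), maxGap = 3,
                          minScore = 60, fdr = 0.25))
}

#' Run the full analysis pipeline on simulated data
#'
#' Replays every stage end-to-end on synthetic data with known ground truth:
#' simulate a genome with annotations, summarize composition, call AT-rich
#' centromere candidates, telomeres and LTR-like repeat clusters, build the
#' segmental-duplication report, estimate the collapsed rDNA copy number
#' from simulated coverage, simulate and analyse a two-condition count
#' table (normalization, DE classes, category rollup, heat-map table),
#' test subtelomeric category enrichment, and run the proteome comparison
#' (reciprocal best hits, dot-plot, synteny blocks, gene losses,
#' divergence). All reports are written as TSV/JSON under `outDir` together
#' with a run manifest; identical config and seed give byte-identical
#' reports.
#'
#' @param config configuration list, see [defaultPipelineConfig()]
#' @param outDir output directory (created)
#' @param seed master seed; stage seeds are derived as seed + 1, 2, 3
#' @return (invisibly) a list with every computed object
#' @export
runPipeline <- function(config = defaultPipelineConfig(), outDir, seed = 1L) {
    stopIfNot(!missing(outDir), "outDir is required")
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    th <- config$thresholds
    p <- function(f) file.path(outDir, f)

    gspec <- do.call(genomeSpec, c(config$genome, list(seed = seed)))
    sim <- makeGenome(gspec)
    writeGenome(sim$genome, p("genome.fasta"))
    writeAnnotationTsv(sim$annotations, p("annotations.tsv"))

    summ <- genomeSummary(sim$genome, sim$annotations)
    writeSummaryJson(summ, p("summary.json"))

    tracks <- genomeGcTracks(sim$genome, th$gcWindow, th$gcStep)
    cands <- do.call(rbind, lapply(seq_along(tracks), function(i)
        findATRichRegions(tracks[[i]], th$gcDrop, th$minSpan, th$maxSpan,
                          th$minEndDistance)))
    write.table(cands, p("centromere_candidates.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)

    telo <- findTelomericRepeats(sim$genome,
                                 minCopies = th$telomereMinCopies,
                                 maxOffset = th$telomereMaxOffset)
    write.table(telo, p("telomeres.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)

    clusters <- findRepeatClusters(sim$genome)
    writeBedTsv(clusters, p("repeat_clusters.tsv"))

    dup <- duplicationReport(sim$genome, sizes = th$fragmentSizes)
    writeDuplicationReportTsv(dup, p("duplication_report.tsv"))

    cov <- simulateCoverage(sim$genome, sim$truth,
                            depth = config$coverage$depth,
                            readLength = config$coverage$readLength,
                            seed = seed + 3L)
    rd <- sim$truth$rdna
    bg <- setdiff(seq_len(summ$chromosomeLengths[rd$chrom]),
                  rd$start:rd$end)
    copyNumber <- estimateCopyNumber(cov[[rd$chrom]][rd$start:rd$end],
                                     cov[[rd$chrom]][bg])

    cspec <- do.call(countSpec, c(config$counts,
                                  list(nGenes = length(sim$annotations),
                                       seed = seed + 1L)))
    cc <- makeCounts(cspec)
    de <- deValues(cc$countTable)
    write.table(de, p("de_table.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    exprSumm <- expressionSummary(cc$countTable, de)
    catMap <- data.frame(gene_id = sim$annotations$gene_id,
                         category = sim$annotations$category,
                         stringsAsFactors = FALSE)
    rollup <- categoryRollup(de, catMap)
    write.table(rollup, p("category_rollup.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    heat <- chromosomeHeatmapTable(cc$countTable, sim$annotations)
    write.table(heat, p("heatmap_table.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)

    sub <- subtelomericGenes(sim$annotations, summ$chromosomeLengths,
                             th$subtelomere)
    enr <- geneSetEnrichment(sub$gene_id[sub$subtelomeric], catMap,
                             universe = sub$gene_id, fdr = th$fdr)
    write.table(enr, p("subtelomere_enrichment.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)

    pspec <- do.call(proteomePairSpec, c(config$proteomes,
                                         list(seed = seed + 2L)))
    pp <- makeProteomePair(pspec)
    rbh <- reciprocalBestHits(allVsAll(pp$proteomeA, pp$proteomeB,
                                       th$minScore),
                              allVsAll(pp$proteomeB, pp$proteomeA,
                                       th$minScore),
                              pp$proteomeA, pp$proteomeB)
    write.table(rbh, p("rbh_pairs.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    dot <- dotplotTable(rbh, pp$positionsA, pp$positionsB)
    write.table(dot, p("dotplot.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    blocks <- syntenyBlocks(rbh, pp$positionsA, pp$positionsB, th$maxGap)
    write.table(blocks, p("synteny_blocks.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    losses <- detectGeneLoss(blocks, pp$positionsA, rbh)
    write.table(losses, p("gene_losses.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)

    report <- list(rdnaCopyNumber = copyNumber,
                   nCentromereCandidates = nrow(cands),
                   nTelomereCalls = nrow(telo),
                   nRepeatClusters = length(clusters),
                   expression = exprSumm,
                   proteomeDivergencePercent = proteomeDivergence(rbh),
                   nSyntenyBlocks = length(unique(blocks$blockId)),
                   nGeneLosses = nrow(losses),
                   nEnrichedCategories = sum(enr$enriched))
    jsonlite::write_json(report, p("report.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    manifest <- list(package = "CompYeast",
                     version = as.character(utils::packageVersion("CompYeast")),
                     seed = seed, config = config,
                     files = sort(list.files(outDir)))
    jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, force = TRUE)
    invisible(list(sim = sim, summary = summ, candidates = cands,
                   telomeres = telo, clusters = clusters, duplication = dup,
                   copyNumber = copyNumber, counts = cc, de = de,
                   rollup = rollup, enrichment = enr, rbh = rbh,
                   blocks = blocks, losses = losses, report = report))
}
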