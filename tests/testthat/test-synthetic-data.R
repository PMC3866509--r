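test_that("simulated genomes carry the planted features deterministically", {
    spec <- genomeSpec(nChromosomes = 2, chromosomeLength = 60000,
                       centromere = list(span = 12000, gcDrop = 15,
                                         ltrUnit = 290, ltrCopies = 3,
                                         includeInverted = TRUE),
                       rdna = list(unit = 3000, copies = 25),
                       telomereCopies = 10, seed = 9)
    sim <- makeGenome(spec)
    ## telomeres: tandem motif at recorded positions, both ends
    motif <- "GGTGGCGG"
    rcMotif <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(motif)))
    for (r in seq_len(nrow(sim$truth$telomeres))) {
        tl <- sim$truth$telomeres[r, ]
        s <- as.character(Biostrings::subseq(sim$genome[[tl$chrom]],
                                             tl$start, tl$stop))
        unit <- if (tl$end == "3prime") motif else rcMotif
        expect_identical(s, paste(rep(unit, tl$copies), collapse = ""))
    }
    ## determinism: same spec, byte-identical output
    sim2 <- makeGenome(spec)
    expect_identical(as.character(sim$genome), as.character(sim2$genome))
    expect_identical(sim$truth, sim2$truth)
    ## truth coordinates lie inside chromosomes, features do not overlap
    expect_true(all(sim$truth$ltr$start >= sim$truth$centromeres$start[
        match(sim$truth$ltr$chrom, sim$truth$centromeres$chrom)]))
})

test_that("planted duplication copies hit their target pairwise identity", {
    for (ident in c(0.85, 0.95)) {
        spec <- genomeSpec(nChromosomes = 1, chromosomeLength = 60000,
                           centromere = list(), rdna = list(),
                           duplications = list(list(length = 3000,
                                                    identity = ident,
                                                    copies = 2)),
                           seed = round(100 * ident))
        sim <- makeGenome(spec)
        cp <- sim$truth$duplications[[1]]$copies
        a <- Biostrings::subseq(sim$genome[[cp$chrom[1]]], cp$start[1],
                                cp$end[1])
        b <- Biostrings::subseq(sim$genome[[cp$chrom[2]]], cp$start[2],
                                cp$end[2])
        pa <- Biostrings::pairwiseAlignment(a, b, type = "global",
            gapOpening = 5, gapExtension = 2,
            substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(2, -3))
        expect_lt(abs(Biostrings::pid(pa, "PID1") / 100 - ident), 0.02)
    }
})

test_that("count simulation plants classes, fold changes and silence", {
    spec <- countSpec(nGenes = 1000, fracUp = 0.4, fracDown = 0.2,
                      fracSilent = 0.05, seed = 2)
    cc <- makeCounts(spec)
    expect_equal(sum(cc$truth$class == "up"), 400)
    expect_equal(sum(cc$truth$class == "down"), 200)
    expect_equal(sum(cc$truth$class == "silent"), 50)
    cts <- counts(cc$countTable)
    expect_equal(sum(rowSums(cts) == 0), 50)
    expect_true(all(cts[cc$truth$class == "silent", ] == 0))
    expect_true(all(abs(cc$truth$log2fc[cc$truth$class == "up"]) >= 1,
                    na.rm = TRUE))
    ## determinism
    cc2 <- makeCounts(spec)
    expect_identical(counts(cc$countTable), counts(cc2$countTable))

    ## dispersion 0 and deep libraries: measured log2 ratios near truth
    deep <- makeCounts(countSpec(nGenes = 200, fracUp = 0.3, fracDown = 0.3,
                                 fracSilent = 0, dispersion = 0,
                                 libraryTotals = c(a = 5e7, b = 5e7),
                                 seed = 3))
    de <- deValues(deep$countTable)
    lfc <- ifelse(is.na(deep$truth$log2fc), 0, deep$truth$log2fc)
    expect_lt(max(abs(de$log2Ratio - lfc)), 0.1)

    expect_error(makeCounts(countSpec(nGenes = 1000,
                                      libraryTotals = c(a = 500, b = 500))),
                 "too small")
})

test_that("proteome pairs record orthologs, losses and families faithfully", {
    ## divergence 0, no edits: identity map
    pp0 <- makeProteomePair(proteomePairSpec(nOrthologs = 10, divergence = 0,
                                             seed = 1))
    expect_identical(as.character(unname(pp0$proteomeA)),
                     as.character(unname(pp0$proteomeB)))
    expect_equal(pp0$truth$orthologs$indexB, pp0$truth$orthologs$indexA)

    ## loss bookkeeping
    pp <- makeProteomePair(proteomePairSpec(nOrthologs = 30, divergence = 0.1,
                                            losses = c(7), seed = 2))
    expect_equal(pp$truth$losses$idA, "A0007")
    expect_false("B0007" %in% names(pp$proteomeB))
    expect_equal(nrow(pp$truth$orthologs), 29)

    ## divergence 0.3: mean pairwise ortholog identity ~70%
    pp3 <- makeProteomePair(proteomePairSpec(nOrthologs = 20,
                                             divergence = 0.3, seed = 5))
    ids <- vapply(seq_len(20), function(i) {
        pa <- Biostrings::pairwiseAlignment(
            pp3$proteomeA[[pp3$truth$orthologs$idA[i]]],
            pp3$proteomeB[[pp3$truth$orthologs$idB[i]]],
            type = "global", substitutionMatrix = "BLOSUM62",
            gapOpening = 11, gapExtension = 1)
        Biostrings::pid(pa, "PID1")
    }, numeric(1))
    expect_lt(abs(mean(ids) - 70), 2)

    ## paralog families are planted with the requested sizes
    ppf <- makeProteomePair(proteomePairSpec(nOrthologs = 20,
                                             divergence = 0.2,
                                             paralogFamilies = c(3, 5),
                                             seed = 6))
    expect_equal(lengths(ppf$truth$families), c(3, 5))
    expect_true(all(unlist(ppf$truth$families) %in% names(ppf$proteomeB)))

    expect_error(proteomePairSpec(divergence = 0.96), "saturation")
    expect_error(proteomePairSpec(nOrthologs = 5, losses = 9), "indices")
})

test_that("coverage simulation reflects depth and collapsed copy number", {
    sim <- makeGenome(genomeSpec(nChromosomes = 1, chromosomeLength = 100000,
                                 centromere = list(), rdna = list(),
                                 telomereCopies = 0, seed = 4))
    cov <- simulateCoverage(sim$genome, sim$truth, depth = 20,
                            readLength = 326, seed = 1)
    m <- mean(cov$chr1[400:99600])   # interior, away from edge truncation
    expect_gt(m, 18); expect_lt(m, 22)

    cov0 <- simulateCoverage(sim$genome, sim$truth, depth = 0, seed = 1)
    expect_true(all(cov0$chr1 == 0))

    ## collapsed 25-copy unit attracts ~25x depth
    simr <- makeGenome(genomeSpec(nChromosomes = 1, chromosomeLength = 200000,
                                  centromere = list(),
                                  rdna = list(unit = 7737, copies = 25),
                                  telomereCopies = 0, seed = 5))
    covr <- simulateCoverage(simr$genome, simr$truth, depth = 20,
                             readLength = 326, seed = 2)
    rd <- simr$truth$rdna
    unitMean <- mean(covr$chr1[rd$start:rd$end])
    bgMed <- median(covr$chr1[setdiff(5000:195000, rd$start:rd$end)])
    expect_gt(unitMean / bgMed, 23)
    expect_lt(unitMean / bgMed, 27)
})
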