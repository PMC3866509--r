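test_that("genome fragmentation drops the trailing remainder", {
    g <- Biostrings::DNAStringSet(c(c1 = paste(rep("A", 10000), collapse = "")))
    f <- fragmentGenome(g, 2000)
    expect_equal(nrow(f), 5L)
    g2 <- Biostrings::DNAStringSet(c(c1 = paste(rep("A", 10500),
                                                collapse = "")))
    f2 <- fragmentGenome(g2, 5000)
    expect_equal(nrow(f2), 2L)
    expect_equal(f2$end, c(5000, 10000))
    ## starts sit on the fragment grid
    for (size in c(1000, 2000, 5000))
        expect_true(all((fragmentGenome(g, size)$start - 1) %% size == 0))
})

test_that("self-search admits hits by aligned fraction and identity", {
    spec <- genomeSpec(nChromosomes = 1, chromosomeLength = 80000,
                       centromere = list(), rdna = list(), telomereCopies = 0,
                       duplications = list(list(length = 6000,
                                                identity = 0.85, copies = 2)),
                       dupAlign = 2000, seed = 11)
    sim <- makeGenome(spec)
    idx <- CompYeast:::genomeKmerIndex(sim$genome)
    frags <- fragmentGenome(sim$genome, 2000)
    cp <- sim$truth$duplications[[1]]$copies

    ## a unique fragment has exactly one hit: itself
    awayFromCopies <- vapply(seq_len(nrow(frags)), function(f)
        all(frags$start[f] > cp$end + 2000 | frags$end[f] < cp$start - 2000),
        logical(1))
    uniqueFrag <- frags[which(awayFromCopies)[1], ]
    h <- selfSearch(sim$genome, uniqueFrag, index = idx)
    expect_equal(nrow(h), 1L)
    expect_true(h$self)
    expect_equal(h$identity, 1)

    ## a fragment inside the planted copy has two hits; the non-self one
    ## carries the planted identity
    inFrag <- frags[frags$start == cp$start[1], ]
    h2 <- selfSearch(sim$genome, inFrag, index = idx)
    expect_equal(nrow(h2), 2L)
    ns <- h2[!h2$self, ]
    expect_gte(ns$identity, 0.80); expect_lte(ns$identity, 0.90)
    expect_true(ns$hitStart >= cp$start[2] - 50 && ns$hitEnd <= cp$end[2] + 50)

    ## a copy covering only 20% of a fragment fails the 1/3 admission rule
    s <- CompYeast:::randomDnaChr(50000, 0.478)
    piece <- substr(s, 4001, 4400)           # first 400 bp of fragment 3
    s20 <- paste0(substr(s, 1, 30000), piece, substr(s, 30401, 50000))
    g20 <- Biostrings::DNAStringSet(c(chr1 = s20))
    h3 <- selfSearch(g20, list(chrom = "chr1", start = 4001, end = 6000))
    expect_equal(nrow(h3[!h3$self, ]), 0L)
    ## but the piece is found once the fragment is mostly covered
    h4 <- selfSearch(g20, list(chrom = "chr1", start = 4001, end = 4500),
                     minAlignedFraction = 1 / 3)
    expect_equal(nrow(h4[!h4$self, ]), 1L)
})

test_that("duplication report tallies planted copies into the right cells", {
    ## duplication-free genome: every cell zero
    bare <- makeGenome(genomeSpec(nChromosomes = 1, chromosomeLength = 60000,
                                  centromere = list(), rdna = list(),
                                  telomereCopies = 0, seed = 13))
    rep0 <- duplicationReport(bare$genome, sizes = 2000)
    expect_true(all(rep0$count == 0))

    ## 2-copy duplication at 0.95: three 2 kbp fragments per copy, all bins
    sim <- makeGenome(genomeSpec(nChromosomes = 1, chromosomeLength = 90000,
                                 centromere = list(), rdna = list(),
                                 telomereCopies = 0,
                                 duplications = list(list(length = 6000,
                                                          identity = 0.95,
                                                          copies = 2)),
                                 dupAlign = 2000, seed = 14))
    rp <- duplicationReport(sim$genome, sizes = 2000)
    for (bin in c(0.7, 0.8, 0.9))
        expect_equal(rp$count[rp$hitCount == 2 & rp$identityBin == bin], 6L)
    expect_true(all(rp$count[rp$hitCount == 3] == 0))

    ## 3-copy at 0.75: hit-count 3 in the >70% bin only
    sim3 <- makeGenome(genomeSpec(nChromosomes = 1, chromosomeLength = 90000,
                                  centromere = list(), rdna = list(),
                                  telomereCopies = 0,
                                  duplications = list(list(length = 4000,
                                                           identity = 0.75,
                                                           copies = 3)),
                                  dupAlign = 2000, seed = 15))
    rp3 <- duplicationReport(sim3$genome, sizes = 2000)
    expect_equal(rp3$count[rp3$hitCount == 3 & rp3$identityBin == 0.7], 6L)
    expect_true(all(rp3$count[rp3$identityBin %in% c(0.8, 0.9)] == 0))

    ## bin monotonicity on a planted single-group genome
    for (hc in c(2, 3)) {
        v <- rp$count[rp$hitCount == hc][order(rp$identityBin[rp$hitCount ==
                                                              hc])]
        expect_true(all(diff(v) <= 0) || all(v == 0))
    }
})

test_that("protein clustering partitions paralog families by identity", {
    set.seed(16)
    uniq <- Biostrings::AAStringSet(setNames(
        vapply(rep(300, 12), CompYeast:::randomProteinChr, character(1)),
        sprintf("u%02d", 1:12)))
    cl <- clusterProteins(uniq)
    expect_equal(cl$nFamilies, 12L)
    expect_true(all(lengths(cl$families) == 1))

    ## planted family of four at ~0.9 identity clusters together
    base <- strsplit(CompYeast:::randomProteinChr(300), "")[[1]]
    fam <- vapply(1:4, function(i) paste(CompYeast:::substitutePositions(
        base, sample.int(300, 30), CompYeast:::AA20), collapse = ""),
        character(1))
    prot <- Biostrings::AAStringSet(c(setNames(fam, paste0("p", 1:4)),
                                      as.character(uniq)))
    cl2 <- clusterProteins(prot)
    expect_equal(cl2$nFamilies, 13L)
    expect_true(list(c("p1", "p2", "p3", "p4")) %in% cl2$families ||
                any(vapply(cl2$families, function(f)
                    identical(sort(f), c("p1", "p2", "p3", "p4")),
                    logical(1))))

    ## clustering is invariant to input order
    cl3 <- clusterProteins(prot[sample(length(prot))])
    expect_identical(cl2$families, cl3$families)

    ## family-size histogram equals the generator's truth
    pp <- makeProteomePair(proteomePairSpec(nOrthologs = 15, divergence = 0.6,
                                            paralogFamilies = c(2, 5, 9),
                                            seed = 17))
    clf <- clusterProteins(pp$proteomeB)
    expect_equal(unname(clf$sizes[c("2", "5", "9")]), c(1L, 1L, 1L),
                 ignore_attr = TRUE)

    expect_error(clusterProteins(Biostrings::AAStringSet()), "empty")
})

test_that("redundancy ratio and copy-number estimation are exact arithmetic", {
    expect_equal(redundancyRatio(5325, 4217), 1.26)
    expect_equal(redundancyRatio(10, 10), 1.00)
    expect_equal(redundancyRatio(10, 5), 2.00)
    expect_error(redundancyRatio(5, 10), "nGenes")
    expect_error(redundancyRatio(5, 0), "nFamilies")

    expect_equal(estimateCopyNumber(rep(500, 100), rep(20, 1000)), 25L)
    expect_equal(estimateCopyNumber(rep(20, 100), rep(20, 1000)), 1L)
    expect_error(estimateCopyNumber(rep(5, 10), rep(0, 10)), "background")

    ## simulated 25-copy collapse at 20x lands within one copy
    sim <- makeGenome(genomeSpec(nChromosomes = 1, chromosomeLength = 550000,
                                 centromere = list(), telomereCopies = 0,
                                 rdna = list(unit = 7737, copies = 25),
                                 seed = 18))
    cov <- simulateCoverage(sim$genome, sim$truth, depth = 20,
                            readLength = 326, seed = 18)
    rd <- sim$truth$rdna
    est <- estimateCopyNumber(cov$chr1[rd$start:rd$end],
                              cov$chr1[-(rd$start:rd$end)])
    expect_true(est %in% 24:26)
})
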