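test_that("all-vs-all search equals the exhaustive alignment oracle", {
    set.seed(21)
    a <- Biostrings::AAStringSet(setNames(
        vapply(sample(200:400, 5, TRUE), CompYeast:::randomProteinChr,
               character(1)), paste0("a", 1:5)))
    ## b: diverged copies of a1/a3 plus unrelated proteins
    mut <- function(s, rate) {
        ch <- strsplit(s, "")[[1]]
        paste(CompYeast:::substitutePositions(ch,
            sample.int(length(ch), round(rate * length(ch))),
            CompYeast:::AA20), collapse = "")
    }
    b <- Biostrings::AAStringSet(setNames(
        c(mut(as.character(a[[1]]), 0.2), mut(as.character(a[[3]]), 0.4),
          vapply(sample(200:400, 3, TRUE), CompYeast:::randomProteinChr,
                 character(1))), paste0("b", 1:5)))
    hits <- allVsAll(a, b, minScore = 60)
    ## oracle: exhaustive local alignment of every pair
    oracle <- do.call(rbind, lapply(1:5, function(i)
        do.call(rbind, lapply(1:5, function(j) {
            al <- CompYeast:::alignPair(a[[i]], b[[j]])
            if (al$score < 60) return(NULL)
            data.frame(query_id = names(a)[i], subject_id = names(b)[j],
                       score = al$score, identity = al$identity,
                       coverage = al$coverage, stringsAsFactors = FALSE)
        }))))
    oracle <- oracle[order(oracle$query_id, -oracle$score,
                           oracle$subject_id), ]
    expect_equal(hits, oracle, ignore_attr = TRUE)

    ## identical proteomes: each protein's top hit is itself at coverage 1
    self <- allVsAll(a, a, minScore = 60)
    for (id in names(a)) {
        hq <- self[self$query_id == id, ]
        expect_equal(hq$subject_id[which.max(hq$score)], id)
        expect_equal(max(hq$coverage), 1)
    }

    ## unrelated random proteins: nothing above the score floor
    set.seed(22)
    r1 <- Biostrings::AAStringSet(setNames(vapply(rep(300, 6),
        CompYeast:::randomProteinChr, character(1)), paste0("x", 1:6)))
    r2 <- Biostrings::AAStringSet(setNames(vapply(rep(300, 6),
        CompYeast:::randomProteinChr, character(1)), paste0("y", 1:6)))
    expect_equal(nrow(allVsAll(r1, r2, minScore = 60)), 0L)
})

test_that("reciprocal best hits are symmetric and refuse ambiguous ties", {
    pp <- makeProteomePair(proteomePairSpec(nOrthologs = 25, divergence = 0.2,
                                            seed = 23))
    ab <- allVsAll(pp$proteomeA, pp$proteomeB)
    ba <- allVsAll(pp$proteomeB, pp$proteomeA)
    rbh <- reciprocalBestHits(ab, ba, pp$proteomeA, pp$proteomeB)
    tru <- pp$truth$orthologs
    expect_gte(sum(paste(rbh$idA, rbh$idB) %in% paste(tru$idA, tru$idB)), 24)

    ## label-swap symmetry
    rbh2 <- reciprocalBestHits(ba, ab, pp$proteomeB, pp$proteomeA)
    expect_equal(sort(paste(rbh$idA, rbh$idB)),
                 sort(paste(rbh2$idB, rbh2$idA)))

    ## identical duplicate in B disqualifies the pair (equal-score tie)
    a <- pp$proteomeA[1:5]
    b <- Biostrings::AAStringSet(setNames(
        c(as.character(a), as.character(a[[3]])),
        c(paste0("b", 1:5), "b3dup")))
    rbhT <- reciprocalBestHits(allVsAll(a, b), allVsAll(b, a))
    expect_false(names(a)[3] %in% rbhT$idA)
    expect_true(all(names(a)[c(1, 2, 4, 5)] %in% rbhT$idA))

    ## identical proteomes give all self pairs
    selfP <- reciprocalBestHits(allVsAll(a, a), allVsAll(a, a))
    expect_equal(nrow(selfP), 5L)
    expect_equal(selfP$idA, selfP$idB)
})

test_that("dot-plot coordinates expose collinearity and breakpoints", {
    pp <- makeProteomePair(proteomePairSpec(nOrthologs = 30, divergence = 0.1,
                                            seed = 24))
    rbh <- reciprocalBestHits(allVsAll(pp$proteomeA, pp$proteomeB),
                              allVsAll(pp$proteomeB, pp$proteomeA))
    dp <- dotplotTable(rbh, pp$positionsA, pp$positionsB)
    expect_equal(dp$indexA, dp$indexB)  # collinear: identity diagonal

    empty <- rbh[0, ]
    expect_equal(nrow(dotplotTable(empty, pp$positionsA, pp$positionsB)), 0L)

    ## one block move breaks the diagonal into offset segments
    ppm <- makeProteomePair(proteomePairSpec(nOrthologs = 30,
                                             divergence = 0.1,
                                             nRearrangements = 1, seed = 25))
    rbhm <- reciprocalBestHits(allVsAll(ppm$proteomeA, ppm$proteomeB),
                               allVsAll(ppm$proteomeB, ppm$proteomeA))
    dpm <- dotplotTable(rbhm, ppm$positionsA, ppm$positionsB)
    expect_gt(sum(dpm$indexA != dpm$indexB), 0)
})

test_that("synteny chaining follows the gap and direction rules", {
    pp <- makeProteomePair(proteomePairSpec(nOrthologs = 40, divergence = 0.1,
                                            seed = 26))
    rbh <- reciprocalBestHits(allVsAll(pp$proteomeA, pp$proteomeB),
                              allVsAll(pp$proteomeB, pp$proteomeA))
    bl <- syntenyBlocks(rbh, pp$positionsA, pp$positionsB)
    expect_equal(length(unique(bl$blockId)), 1L)   # identical order: 1 block
    expect_equal(unique(bl$orientation), "same")
    ## every pair in exactly one block
    expect_equal(nrow(bl), nrow(rbh))
    expect_false(any(duplicated(bl$idA)))

    ## max_gap 0 splits the chain at an internal loss
    ppl <- makeProteomePair(proteomePairSpec(nOrthologs = 40,
                                             divergence = 0.1, losses = 20,
                                             seed = 27))
    rbhl <- reciprocalBestHits(allVsAll(ppl$proteomeA, ppl$proteomeB),
                               allVsAll(ppl$proteomeB, ppl$proteomeA))
    bl0 <- syntenyBlocks(rbhl, ppl$positionsA, ppl$positionsB, maxGap = 0)
    expect_equal(length(unique(bl0$blockId)), 2L)
    bl3 <- syntenyBlocks(rbhl, ppl$positionsA, ppl$positionsB, maxGap = 3)
    expect_equal(length(unique(bl3$blockId)), 1L)
})

test_that("gene-loss calls need both flanking anchors in one block", {
    pp <- makeProteomePair(proteomePairSpec(nOrthologs = 50, divergence = 0.15,
                                            losses = c(12, 30), seed = 28))
    rbh <- reciprocalBestHits(allVsAll(pp$proteomeA, pp$proteomeB),
                              allVsAll(pp$proteomeB, pp$proteomeA))
    bl <- syntenyBlocks(rbh, pp$positionsA, pp$positionsB)
    losses <- detectGeneLoss(bl, pp$positionsA, rbh)
    expect_equal(sort(losses$missingGeneId), c("A0012", "A0030"))
    expect_equal(losses$leftFlank[losses$missingGeneId == "A0012"], "A0011")
    expect_equal(losses$rightFlank[losses$missingGeneId == "A0012"], "A0013")

    ## no losses: empty
    ppn <- makeProteomePair(proteomePairSpec(nOrthologs = 20,
                                             divergence = 0.15, seed = 29))
    rbhn <- reciprocalBestHits(allVsAll(ppn$proteomeA, ppn$proteomeB),
                               allVsAll(ppn$proteomeB, ppn$proteomeA))
    bln <- syntenyBlocks(rbhn, ppn$positionsA, ppn$positionsB)
    expect_equal(nrow(detectGeneLoss(bln, ppn$positionsA, rbhn)), 0L)

    ## a loss at the chain edge (no right flank) is not called
    ppe <- makeProteomePair(proteomePairSpec(nOrthologs = 20,
                                             divergence = 0.15, losses = 20,
                                             seed = 30))
    rbhe <- reciprocalBestHits(allVsAll(ppe$proteomeA, ppe$proteomeB),
                               allVsAll(ppe$proteomeB, ppe$proteomeA))
    ble <- syntenyBlocks(rbhe, ppe$positionsA, ppe$positionsB)
    expect_equal(nrow(detectGeneLoss(ble, ppe$positionsA, rbhe)), 0L)
})

test_that("locus synteny maps mirror loss and relocation", {
    pp <- makeProteomePair(proteomePairSpec(nOrthologs = 30, divergence = 0.1,
                                            losses = 15, seed = 31))
    rbh <- reciprocalBestHits(allVsAll(pp$proteomeA, pp$proteomeB),
                              allVsAll(pp$proteomeB, pp$proteomeA))
    others <- list(B = list(pairs = rbh, positions = pp$positionsB))
    m <- locusSyntenyMap("A0015", 3, pp$positionsA, others)
    expect_equal(nrow(m), 7L)
    expect_true(is.na(m$B_id[m$focal]))
    expect_true(all(!is.na(m$B_id[!m$focal])))
    expect_equal(m$B_index[!m$focal], sort(m$B_index[!m$focal]))

    ## full collinear context: all window genes matched in order
    m2 <- locusSyntenyMap("A0005", 2, pp$positionsA, others)
    expect_true(all(!is.na(m2$B_id)))

    ## relocated ortholog carries its foreign chromosome label
    posB <- pp$positionsB
    posB$chrom[posB$id == "B0010"] <- "chrB_2"
    m3 <- locusSyntenyMap("A0010", 1, pp$positionsA,
                          list(B = list(pairs = rbh, positions = posB)))
    expect_equal(m3$B_chrom[m3$focal], "chrB_2")
    expect_error(locusSyntenyMap("missing", 2, pp$positionsA, others),
                 "not found")
})

test_that("proteome divergence is the mean identity shortfall", {
    pairs <- data.frame(idA = "a", idB = "b", score = 1, identity = 0.478)
    expect_equal(proteomeDivergence(pairs), 52.2)
    pairsI <- data.frame(idA = c("a", "b"), idB = c("x", "y"), score = 1,
                         identity = c(1, 1))
    expect_equal(proteomeDivergence(pairsI), 0)
    expect_error(proteomeDivergence(pairs[0, ]), "pair")

    ## generator divergence 0.5 recovered within 2 points
    pp <- makeProteomePair(proteomePairSpec(nOrthologs = 30, divergence = 0.5,
                                            seed = 32))
    rbh <- reciprocalBestHits(allVsAll(pp$proteomeA, pp$proteomeB),
                              allVsAll(pp$proteomeB, pp$proteomeA),
                              pp$proteomeA, pp$proteomeB)
    expect_lt(abs(proteomeDivergence(rbh) - 50), 2)
})

test_that("three-way partition assigns families to the correct cells", {
    ## identical proteomes: everything in the core
    set.seed(33)
    a <- Biostrings::AAStringSet(setNames(vapply(rep(250, 8),
        CompYeast:::randomProteinChr, character(1)), paste0("g", 1:8)))
    cells <- coreAndUnique(a, a, a)
    expect_equal(unname(cells["ABC"]), 8L)
    expect_equal(sum(cells), 8L)

    ## planted losses and species-specific families match the recorded truth
    tri <- makeProteomeTriple(
        proteomePairSpec(nOrthologs = 20, divergence = 0.15, losses = c(3, 4),
                         paralogFamilies = c(3), seed = 34),
        proteomePairSpec(nOrthologs = 20, divergence = 0.15, losses = c(4, 9),
                         paralogFamilies = c(2, 2), seed = 35))
    cells2 <- coreAndUnique(tri$proteomeA, tri$proteomeB, tri$proteomeC)
    expect_equal(cells2[names(tri$truthCells)], tri$truthCells,
                 ignore_attr = TRUE)

    ## an empty proteome empties its cells
    cells3 <- coreAndUnique(a, a, Biostrings::AAStringSet())
    expect_equal(unname(cells3["AB"]), 8L)
    expect_equal(unname(cells3["ABC"] + cells3["AC"] + cells3["BC"] +
                        cells3["C"]), 0L)
})
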