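#' All-vs-all protein similarity search
#'
#' For every query protein, candidate subjects sharing at least `minShared`
#' 4-mers are aligned locally (BLOSUM62, affine gaps: open 11, extend 1 --
#' standard protein-search scoring) and hits at `minScore` or better are
#' reported with identity and coverage of the shorter sequence.
#'
#' @param query,subject named `AAStringSet`s
#' @param minScore minimum local alignment score (default 60, above the
#'   chance-similarity range of unrelated yeast-sized proteins)
#' @param k seed word length
#' @param minShared minimum shared k-mers to trigger an alignment
#' @return data.frame: `query_id`, `subject_id`, `score`, `identity`,
#'   `coverage`
#' @export
allVsAll <- function(query, subject, minScore = 60, k = 4, minShared = 3) {
    stopIfNot(length(query) > 0 && length(subject) > 0, "empty proteome")
    cand <- kmerCandidatePairs(query, subject, k = k, minShared = minShared)
    rows <- lapply(seq_len(nrow(cand)), function(r) {
        al <- alignPair(query[[cand$i[r]]], subject[[cand$j[r]]])
        if (al$score < minScore) return(NULL)
        data.frame(query_id = names(query)[cand$i[r]],
                   subject_id = names(subject)[cand$j[r]],
                   score = al$score, identity = al$identity,
                   coverage = al$coverage, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    if (is.null(out))
        out <- data.frame(query_id = character(), subject_id = character(),
                          score = numeric(), identity = numeric(),
                          coverage = numeric())
    out[order(out$query_id, -out$score, out$subject_id), , drop = FALSE]
}

#' Reciprocal best hits between two proteomes
#'
#' A pair (a, b) is kept iff b is a's unique best subject and a is b's
#' unique best query (a symmetrical best hit). An equal-score tie for the
#' top disqualifies the gene: an ambiguous best hit, typically a recent
#' duplicate, is not a trustworthy ortholog call. When the proteomes are
#' supplied, pair identity is recomputed from a global alignment (local
#' identity can be inflated by end trimming).
#'
#' @param hitsAB hits from `allVsAll(A, B)`
#' @param hitsBA hits from `allVsAll(B, A)`
#' @param proteomeA,proteomeB optional `AAStringSet`s for global-identity
#'   recomputation
#' @return data.frame of ortholog pairs: `idA`, `idB`, `score`, `identity`
#' @export
reciprocalBestHits <- function(hitsAB, hitsBA,
                               proteomeA = NULL, proteomeB = NULL) {
    bestAB <- uniqueBest(hitsAB)
    bestBA <- uniqueBest(hitsBA)
    m <- merge(bestAB, setNames(bestBA, c("subject_id", "query_id",
                                          "score_ba", "identity_ba")),
               by = c("query_id", "subject_id"))
    pairs <- data.frame(idA = m$query_id, idB = m$subject_id,
                        score = m$score, identity = m$identity,
                        stringsAsFactors = FALSE)
    if (!is.null(proteomeA) && !is.null(proteomeB) && nrow(pairs))
        pairs$identity <- vapply(seq_len(nrow(pairs)), function(r) {
            pa <- Biostrings::pairwiseAlignment(
                proteomeA[[pairs$idA[r]]], proteomeB[[pairs$idB[r]]],
                type = "global", substitutionMatrix = "BLOSUM62",
                gapOpening = 11, gapExtension = 1)
            Biostrings::pid(pa, "PID1") / 100
        }, numeric(1))
    pairs[order(pairs$idA), , drop = FALSE]
}

## unique best subject per query; equal-score ties drop the query
uniqueBest <- function(hits) {
    if (!nrow(hits))
        return(data.frame(query_id = character(), subject_id = character(),
                          score = numeric(), identity = numeric()))
    rows <- lapply(split(hits, hits$query_id), function(h) {
        top <- h[h$score == max(h$score), , drop = FALSE]
        if (nrow(top) > 1) return(NULL)   # ambiguous best: disqualified
        top[, c("query_id", "subject_id", "score", "identity")]
    })
    out <- do.call(rbind, rows)
    if (is.null(out)) data.frame(query_id = character(),
                                 subject_id = character(),
                                 score = numeric(), identity = numeric())
    else out
}

## join gene-order positions onto ortholog pairs
pairPositions <- function(pairs, positionsA, positionsB) {
    ia <- match(pairs$idA, positionsA$id)
    ib <- match(pairs$idB, positionsB$id)
    stopIfNot(!anyNA(ia) && !anyNA(ib),
              "ortholog pair gene missing from the position tables")
    cbind(pairs,
          data.frame(chromA = positionsA$chrom[ia],
                     indexA = positionsA$index[ia],
                     chromB = positionsB$chrom[ib],
                     indexB = positionsB$index[ib],
                     stringsAsFactors = FALSE))
}

#' Dot-plot coordinates for ortholog pairs
#'
#' One point per reciprocal best hit, in gene-order coordinates of the two
#' genomes; plot-ready with any tool.
#'
#' @param pairs pairs from [reciprocalBestHits()]
#' @param positionsA,positionsB data.frames `id`, `chrom`, `index`
#' @return data.frame: `idA`, `idB`, `chromA`, `indexA`, `chromB`, `indexB`
#' @export
dotplotTable <- function(pairs, positionsA, positionsB) {
    if (!nrow(pairs))
        return(data.frame(idA = character(), idB = character(),
                          chromA = character(), indexA = integer(),
                          chromB = character(), indexB = integer()))
    pairPositions(pairs, positionsA, positionsB)[
        c("idA", "idB", "chromA", "indexA", "chromB", "indexB")]
}

#' Chain ortholog pairs into synteny blocks
#'
#' Pairs are sorted by gene order in genome A and chained greedily: a pair
#' extends the current block when both chromosomes match, the gene-index gap
#' is at most `maxGap` on both sides, and the direction on genome B stays
#' monotone (same or inverted orientation). Every pair lands in exactly one
#' block; single-pair blocks are kept.
#'
#' @inheritParams dotplotTable
#' @param maxGap maximal number of skipped genes inside a block (default 3)
#' @return data.frame of pairs with `blockId` and `orientation` columns;
#'   blocks are numbered in genome-A order
#' @export
syntenyBlocks <- function(pairs, positionsA, positionsB, maxGap = 3) {
    if (!nrow(pairs))
        return(cbind(dotplotTable(pairs, positionsA, positionsB),
                     blockId = integer(), orientation = character()))
    pp <- pairPositions(pairs, positionsA, positionsB)
    pp <- pp[order(pp$chromA, pp$indexA), , drop = FALSE]
    n <- nrow(pp)
    blockId <- integer(n)
    orient <- character(n)
    bid <- 1L
    blockId[1] <- bid
    dir <- 0L
    for (r in 2:max(2, n)) {
        if (n < 2) break
        sameChrom <- pp$chromA[r] == pp$chromA[r - 1] &&
                     pp$chromB[r] == pp$chromB[r - 1]
        gapA <- pp$indexA[r] - pp$indexA[r - 1] - 1
        stepB <- pp$indexB[r] - pp$indexB[r - 1]
        gapB <- abs(stepB) - 1
        okDir <- dir == 0L || sign(stepB) == dir
        if (sameChrom && gapA <= maxGap && gapB <= maxGap && stepB != 0 &&
            okDir) {
            if (dir == 0L) dir <- sign(stepB)
        } else {
            bid <- bid + 1L
            dir <- 0L
        }
        blockId[r] <- bid
    }
    pp$blockId <- blockId
    for (b in unique(blockId)) {
        sel <- blockId == b
        d <- diff(pp$indexB[sel])
        orient[sel] <- if (!length(d)) "same"
                       else if (all(d > 0)) "same" else "inverted"
    }
    pp$orientation <- orient
    pp
}

#' Detect gene-loss candidates inside synteny blocks
#'
#' A gene of genome A is reported as lost from genome B when it lies between
#' two consecutive ortholog anchors of one synteny block and has no ortholog
#' in B at all. Requiring both flanking anchors in the same block separates
#' a genuine loss (a gap in otherwise conserved gene order, the signature of
#' e.g. a methanol-oxidase deletion) from an ordinary block boundary; genes
#' missing at a block edge are not called.
#'
#' @param blocks result of [syntenyBlocks()]
#' @param positionsA full gene-order table of genome A (`id`, `chrom`,
#'   `index`), including genes without orthologs
#' @param pairs all ortholog pairs (to know which A genes have any ortholog)
#' @return data.frame: `missingGeneId`, `indexA`, `blockId`, `leftFlank`,
#'   `rightFlank`
#' @export
detectGeneLoss <- function(blocks, positionsA, pairs) {
    out <- list()
    hasOrtholog <- positionsA$id %in% pairs$idA
    for (b in unique(blocks$blockId)) {
        bl <- blocks[blocks$blockId == b, , drop = FALSE]
        bl <- bl[order(bl$indexA), , drop = FALSE]
        if (nrow(bl) < 2) next
        for (r in seq_len(nrow(bl) - 1)) {
            lo <- bl$indexA[r]; hi <- bl$indexA[r + 1]
            if (hi - lo < 2) next
            gapIdx <- which(positionsA$chrom == bl$chromA[1] &
                            positionsA$index > lo & positionsA$index < hi &
                            !hasOrtholog)
            for (gi in gapIdx)
                out[[length(out) + 1L]] <- data.frame(
                    missingGeneId = positionsA$id[gi],
                    indexA = positionsA$index[gi], blockId = b,
                    leftFlank = bl$idA[r], rightFlank = bl$idA[r + 1],
                    stringsAsFactors = FALSE)
        }
    }
    if (!length(out))
        return(data.frame(missingGeneId = character(), indexA = integer(),
                          blockId = integer(), leftFlank = character(),
                          rightFlank = character()))
    do.call(rbind, out)
}

#' Gene-order map around a focal locus
#'
#' Builds a table of the `windowGenes` genes on either side of a focal gene
#' in genome A, with each gene's ortholog (id, chromosome, gene index) in
#' every other genome -- the row structure of a locus synteny figure. A
#' planted loss appears as an empty row cell with matched flanks; a
#' relocated ortholog carries its foreign chromosome label.
#'
#' @param focalGene gene id in genome A
#' @param windowGenes number of genes on each side
#' @param positionsA gene-order table of genome A
#' @param others named list; each element is `list(pairs = , positions = )`
#'   for one other genome
#' @return data.frame with one row per window gene and three columns
#'   (`<genome>_id`, `<genome>_chrom`, `<genome>_index`) per other genome
#' @export
locusSyntenyMap <- function(focalGene, windowGenes, positionsA, others) {
    fi <- match(focalGene, positionsA$id)
    stopIfNot(!is.na(fi), "focal gene not found in genome A")
    fChrom <- positionsA$chrom[fi]
    fIndex <- positionsA$index[fi]
    sel <- positionsA$chrom == fChrom &
           abs(positionsA$index - fIndex) <= windowGenes
    win <- positionsA[sel, , drop = FALSE]
    win <- win[order(win$index), , drop = FALSE]
    out <- data.frame(geneA = win$id, indexA = win$index, focal = win$id ==
                      focalGene, stringsAsFactors = FALSE)
    for (nm in names(others)) {
        prs <- others[[nm]]$pairs
        pos <- others[[nm]]$positions
        j <- match(win$id, prs$idA)
        idB <- prs$idB[j]
        pj <- match(idB, pos$id)
        out[[paste0(nm, "_id")]] <- idB
        out[[paste0(nm, "_chrom")]] <- pos$chrom[pj]
        out[[paste0(nm, "_index")]] <- pos$index[pj]
    }
    out
}

#' Mean proteome divergence over ortholog pairs
#'
#' `100 - mean(identity x 100)` over reciprocal-best-hit pairs, unweighted:
#' the established way to put a single percentage on the sequence variation
#' between two genomes (a single pair at identity 0.478 gives 52.2%).
#'
#' @param pairs pairs from [reciprocalBestHits()]
#' @return percent divergence
#' @export
proteomeDivergence <- function(pairs) {
    stopIfNot(nrow(pairs) >= 1, "need at least one ortholog pair")
    100 - mean(pairs$identity * 100)
}

#' Shared and unique protein families across three proteomes
#'
#' Joins genes into families by combining cross-species reciprocal best hits
#' with within-species paralog clustering ([clusterProteins()]), then assigns
#' every family (connected component) to one of the 7 cells of the three-way
#' shared/unique partition by which species contribute members. Genes with
#' no ortholog or paralog anywhere are species-specific singleton families.
#'
#' @param proteomeA,proteomeB,proteomeC named `AAStringSet`s
#' @param minScore passed to [allVsAll()]
#' @return named integer vector with cells `ABC`, `AB`, `AC`, `BC`, `A`,
#'   `B`, `C`
#' @export
coreAndUnique <- function(proteomeA, proteomeB, proteomeC, minScore = 60) {
    prots <- list(A = proteomeA, B = proteomeB, C = proteomeC)
    ids <- unlist(lapply(names(prots), function(s)
        if (length(prots[[s]])) paste0(s, ":", names(prots[[s]])) else
            character(0)))
    species <- sub(":.*", "", ids)
    edges <- matrix(integer(0), ncol = 2)
    for (pairNm in list(c("A", "B"), c("A", "C"), c("B", "C"))) {
        p1 <- prots[[pairNm[1]]]; p2 <- prots[[pairNm[2]]]
        if (!length(p1) || !length(p2)) next
        rbh <- reciprocalBestHits(allVsAll(p1, p2, minScore),
                                  allVsAll(p2, p1, minScore))
        if (!nrow(rbh)) next
        e1 <- match(paste0(pairNm[1], ":", rbh$idA), ids)
        e2 <- match(paste0(pairNm[2], ":", rbh$idB), ids)
        edges <- rbind(edges, cbind(e1, e2))
    }
    for (s in names(prots)) {   # lineage-specific paralogs form one family
        if (!length(prots[[s]])) next
        fams <- clusterProteins(prots[[s]])$families
        for (f in fams[lengths(fams) > 1]) {
            e <- match(paste0(s, ":", f), ids)
            edges <- rbind(edges, cbind(e[-length(e)], e[-1]))
        }
    }
    comp <- ufComponents(length(ids), edges)
    cells <- c(ABC = 0L, AB = 0L, AC = 0L, BC = 0L, A = 0L, B = 0L, C = 0L)
    for (cc in split(seq_along(ids), comp)) {
        sp <- sort(unique(species[cc]))
        cell <- paste(sp, collapse = "")
        cells[cell] <- cells[cell] + 1L
    }
    cells
}
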