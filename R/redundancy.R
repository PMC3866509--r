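#' Split a genome into non-overlapping fragments
#'
#' Consecutive windows of `size` bp per chromosome; a trailing remainder
#' shorter than `size` is discarded.
#'
#' @param genome named `DNAStringSet`
#' @param size fragment size in bp (2000 or 5000 in the classic protocol)
#' @return data.frame `chrom`, `start`, `end`
#' @export
fragmentGenome <- function(genome, size) {
    stopIfNot(size > 0, "size must be > 0")
    out <- lapply(seq_along(genome), function(i) {
        n <- Biostrings::width(genome)[i] %/% size
        if (!n) return(NULL)
        data.frame(chrom = names(genome)[i],
                   start = (seq_len(n) - 1L) * size + 1L,
                   end = seq_len(n) * size, stringsAsFactors = FALSE)
    })
    do.call(rbind, c(out, list(make.row.names = FALSE)))
}

## k-mer position index of the forward genome, keyed by numeric code
genomeKmerIndex <- function(genome, k = 13) {
    dts <- lapply(seq_along(genome), function(i) {
        code <- kmerCodes(as.character(genome[[i]]), k)
        data.table::data.table(code = code, chrom = i,
                               pos = seq_along(code))[!is.na(code)]
    })
    idx <- data.table::rbindlist(dts)
    data.table::setkey(idx, code)
    structure(list(index = idx, k = k, genome = genome), class = "kmerIndex")
}

#' Search a genome for copies of one of its fragments
#'
#' k-mer seeded, alignment-extended genome self-search: seed matches on both
#' strands are grouped by diagonal (within 100 bp, which also merges
#' collinear sub-alignments), each candidate locus is re-aligned locally
#' (match 2, mismatch -3, gap open 5, extend 2) and admitted when it covers
#' at least `minAlignedFraction` of the fragment at `minIdentity` or better.
#' The identity/coverage admission rule replaces a BLAST e-value cutoff: the
#' downstream report bins fragments by exactly these two quantities. The hit
#' overlapping the fragment's own locus is flagged `self`.
#'
#' @param genome named `DNAStringSet`
#' @param fragment one row of [fragmentGenome()] output (or any list with
#'   `chrom`, `start`, `end`)
#' @param minAlignedFraction minimum fraction of the fragment aligned (1/3)
#' @param minIdentity minimum alignment identity (0.70)
#' @param index optional prebuilt index from repeated searches
#' @param k seed length (13 keeps chance diagonal seed pairs rare while an
#'   admissible hit still carries many seeds)
#' @return data.frame of hits: `hitChrom`, `hitStart`, `hitEnd`, `strand`,
#'   `alignedFraction`, `identity`, `score`, `self`
#' @export
selfSearch <- function(genome, fragment, minAlignedFraction = 1 / 3,
                       minIdentity = 0.70, index = NULL, k = 13) {
    if (is.null(index)) index <- genomeKmerIndex(genome, k)
    k <- index$k
    fragChromIdx <- match(fragment$chrom, names(genome))
    stopIfNot(!is.na(fragChromIdx), "fragment chromosome not in genome")
    fragSeq <- Biostrings::subseq(genome[[fragChromIdx]],
                                  fragment$start, fragment$end)
    fragLen <- length(fragSeq)
    patterns <- list(`+` = fragSeq,
                     `-` = Biostrings::reverseComplement(fragSeq))
    ## a real hit covering minAlignedFraction at minIdentity carries about
    ## minAF * fragLen * minIdentity^k seeds; ask for a quarter of that
    minSeeds <- max(2, floor(minAlignedFraction * fragLen *
                             minIdentity^k / 4))
    hits <- list()
    code <- NULL  # data.table NSE
    for (strand in c("+", "-")) {
        pc <- kmerCodes(as.character(patterns[[strand]]), k)
        qdt <- data.table::data.table(code = pc, qpos = seq_along(pc))[
            !is.na(code)]
        nSeeds <- nrow(qdt)
        m <- index$index[qdt, on = "code", nomatch = NULL, allow.cartesian = TRUE]
        if (!nrow(m)) next
        m$diag <- m$pos - m$qpos
        data.table::setorder(m, chrom, diag)
        for (ch in unique(m$chrom)) {
            mc <- m[m$chrom == ch]
            grp <- splitByGap(mc$diag, 100)
            for (g in split(seq_len(nrow(mc)), grp)) {
                if (length(g) < minSeeds) next  # chance diagonal seeds
                dmin <- mc$diag[g[1]]; dmax <- mc$diag[g[length(g)]]
                ## an exact full-length self match needs no alignment
                if (strand == "+" && ch == fragChromIdx &&
                    dmin == dmax && dmin == fragment$start - 1L &&
                    length(g) == nSeeds) {
                    hits[[length(hits) + 1L]] <- data.frame(
                        hitChrom = names(genome)[ch],
                        hitStart = fragment$start, hitEnd = fragment$end,
                        strand = "+", alignedFraction = 1, identity = 1,
                        score = 2 * fragLen, stringsAsFactors = FALSE)
                    next
                }
                ## seed span bounds the aligned span; skip hopeless groups
                qspan <- diff(range(mc$qpos[g])) + k
                if (qspan + 300 < minAlignedFraction * fragLen) next
                chromLen <- Biostrings::width(genome)[ch]
                ws <- max(1L, dmin + 1L - 50L)
                we <- min(chromLen, dmax + fragLen + 50L)
                pa <- Biostrings::pairwiseAlignment(
                    patterns[[strand]],
                    Biostrings::subseq(genome[[ch]], ws, we),
                    type = "local", gapOpening = 5, gapExtension = 2,
                    substitutionMatrix =
                        Biostrings::nucleotideSubstitutionMatrix(2, -3))
                af <- (Biostrings::end(Biostrings::pattern(pa)) -
                       Biostrings::start(Biostrings::pattern(pa)) + 1) / fragLen
                ident <- Biostrings::pid(pa, "PID1") / 100
                if (af >= minAlignedFraction && ident >= minIdentity) {
                    hs <- ws + Biostrings::start(Biostrings::subject(pa)) - 1L
                    he <- ws + Biostrings::end(Biostrings::subject(pa)) - 1L
                    hits[[length(hits) + 1L]] <- data.frame(
                        hitChrom = names(genome)[ch], hitStart = hs,
                        hitEnd = he, strand = strand,
                        alignedFraction = af, identity = ident,
                        score = BiocGenerics::score(pa),
                        stringsAsFactors = FALSE)
                }
            }
        }
    }
    if (!length(hits))
        return(data.frame(hitChrom = character(), hitStart = integer(),
                          hitEnd = integer(), strand = character(),
                          alignedFraction = numeric(), identity = numeric(),
                          score = numeric(), self = logical()))
    df <- do.call(rbind, hits)
    df <- dedupeHits(df)
    df$self <- df$hitChrom == fragment$chrom & df$strand == "+" &
        df$hitStart <= fragment$end & df$hitEnd >= fragment$start
    df[order(-df$score), , drop = FALSE]
}

## collapse hits that cover the same locus (>=50% reciprocal overlap, same
## chromosome); keep the best-scoring one
dedupeHits <- function(df) {
    df <- df[order(-df$score), , drop = FALSE]
    keep <- rep(TRUE, nrow(df))
    for (i in seq_len(nrow(df))) {
        if (!keep[i]) next
        for (j in seq_len(nrow(df))) {
            if (j <= i || !keep[j]) next
            if (df$hitChrom[i] != df$hitChrom[j]) next
            ov <- min(df$hitEnd[i], df$hitEnd[j]) -
                  max(df$hitStart[i], df$hitStart[j]) + 1
            if (ov > 0 && ov >= 0.5 * min(df$hitEnd[i] - df$hitStart[i] + 1,
                                          df$hitEnd[j] - df$hitStart[j] + 1))
                keep[j] <- FALSE
        }
    }
    df[keep, , drop = FALSE]
}

#' Segmental-duplication report for a genome
#'
#' Splits the genome into non-overlapping fragments of each size, runs the
#' genome self-search for every fragment, and tallies fragments whose total
#' hit count (self hit included, so 2 hits = one extra copy) is exactly 2 or
#' exactly 3 at identity above each bin threshold.
#'
#' @param genome named `DNAStringSet`
#' @param sizes fragment sizes in bp
#' @param identityBins lower identity bounds of the report bins
#' @param hitCounts hit-count cells (total hits including self)
#' @param countSelf logical; if `FALSE`, the self hit is excluded from the
#'   hit counts (so 1 hit = one extra copy)
#' @inheritParams selfSearch
#' @return data.frame `fragmentSize` x `hitCount` x `identityBin` tallies
#' @export
duplicationReport <- function(genome, sizes = c(2000, 5000),
                              identityBins = c(0.7, 0.8, 0.9),
                              hitCounts = c(2, 3), countSelf = TRUE,
                              minAlignedFraction = 1 / 3, k = 13) {
    index <- genomeKmerIndex(genome, k)
    grid <- expand.grid(fragmentSize = sizes, hitCount = hitCounts,
                        identityBin = identityBins)
    grid$count <- 0L
    for (size in sizes) {
        frags <- fragmentGenome(genome, size)
        for (f in seq_len(nrow(frags))) {
            hits <- selfSearch(genome, frags[f, ],
                               minAlignedFraction = minAlignedFraction,
                               minIdentity = min(identityBins), index = index)
            if (!countSelf) hits <- hits[!hits$self, , drop = FALSE]
            for (bin in identityBins) {
                nh <- sum(hits$identity > bin)
                sel <- grid$fragmentSize == size & grid$identityBin == bin &
                       grid$hitCount == nh
                grid$count[sel] <- grid$count[sel] + 1L
            }
        }
    }
    grid
}

#' Write a duplication report as a TSV matrix
#'
#' Rows: fragment size x hit count; columns: identity bins.
#'
#' @param report result of [duplicationReport()]
#' @param path output file
#' @export
writeDuplicationReportTsv <- function(report, path) {
    wide <- reshapeReport(report)
    write.table(wide, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

reshapeReport <- function(report) {
    bins <- sort(unique(report$identityBin))
    rows <- unique(report[c("fragmentSize", "hitCount")])
    for (b in bins) {
        sub <- report[report$identityBin == b, ]
        rows[[sprintf(">%d%%", round(100 * b))]] <-
            sub$count[match(paste(rows$fragmentSize, rows$hitCount),
                            paste(sub$fragmentSize, sub$hitCount))]
    }
    rows
}

#' Single-linkage protein-family clustering
#'
#' Builds a similarity graph with an edge wherever two proteins align at
#' `minIdentity` or better over at least `minCoverage` of the shorter
#' sequence (local alignment, BLOSUM62, affine gaps 11/1; candidate pairs
#' are pre-filtered by shared 4-mers) and returns its connected components.
#' Output is deterministic and invariant to input order: members and
#' families are sorted by id.
#'
#' @param proteome named `AAStringSet`
#' @param minIdentity minimum pairwise identity (default 0.5)
#' @param minCoverage minimum aligned fraction of the shorter sequence (0.5)
#' @return list with `families` (list of member-id vectors), `nGenes`,
#'   `nFamilies` and `sizes` (family-size table)
#' @export
clusterProteins <- function(proteome, minIdentity = 0.5, minCoverage = 0.5) {
    stopIfNot(length(proteome) > 0, "empty proteome")
    stopIfNot(all(Biostrings::width(proteome) > 0),
              "empty sequences in proteome")
    ord <- order(names(proteome))
    proteome <- proteome[ord]
    n <- length(proteome)
    cand <- kmerCandidatePairs(proteome, proteome, k = 4, minShared = 3)
    cand <- cand[cand$i < cand$j, , drop = FALSE]
    edges <- matrix(integer(0), ncol = 2)
    if (nrow(cand)) {
        keep <- logical(nrow(cand))
        for (r in seq_len(nrow(cand))) {
            al <- alignPair(proteome[[cand$i[r]]], proteome[[cand$j[r]]])
            keep[r] <- al$identity >= minIdentity && al$coverage >= minCoverage
        }
        edges <- cbind(cand$i[keep], cand$j[keep])
    }
    comp <- ufComponents(n, edges)
    fams <- lapply(split(names(proteome), comp), sort)
    fams <- fams[order(vapply(fams, `[`, character(1), 1))]
    names(fams) <- NULL
    list(families = fams, nGenes = n, nFamilies = length(fams),
         sizes = table(lengths(fams)))
}

## local protein alignment summary used by clustering and all-vs-all
alignPair <- function(a, b) {
    pa <- Biostrings::pairwiseAlignment(a, b, type = "local",
        substitutionMatrix = "BLOSUM62", gapOpening = 11, gapExtension = 1)
    shorter <- min(length(a), length(b))
    cov <- (Biostrings::end(Biostrings::pattern(pa)) -
            Biostrings::start(Biostrings::pattern(pa)) + 1) / shorter
    list(score = BiocGenerics::score(pa),
         identity = Biostrings::pid(pa, "PID1") / 100,
         coverage = min(1, cov))
}

## candidate (i, j) pairs sharing >= minShared k-mers; i indexes `a`,
## j indexes `b`
kmerCandidatePairs <- function(a, b, k = 4, minShared = 3) {
    kmersOf <- function(s) {
        if (nchar(s) < k) return(character(0))
        unique(substring(s, 1:(nchar(s) - k + 1), k:nchar(s)))
    }
    ka <- lapply(as.character(a), kmersOf)
    kb <- lapply(as.character(b), kmersOf)
    dtb <- data.table::data.table(
        kmer = unlist(kb), j = rep(seq_along(kb), lengths(kb)))
    data.table::setkey(dtb, kmer)
    res <- lapply(seq_along(ka), function(i) {
        if (!length(ka[[i]])) return(NULL)
        m <- dtb[data.table::data.table(kmer = ka[[i]]), on = "kmer",
                 nomatch = NULL]
        tab <- m[, .N, by = "j"]
        js <- tab$j[tab$N >= minShared]
        if (!length(js)) return(NULL)
        data.frame(i = i, j = js)
    })
    out <- do.call(rbind, res)
    if (is.null(out)) data.frame(i = integer(), j = integer()) else out
}

#' Raw genome redundancy ratio
#'
#' Total protein-coding genes divided by the number of distinct protein
#' families, rounded half-up to two decimals (5325 genes over 4217 families
#' gives 1.26).
#'
#' @param nGenes total protein-coding genes
#' @param nFamilies number of distinct protein families
#' @export
redundancyRatio <- function(nGenes, nFamilies) {
    stopIfNot(nFamilies >= 1, "nFamilies must be >= 1")
    stopIfNot(nGenes >= nFamilies, "nGenes must be >= nFamilies")
    roundHalfUp(nGenes / nFamilies, 2)
}

#' Copy number of a collapsed repeat from read depth
#'
#' `round(mean depth over the unit / median depth over single-copy
#' background)`; a tandem array collapsed to one assembly copy attracts
#' copy-number-fold coverage, so the depth ratio recovers the copy number.
#'
#' @param unitDepth per-base depths over the collapsed unit
#' @param backgroundDepth per-base depths over single-copy background
#' @return integer copy-number estimate
#' @export
estimateCopyNumber <- function(unitDepth, backgroundDepth) {
    med <- median(backgroundDepth)
    stopIfNot(is.finite(med) && med > 0, "zero background coverage")
    as.integer(round(mean(unitDepth) / med))
}
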