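## Independent oracles used across the suite. These deliberately avoid the
## code paths they check: counting by character vectors, probabilities by
## binomial-coefficient ratios, and search by exhaustive window alignment.

## GC by naive character counting
naiveGC <- function(s) {
    ch <- strsplit(toupper(s), "")[[1]]
    sum(ch %in% c("G", "C")) / sum(ch %in% c("A", "C", "G", "T"))
}

## one-sided (greater) Fisher p by explicit enumeration of all tables with
## the observed margins, probabilities from choose() ratios
bruteFisherGreater <- function(a, b, c, d) {
    K <- a + c; n <- a + b; N <- a + b + c + d
    if (N == 0) return(1)
    xs <- max(0, n - (N - K)):min(n, K)
    probs <- choose(K, xs) * choose(N - K, n - xs) / choose(N, n)
    sum(probs[xs >= a])
}

## BH step-up by the direct definition: q_(i) = min_{j >= i} m p_(j) / j
directBH <- function(p) {
    m <- length(p)
    o <- order(p)
    ps <- p[o]
    qs <- vapply(seq_len(m), function(i)
        min(1, min(m * ps[i:m] / (i:m))), numeric(1))
    qs[order(o)]
}

## exhaustive self-search: align the fragment (both strands) against every
## overlapping window of the genome and keep admissible loci
## windowSize - fragLen must exceed step so every admissible locus fits
## entirely inside at least one window; partial detections in neighbouring
## windows are sub-intervals of the full hit and merge away below
exhaustiveSelfSearch <- function(genome, fragment, minAF = 1 / 3,
                                 minIdent = 0.7, windowSize = 3500,
                                 step = 1000) {
    ci <- match(fragment$chrom, names(genome))
    fragSeq <- Biostrings::subseq(genome[[ci]], fragment$start, fragment$end)
    fragLen <- length(fragSeq)
    pats <- list(`+` = fragSeq,
                 `-` = Biostrings::reverseComplement(fragSeq))
    sm <- Biostrings::nucleotideSubstitutionMatrix(2, -3)
    hits <- list()
    for (i in seq_along(genome)) {
        L <- Biostrings::width(genome)[i]
        starts <- unique(c(seq(1, max(1, L - windowSize + 1), by = step)))
        for (ws in starts) {
            we <- min(L, ws + windowSize - 1)
            for (strand in c("+", "-")) {
                pa <- Biostrings::pairwiseAlignment(pats[[strand]],
                    Biostrings::subseq(genome[[i]], ws, we), type = "local",
                    gapOpening = 5, gapExtension = 2,
                    substitutionMatrix = sm)
                af <- (BiocGenerics::end(Biostrings::pattern(pa)) -
                       BiocGenerics::start(Biostrings::pattern(pa)) + 1) /
                      fragLen
                ident <- Biostrings::pid(pa, "PID1") / 100
                if (af >= minAF && ident >= minIdent)
                    hits[[length(hits) + 1L]] <- data.frame(
                        chrom = names(genome)[i],
                        start = ws + BiocGenerics::start(
                            Biostrings::subject(pa)) - 1L,
                        end = ws + BiocGenerics::end(
                            Biostrings::subject(pa)) - 1L,
                        strand = strand, identity = ident,
                        score = BiocGenerics::score(pa))
            }
        }
    }
    if (!length(hits)) return(NULL)
    df <- do.call(rbind, hits)
    ## merge window-overlapping detections of one locus, keep the best
    df <- df[order(-df$score), , drop = FALSE]
    keep <- rep(TRUE, nrow(df))
    for (i in seq_len(nrow(df))) {
        if (!keep[i]) next
        for (j in seq_len(nrow(df))) {
            if (j <= i || !keep[j]) next
            if (df$chrom[i] != df$chrom[j] || df$strand[i] != df$strand[j])
                next
            ov <- min(df$end[i], df$end[j]) - max(df$start[i], df$start[j]) + 1
            if (ov >= 0.5 * min(df$end[i] - df$start[i] + 1,
                                df$end[j] - df$start[j] + 1))
                keep[j] <- FALSE
        }
    }
    df[keep, , drop = FALSE]
}

## reference synteny segmentation applied to a planted ortholog map:
## count maximal runs under the max-gap / monotone-direction rule
referenceBlockCount <- function(indexA, indexB, maxGap = 3) {
    o <- order(indexA)
    ia <- indexA[o]; ib <- indexB[o]
    n <- length(ia)
    if (n <= 1) return(n)
    blocks <- 1L
    dir <- 0L
    for (r in 2:n) {
        gapA <- ia[r] - ia[r - 1] - 1
        stepB <- ib[r] - ib[r - 1]
        ok <- gapA <= maxGap && abs(stepB) - 1 <= maxGap &&
              (dir == 0L || sign(stepB) == dir)
        if (ok) {
            if (dir == 0L) dir <- sign(stepB)
        } else {
            blocks <- blocks + 1L
            dir <- 0L
        }
    }
    blocks
}

## random single-exon annotation GRanges on given chromosome lengths
randomAnnotations <- function(chromLens, n) {
    chrom <- sample(names(chromLens), n, replace = TRUE)
    start <- vapply(chrom, function(ch)
        sample.int(chromLens[[ch]] - 2000, 1), numeric(1))
    gr <- GenomicRanges::GRanges(chrom,
        IRanges::IRanges(start, start + sample(200:1500, n, replace = TRUE)),
        strand = sample(c("+", "-"), n, replace = TRUE))
    gr$gene_id <- sprintf("R%04d", seq_len(n))
    gr$exons <- IRanges::IRangesList(lapply(seq_len(n), function(i)
        IRanges::IRanges()))
    gr
}
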