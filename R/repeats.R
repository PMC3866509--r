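#' Detect tandem telomeric repeats at chromosome ends
#'
#' Scans for tandem runs of the telomeric motif (forward motif near the 3'
#' end, its reverse complement near the 5' end) and calls an end telomeric
#' when a run of at least `minCopies` exact copies starts within `maxOffset`
#' of the end. The motif is matched exactly: assembled yeast telomeres carry
#' the pure repeat.
#'
#' @param genome named `DNAStringSet`
#' @param motif telomeric repeat unit, 3'-end orientation (GGTGGCGG)
#' @param minCopies minimum tandem copies (default 3)
#' @param maxOffset maximal distance of the run from the chromosome end (bp)
#' @return data.frame: `chrom`, `end` (5prime/3prime), `motif`, `copies`,
#'   `offsetFromEnd`, `start`, `stop`
#' @export
findTelomericRepeats <- function(genome, motif = "GGTGGCGG", minCopies = 3,
                                 maxOffset = 200) {
    stopIfNot(nchar(motif) > 0, "empty motif")
    rcMotif <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(motif)))
    calls <- list()
    for (i in seq_along(genome)) {
        s <- as.character(genome[[i]])
        L <- nchar(s)
        for (side in c("5prime", "3prime")) {
            m <- if (side == "3prime") motif else rcMotif
            runs <- gregexpr(paste0("(?:", m, ")+"), s)[[1]]
            if (runs[1] == -1) next
            lens <- attr(runs, "match.length")
            for (r in seq_along(runs)) {
                copies <- lens[r] %/% nchar(motif)
                off <- if (side == "3prime") L - (runs[r] + lens[r] - 1)
                       else runs[r] - 1
                if (copies >= minCopies && off <= maxOffset)
                    calls[[length(calls) + 1L]] <- data.frame(
                        chrom = names(genome)[i], end = side, motif = motif,
                        copies = copies, offsetFromEnd = off,
                        start = runs[r], stop = runs[r] + lens[r] - 1L,
                        stringsAsFactors = FALSE)
            }
        }
    }
    if (!length(calls))
        return(data.frame(chrom = character(), end = character(),
                          motif = character(), copies = integer(),
                          offsetFromEnd = integer(), start = integer(),
                          stop = integer()))
    do.call(rbind, calls)
}

#' Flag subtelomeric genes
#'
#' A gene is subtelomeric when its interval overlaps the first or last
#' `distance` bp of its chromosome (any overlap counts, the conservative
#' reading of "within 50 kbp from the chromosome ends"). On a chromosome
#' shorter than twice the distance the two windows overlap and every gene is
#' subtelomeric.
#'
#' @param annotations gene `GRanges`
#' @param chromosomeLengths named vector covering all annotated chromosomes
#' @param distance window size from each end (default 50,000 bp)
#' @return the input `GRanges` with a logical mcol `subtelomeric`
#' @export
subtelomericGenes <- function(annotations, chromosomeLengths,
                              distance = 50000) {
    validateAnnotation(annotations, chromosomeLengths)
    chrom <- as.character(GenomicRanges::seqnames(annotations))
    L <- chromosomeLengths[chrom]
    st <- GenomicRanges::start(annotations)
    en <- GenomicRanges::end(annotations)
    annotations$subtelomeric <- unname(st <= distance |
                                       en >= L - distance + 1)
    annotations
}

#' Find clusters of LTR-like repeated units
#'
#' Discovers repeated units of approximately `unitLength` by exact k-mer
#' self-matching (both strands), merges seed-covered positions into member
#' intervals, keeps members of plausible unit length, groups members within
#' `maxClusterGap` on one chromosome into clusters, orients every member
#' against the cluster majority, builds a majority consensus, and reports
#' each member's identity to that consensus. Clusters need at least two
#' members at `minIdentity` or better.
#'
#' @param genome named `DNAStringSet`
#' @param unitLength expected repeat unit length in bp (~290 for solo LTRs)
#' @param tolerance admissible deviation of member length from `unitLength`
#' @param minIdentity minimum member identity to the cluster consensus
#' @param maxClusterGap members closer than this on one chromosome are one
#'   cluster (bp)
#' @param k seed length
#' @return list of clusters; each cluster is a list with `chrom`, `start`,
#'   `end` (union of member intervals) and a data.frame `members` with
#'   `start`, `end`, `orientation` (direct = majority strand), `identity`
#' @export
findRepeatClusters <- function(genome, unitLength = 290, tolerance = 60,
                               minIdentity = 0.8, maxClusterGap = 5000,
                               k = 15) {
    stopIfNot(unitLength >= 50, "unitLength must be >= 50")
    members <- repeatMemberIntervals(genome, unitLength, tolerance, k)
    if (!nrow(members)) return(list())
    clusters <- list()
    for (ch in unique(members$chrom)) {
        mc <- members[members$chrom == ch, , drop = FALSE]
        mc <- mc[order(mc$start), , drop = FALSE]
        grp <- splitByGap(mc$start, maxClusterGap)
        for (g in split(seq_len(nrow(mc)), grp)) {
            if (length(g) < 2) next
            cl <- annotateCluster(genome, ch, mc[g, , drop = FALSE],
                                  minIdentity)
            if (!is.null(cl)) clusters[[length(clusters) + 1L]] <- cl
        }
    }
    clusters
}

## candidate member intervals: positions whose k-mer recurs elsewhere in the
## genome (either strand), merged with a 60 bp bridge, filtered by length
repeatMemberIntervals <- function(genome, unitLength, tolerance, k) {
    fwd <- lapply(seq_along(genome), function(i)
        kmerCodes(as.character(genome[[i]]), k))
    rev <- lapply(seq_along(genome), function(i)
        kmerCodes(as.character(Biostrings::reverseComplement(genome[[i]])), k))
    ## canonical code = min(code, revcomp code) makes strands comparable
    canon <- lapply(seq_along(genome), function(i) {
        rc <- rev[[i]][length(rev[[i]]):1]   # rc[j]: k-mer starting at j
        pmin(fwd[[i]], rc)
    })
    all <- unlist(canon)
    dup <- all[!is.na(all)]
    dupCodes <- unique(dup[duplicated(dup)])
    out <- list()
    for (i in seq_along(genome)) {
        hit <- which(canon[[i]] %in% dupCodes)
        if (!length(hit)) next
        grp <- splitByGap(hit, 60)
        for (g in split(hit, grp)) {
            st <- g[1]; en <- g[length(g)] + k - 1L
            w <- en - st + 1L
            if (abs(w - unitLength) <= tolerance)
                out[[length(out) + 1L]] <- data.frame(
                    chrom = names(genome)[i], start = st, end = en,
                    stringsAsFactors = FALSE)
        }
    }
    if (!length(out))
        return(data.frame(chrom = character(), start = integer(),
                          end = integer()))
    do.call(rbind, out)
}

annotateCluster <- function(genome, chrom, members, minIdentity) {
    ci <- match(chrom, names(genome))
    seqs <- Biostrings::DNAStringSet(lapply(seq_len(nrow(members)),
        function(j) Biostrings::subseq(genome[[ci]], members$start[j],
                                       members$end[j])))
    ## orient every member against the first, then call the majority "direct"
    sameAsFirst <- vapply(seq_along(seqs), function(j) {
        if (j == 1) return(TRUE)
        f <- Biostrings::pairwiseAlignment(seqs[[j]], seqs[[1]],
            type = "local", gapOpening = 5, gapExtension = 2,
            substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(2, -3))
        r <- Biostrings::pairwiseAlignment(
            Biostrings::reverseComplement(seqs[[j]]), seqs[[1]],
            type = "local", gapOpening = 5, gapExtension = 2,
            substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(2, -3))
        BiocGenerics::score(f) >= BiocGenerics::score(r)
    }, logical(1))
    majority <- sum(sameAsFirst) >= length(seqs) / 2
    direct <- sameAsFirst == majority
    oriented <- Biostrings::DNAStringSet(lapply(seq_along(seqs), function(j)
        if (direct[j]) seqs[[j]]
        else Biostrings::reverseComplement(seqs[[j]])))
    cons <- majorityConsensus(oriented)
    ident <- vapply(seq_along(oriented), function(j) {
        pa <- Biostrings::pairwiseAlignment(oriented[[j]], cons,
            type = "global", gapOpening = 5, gapExtension = 2,
            substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(2, -3))
        Biostrings::pid(pa, "PID1") / 100
    }, numeric(1))
    keep <- ident >= minIdentity
    if (sum(keep) < 2) return(NULL)
    list(chrom = chrom,
         start = min(members$start[keep]), end = max(members$end[keep]),
         members = data.frame(
             start = members$start[keep], end = members$end[keep],
             orientation = ifelse(direct[keep], "direct", "inverted"),
             identity = ident[keep], stringsAsFactors = FALSE))
}

## majority consensus: members are projected onto the longest member by
## global alignment (members can start a few bp off), then a per-column
## majority is taken over the stacked projections
majorityConsensus <- function(seqs) {
    ref <- seqs[[which.max(Biostrings::width(seqs))]]
    rows <- vapply(seq_along(seqs), function(j) {
        if (isTRUE(all.equal(as.character(seqs[[j]]), as.character(ref))))
            return(as.character(ref))
        pa <- Biostrings::pairwiseAlignment(seqs[[j]], ref, type = "global",
            gapOpening = 5, gapExtension = 2,
            substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(2, -3))
        as.character(Biostrings::aligned(pa))
    }, character(1))
    m <- Biostrings::consensusMatrix(Biostrings::DNAStringSet(rows))
    bases <- c("A", "C", "G", "T")
    Biostrings::DNAString(paste(bases[apply(m[bases, , drop = FALSE], 2,
                                            which.max)], collapse = ""))
}

#' Write telomere calls / repeat clusters as BED-like TSV
#'
#' Columns: chrom, start (0-based), end, name, score, strand.
#'
#' @param calls data.frame from [findTelomericRepeats()] or a cluster list
#'   from [findRepeatClusters()]
#' @param path output file
#' @export
writeBedTsv <- function(calls, path) {
    if (is.data.frame(calls)) {
        df <- data.frame(chrom = calls$chrom, start = calls$start - 1L,
                         end = calls$stop,
                         name = paste0("telomere_", calls$end),
                         score = calls$copies, strand = ".")
    } else {
        rows <- lapply(seq_along(calls), function(i) {
            cl <- calls[[i]]
            data.frame(chrom = cl$chrom, start = cl$members$start - 1L,
                       end = cl$members$end,
                       name = sprintf("cluster%d", i),
                       score = round(cl$members$identity, 3),
                       strand = ifelse(cl$members$orientation == "direct",
                                       "+", "-"))
        })
        df <- do.call(rbind, rows)
    }
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
    invisible(path)
}
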