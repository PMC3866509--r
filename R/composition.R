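#' GC content of a sequence
#'
#' `(G + C) / (A + C + G + T)`; ambiguous bases are excluded from the
#' denominator. An all-ambiguous (or empty) sequence is an error.
#'
#' @param x a `DNAString`, single-sequence `DNAStringSet`, or character scalar
#' @return GC fraction in \[0, 1\]
#' @export
gcContent <- function(x) {
    x <- asDnaString(x)
    f <- Biostrings::letterFrequency(x, c("A", "C", "G", "T"))
    tot <- sum(f)
    stopIfNot(tot > 0, "sequence has no unambiguous bases")
    unname((f[, "G"] + f[, "C"]) / tot)
}

asDnaString <- function(x) {
    if (is(x, "DNAString")) return(Biostrings::DNAStringSet(x))
    if (is(x, "DNAStringSet")) {
        stopIfNot(length(x) == 1, "expected a single sequence")
        return(x)
    }
    Biostrings::DNAStringSet(toupper(as.character(x)))
}

#' Sliding-window GC track
#'
#' Windows of `window` bp every `step` bp; the last window is the last one
#' that fits entirely, so a track over a chromosome of length L has
#' `floor((L - window) / step) + 1` values.
#'
#' @param x sequence (see [gcContent()])
#' @param window window size in bp (default 1000)
#' @param step step size in bp (default 200)
#' @param chromosomeId chromosome name attached to the track
#' @return `GRanges` with an mcol `gc`; window/step stored in `metadata`
#' @export
slidingGC <- function(x, window = 1000, step = 200, chromosomeId = "chr") {
    x <- asDnaString(x)[[1]]
    L <- length(x)
    stopIfNot(step > 0, "step must be > 0")
    stopIfNot(window <= L, "window larger than the sequence")
    starts <- seq.int(1L, L - window + 1L, by = step)
    v <- Biostrings::Views(x, start = starts, width = window)
    f <- Biostrings::letterFrequency(v, c("A", "C", "G", "T"))
    tot <- rowSums(f)
    gc <- ifelse(tot > 0, (f[, "G"] + f[, "C"]) / tot, NA_real_)
    gr <- GenomicRanges::GRanges(chromosomeId,
            IRanges::IRanges(starts, width = window), gc = gc)
    S4Vectors::metadata(gr) <- list(window = window, step = step,
                                    chromosomeLength = L)
    gr
}

#' Sliding-window GC tracks for a whole genome
#'
#' @param genome named `DNAStringSet`
#' @inheritParams slidingGC
#' @return `GRangesList`, one track per chromosome
#' @export
genomeGcTracks <- function(genome, window = 1000, step = 200) {
    GenomicRanges::GRangesList(lapply(setNames(seq_along(genome),
                                               names(genome)),
        function(i) slidingGC(genome[[i]], window, step, names(genome)[i])))
}

#' AT-rich (centromere-candidate) region detection
#'
#' Finds maximal runs of GC-track windows whose GC is at least `drop`
#' percentage points below the chromosome mean, merges runs separated by at
#' most `step` bp, and reports merged spans within `[minSpan, maxSpan]` whose
#' both ends lie at least `minEndDistance` from the chromosome ends. The GC
#' baseline is chromosome-relative because chromosomes of one genome can
#' differ by more than two GC points.
#'
#' @param track a GC track from [slidingGC()]
#' @param drop GC drop in percentage points (default 5)
#' @param minSpan,maxSpan admissible span bounds in bp (defaults 5--30 kbp)
#' @param minEndDistance minimal distance of the span from either chromosome
#'   end (default 50 kbp: a centromere candidate sits mid-chromosome)
#' @return data.frame with one row per candidate: `chrom`, `start`, `end`,
#'   `meanGC`, `distanceToNearestEnd`
#' @export
findATRichRegions <- function(track, drop = 5, minSpan = 5000,
                              maxSpan = 30000, minEndDistance = 50000) {
    md <- S4Vectors::metadata(track)
    step <- md$step
    L <- md$chromosomeLength
    gc <- track$gc
    thr <- mean(gc, na.rm = TRUE) - drop / 100
    low <- which(!is.na(gc) & gc <= thr)
    out <- data.frame(chrom = character(), start = integer(), end = integer(),
                      meanGC = numeric(), distanceToNearestEnd = integer(),
                      stringsAsFactors = FALSE)
    if (!length(low)) return(out)
    starts <- GenomicRanges::start(track)[low]
    ## windows step bp apart are in one run; a genomic gap of up to `step`
    ## between successive qualifying windows is bridged
    grp <- splitByGap(starts, md$window + step)
    for (g in split(low, grp)) {
        s <- GenomicRanges::start(track)[g[1]]
        e <- GenomicRanges::end(track)[g[length(g)]]
        span <- e - s + 1
        dist <- min(s - 1, L - e)
        if (span >= minSpan && span <= maxSpan && dist >= minEndDistance)
            out[nrow(out) + 1L, ] <- list(
                as.character(GenomicRanges::seqnames(track))[1], s, e,
                mean(gc[g]), dist)
    }
    out
}

#' Codon usage table
#'
#' Counts all codons (stop codons included) over a set of coding sequences
#' and normalizes to frequencies. Sequences whose length is not a multiple of
#' three are skipped with a warning.
#'
#' @param cds `DNAStringSet` of coding sequences
#' @return data.frame with `codon`, `aa` (standard genetic code) and
#'   `frequency` (sums to 1)
#' @export
codonUsage <- function(cds) {
    cds <- Biostrings::DNAStringSet(toupper(as.character(cds)))
    bad <- Biostrings::width(cds) %% 3 != 0
    if (any(bad)) {
        warning(sum(bad), " sequence(s) skipped: length not a multiple of 3")
        cds <- cds[!bad]
    }
    stopIfNot(length(cds) > 0 && sum(Biostrings::width(cds)) > 0,
              "no usable coding sequence")
    cnt <- colSums(Biostrings::oligonucleotideFrequency(cds, 3, step = 3))
    data.frame(codon = names(cnt),
               aa = unname(Biostrings::GENETIC_CODE[names(cnt)]),
               frequency = unname(cnt / sum(cnt)),
               stringsAsFactors = FALSE)
}

#' GC fraction at each codon position
#'
#' Reports GC computed over the concatenation of all first, second, and third
#' codon-position bases. A bias toward G/C at specific positions is a
#' hallmark of high-GC yeast coding sequence.
#'
#' @inheritParams codonUsage
#' @return numeric vector `c(gc1, gc2, gc3)`
#' @export
positionalGC <- function(cds) {
    cds <- Biostrings::DNAStringSet(toupper(as.character(cds)))
    bad <- Biostrings::width(cds) %% 3 != 0
    if (any(bad)) {
        warning(sum(bad), " sequence(s) skipped: length not a multiple of 3")
        cds <- cds[!bad]
    }
    stopIfNot(length(cds) > 0, "no usable coding sequence")
    tallies <- matrix(0, nrow = 3, ncol = 2,
                      dimnames = list(NULL, c("gc", "at")))
    for (s in as.character(cds)) {
        ch <- strsplit(s, "", fixed = TRUE)[[1]]
        posn <- rep_len(1:3, length(ch))
        for (k in 1:3) {
            b <- ch[posn == k]
            tallies[k, "gc"] <- tallies[k, "gc"] + sum(b %in% c("G", "C"))
            tallies[k, "at"] <- tallies[k, "at"] + sum(b %in% c("A", "T"))
        }
    }
    stopIfNot(all(rowSums(tallies) > 0), "all-ambiguous codon position")
    setNames(tallies[, "gc"] / rowSums(tallies), c("gc1", "gc2", "gc3"))
}

#' Export a GC track as bedGraph-like TSV
#'
#' Columns `chrom`, `start` (0-based), `end`, `value`.
#'
#' @param track GC track from [slidingGC()]
#' @param path output file
#' @export
writeTrackTsv <- function(track, path) {
    df <- data.frame(chrom = as.character(GenomicRanges::seqnames(track)),
                     start = GenomicRanges::start(track) - 1L,
                     end = GenomicRanges::end(track),
                     value = track$gc)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
    invisible(path)
}
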