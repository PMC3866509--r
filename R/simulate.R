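#' Simulate a multi-chromosome yeast-like genome with planted features
#'
#' Builds i.i.d. background sequence at the requested GC and plants, per
#' chromosome: tandem telomeric repeats at both ends (motif at the 3' end,
#' its reverse complement at the 5' end), one mid-chromosome AT-rich block
#' carrying a cluster of ~290 bp LTR-like repeats (direct and, optionally,
#' inverted copies of one master unit at ~98% identity), and, genome-wide,
#' segmental duplications at chosen identities and a collapsed rDNA-like
#' tandem unit. Gene annotations are tiled over the remaining sequence
#' (~1.4 kbp genes, ~8.5% with one short intron) and given generic functional
#' category labels with a transporter bias near chromosome ends.
#'
#' Duplication copies are "star" mutated: every copy carries substitutions at
#' `(1 - identity)/2` of its positions on sites disjoint between copies, so
#' each *pair* of copies differs at exactly `1 - identity` of positions.
#'
#' All planted coordinates are recorded in the returned truth record; the
#' same seed always yields a byte-identical genome.
#'
#' @param spec a [genomeSpec()]
#' @param telomereMotif telomeric repeat unit (3'-end orientation)
#' @return `list(genome, annotations, truth)`
#' @export
makeGenome <- function(spec, telomereMotif = "GGTGGCGG") {
    stopIfNot(is(spec, "GenomeSpec"), "'spec' must be a GenomeSpec")
    set.seed(spec@seed)
    nChr <- spec@nChromosomes
    L <- spec@chromosomeLength
    motifChars <- strsplit(telomereMotif, "")[[1]]
    motifRcChars <- strsplit(as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(telomereMotif))), "")[[1]]
    mlen <- length(motifChars)
    teloLen <- mlen * spec@telomereCopies
    cen <- spec@centromere
    stopIfNot(L > 2 * teloLen + 2 * 2000 +
              (if (length(cen)) cen$span else 0),
              "infeasible packing: chromosome too short for planted features")

    chroms <- vector("list", nChr)
    names(chroms) <- paste0("chr", seq_len(nChr))
    occupied <- lapply(seq_len(nChr), function(i)
        list(c(1, teloLen + 1000), c(L - teloLen - 1000 + 1, L)))
    truth <- list(seed = spec@seed,
                  chromosomeLengths = setNames(rep(L, nChr), names(chroms)),
                  telomeres = NULL, centromeres = NULL, ltr = NULL,
                  rdna = NULL, duplications = list())

    for (i in seq_len(nChr)) {
        s <- sample(c("A", "C", "G", "T"), L, replace = TRUE,
                    prob = c((1 - spec@baseGC) / 2, spec@baseGC / 2,
                             spec@baseGC / 2, (1 - spec@baseGC) / 2))
        if (spec@telomereCopies > 0) {
            s[1:teloLen] <- rep(motifRcChars, spec@telomereCopies)
            s[(L - teloLen + 1):L] <- rep(motifChars, spec@telomereCopies)
            truth$telomeres <- rbind(truth$telomeres, data.frame(
                chrom = names(chroms)[i],
                end = c("5prime", "3prime"),
                start = c(1L, L - teloLen + 1L),
                stop = c(teloLen, L),
                copies = spec@telomereCopies,
                stringsAsFactors = FALSE))
        }
        if (length(cen)) {
            cenStart <- floor((L - cen$span) / 2) + 1L
            cenEnd <- cenStart + cen$span - 1L
            lowGC <- max(0.05, spec@baseGC - cen$gcDrop / 100)
            s[cenStart:cenEnd] <- strsplit(randomDnaChr(cen$span, lowGC),
                                           "")[[1]]
            occupied[[i]] <- c(occupied[[i]], list(c(cenStart, cenEnd)))
            truth$centromeres <- rbind(truth$centromeres, data.frame(
                chrom = names(chroms)[i], start = cenStart, end = cenEnd,
                gc = lowGC, stringsAsFactors = FALSE))
            if (cen$ltrCopies >= 1) {
                ## one master unit per genome, Ty-family style; solo LTRs at
                ## the AT-rich loci share the low-GC landscape
                if (i == 1)
                    ltrMaster <- strsplit(randomDnaChr(cen$ltrUnit, lowGC),
                                          "")[[1]]
                nInv <- if (isTRUE(cen$includeInverted))
                    floor((cen$ltrCopies - 1) / 2) else 0L
                orient <- c(rep("direct", cen$ltrCopies - nInv),
                            rep("inverted", nInv))
                gaps <- sample(100:600, cen$ltrCopies, replace = TRUE)
                need <- cen$ltrCopies * cen$ltrUnit + sum(gaps)
                stopIfNot(need <= cen$span,
                          "infeasible packing: LTR cluster exceeds centromere")
                pos <- cenStart + floor((cen$span - need) / 2) +
                       cumsum(gaps) +
                       (seq_len(cen$ltrCopies) - 1L) * cen$ltrUnit
                for (j in seq_len(cen$ltrCopies)) {
                    copy <- substitutePositions(ltrMaster,
                        sample.int(cen$ltrUnit, round(0.02 * cen$ltrUnit)),
                        c("A", "C", "G", "T"))
                    if (orient[j] == "inverted")
                        copy <- strsplit(as.character(
                            Biostrings::reverseComplement(Biostrings::DNAString(
                                paste(copy, collapse = "")))), "")[[1]]
                    s[pos[j]:(pos[j] + cen$ltrUnit - 1L)] <- copy
                    truth$ltr <- rbind(truth$ltr, data.frame(
                        chrom = names(chroms)[i], start = pos[j],
                        end = pos[j] + cen$ltrUnit - 1L,
                        orientation = orient[j], cluster = i,
                        stringsAsFactors = FALSE))
                }
            }
        }
        chroms[[i]] <- s
    }

    allocate <- function(len, align = 1) {
        ## rejection-sample a free interval on a random chromosome
        for (try in 1:500) {
            ci <- sample.int(nChr, 1)
            lo <- teloLen + 1500
            hi <- L - teloLen - 1500 - len
            if (hi <= lo) next
            st <- sample(lo:hi, 1)
            if (align > 1) st <- (st %/% align) * align + 1
            if (st < lo || st + len - 1 > hi + len) next
            iv <- c(st, st + len - 1)
            clash <- any(vapply(occupied[[ci]], function(o)
                iv[1] <= o[2] + 500 && o[1] <= iv[2] + 500, logical(1)))
            if (!clash) {
                occupied[[ci]] <<- c(occupied[[ci]], list(iv))
                return(list(chrom = ci, start = st, end = st + len - 1))
            }
        }
        stop("infeasible packing: could not place a feature of length ", len,
             call. = FALSE)
    }

    if (length(spec@rdna)) {
        unit <- spec@rdna$unit
        loc <- allocate(unit)
        chroms[[loc$chrom]][loc$start:loc$end] <-
            strsplit(randomDnaChr(unit, spec@baseGC + 0.02), "")[[1]]
        truth$rdna <- data.frame(chrom = names(chroms)[loc$chrom],
                                 start = loc$start, end = loc$end,
                                 unit = unit, copies = spec@rdna$copies,
                                 stringsAsFactors = FALSE)
    }

    for (d in spec@duplications) {
        donor <- strsplit(randomDnaChr(d$length, spec@baseGC), "")[[1]]
        r <- 1 - d$identity
        nmut <- round(r / 2 * d$length)
        pool <- sample.int(d$length)   # disjoint mutation sites across copies
        rows <- NULL
        for (cpy in seq_len(d$copies)) {
            sites <- pool[((cpy - 1) * nmut + 1):(cpy * nmut)]
            copy <- substitutePositions(donor, sites, c("A", "C", "G", "T"))
            loc <- allocate(d$length, align = spec@dupAlign)
            chroms[[loc$chrom]][loc$start:loc$end] <- copy
            rows <- rbind(rows, data.frame(chrom = names(chroms)[loc$chrom],
                                           start = loc$start, end = loc$end,
                                           stringsAsFactors = FALSE))
        }
        truth$duplications <- c(truth$duplications,
            list(list(copies = rows, identity = d$identity,
                      length = d$length)))
    }

    genome <- Biostrings::DNAStringSet(vapply(chroms, paste, character(1),
                                              collapse = ""))
    annotations <- tileGenes(names(chroms), occupied, L, teloLen)
    list(genome = genome, annotations = annotations, truth = truth)
}

## tile gene annotations into the non-reserved parts of each chromosome;
## genes within 50 kbp of an end are biased toward the "transport" category
tileGenes <- function(chromNames, occupied, L, teloLen) {
    categories <- c("transport", "oxidoreduction", "carbohydrate_metabolism",
                    "energy", "translation", "transcription", "stress",
                    "lipid_metabolism", "signaling", "unknown")
    rows <- list()
    gid <- 0L
    for (i in seq_along(chromNames)) {
        occ <- occupied[[i]]
        pos <- teloLen + 1200
        while (TRUE) {
            glen <- max(300, round(rnorm(1, 1400, 250)))
            gap <- max(50, round(rnorm(1, 300, 120)))
            st <- pos + gap
            en <- st + glen - 1
            if (en > L - teloLen - 1200) break
            clash <- vapply(occ, function(o) st <= o[2] && o[1] <= en,
                            logical(1))
            if (any(clash)) {
                pos <- max(vapply(occ[clash], `[`, numeric(1), 2)) + 200
                next
            }
            gid <- gid + 1L
            nearEnd <- st <= 50000 || en >= L - 50000 + 1
            cat1 <- if (nearEnd && runif(1) < 0.5) "transport"
                    else sample(categories, 1)
            rows[[length(rows) + 1L]] <- data.frame(
                gene_id = sprintf("G%05d", gid), chrom = chromNames[i],
                start = st, end = en,
                strand = sample(c("+", "-"), 1),
                category = cat1, hasIntron = runif(1) < 0.085,
                stringsAsFactors = FALSE)
            pos <- en
        }
    }
    if (!length(rows)) {
        gr <- GenomicRanges::GRanges()
        gr$gene_id <- character(0)
        gr$category <- character(0)
        gr$exons <- IRanges::IRangesList()
        return(gr)
    }
    df <- do.call(rbind, rows)
    gr <- GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start, df$end),
                                 strand = df$strand)
    gr$gene_id <- df$gene_id
    gr$category <- df$category
    gr$exons <- IRanges::IRangesList(lapply(seq_len(nrow(df)), function(j) {
        if (!df$hasIntron[j] || df$end[j] - df$start[j] < 500)
            return(IRanges::IRanges())
        mid <- df$start[j] + floor((df$end[j] - df$start[j]) / 2)
        IRanges::IRanges(c(df$start[j], mid + 66),
                         c(mid, df$end[j]))  # one 65 bp intron
    }))
    gr
}

#' Simulate a two-condition count table with planted fold changes
#'
#' Gene baseline expression is log-normal; planted classes are `up`, `down`
#' (|log2 fold change| drawn from a truncated normal, at least 1), `silent`
#' (zero counts in both conditions) and `unchanged`. Expression is an
#' absolute library share (reads in gene / total mapped reads), so the
#' library totals are fixed sequencing depths and planted fold changes hold
#' exactly on the normalized scale; the portion of each library not in genes
#' represents non-genic mapped reads. Counts are negative-binomial draws at
#' the stated dispersion (Poisson when dispersion is 0).
#'
#' @param spec a [countSpec()]
#' @param genicFraction target fraction of the denominator-condition library
#'   that falls in annotated genes (reduced automatically if the planted
#'   up-regulation would push the numerator condition past its total)
#' @return `list(countTable, truth)`; truth holds each gene's class and
#'   planted log2 fold change
#' @export
makeCounts <- function(spec, genicFraction = 0.85) {
    stopIfNot(is(spec, "CountSpec"), "'spec' must be a CountSpec")
    set.seed(spec@seed)
    n <- spec@nGenes
    lib <- spec@libraryTotals
    stopIfNot(length(lib) == 2, "exactly two conditions are supported")
    if (is.null(names(lib))) names(lib) <- c("cond1", "cond2")
    nUp <- round(spec@fracUp * n)
    nDown <- round(spec@fracDown * n)
    nSilent <- round(spec@fracSilent * n)
    stopIfNot(nUp + nDown + nSilent <= n, "class fractions exceed 1")
    cls <- sample(c(rep("up", nUp), rep("down", nDown),
                    rep("silent", nSilent),
                    rep("unchanged", n - nUp - nDown - nSilent)))
    nNonSilent <- n - nSilent
    if (min(lib) * genicFraction / max(1, nNonSilent) < 10)
        stop("library totals too small to realize fracSilent: ",
             "expected depth per expressed gene < 10 reads", call. = FALSE)

    lfc <- numeric(n)
    lfc[cls == "up"] <- pmax(spec@log2fcMin,
                             rnorm(nUp, spec@log2fcMean, spec@log2fcSd))
    lfc[cls == "down"] <- -pmax(spec@log2fcMin,
                                rnorm(nDown, spec@log2fcMean, spec@log2fcSd))
    lfc[cls == "silent"] <- NA_real_

    b <- rlnorm2(n)
    b[cls == "silent"] <- 0
    eDen <- b / sum(b)                    # shares within the genic portion
    ratio <- ifelse(is.na(lfc), 0, 2^lfc)
    ## keep both conditions' genic shares feasible (< 95% of the library)
    gf <- min(genicFraction, 0.95 / sum(eDen * ratio))
    eDen <- eDen * gf
    eNum <- eDen * ratio

    muDen <- lib[1] * eDen
    muNum <- lib[2] * eNum
    draw <- function(mu) {
        if (spec@dispersion > 0)
            rnbinom(n, mu = mu, size = 1 / spec@dispersion)
        else rpois(n, mu)
    }
    cts <- cbind(draw(muDen), draw(muNum))
    cts[cls == "silent", ] <- 0
    cts <- pmin(cts, matrix(lib, n, 2, byrow = TRUE))
    dimnames(cts) <- list(sprintf("G%05d", seq_len(n)), names(lib))
    truth <- data.frame(gene_id = rownames(cts), class = cls, log2fc = lfc,
                        expressionDen = eDen, expressionNum = eNum,
                        stringsAsFactors = FALSE)
    list(countTable = countTable(cts, lib), truth = truth)
}

## log-normal baseline expression with moderate spread
rlnorm2 <- function(n) exp(rnorm(n, mean = 4, sd = 0.9))

#' Simulate a pair of proteomes related by known evolutionary events
#'
#' Proteome B derives from A by: substitutions at the stated divergence (each
#' ortholog differs from its partner at exactly `round(divergence * length)`
#' positions), `nRearrangements` random gene-order block moves (half of them
#' inverting the block), deletion of the `losses` genes, and insertion of
#' lineage-specific paralog families (near-identical copies of novel
#' proteins). The truth record carries the ortholog map with gene-order
#' positions on both sides, the loss records with their flanking genes, the
#' family membership, and the final order of B as a permutation of A indices.
#'
#' @param spec a [proteomePairSpec()]
#' @return `list(proteomeA, proteomeB, positionsA, positionsB, truth)` where
#'   proteomes are named `AAStringSet`s and positions are data.frames with
#'   `id`, `chrom`, `index`
#' @export
makeProteomePair <- function(spec) {
    stopIfNot(is(spec, "ProteomePairSpec"), "'spec' must be a ProteomePairSpec")
    set.seed(spec@seed)
    derived <- deriveProteome(baseProteome(spec@nOrthologs, prefix = "A"),
                              spec, prefix = "B")
    c(list(proteomeA = derived$ancestor,
           positionsA = data.frame(id = names(derived$ancestor), chrom = "chrA",
                                   index = seq_along(derived$ancestor),
                                   stringsAsFactors = FALSE)),
      derived[c("proteome", "positions", "truth")] |>
          setNames(c("proteomeB", "positionsB", "truth")))
}

baseProteome <- function(n, prefix) {
    lens <- sample(200:500, n, replace = TRUE)
    Biostrings::AAStringSet(setNames(
        vapply(lens, randomProteinChr, character(1)),
        sprintf("%s%04d", prefix, seq_len(n))))
}

## derive one descendant proteome from an ancestor; shared by pair/triple
deriveProteome <- function(ancestor, spec, prefix) {
    n <- length(ancestor)
    seqsB <- as.character(ancestor)
    for (i in seq_len(n)) {
        ch <- strsplit(seqsB[i], "")[[1]]
        nm <- round(spec@divergence * length(ch))
        if (nm > 0)
            ch <- substitutePositions(ch, sample.int(length(ch), nm), AA20)
        seqsB[i] <- paste(ch, collapse = "")
    }
    idsB <- sprintf("%s%04d", prefix, seq_len(n))   # idsB[i] ~ ancestor i
    ord <- seq_len(n)                               # B order as A indices
    for (m in seq_len(spec@nRearrangements)) {
        blen <- sample(3:max(3, round(n / 10)), 1)
        st <- sample.int(length(ord) - blen + 1, 1)
        block <- ord[st:(st + blen - 1)]
        if (runif(1) < 0.5) block <- rev(block)
        rest <- ord[-(st:(st + blen - 1))]
        at <- sample.int(length(rest) + 1, 1)
        ord <- append(rest, block, after = at - 1)
    }
    lost <- as.integer(spec@losses)
    ordKept <- ord[!ord %in% lost]
    bNames <- idsB[ordKept]
    bSeqs <- seqsB[ordKept]
    families <- list()
    if (length(spec@paralogFamilies)) {
        for (f in seq_along(spec@paralogFamilies)) {
            sz <- spec@paralogFamilies[f]
            base <- strsplit(randomProteinChr(sample(200:500, 1)), "")[[1]]
            ids <- sprintf("%spar%02d_%d", prefix, f, seq_len(sz))
            for (j in seq_len(sz)) {
                copy <- substitutePositions(base,
                    sample.int(length(base), round(0.03 * length(base))), AA20)
                at <- sample.int(length(bNames) + 1, 1)
                bNames <- append(bNames, ids[j], after = at - 1)
                bSeqs <- append(bSeqs, paste(copy, collapse = ""),
                                after = at - 1)
            }
            families[[f]] <- ids
        }
    }
    proteome <- Biostrings::AAStringSet(setNames(bSeqs, bNames))
    positions <- data.frame(id = bNames, chrom = paste0("chr", prefix),
                            index = seq_along(bNames), stringsAsFactors = FALSE)
    keptA <- setdiff(seq_len(n), lost)
    orth <- data.frame(idA = names(ancestor)[keptA], idB = idsB[keptA],
                       indexA = keptA,
                       indexB = match(idsB[keptA], bNames),
                       stringsAsFactors = FALSE)
    lossDf <- if (length(lost)) data.frame(
        idA = names(ancestor)[lost], indexA = lost,
        leftFlankA = ifelse(lost > 1, names(ancestor)[lost - 1], NA),
        rightFlankA = ifelse(lost < n, names(ancestor)[pmin(lost + 1, n)], NA),
        stringsAsFactors = FALSE) else NULL
    list(ancestor = ancestor, proteome = proteome, positions = positions,
         truth = list(orthologs = orth, losses = lossDf,
                      families = families, orderAsAIndices = ord,
                      divergence = spec@divergence))
}

#' Simulate a triple of proteomes sharing one ancestor
#'
#' Proteomes B and C are derived independently from the common proteome A
#' with their own specs (so the expected B--C divergence is roughly the sum
#' of the two). The truth record includes per-cell counts for the 7-cell
#' shared/unique partition implied by the planted losses and
#' lineage-specific families.
#'
#' @param specB,specC [proteomePairSpec()]s for the two derived lineages
#' @return list with `proteomeA/B/C`, `positionsA/B/C`, `truthB`, `truthC`
#'   and `truthCells` (named 7-cell counts)
#' @export
makeProteomeTriple <- function(specB, specC) {
    set.seed(specB@seed)
    A <- baseProteome(specB@nOrthologs, prefix = "A")
    dB <- deriveProteome(A, specB, prefix = "B")
    dC <- deriveProteome(A, specC, prefix = "C")
    inB <- !seq_along(A) %in% specB@losses
    inC <- !seq_along(A) %in% specC@losses
    cells <- c(ABC = sum(inB & inC), AB = sum(inB & !inC),
               AC = sum(!inB & inC), A = sum(!inB & !inC),
               B = length(dB$truth$families), C = length(dC$truth$families),
               BC = 0)
    list(proteomeA = A,
         positionsA = data.frame(id = names(A), chrom = "chrA",
                                 index = seq_along(A), stringsAsFactors = FALSE),
         proteomeB = dB$proteome, positionsB = dB$positions,
         proteomeC = dC$proteome, positionsC = dC$positions,
         truthB = dB$truth, truthC = dC$truth, truthCells = cells)
}

#' Simulate per-base read coverage over a genome
#'
#' Read starts are Poisson with per-base rate `depth / readLength`, scaled by
#' the collapsed copy number of any region the truth record marks as a
#' collapsed tandem array (the rDNA unit), so such a region attracts
#' `copies`-fold coverage. No error model: downstream copy-number estimation
#' uses depth ratios only.
#'
#' @param genome named `DNAStringSet`
#' @param truth truth record from [makeGenome()] (may be `NULL`)
#' @param depth target fold coverage of single-copy sequence
#' @param readLength read length in bp (default 326, a typical 454 read)
#' @param seed RNG seed
#' @return named list of integer per-base depth vectors, one per chromosome
#' @export
simulateCoverage <- function(genome, truth = NULL, depth = 20,
                             readLength = 326, seed = 1L) {
    stopIfNot(depth >= 0, "depth must be >= 0")
    set.seed(seed)
    out <- vector("list", length(genome))
    names(out) <- names(genome)
    rate <- depth / readLength
    slide <- function(starts, rl) {
        cs <- cumsum(starts)
        cs - c(rep(0, min(rl, length(starts))),
               head(cs, max(0, length(starts) - rl)))
    }
    for (i in seq_along(genome)) {
        L <- Biostrings::width(genome)[i]
        if (depth == 0) { out[[i]] <- integer(L); next }
        starts <- rpois(L, rate)
        cov <- slide(starts, readLength)
        rd <- if (is.null(truth$rdna)) NULL else
            truth$rdna[truth$rdna$chrom == names(genome)[i], , drop = FALSE]
        for (j in seq_len(NROW(rd))) {
            ## a collapsed tandem array is covered circularly: reads spanning
            ## copy-to-copy junctions map back onto the single assembly copy,
            ## so there is no edge ramp at copies-fold depth
            span <- rd$start[j]:rd$end[j]
            uL <- length(span)
            su <- rpois(uL, rate * (rd$copies[j] - 1))
            covU <- slide(c(su, su), readLength)[(uL + 1):(2 * uL)]
            cov[span] <- cov[span] + covU
        }
        out[[i]] <- as.integer(cov)
    }
    out
}

#' Write simulated data to disk (FASTA + annotation TSV + counts TSV + truth)
#'
#' @param sim result of [makeGenome()]
#' @param dir output directory (created if needed)
#' @export
writeSimulatedGenome <- function(sim, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    writeGenome(sim$genome, file.path(dir, "genome.fasta"))
    writeAnnotationTsv(sim$annotations, file.path(dir, "annotations.tsv"))
    jsonlite::write_json(sim$truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
    invisible(dir)
}
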