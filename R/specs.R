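#' Simulation specification objects
#'
#' The synthetic-data generators are driven by small S4 specification objects
#' whose defaults describe a compact methylotrophic-yeast-like genome: seven
#' chromosomes of ~1.29 Mbp at base GC 0.478, (GGTGGCGG)x10 telomeric repeats
#' at every end, one mid-chromosome 15 kbp AT-rich block (GC lowered by 15
#' percentage points) carrying clustered ~290 bp LTR-like repeats, and a
#' 7,737 bp rDNA unit present once in the assembly but representing a 25-copy
#' tandem array (so simulated coverage over it is ~25x the background).
#'
#' @name simulation-specs
NULL

#' @rdname simulation-specs
#' @slot nChromosomes number of chromosomes
#' @slot chromosomeLength length of every chromosome (bp)
#' @slot baseGC background GC fraction
#' @slot telomereCopies tandem telomere-motif copies planted at each end
#' @slot centromere list(span, gcDrop, ltrUnit, ltrCopies, includeInverted):
#'   AT-rich block span (bp), its GC drop in percentage points, LTR-like unit
#'   length (bp), number of clustered copies, and whether some copies are
#'   inverted
#' @slot duplications list of list(length, identity, copies) segmental
#'   duplications to plant; identity in (0.5, 1], copies 2 or 3
#' @slot rdna list(unit, copies): collapsed tandem unit length and its true
#'   copy number (the assembly carries one copy)
#' @slot dupAlign placement grid (bp) for duplication copies; 1 = free
#' @slot seed RNG seed
#' @export
setClass("GenomeSpec", representation(
    nChromosomes = "numeric", chromosomeLength = "numeric",
    baseGC = "numeric", telomereCopies = "numeric",
    centromere = "list", duplications = "list", rdna = "list",
    dupAlign = "numeric", seed = "numeric"))

setValidity("GenomeSpec", function(object) {
    msg <- character()
    if (object@nChromosomes < 1) msg <- c(msg, "need >= 1 chromosome")
    if (object@baseGC <= 0 || object@baseGC >= 1)
        msg <- c(msg, "baseGC must be in (0,1)")
    for (d in object@duplications) {
        if (d$identity <= 0.5 || d$identity > 1)
            msg <- c(msg, "duplication identity must be in (0.5, 1]")
        if (!d$copies %in% c(2, 3))
            msg <- c(msg, "duplication copies must be 2 or 3")
    }
    cen <- object@centromere
    if (length(cen) && (cen$span < 0 || cen$span > object@chromosomeLength / 2))
        msg <- c(msg, "centromere span does not fit inside the chromosome")
    if (length(msg)) msg else TRUE
})

#' @rdname simulation-specs
#' @param nChromosomes,chromosomeLength,baseGC,telomereCopies,centromere,duplications,rdna,dupAlign,seed
#'   see the slot documentation
#' @export
genomeSpec <- function(nChromosomes = 7, chromosomeLength = 1290000,
        baseGC = 0.478, telomereCopies = 10,
        centromere = list(span = 15000, gcDrop = 15, ltrUnit = 290,
                          ltrCopies = 5, includeInverted = TRUE),
        duplications = list(),
        rdna = list(unit = 7737, copies = 25),
        dupAlign = 1, seed = 1L) {
    new("GenomeSpec", nChromosomes = nChromosomes,
        chromosomeLength = chromosomeLength, baseGC = baseGC,
        telomereCopies = telomereCopies, centromere = centromere,
        duplications = duplications, rdna = rdna, dupAlign = dupAlign,
        seed = seed)
}

setMethod("show", "GenomeSpec", function(object) {
    cat("GenomeSpec:", object@nChromosomes, "chromosomes x",
        format(object@chromosomeLength, big.mark = ","), "bp, GC",
        object@baseGC, ", seed", object@seed, "\n")
})

#' @rdname simulation-specs
#' @slot nGenes number of genes
#' @slot fracUp,fracDown,fracSilent fractions of genes planted as up-regulated,
#'   down-regulated and silent (zero counts in both conditions)
#' @slot log2fcMean,log2fcSd magnitude distribution of planted |log2 fold
#'   changes| (normal, truncated below at `log2fcMin`)
#' @slot log2fcMin truncation floor of planted |log2 fold changes|; the
#'   default 1 is the two-fold differential-expression rule
#' @slot libraryTotals named numeric, target total mapped reads per condition
#' @slot dispersion negative-binomial overdispersion (0 = Poisson)
#' @export
setClass("CountSpec", representation(
    nGenes = "numeric", fracUp = "numeric", fracDown = "numeric",
    fracSilent = "numeric", log2fcMean = "numeric", log2fcSd = "numeric",
    log2fcMin = "numeric", libraryTotals = "numeric",
    dispersion = "numeric", seed = "numeric"))

setValidity("CountSpec", function(object) {
    msg <- character()
    fr <- c(object@fracUp, object@fracDown, object@fracSilent)
    if (any(fr < 0) || sum(fr) > 1)
        msg <- c(msg, "fracUp + fracDown + fracSilent must be <= 1")
    if (any(object@libraryTotals <= 0))
        msg <- c(msg, "library totals must be positive")
    if (object@dispersion < 0) msg <- c(msg, "dispersion must be >= 0")
    if (object@log2fcMin < 0) msg <- c(msg, "log2fcMin must be >= 0")
    if (length(msg)) msg else TRUE
})

#' @rdname simulation-specs
#' @param nGenes,fracUp,fracDown,fracSilent,log2fcMean,log2fcSd,log2fcMin,libraryTotals,dispersion
#'   see the slot documentation. Library-size defaults are the scale of a
#'   two-condition 454 RNA-seq experiment (~7e5 mapped reads per condition).
#' @export
countSpec <- function(nGenes = 5325, fracUp = 0.43, fracDown = 0.18,
        fracSilent = 0.016, log2fcMean = 2.5, log2fcSd = 1, log2fcMin = 1,
        libraryTotals = c(glucose = 709815, methanol = 733393),
        dispersion = 0.05, seed = 1L) {
    new("CountSpec", nGenes = nGenes, fracUp = fracUp, fracDown = fracDown,
        fracSilent = fracSilent, log2fcMean = log2fcMean, log2fcSd = log2fcSd,
        log2fcMin = log2fcMin, libraryTotals = libraryTotals,
        dispersion = dispersion, seed = seed)
}

setMethod("show", "CountSpec", function(object) {
    cat("CountSpec:", object@nGenes, "genes; up/down/silent =",
        object@fracUp, object@fracDown, object@fracSilent,
        "; dispersion", object@dispersion, "; seed", object@seed, "\n")
})

#' @rdname simulation-specs
#' @slot nOrthologs number of one-to-one ortholog pairs
#' @slot divergence expected fraction of differing residues between orthologs
#' @slot nRearrangements number of gene-order block moves applied to genome B
#' @slot losses indices (in genome A order) of genes deleted from genome B
#' @slot paralogFamilies sizes (2-9) of lineage-specific paralog families
#'   added to genome B
#' @export
setClass("ProteomePairSpec", representation(
    nOrthologs = "numeric", divergence = "numeric",
    nRearrangements = "numeric", losses = "numeric",
    paralogFamilies = "numeric", seed = "numeric"))

setValidity("ProteomePairSpec", function(object) {
    msg <- character()
    if (object@divergence < 0 || object@divergence >= 0.95)
        msg <- c(msg, "divergence must be in [0, 0.95) (saturation)")
    if (length(object@losses) &&
        (any(object@losses < 1) || any(object@losses > object@nOrthologs)))
        msg <- c(msg, "losses must be ortholog indices")
    if (length(object@paralogFamilies) &&
        (any(object@paralogFamilies < 2) || any(object@paralogFamilies > 9)))
        msg <- c(msg, "paralog family sizes must be in 2..9")
    if (length(msg)) msg else TRUE
})

#' @rdname simulation-specs
#' @param nOrthologs,divergence,nRearrangements,losses,paralogFamilies
#'   see the slot documentation
#' @export
proteomePairSpec <- function(nOrthologs = 100, divergence = 0.2,
        nRearrangements = 0, losses = numeric(), paralogFamilies = numeric(),
        seed = 1L) {
    new("ProteomePairSpec", nOrthologs = nOrthologs, divergence = divergence,
        nRearrangements = nRearrangements, losses = losses,
        paralogFamilies = paralogFamilies, seed = seed)
}

setMethod("show", "ProteomePairSpec", function(object) {
    cat("ProteomePairSpec:", object@nOrthologs, "orthologs, divergence",
        object@divergence, ",", object@nRearrangements, "rearrangements,",
        length(object@losses), "losses, seed", object@seed, "\n")
})
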