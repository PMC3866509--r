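#' Read a genome from a FASTA file
#'
#' Sequence names are truncated at the first whitespace; sequences are
#' upper-cased. Duplicate ids or non-IUPAC characters raise a format error.
#'
#' @param path FASTA file
#' @return a named [Biostrings::DNAStringSet] (one entry per chromosome or
#'   contig)
#' @export
readGenome <- function(path) {
    ## readDNAStringSet silently drops invalid letters; reject them instead
    lines <- readLines(path)
    seqLines <- lines[!startsWith(lines, ">") & nzchar(lines)]
    bad <- grepl("[^ACGTRYSWKMBDHVNacgtryswkmbdhvn]", seqLines)
    if (any(bad))
        stop("non-IUPAC characters in '", path, "' (first offending line: ",
             utils::head(seqLines[bad], 1), ")", call. = FALSE)
    x <- tryCatch(Biostrings::readDNAStringSet(path),
        error = function(e) stop("malformed FASTA ('", path, "'): ",
                                 conditionMessage(e), call. = FALSE))
    names(x) <- sub("\\s.*$", "", names(x))
    if (anyDuplicated(names(x)))
        stop("duplicate sequence ids in '", path, "': ",
             paste(unique(names(x)[duplicated(names(x))]), collapse = ", "),
             call. = FALSE)
    toUpperDna(x)
}

toUpperDna <- function(x) {
    chr <- toupper(as.character(x))
    tryCatch(Biostrings::DNAStringSet(setNames(chr, names(x))),
        error = function(e) stop("non-IUPAC characters in sequence: ",
                                 conditionMessage(e), call. = FALSE))
}

#' Write a genome to a FASTA file
#'
#' @param genome named `DNAStringSet`
#' @param path output file
#' @export
writeGenome <- function(genome, path) {
    Biostrings::writeXStringSet(genome, path)
    invisible(path)
}

#' Read gene annotations (GFF3 or position TSV)
#'
#' Coordinates in both formats are 1-based inclusive; they are kept 1-based
#' closed internally as a `GRanges` (the Bioconductor convention), so a gene
#' with start 1 and end 10 has width 10. The TSV format has columns
#' `gene_id, chrom, start, end, strand` plus any number of label columns
#' (e.g. `family`, `category`). In GFF3, `gene` features define genes and
#' `exon` features with a matching `Parent`/`ID` define their exon structure.
#'
#' @param path input file
#' @param format `"tsv"` or `"gff3"`
#' @param chromosomeLengths optional named vector; genes on unknown
#'   chromosomes or beyond a chromosome end raise a validation error
#' @return `GRanges` with mcols `gene_id`, any label columns, and an `exons`
#'   `IRangesList` column (absolute coordinates; empty for genes without
#'   annotated exons)
#' @export
readAnnotation <- function(path, format = c("tsv", "gff3"),
                           chromosomeLengths = NULL) {
    format <- match.arg(format)
    gr <- if (format == "tsv") readAnnotationTsv(path)
          else readAnnotationGff3(path)
    validateAnnotation(gr, chromosomeLengths)
    gr
}

readAnnotationTsv <- function(path) {
    df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
    need <- c("gene_id", "chrom", "start", "end", "strand")
    stopIfNot(all(need %in% names(df)),
              paste("annotation TSV needs columns:", paste(need, collapse = ", ")))
    buildGeneRanges(df$gene_id, df$chrom, df$start, df$end, df$strand,
                    labels = df[setdiff(names(df), need)])
}

readAnnotationGff3 <- function(path) {
    gff <- rtracklayer::import(path, format = "gff3")
    genes <- gff[gff$type == "gene"]
    ids <- if (!is.null(genes$ID)) as.character(genes$ID) else genes$Name
    gr <- buildGeneRanges(ids, as.character(GenomicRanges::seqnames(genes)),
                          GenomicRanges::start(genes),
                          GenomicRanges::end(genes),
                          as.character(GenomicRanges::strand(genes)))
    exons <- gff[gff$type == "exon"]
    if (length(exons)) {
        par <- vapply(exons$Parent, function(p) as.character(p[1]),
                      character(1))
        byGene <- split(IRanges::IRanges(GenomicRanges::start(exons),
                                         GenomicRanges::end(exons)), par)
        idx <- match(gr$gene_id, names(byGene))
        ex <- IRanges::IRangesList(lapply(idx, function(i)
            if (is.na(i)) IRanges::IRanges() else sort(byGene[[i]])))
        gr$exons <- ex
    }
    gr
}

buildGeneRanges <- function(ids, chrom, start, end, strand, labels = NULL) {
    stopIfNot(!anyDuplicated(ids) && !any(is.na(ids)) && all(nzchar(ids)),
              "gene ids must be unique and non-empty")
    stopIfNot(all(end >= start), "gene end < start")
    stopIfNot(all(strand %in% c("+", "-")),
              "strand must be '+' or '-'")
    gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end),
                                 strand = strand)
    gr$gene_id <- as.character(ids)
    if (!is.null(labels) && ncol(as.data.frame(labels)))
        S4Vectors::mcols(gr) <- cbind(S4Vectors::mcols(gr),
                                      S4Vectors::DataFrame(labels))
    gr$exons <- IRanges::IRangesList(lapply(seq_along(gr), function(i)
        IRanges::IRanges()))
    gr
}

validateAnnotation <- function(gr, chromosomeLengths = NULL) {
    if (!is.null(chromosomeLengths)) {
        chrom <- as.character(GenomicRanges::seqnames(gr))
        unknown <- setdiff(chrom, names(chromosomeLengths))
        stopIfNot(!length(unknown),
                  paste("unknown chromosome(s):", paste(unknown, collapse = ", ")))
        beyond <- GenomicRanges::end(gr) > chromosomeLengths[chrom] |
                  GenomicRanges::start(gr) < 1
        stopIfNot(!any(beyond),
                  paste("gene(s) outside chromosome bounds:",
                        paste(gr$gene_id[beyond], collapse = ", ")))
    }
    if (!is.null(gr$exons)) {
        ok <- vapply(seq_along(gr), function(i) {
            ex <- gr$exons[[i]]
            !length(ex) || (min(IRanges::start(ex)) >= GenomicRanges::start(gr)[i] &&
                            max(IRanges::end(ex)) <= GenomicRanges::end(gr)[i])
        }, logical(1))
        stopIfNot(all(ok), "exons outside their gene interval")
    }
    invisible(gr)
}

#' Write gene annotations as a position TSV
#'
#' @param genes `GRanges` as returned by [readAnnotation()]
#' @param path output file
#' @export
writeAnnotationTsv <- function(genes, path) {
    mc <- S4Vectors::mcols(genes)
    labels <- as.data.frame(mc[setdiff(names(mc), c("gene_id", "exons"))])
    df <- data.frame(gene_id = genes$gene_id,
                     chrom = as.character(GenomicRanges::seqnames(genes)),
                     start = GenomicRanges::start(genes),
                     end = GenomicRanges::end(genes),
                     strand = as.character(GenomicRanges::strand(genes)),
                     stringsAsFactors = FALSE)
    if (ncol(labels)) df <- cbind(df, labels)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Total length of a scaffold composition
#'
#' Sum of contig lengths plus `unitLength * copies` for every collapsed
#' repeat part, reproducing assembly-report arithmetic such as
#' 297,310 + 7,737(x25) + 650,519 = 1,141,254 bp.
#'
#' @param composition a [ScaffoldComposition]
#' @return length in bp
#' @export
scaffoldLength <- function(composition) {
    stopIfNot(is(composition, "ScaffoldComposition"),
              "'composition' must be a ScaffoldComposition")
    sum(vapply(composition@parts, function(p)
        if (p$type == "contig") p$length else p$unitLength * p$copies,
        numeric(1)))
}

#' Gene density per 10 kbp
#'
#' `genes / (total bp / 10,000)`, rounded half-up to two decimals as in
#' genome-overview tables (e.g. 5325 genes on 9,056,077 bp -> 5.88).
#'
#' @param nGenes gene count
#' @param totalBp genome length in bp
#' @export
geneDensityPer10kbp <- function(nGenes, totalBp) {
    stopIfNot(totalBp > 0, "totalBp must be > 0")
    roundHalfUp(nGenes / (totalBp / 1e4), 2)
}

#' Genome and annotation summary statistics
#'
#' Computes the quantities of a genome-overview table: total length,
#' per-chromosome and overall GC%, gene count, coding fraction, average
#' gene/exon/intron lengths, exon frequency and gene density per 10 kbp.
#' With no genes the averages are reported as `NA` and the density as 0.
#'
#' @param genome named `DNAStringSet`
#' @param annotations gene `GRanges` (see [readAnnotation()])
#' @return a list of summary statistics
#' @export
genomeSummary <- function(genome, annotations) {
    stopIfNot(length(genome) > 0, "empty genome")
    lens <- Biostrings::width(genome)
    chromGC <- vapply(seq_along(genome), function(i)
        gcContent(genome[[i]]), numeric(1))
    totalBp <- sum(lens)
    totGC <- sum(chromGC * lens) / totalBp
    n <- length(annotations)
    widths <- GenomicRanges::width(annotations)
    exonStats <- exonIntronStats(annotations)
    list(totalLength = totalBp,
         chromosomeLengths = setNames(lens, names(genome)),
         chromosomeGcPercent = setNames(roundHalfUp(100 * chromGC, 1),
                                        names(genome)),
         gcPercent = roundHalfUp(100 * totGC, 1),
         nGenes = n,
         codingFraction = if (n) sum(widths) / totalBp else 0,
         avgGeneLength = if (n) mean(widths) else NA_real_,
         avgExonLength = exonStats$avgExonLength,
         avgIntronLength = exonStats$avgIntronLength,
         exonFrequency = exonStats$exonFrequency,
         geneDensityPer10kbp = if (n) geneDensityPer10kbp(n, totalBp) else 0)
}

## exon/intron averages; genes without annotated exons count as single-exon
exonIntronStats <- function(annotations) {
    n <- length(annotations)
    if (!n || is.null(annotations$exons))
        return(list(avgExonLength = NA_real_, avgIntronLength = NA_real_,
                    exonFrequency = if (n) 1 else NA_real_))
    exonLens <- intronLens <- numeric(0)
    nExons <- integer(n)
    for (i in seq_len(n)) {
        ex <- annotations$exons[[i]]
        if (!length(ex)) {
            nExons[i] <- 1L
            exonLens <- c(exonLens, GenomicRanges::width(annotations)[i])
        } else {
            ex <- sort(ex)
            nExons[i] <- length(ex)
            exonLens <- c(exonLens, IRanges::width(ex))
            if (length(ex) > 1)
                intronLens <- c(intronLens,
                    IRanges::start(ex)[-1] - IRanges::end(ex)[-length(ex)] - 1)
        }
    }
    list(avgExonLength = mean(exonLens),
         avgIntronLength = if (length(intronLens)) mean(intronLens) else NA_real_,
         exonFrequency = mean(nExons))
}

#' Write a genome summary as JSON
#'
#' @param summary result of [genomeSummary()]
#' @param path output file
#' @export
writeSummaryJson <- function(summary, path) {
    jsonlite::write_json(summary, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    invisible(path)
}
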