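#' @import methods
#' @importFrom stats median rbinom rnbinom rnorm rpois runif setNames phyper
#'   dhyper p.adjust quantile
#' @importFrom utils read.delim write.table head tail
#' @importFrom data.table data.table setkey setorder rbindlist .N
#' @importFrom BiocGenerics sort start end width strand score
NULL

## make data.table subsetting semantics apply inside this namespace
.datatable.aware <- TRUE

#' ScaffoldComposition: a chromosome as an ordered list of parts
#'
#' A scaffold is described by its ordered parts: plain contigs (known length,
#' sequence optional) and collapsed tandem repeat units with a copy number.
#' This mirrors how assembly reports print a chromosome such as
#' "297,310 + 7,737(x25) + 650,519" and makes the length arithmetic testable
#' without any sequence.
#'
#' @slot chromosomeId single character id
#' @slot parts list of parts built with [contigPart()] / [repeatPart()]
#' @seealso [scaffoldLength()]
#' @export
setClass("ScaffoldComposition",
    representation(chromosomeId = "character", parts = "list"))

setValidity("ScaffoldComposition", function(object) {
    msg <- character()
    if (length(object@chromosomeId) != 1L || is.na(object@chromosomeId))
        msg <- c(msg, "'chromosomeId' must be a single non-NA string")
    for (p in object@parts) {
        if (!is.list(p) || is.null(p$type))
            msg <- c(msg, "each part must come from contigPart()/repeatPart()")
        else if (p$type == "contig") {
            if (!is.numeric(p$length) || p$length < 0)
                msg <- c(msg, "contig length must be >= 0")
        } else if (p$type == "repeat_unit") {
            if (!is.numeric(p$unitLength) || p$unitLength <= 0)
                msg <- c(msg, "repeat unit length must be > 0")
            if (!is.numeric(p$copies) || p$copies < 1)
                msg <- c(msg, "repeat copies must be >= 1")
        } else msg <- c(msg, sprintf("unknown part type '%s'", p$type))
    }
    if (length(msg)) msg else TRUE
})

#' @describeIn ScaffoldComposition constructor
#' @param chromosomeId chromosome name
#' @param parts ordered list of parts
#' @export
scaffoldComposition <- function(chromosomeId, parts) {
    new("ScaffoldComposition", chromosomeId = as.character(chromosomeId),
        parts = parts)
}

#' @describeIn ScaffoldComposition a contig part of known length
#' @param length contig length in bp
#' @export
contigPart <- function(length) list(type = "contig", length = as.numeric(length))

#' @describeIn ScaffoldComposition a collapsed tandem repeat part
#' @param unitLength repeat unit length in bp
#' @param copies number of tandem copies
#' @export
repeatPart <- function(unitLength, copies)
    list(type = "repeat_unit", unitLength = as.numeric(unitLength),
         copies = as.numeric(copies))

setMethod("show", "ScaffoldComposition", function(object) {
    fmt <- vapply(object@parts, function(p) {
        if (p$type == "contig") format(p$length, big.mark = ",")
        else sprintf("%s(x%d)", format(p$unitLength, big.mark = ","),
                     as.integer(p$copies))
    }, character(1))
    cat("ScaffoldComposition ", object@chromosomeId, ": ",
        paste(fmt, collapse = " + "),
        " = ", format(scaffoldLength(object), big.mark = ","), " bp\n", sep = "")
})

#' CountTable: per-gene read counts for a set of conditions
#'
#' Holds the raw mapped-read counts per gene and condition together with the
#' per-condition library totals (total mapped reads) used for normalization.
#' Counts are whole numbers; each count can not exceed its library total.
#'
#' @slot counts integer-like matrix, genes x conditions, with rownames
#'   (gene ids) and colnames (condition names)
#' @slot libraryTotals numeric vector of total mapped reads, one per condition
#' @export
setClass("CountTable",
    representation(counts = "matrix", libraryTotals = "numeric"))

setValidity("CountTable", function(object) {
    cts <- object@counts
    msg <- character()
    if (is.null(rownames(cts)) || anyDuplicated(rownames(cts)))
        msg <- c(msg, "counts must have unique rownames (gene ids)")
    if (is.null(colnames(cts)))
        msg <- c(msg, "counts must have colnames (condition names)")
    if (any(cts < 0) || any(cts != round(cts)))
        msg <- c(msg, "counts must be non-negative integers")
    if (length(object@libraryTotals) != ncol(cts))
        msg <- c(msg, "one library total per condition required")
    if (any(object@libraryTotals <= 0))
        msg <- c(msg, "library totals must be > 0")
    if (ncol(cts) > 0 && nrow(cts) > 0 &&
        any(sweep(cts, 2, object@libraryTotals) > 0))
        msg <- c(msg, "per-gene counts can not exceed the library total")
    if (length(msg)) msg else TRUE
})

#' @describeIn CountTable constructor. When `libraryTotals` is missing the
#'   column sums are used (every mapped read lies in a gene).
#' @param counts genes x conditions count matrix
#' @param libraryTotals per-condition total mapped reads
#' @export
countTable <- function(counts, libraryTotals = colSums(counts)) {
    storage.mode(counts) <- "double"
    if (is.null(names(libraryTotals))) names(libraryTotals) <- colnames(counts)
    new("CountTable", counts = counts, libraryTotals = libraryTotals)
}

#' @describeIn CountTable gene ids
#' @param x a CountTable
#' @export
setMethod("rownames", "CountTable", function(x) rownames(x@counts))

#' @describeIn CountTable condition names
#' @export
setMethod("colnames", "CountTable", function(x) colnames(x@counts))

#' @describeIn CountTable count matrix accessor
#' @param object a CountTable
#' @importFrom BiocGenerics counts
#' @export
setMethod("counts", "CountTable", function(object, ...) object@counts)

#' @export
setGeneric("libraryTotals", function(object) standardGeneric("libraryTotals"))

#' @describeIn CountTable library totals accessor
#' @export
setMethod("libraryTotals", "CountTable", function(object) object@libraryTotals)

setMethod("show", "CountTable", function(object) {
    cat("CountTable:", nrow(object@counts), "genes x",
        ncol(object@counts), "conditions\n")
    cat("  conditions:", paste(colnames(object@counts), collapse = ", "), "\n")
    cat("  library totals:",
        paste(format(object@libraryTotals, big.mark = ","), collapse = ", "),
        "\n")
})
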