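#' Library-size normalization of a count table
#'
#' Normalized expression of a gene = reads mapped to the gene / total mapped
#' reads of the library; also reported as reads per million. Doubling every
#' count together with the library total leaves expression unchanged.
#'
#' @param counts a [CountTable]
#' @return data.frame: `gene_id`, one `<condition>` column per condition
#'   (library-share scale) and one `<condition>_rpm` column
#' @export
normalizeCounts <- function(counts) {
    stopIfNot(is(counts, "CountTable"), "'counts' must be a CountTable")
    cts <- counts(counts)
    lt <- libraryTotals(counts)
    expr <- sweep(cts, 2, lt, "/")
    out <- data.frame(gene_id = rownames(cts), expr,
                      stringsAsFactors = FALSE, check.names = FALSE)
    for (cn in colnames(cts)) out[[paste0(cn, "_rpm")]] <- expr[, cn] * 1e6
    rownames(out) <- NULL
    out
}

#' Differential-expression values and classes
#'
#' For each gene, `log2` of the ratio of normalized expression in the
#' numerator condition (methanol, by convention) over the denominator
#' condition (glucose). A pseudocount of `pseudocount` reads is added to
#' both conditions at the count level only when exactly one condition has a
#' zero count; a gene with zero counts in both conditions is `silent` and
#' gets no ratio. Classes at the two-fold rule, boundary inclusive:
#' `up` when log2 ratio >= 1, `down` when <= -1, otherwise `unchanged`.
#'
#' @param counts a [CountTable]
#' @param condNum,condDen numerator / denominator condition names; defaults
#'   are the second and first condition of the table
#' @param pseudocount reads added on the zero side (default 0.5)
#' @return data.frame: `gene_id`, `exprDen`, `exprNum`, `log2Ratio`, `class`
#' @export
deValues <- function(counts, condNum = NULL, condDen = NULL,
                     pseudocount = 0.5) {
    stopIfNot(is(counts, "CountTable"), "'counts' must be a CountTable")
    cn <- colnames(counts)
    stopIfNot(length(cn) >= 2, "need two conditions")
    if (is.null(condNum)) condNum <- cn[2]
    if (is.null(condDen)) condDen <- cn[1]
    stopIfNot(all(c(condNum, condDen) %in% cn), "unknown condition name")
    cts <- counts(counts)
    lt <- libraryTotals(counts)
    num <- cts[, condNum]
    den <- cts[, condDen]
    oneZero <- xor(num == 0, den == 0)
    numAdj <- ifelse(oneZero, num + pseudocount, num)
    denAdj <- ifelse(oneZero, den + pseudocount, den)
    silent <- num == 0 & den == 0
    l2 <- log2((numAdj / lt[condNum]) / (denAdj / lt[condDen]))
    l2[silent] <- NA_real_
    cls <- ifelse(silent, "silent",
           ifelse(l2 >= 1, "up", ifelse(l2 <= -1, "down", "unchanged")))
    data.frame(gene_id = rownames(cts),
               exprDen = den / lt[condDen], exprNum = num / lt[condNum],
               log2Ratio = l2, class = cls,
               stringsAsFactors = FALSE, row.names = NULL)
}

#' Expression landscape summary
#'
#' Expressed-gene counts and fractions per condition (expressed = at least
#' one mapped read), the silent count, and up/down counts at the two-fold
#' rule.
#'
#' @param counts a [CountTable]
#' @param de optional precomputed [deValues()] result
#' @return list of summary counts and fractions
#' @export
expressionSummary <- function(counts, de = deValues(counts)) {
    cts <- counts(counts)
    n <- nrow(cts)
    expressed <- colSums(cts >= 1)
    list(nGenes = n,
         expressedPerCondition = expressed,
         expressedFractionPerCondition = expressed / n,
         expressedAny = sum(rowSums(cts) >= 1),
         silent = sum(de$class == "silent"),
         up = sum(de$class == "up"),
         down = sum(de$class == "down"),
         unchanged = sum(de$class == "unchanged"))
}

#' Per-category up/down/unchanged proportions
#'
#' Rolls differential-expression classes up into functional categories
#' (e.g. KEGG-style groups). Fractions are over the non-silent members of
#' each category and sum to 1; a gene in several categories counts in each;
#' categories without non-silent members are dropped.
#'
#' @param de [deValues()] result
#' @param categoryMap data.frame `gene_id`, `category` (one row per
#'   membership)
#' @return data.frame: `category`, `n`, `fracUp`, `fracDown`, `fracUnchanged`
#' @export
categoryRollup <- function(de, categoryMap) {
    stopIfNot(all(c("gene_id", "category") %in% names(categoryMap)),
              "categoryMap needs gene_id and category columns")
    miss <- setdiff(categoryMap$gene_id, de$gene_id)
    stopIfNot(!length(miss),
              paste("categorized gene(s) without DE record:",
                    paste(head(miss, 5), collapse = ", ")))
    cls <- de$class[match(categoryMap$gene_id, de$gene_id)]
    rows <- lapply(split(cls, categoryMap$category), function(x) {
        x <- x[x != "silent"]
        if (!length(x)) return(NULL)
        data.frame(n = length(x),
                   fracUp = mean(x == "up"), fracDown = mean(x == "down"),
                   fracUnchanged = mean(x == "unchanged"))
    })
    rows <- rows[!vapply(rows, is.null, logical(1))]
    out <- do.call(rbind, rows)
    out <- cbind(data.frame(category = names(rows),
                            stringsAsFactors = FALSE), out)
    rownames(out) <- NULL
    out
}

#' Plot-ready chromosomal expression table
#'
#' One row per gene that is both annotated and profiled, ordered by
#' chromosome and coordinate, with the log2 tag count per condition (silent
#' genes carry the sentinel value `NA`) -- the data behind a chromosomal
#' expression heat map.
#'
#' @param counts a [CountTable]
#' @param annotations gene `GRanges`
#' @return data.frame: `gene_id`, `chrom`, `start`, `end`,
#'   `log2Count_<condition>` columns
#' @export
chromosomeHeatmapTable <- function(counts, annotations) {
    cts <- counts(counts)
    keep <- annotations$gene_id %in% rownames(cts)
    ann <- annotations[keep]
    ord <- order(as.character(GenomicRanges::seqnames(ann)),
                 GenomicRanges::start(ann))
    ann <- ann[ord]
    out <- data.frame(gene_id = ann$gene_id,
                      chrom = as.character(GenomicRanges::seqnames(ann)),
                      start = GenomicRanges::start(ann),
                      end = GenomicRanges::end(ann),
                      stringsAsFactors = FALSE)
    for (cn in colnames(cts)) {
        v <- cts[out$gene_id, cn]
        out[[paste0("log2Count_", cn)]] <- ifelse(v >= 1, log2(v), NA_real_)
    }
    out
}

#' Call retained introns from exon/intron coverage
#'
#' An intron is called retained when its median read depth reaches at least
#' `retainedRatio` times the mean depth of the flanking exons and at least
#' `minDepth` reads. The isoform ratio (median intron depth / mean flanking
#' exon depth) is reported, with an `approximatelyEqual` flag when it lies
#' in \[0.5, 2\] -- two transcript forms of comparable abundance.
#'
#' @param geneId gene identifier for the report
#' @param exonDepths list of numeric per-base depth vectors, one per exon in
#'   gene order
#' @param intronDepths list of numeric per-base depth vectors, one per
#'   intron (between consecutive exons); an intronless gene yields no calls
#' @param minDepth minimum median intron depth (default 5 reads)
#' @param retainedRatio minimum intron/exon depth ratio (default 0.25)
#' @return data.frame with one row per retained intron: `gene_id`, `intron`
#'   (index), `type`, `isoformRatio`, `approximatelyEqual`
#' @export
callRetainedIntrons <- function(geneId, exonDepths, intronDepths,
                                minDepth = 5, retainedRatio = 0.25) {
    if (!length(intronDepths))
        return(data.frame(gene_id = character(), intron = integer(),
                          type = character(), isoformRatio = numeric(),
                          approximatelyEqual = logical()))
    stopIfNot(length(exonDepths) == length(intronDepths) + 1,
              "need one more exon than introns")
    rows <- list()
    for (i in seq_along(intronDepths)) {
        flank <- mean(c(mean(exonDepths[[i]]), mean(exonDepths[[i + 1]])))
        med <- median(intronDepths[[i]])
        ratio <- if (flank > 0) med / flank else Inf
        if (med >= minDepth && med >= retainedRatio * flank)
            rows[[length(rows) + 1L]] <- data.frame(
                gene_id = geneId, intron = i, type = "retained_intron",
                isoformRatio = ratio,
                approximatelyEqual = ratio >= 0.5 && ratio <= 2,
                stringsAsFactors = FALSE)
    }
    if (!length(rows))
        return(data.frame(gene_id = character(), intron = integer(),
                          type = character(), isoformRatio = numeric(),
                          approximatelyEqual = logical()))
    do.call(rbind, rows)
}
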